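#' Read a projection matrix from CSV
#'
#' Plain comma-separated decimal values, m rows by m columns, no header;
#' row 1 holds the fertilities. The matrix is validated on read.
#'
#' @param path CSV file path.
#' @return a validated `stage_matrix`.
#' @export
read_stage_matrix <- function(path) {
  if (!file.exists(path)) {
    plan_error("input_error", sprintf("matrix file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "numeric",
                    strip.white = TRUE),
    error = function(e) plan_error("input_error",
                                   sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))),
    warning = function(w) plan_error("input_error",
                                     sprintf("cannot parse %s: %s", path,
                                             conditionMessage(w))))
  validate_stage_matrix(as.matrix(df))
}

#' Write a projection matrix to CSV
#'
#' Inverse of [read_stage_matrix()]: no header, full precision (17
#' significant digits, so a write/read round trip reproduces entries to at
#' least 12 significant digits).
#'
#' @param M a `stage_matrix` (or raw matrix).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_matrix <- function(M, path) {
  M <- unclass(as.matrix(M))
  lines <- apply(M, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

# --- JSON serializers -------------------------------------------------------

eigen_summary_json <- function(es, path = NULL) {
  obj <- list(lambda1 = es$lambda1,
              ssp = es$ssp,
              m = es$m,
              lambda1_display = sprintf("%.3f", trunc_dec(es$lambda1, 3)),
              ssp_pct_display = as.integer(trunc_dec(es$ssp * 100)))
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

release_plan_json <- function(plan, path = NULL) {
  sched <- cbind(time = 0:plan$goal$T, unname(plan$schedule))
  obj <- list(lambda1 = plan$eigen$lambda1,
              ssp = plan$eigen$ssp,
              n_T = plan$n_T,
              n_0 = plan$n_0,
              total_release = plan$total_release,
              schedule = apply(sched, 1L, as.numeric, simplify = FALSE),
              n_0_display = as.integer(trunc_dec(plan$n_0)),
              n_T_display = as.integer(trunc_dec(plan$n_T)),
              total_release_display = as.integer(trunc_dec(plan$total_release)))
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- CSV writers (fixed formatting: 12 significant digits, LF) --------------

write_schedule_csv <- function(plan, path) {
  m <- plan$eigen$m
  header <- paste(c("time", paste0("stage_", seq_len(m))), collapse = ",")
  rows <- vapply(0:plan$goal$T, function(t)
    paste(c(t, fmt_num(plan$schedule[t + 1L, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

write_candidates_csv <- function(pool, path) {
  df <- as.data.frame(pool)
  header <- paste(colnames(df), collapse = ",")
  rows <- apply(df, 1L, function(r) paste(fmt_num(as.numeric(r)),
                                          collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

write_comparison_csv <- function(cmp, path) {
  m <- ncol(cmp$stable)
  T <- nrow(cmp$stable) - 1L
  header <- "time,stage,stable_abundance,transient_abundance"
  rows <- character(0)
  for (t in 0:T) {
    for (s in seq_len(m)) {
      rows <- c(rows, paste(c(t, s,
                              fmt_num(cmp$stable[t + 1L, s]),
                              fmt_num(cmp$transient[t + 1L, s])),
                            collapse = ","))
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
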