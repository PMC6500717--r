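#' Sample a matrix with the same life history and similar vital rates
#'
#' Draws one alternative projection matrix with exactly the user matrix's
#' zero/nonzero pattern ("identical life history structure") and every
#' nonzero vital rate perturbed within +/- 0.5 of the user's value:
#' fertilities uniform on `[max(0, f - 0.5), f + 0.5]`, transition
#' probabilities uniform on `[max(0, p - 0.5), min(1, p + 0.5)]`. Draws
#' violating the per-column survival budget or primitivity are rejected
#' and resampled, up to `max_tries` attempts.
#'
#' Uses the current R random number stream; seed with `set.seed()` or let
#' [build_pool()] manage seeding.
#'
#' @param user a validated `stage_matrix`.
#' @param freeze optional logical m x m mask; `TRUE` entries keep the
#'   user's value (e.g. fertilities fixed by biology). Default: nothing
#'   frozen.
#' @param max_tries rejection cap before giving up (default 1000).
#' @return a valid `stage_matrix`.
#' @export
sample_similar_matrix <- function(user, freeze = NULL, max_tries = 1000L) {
  if (!inherits(user, "stage_matrix")) user <- validate_stage_matrix(user)
  m <- n_stages(user)
  U <- unclass(user)
  nz <- U > 0
  if (!is.null(freeze)) {
    stopifnot(is.logical(freeze), all(dim(freeze) == c(m, m)))
  }
  lo <- hi <- U
  lo[nz] <- pmax(0, U[nz] - 0.5)
  hi[nz] <- U[nz] + 0.5
  hi[-1L, ][nz[-1L, ]] <- pmin(1, hi[-1L, ][nz[-1L, ]])
  if (!is.null(freeze)) {
    lo[freeze] <- U[freeze]
    hi[freeze] <- U[freeze]
  }
  for (i in seq_len(max_tries)) {
    cand <- U
    cand[nz] <- lo[nz] + stats::runif(sum(nz)) * (hi[nz] - lo[nz])
    ok <- tryCatch({
      validate_stage_matrix(cand)
      TRUE
    }, reintroplan_error = function(e) FALSE)
    if (ok) return(validate_stage_matrix(cand))
  }
  plan_error("sampling_exhausted_error",
             sprintf("no valid similar matrix found in %d draws", max_tries))
}

#' Build and rank a pool of candidate matrix models
#'
#' Generates `pool_size` matrices similar to the user's (see
#' [sample_similar_matrix()]), computes each one's dominant eigenvalue and
#' the total release abundance it would require for the shared management
#' goal, and keeps the `x - 1` alternatives with the smallest totals,
#' sorted ascending -- so row 2 of the table is the most "efficient"
#' alternative model (fewest females to release). The user's own model is
#' always row 1. Ties on total release are broken by higher eigenvalue,
#' then by generation order (stable).
#'
#' @param user a `stage_matrix`.
#' @param goal a [management_goal()]; its `x` is the number of listed
#'   models (user's + `x - 1` alternates).
#' @param pool_size matrices to simulate (default 2000); must be
#'   >= `goal$x - 1`.
#' @param seed optional integer seed for reproducible pools.
#' @return an object of class `candidate_pool`: a data.frame with the
#'   matrix entries unraveled row-wise (`a11 ... amm`), `lambda1` and
#'   `total_release`; the user's model is the first row. The full
#'   simulated pool (lambda1 and total_release for every draw) is kept in
#'   attribute `"pool"`.
#' @examples
#' pool <- build_pool(ungulate_matrix(), management_goal(7, 100, x = 5),
#'                    pool_size = 200, seed = 1)
#' @export
build_pool <- function(user, goal, pool_size = 2000L, seed = NULL) {
  if (!inherits(user, "stage_matrix")) user <- validate_stage_matrix(user)
  stopifnot(inherits(goal, "management_goal"))
  n_alt <- goal$x - 1L
  if (pool_size < n_alt) {
    plan_error("insufficient_pool_error",
               sprintf("pool_size %d < requested alternates %d",
                       pool_size, n_alt))
  }
  if (!is.null(seed)) set.seed(seed)
  m <- n_stages(user)

  row_for <- function(M) {
    plan <- release_abundances(M, goal)
    c(as.vector(t(unclass(M))), plan$eigen$lambda1, plan$total_release)
  }

  rows <- matrix(NA_real_, nrow = pool_size + 1L, ncol = m^2 + 2L)
  rows[1L, ] <- row_for(user)
  for (i in seq_len(pool_size)) {
    rows[i + 1L, ] <- row_for(sample_similar_matrix(user))
  }
  colnames(rows) <- c(paste0("a", rep(1:m, each = m), rep(1:m, m)),
                      "lambda1", "total_release")
  df <- as.data.frame(rows)

  alt <- df[-1L, , drop = FALSE]
  ord <- order(alt$total_release, -alt$lambda1, seq_len(nrow(alt)))
  selected <- alt[ord[seq_len(n_alt)], , drop = FALSE]
  out <- rbind(df[1L, , drop = FALSE], selected)
  rownames(out) <- c("user", if (n_alt > 0L) paste0("alt_", seq_len(n_alt)))
  structure(out,
            pool = df[-1L, c("lambda1", "total_release")],
            goal = goal,
            class = c("candidate_pool", "data.frame"))
}

#' Reassemble a stage matrix from a candidate-table row
#'
#' @param row one row of a [build_pool()] table (or any vector whose first
#'   m^2 entries are the row-wise unraveled matrix).
#' @param m stage count.
#' @return a validated `stage_matrix`.
#' @export
candidate_matrix <- function(row, m) {
  entries <- as.numeric(row)[seq_len(m^2)]
  validate_stage_matrix(matrix(entries, nrow = m, byrow = TRUE))
}
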