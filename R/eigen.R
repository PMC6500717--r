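#' Dominant eigenvalue and stable stage proportions
#'
#' Computes the Perron root \eqn{\lambda_1} (the asymptotic per-time-unit
#' multiplicative growth rate: > 1 growth, < 1 decline, = 1 stationary) and
#' the stable stage proportions (SSP) -- the associated right eigenvector
#' normalized to sum to 1. For a primitive nonnegative matrix the dominant
#' eigenvalue is real, positive and strictly larger in modulus than every
#' other eigenvalue, and its eigenvector is strictly positive, so both
#' quantities are well defined.
#'
#' @param M a validated `stage_matrix` (a raw matrix is validated first).
#' @return an object of class `eigen_summary`: a list with `lambda1`
#'   (dominant eigenvalue), `ssp` (length-m stable stage proportions,
#'   positive, summing to 1) and `m`.
#' @examples
#' es <- eigen_summary(ungulate_matrix())
#' trunc_dec(es$lambda1, 3)      # 0.904
#' trunc_dec(es$ssp * 100)       # 43  6 50
#' @export
eigen_summary <- function(M) {
  if (!inherits(M, "stage_matrix")) M <- validate_stage_matrix(M)
  dec <- tryCatch(eigen(unclass(M)),
                  error = function(e) {
                    plan_error("convergence_error",
                               paste("eigendecomposition failed:",
                                     conditionMessage(e)))
                  })
  idx <- which.max(Mod(dec$values))
  lambda1 <- dec$values[idx]
  if (abs(Im(lambda1)) > 1e-8 * max(1, Mod(lambda1))) {
    plan_error("convergence_error",
               "dominant eigenvalue is not numerically real")
  }
  lambda1 <- Re(lambda1)
  v <- Re(dec$vectors[, idx])
  if (sum(v) < 0) v <- -v          # solvers may return the negated vector
  if (any(v <= 0)) {
    plan_error("convergence_error",
               "dominant eigenvector is not strictly positive")
  }
  structure(list(lambda1 = lambda1, ssp = v / sum(v), m = n_stages(M)),
            class = "eigen_summary")
}

#' @export
print.eigen_summary <- function(x, ...) {
  cat(sprintf("lambda1 = %s (displays as %.3f)\n",
              fmt_num(x$lambda1), trunc_dec(x$lambda1, 3)))
  pct <- trunc_dec(x$ssp * 100)
  cat("stable stage proportions (%):",
      paste(sprintf("stage %d: %d", seq_len(x$m), as.integer(pct)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic projection of a stage-abundance vector
#'
#' Iterates the one-step projection \eqn{n_{t+1} = M n_t} for `T` steps,
#' returning the whole trajectory.
#'
#' @param M a `stage_matrix`.
#' @param n0 length-m nonnegative vector of female abundances at time 0.
#' @param T number of time units to project (\eqn{\ge 0}).
#' @return a `(T+1) x m` numeric matrix; row `t+1` holds the abundances at
#'   time `t` (row 1 is `n0` unchanged). Rows are named `t0 ... tT`,
#'   columns `stage_1 ... stage_m`.
#' @examples
#' project(ungulate_matrix(), c(50, 0, 0), 1)   # t1 row: 0 7.05 0
#' @export
project <- function(M, n0, T) {
  if (!inherits(M, "stage_matrix")) M <- validate_stage_matrix(M)
  m <- n_stages(M)
  n0 <- as.numeric(n0)
  if (length(n0) != m) {
    plan_error("dimension_mismatch_error",
               sprintf("release vector has length %d, matrix has %d stages",
                       length(n0), m))
  }
  if (any(n0 < 0)) {
    plan_error("negative_entry_error", "abundances must be nonnegative")
  }
  T <- as.integer(T)
  if (is.na(T) || T < 0L) {
    plan_error("input_error", "projection horizon T must be >= 0")
  }
  out <- matrix(0, nrow = T + 1L, ncol = m,
                dimnames = list(paste0("t", 0:T),
                                paste0("stage_", seq_len(m))))
  out[1L, ] <- n0
  A <- unclass(M)
  for (t in seq_len(T)) out[t + 1L, ] <- A %*% out[t, ]
  out
}
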