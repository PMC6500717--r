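#' Validate a stage-structured projection matrix
#'
#' Checks that a raw square matrix is a usable female-only population
#' projection matrix: the top row holds fertilities (average female
#' offspring per female per time unit, any value \eqn{\ge 0}); every other
#' nonzero entry is a transition probability in \eqn{[0, 1]}; per stage
#' (column), the summed transition probabilities do not exceed 1 (an
#' individual survives into at most one stage); and the matrix is primitive,
#' so the dominant eigenvalue and the stable stage distribution are well
#' defined (Perron--Frobenius).
#'
#' Between 2 and 5 stages are supported, the range of iteroparous life
#' histories the planner targets. Sparsity is not forced into a strict
#' Lefkovitch pattern: any arrangement of stasis/growth probabilities is
#' accepted as long as the matrix is primitive.
#'
#' @param raw a numeric \eqn{m \times m} matrix (or something coercible),
#'   \eqn{2 \le m \le 5}; row 1 = fertilities, rows 2..m = transitions.
#' @param tol tolerance for the per-column survival budget and the
#'   transition upper bound (entry round-off), default `1e-9`.
#' @return the matrix with class `stage_matrix` and attribute `m`.
#' @seealso [is_primitive()], [eigen_summary()], [project()]
#' @examples
#' validate_stage_matrix(ungulate_matrix())
#' @export
validate_stage_matrix <- function(raw, tol = 1e-9) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || anyNA(raw) || any(!is.finite(raw))) {
    plan_error("negative_entry_error",
               "matrix entries must be finite numbers")
  }
  if (nrow(raw) != ncol(raw)) {
    plan_error("non_square_error",
               sprintf("matrix must be square, got %d x %d",
                       nrow(raw), ncol(raw)))
  }
  m <- nrow(raw)
  if (m < 2L || m > 5L) {
    plan_error("stage_count_error",
               sprintf("stage count m must be between 2 and 5, got %d", m))
  }
  if (any(raw < 0)) {
    bad <- which(raw < 0, arr.ind = TRUE)[1L, ]
    plan_error("negative_entry_error",
               sprintf("entry (%d,%d) is negative: %g",
                       bad[1L], bad[2L], raw[bad[1L], bad[2L]]))
  }
  trans <- raw[-1L, , drop = FALSE]
  if (any(trans > 1 + tol)) {
    bad <- which(trans > 1 + tol, arr.ind = TRUE)[1L, ]
    plan_error("transition_bound_error",
               sprintf("transition entry (%d,%d) exceeds 1: %g",
                       bad[1L] + 1L, bad[2L], trans[bad[1L], bad[2L]]))
  }
  survival <- colSums(trans)
  if (any(survival > 1 + tol)) {
    i <- which.max(survival)
    plan_error("survival_budget_error",
               sprintf(paste0("stage-%d total survival (stasis + growth) ",
                              "is %g > 1"), i, survival[i]))
  }
  if (all(raw[1L, ] == 0)) {
    plan_error("no_breeding_stage_error",
               "at least one fertility (top-row entry) must be positive")
  }
  if (!is_primitive(raw)) {
    plan_error("imprimitive_error",
               paste("matrix is not primitive: no unique dominant",
                     "eigenvalue / stable stage distribution exists"))
  }
  structure(unname(raw), class = "stage_matrix", m = m)
}

#' Test primitivity of a nonnegative matrix
#'
#' A nonnegative square matrix is primitive iff some power of it is
#' entrywise positive; by Wielandt's bound the power \eqn{m^2 - 2m + 2}
#' suffices, so the test raises the zero/nonzero pattern to exactly that
#' power (at most 17 for \eqn{m = 5}) and checks positivity. Entries are
#' classified as zero at exactly 0 -- users enter literal zeros for
#' structurally impossible transitions.
#'
#' @param M nonnegative square numeric matrix (a `stage_matrix` or raw).
#' @return `TRUE` iff `M` is primitive.
#' @examples
#' is_primitive(matrix(c(0, 1, 1, 0), 2, 2))  # FALSE: period-2 cycle
#' is_primitive(matrix(1, 2, 2))              # TRUE: already positive
#' @export
is_primitive <- function(M) {
  M <- as.matrix(M)
  m <- nrow(M)
  pat <- (M > 0) * 1
  acc <- pat
  wielandt <- m^2 - 2L * m + 2L
  k <- 1L
  while (k < wielandt) {
    acc <- ((acc %*% pat) > 0) * 1
    k <- k + 1L
    if (all(acc > 0)) return(TRUE)  # positive pattern persists thereafter
  }
  all(acc > 0)
}

#' The worked-example ungulate projection matrix
#'
#' A published 3-stage female-only matrix for an ungulate species, used
#' throughout the documentation and tests: juveniles (stage 1), subadults
#' (stage 2) and adults (stage 3), with fertilities 0.581 and 0.701 for
#' stages 2 and 3. Its dominant eigenvalue is about 0.905, i.e. the
#' population declines by roughly 10\% per time unit.
#'
#' @param validate return a validated `stage_matrix` (default) or the raw
#'   numeric matrix.
#' @return a 3x3 `stage_matrix`.
#' @export
ungulate_matrix <- function(validate = TRUE) {
  A <- matrix(c(0,     0.581, 0.701,
                0.141, 0,     0,
                0,     0.775, 0.801),
              nrow = 3, byrow = TRUE)
  if (validate) validate_stage_matrix(A) else A
}

#' @export
print.stage_matrix <- function(x, ...) {
  m <- attr(x, "m")
  cat(sprintf("stage_matrix: %d stages (row 1 = fertilities)\n", m))
  mat <- unclass(x)
  attr(mat, "m") <- NULL
  dimnames(mat) <- list(paste0("stage_", seq_len(m)),
                        paste0("stage_", seq_len(m)))
  print(mat, ...)
  invisible(x)
}

n_stages <- function(M) {
  m <- attr(M, "m")
  if (is.null(m)) nrow(M) else m
}
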