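#' Specification for a random life-history fixture
#'
#' Parameters for [random_life_history()], the seeded generator behind the
#' package's property tests: every generated matrix is a valid, primitive
#' Lefkovitch life history, reproducible per seed. Default fertilities are
#' uniform on [0, 2] (ungulate-like magnitudes) and each stage's survival
#' is a uniform draw within `survival_budget`, split between stasis
#' (diagonal) and growth (sub-diagonal).
#'
#' @param m stage count, 2-5.
#' @param seed integer seed.
#' @param fertility_range length-2 nonnegative interval for fertilities.
#' @param survival_budget upper bound on per-stage survival, in (0, 1].
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(m, seed,
                         fertility_range = c(0, 2),
                         survival_budget = 1) {
  if (length(m) != 1L || m < 2 || m > 5 || m != trunc(m)) {
    plan_error("stage_count_error", "m must be an integer in 2..5")
  }
  stopifnot(length(fertility_range) == 2L, all(fertility_range >= 0),
            diff(fertility_range) >= 0,
            survival_budget > 0, survival_budget <= 1)
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 fertility_range = as.numeric(fertility_range),
                 survival_budget = as.numeric(survival_budget)),
            class = "fixture_spec")
}

#' Generate one random valid life-history matrix
#'
#' Draws a Lefkovitch-pattern matrix -- fertilities on the top row (at
#' least one positive), growth on the sub-diagonal, stasis on the
#' diagonal of stages 2..m -- with per-stage survival within the budget,
#' rejection-sampled until the matrix passes full validation (including
#' primitivity). Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @param max_tries rejection cap (default 1000).
#' @return a valid `stage_matrix`.
#' @examples
#' random_life_history(fixture_spec(3, seed = 42))
#' @export
random_life_history <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  m <- spec$m
  fr <- spec$fertility_range
  for (i in seq_len(max_tries)) {
    A <- matrix(0, m, m)
    A[1L, ] <- stats::runif(m, fr[1L], fr[2L])
    # stage-1 survival goes entirely to growth (its diagonal cell belongs
    # to the fertility row); later stages split survival stasis/growth
    surv <- stats::runif(m, 0, spec$survival_budget)
    A[2L, 1L] <- surv[1L]
    if (m > 2L) {
      split <- stats::runif(m - 2L)
      for (j in 2:(m - 1L)) {
        A[j, j] <- surv[j] * split[j - 1L]
        A[j + 1L, j] <- surv[j] * (1 - split[j - 1L])
      }
    }
    A[m, m] <- if (m > 1L) surv[m] else 0
    ok <- tryCatch({
      validate_stage_matrix(A)
      TRUE
    }, reintroplan_error = function(e) FALSE)
    if (ok) return(validate_stage_matrix(A))
  }
  plan_error("sampling_exhausted_error",
             sprintf("no valid life history found in %d draws", max_tries))
}
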