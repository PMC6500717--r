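#' Define a management goal
#'
#' A reintroduction goal: reach `B` breeding females after `T` discrete
#' time units, and compare `x` candidate matrix models. `T` carries no
#' calendar semantics -- "7 years" is 7 units if the matrix is annual.
#'
#' @param T positive integer timeline, in the matrix's time units.
#' @param B positive desired abundance of breeding females at time `T`
#'   (females in stages with positive fertility).
#' @param x positive integer number of candidate models to list
#'   (default 1: the user's model only).
#' @return an object of class `management_goal`.
#' @examples
#' management_goal(T = 7, B = 100)
#' @export
management_goal <- function(T, B, x = 1L) {
  if (length(T) != 1L || is.na(T) || T < 1 || T != trunc(T)) {
    plan_error("goal_error", "timeline T must be a positive integer")
  }
  if (length(B) != 1L || is.na(B) || B <= 0) {
    plan_error("goal_error", "desired breeding females B must be > 0")
  }
  if (length(x) != 1L || is.na(x) || x < 1 || x != trunc(x)) {
    plan_error("goal_error", "candidate count x must be a positive integer")
  }
  structure(list(T = as.integer(T), B = as.numeric(B), x = as.integer(x)),
            class = "management_goal")
}

#' Stages whose members count as breeding females
#'
#' A breeding stage is one with strictly positive fertility (top-row
#' entry). In the ungulate example stages 2 and 3 breed and stage 1 does
#' not, so the goal's `B` females are partitioned between stages 2 and 3.
#'
#' @param M a `stage_matrix`.
#' @return integer vector of 1-based breeding stage indices.
#' @examples
#' breeding_stage_indices(ungulate_matrix())  # 2 3
#' @export
breeding_stage_indices <- function(M) {
  if (!inherits(M, "stage_matrix")) M <- validate_stage_matrix(M)
  idx <- which(unclass(M)[1L, ] > 0)
  if (length(idx) == 0L) {
    plan_error("no_breeding_stage_error", "no stage has positive fertility")
  }
  idx
}

#' Stable-stage target vector for a breeding-female goal
#'
#' Scales the stable stage proportions so that the abundances summed over
#' the breeding stages equal `B` exactly:
#' \eqn{n_T = B \, w / \sum_{i \in breeding} w_i}, where `w` is the SSP.
#' The resulting vector is the population the plan aims to hold at time
#' `T`, partitioned across all stages in stable proportion.
#'
#' @param M a `stage_matrix`.
#' @param B desired breeding-female abundance (> 0).
#' @return length-m numeric target vector (continuous; truncate only for
#'   display).
#' @examples
#' trunc_dec(ssd_target_vector(ungulate_matrix(), 100))  # 75 11 88
#' @export
ssd_target_vector <- function(M, B) {
  if (!inherits(M, "stage_matrix")) M <- validate_stage_matrix(M)
  if (length(B) != 1L || is.na(B) || B <= 0) {
    plan_error("goal_error", "B must be > 0")
  }
  es <- eigen_summary(M)
  breeding <- breeding_stage_indices(M)
  as.numeric(es$ssp * B / sum(es$ssp[breeding]))
}

#' Stable-stage-aligned release plan
#'
#' The core planning step: build the stable-stage target vector
#' \eqn{n_T} for the goal's `B` breeding females, then back-project it
#' through the dominant eigenvalue, \eqn{n_0 = \lambda_1^{-T} n_T}.
#' Because both \eqn{n_0} and \eqn{n_T} lie on the stable-stage ray, the
#' released population keeps fixed stage proportions and grows (or
#' declines) by exactly \eqn{\lambda_1} per step, so the schedule row at
#' time `t` is simply \eqn{n_0 \lambda_1^t} -- equal to repeated matrix
#' multiplication, but numerically cleaner.
#'
#' Abundances are continuous reals; whole-animal display values are
#' obtained by truncation (see [trunc_dec()]) and never fed back into
#' computation.
#'
#' @param M a `stage_matrix`.
#' @param goal a [management_goal()].
#' @return an object of class `release_plan`: list with `matrix`, `goal`,
#'   `eigen` (the [eigen_summary()]), `n_T`, `n_0`, `schedule`
#'   (`(T+1) x m` abundance table) and `total_release` (`sum(n_0)`).
#' @examples
#' plan <- release_abundances(ungulate_matrix(), management_goal(7, 100))
#' trunc_dec(plan$n_T)   # 75 11 88
#' @export
release_abundances <- function(M, goal) {
  if (!inherits(M, "stage_matrix")) M <- validate_stage_matrix(M)
  stopifnot(inherits(goal, "management_goal"))
  es <- eigen_summary(M)
  n_T <- ssd_target_vector(M, goal$B)
  n_0 <- n_T / es$lambda1^goal$T
  schedule <- outer(es$lambda1^(0:goal$T), n_0)
  dimnames(schedule) <- list(paste0("t", 0:goal$T),
                             paste0("stage_", seq_len(es$m)))
  structure(list(matrix = M, goal = goal, eigen = es,
                 n_T = n_T, n_0 = n_0,
                 schedule = schedule, total_release = sum(n_0)),
            class = "release_plan")
}

#' Rescale a release plan to a fixed total release
#'
#' Any scaling up or down of a stable-stage release leaves the trajectory
#' stable: proportions are unchanged and every schedule row is multiplied
#' by the same factor. The goal's `B` is recomputed to the breeding-female
#' abundance the rescaled plan actually reaches at time `T` (no longer the
#' user's original `B`).
#'
#' @param plan a `release_plan`.
#' @param new_total desired total number of released females (> 0).
#' @return a rescaled `release_plan`.
#' @export
scale_plan <- function(plan, new_total) {
  stopifnot(inherits(plan, "release_plan"))
  if (length(new_total) != 1L || is.na(new_total) || new_total <= 0) {
    plan_error("non_positive_total_error", "new_total must be > 0")
  }
  f <- new_total / plan$total_release
  breeding <- breeding_stage_indices(plan$matrix)
  new_goal <- management_goal(plan$goal$T,
                              sum(plan$n_T[breeding]) * f,
                              plan$goal$x)
  structure(list(matrix = plan$matrix, goal = new_goal, eigen = plan$eigen,
                 n_T = plan$n_T * f, n_0 = plan$n_0 * f,
                 schedule = plan$schedule * f,
                 total_release = new_total),
            class = "release_plan")
}

#' @export
print.release_plan <- function(x, ...) {
  es <- x$eigen
  cat(sprintf("Release plan: %s breeding females in %d time units\n",
              fmt_num(x$goal$B), x$goal$T))
  cat(sprintf("  lambda1 = %s (displays as %.3f)\n",
              fmt_num(es$lambda1), trunc_dec(es$lambda1, 3)))
  cat("  release n_0 (whole females, truncated):",
      paste(as.integer(trunc_dec(x$n_0)), collapse = " "),
      sprintf(" | total %s\n", fmt_num(x$total_release)))
  cat("  target  n_T (whole females, truncated):",
      paste(as.integer(trunc_dec(x$n_T)), collapse = " "), "\n")
  invisible(x)
}
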