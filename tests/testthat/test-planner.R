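test_that("management goals are validated", {
  g <- management_goal(7, 100, 3)
  expect_identical(g$T, 7L)
  expect_error(management_goal(0, 100), class = "goal_error")
  expect_error(management_goal(7, 0), class = "goal_error")
  expect_error(management_goal(7, 100, 0), class = "goal_error")
  expect_error(management_goal(2.5, 100), class = "goal_error")
})

test_that("breeding stages are those with positive fertility", {
  expect_equal(breeding_stage_indices(ungulate_matrix()), c(2L, 3L))
  all_breed <- validate_stage_matrix(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  expect_equal(breeding_stage_indices(all_breed), c(1L, 2L))
  late_breed <- validate_stage_matrix(matrix(c(0, 0.9, 0.8, 0.1), 2, 2,
                                             byrow = TRUE))
  expect_equal(breeding_stage_indices(late_breed), 2L)
})

test_that("stable-stage target for 100 breeding females matches the example", {
  n_T <- ssd_target_vector(ungulate_matrix(), 100)
  expect_equal(trunc_dec(n_T[1]), 75)
  expect_equal(trunc_dec(n_T[2]), 11)
  # breeding stages sum to B exactly
  expect_equal(n_T[2] + n_T[3], 100, tolerance = 1e-12)
  # proportional to the SSP
  es <- eigen_summary(ungulate_matrix())
  expect_equal(n_T / sum(n_T), es$ssp, tolerance = 1e-12)
})

test_that("when every stage breeds, the B = 1 target is the SSP itself", {
  M <- validate_stage_matrix(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  expect_equal(ssd_target_vector(M, 1), eigen_summary(M)$ssp,
               tolerance = 1e-12)
})

test_that("a stationary population (lambda1 = 1) releases n_T directly", {
  M <- validate_stage_matrix(matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2,
                                    byrow = TRUE))
  expect_equal(eigen_summary(M)$lambda1, 1, tolerance = 1e-12)
  plan <- release_abundances(M, management_goal(5, 10))
  expect_equal(plan$n_0, plan$n_T, tolerance = 1e-12)
})

test_that("back-projected releases reproduce the target after T steps", {
  plan <- release_abundances(ungulate_matrix(), management_goal(7, 100))
  traj <- project(ungulate_matrix(), plan$n_0, 7)
  expect_equal(unname(traj[8, ]), plan$n_T, tolerance = 1e-8)
  expect_equal(plan$total_release, sum(plan$n_0))
  # schedule endpoints
  expect_equal(unname(plan$schedule[1, ]), plan$n_0)
  expect_equal(unname(plan$schedule[8, ]), plan$n_T, tolerance = 1e-10)
})

test_that("release vector agrees with a direct linear-solve oracle", {
  # independent route: n_0 is the exact preimage of n_T under M^T
  for (seed in 1:10) {
    M <- random_life_history(fixture_spec(2, seed = 6000 + seed))
    goal <- management_goal(3, 10)
    plan <- release_abundances(M, goal)
    n0_oracle <- as.numeric(solve(mat_pow(M, 3), plan$n_T))
    expect_equal(plan$n_0, n0_oracle, tolerance = 1e-8)
  }
})

test_that("round trip holds across random life histories of every size", {
  for (M in random_valid_matrices(per_m = 15, seed_base = 7000)) {
    goal <- management_goal(6, 50)
    plan <- release_abundances(M, goal)
    final <- project(M, plan$n_0, 6)[7, ]
    expect_equal(unname(final), plan$n_T, tolerance = 1e-8)
  }
})

test_that("release scales linearly in the goal (homogeneity)", {
  M <- ungulate_matrix()
  p1 <- release_abundances(M, management_goal(7, 100))
  p2 <- release_abundances(M, management_goal(7, 200))
  expect_equal(p2$n_0 / p1$n_0, rep(2, 3), tolerance = 1e-12)
})

test_that("all schedule rows share the same stage proportions", {
  plan <- release_abundances(modified_ungulate(), management_goal(7, 100))
  props <- plan$schedule / rowSums(plan$schedule)
  expect_lt(max(abs(sweep(props, 2, plan$eigen$ssp))), 1e-9)
})

test_that("rescaling a plan preserves proportions and per-step totals", {
  plan <- release_abundances(ungulate_matrix(), management_goal(7, 100))
  # identity rescale
  same <- scale_plan(plan, plan$total_release)
  expect_equal(same$n_0, plan$n_0, tolerance = 1e-12)
  scaled <- scale_plan(plan, 50)
  expect_equal(sum(scaled$n_0), 50, tolerance = 1e-12)
  expect_equal(trunc_dec(100 * scaled$n_0 / sum(scaled$n_0)), c(43, 6, 50))
  lambda1 <- plan$eigen$lambda1
  expect_equal(unname(rowSums(scaled$schedule)), 50 * lambda1^(0:7),
               tolerance = 1e-10)
  # goal B is recomputed to what the rescaled plan actually achieves
  expect_equal(scaled$goal$B, sum(scaled$n_T[2:3]), tolerance = 1e-12)
  expect_error(scale_plan(plan, 0), class = "non_positive_total_error")
})
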