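# Shared fixtures for the suite.

ungulate_raw <- function() {
  matrix(c(0,     0.581, 0.701,
           0.141, 0,     0,
           0,     0.775, 0.801),
         nrow = 3, byrow = TRUE)
}

modified_ungulate <- function() {
  A <- ungulate_raw()
  A[3, 3] <- 0.95
  validate_stage_matrix(A)
}

# Independent brute-force primitivity oracle: check whether any power of
# the zero pattern up to `kmax` is entrywise positive (a matrix is
# primitive iff its pattern becomes positive at some finite power; for
# m <= 5 the Wielandt exponent 17 is an upper bound, so kmax = 25 is safe).
brute_force_primitive <- function(M, kmax = 25) {
  P <- (as.matrix(M) > 0) * 1
  acc <- P
  for (k in seq_len(kmax)) {
    if (all(acc > 0)) return(TRUE)
    acc <- ((acc %*% P) > 0) * 1
  }
  all(acc > 0)
}

# Independent eigenvalue oracle: plain power iteration, run to
# convergence (slow-damping matrices need far more than a few hundred
# steps for 1e-8 agreement).
power_iteration_lambda <- function(M, tol = 1e-13, max_iter = 200000) {
  M <- unclass(as.matrix(M))
  v <- rep(1, nrow(M))
  lambda <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- as.numeric(M %*% v)
    new_lambda <- sum(w) / sum(v)
    v <- w / sum(w)
    if (i > 1 && abs(new_lambda - lambda) <= tol * abs(new_lambda)) {
      return(new_lambda)
    }
    lambda <- new_lambda
  }
  lambda
}

# |subdominant| / dominant eigenvalue modulus ratio (damping).
damping_ratio <- function(M) {
  mods <- sort(Mod(eigen(unclass(as.matrix(M)),
                         only.values = TRUE)$values),
               decreasing = TRUE)
  mods[2] / mods[1]
}

# Matrix power by repeated multiplication (oracle helper).
mat_pow <- function(M, k) {
  M <- unclass(as.matrix(M))
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

random_valid_matrices <- function(per_m = 100, ms = 2:5, seed_base = 1000) {
  out <- list()
  for (m in ms) {
    for (i in seq_len(per_m)) {
      out[[length(out) + 1L]] <-
        random_life_history(fixture_spec(m, seed = seed_base + 100L * m + i))
    }
  }
  out
}
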