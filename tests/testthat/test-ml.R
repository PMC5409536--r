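# Maximum-likelihood inference: likelihood values, solver correctness
# against brute-force oracles, Hessian, and ensemble error metrics.

test_that("log-likelihood matches direct substitution", {
  # one event, tau_b = tau_u = 1, k = r = c = 1:
  # -Tu * kc + log(k c r e^{-r tau_b}) = -1 + (0 - 1) = -2
  tr <- binding_trace(tau_b = 1, tau_u = 1)
  mix <- single_species_mixture()
  expect_equal(log_likelihood(tr, 1, mix), -2)

  # with the second species absent, D reduces to the cognate term
  mix2 <- std_mixture(r_c = 0.2, c_c = 0.7)
  tr2 <- sample_trace(mix2, 20, seed = 1)
  ll <- log_likelihood(tr2, c(0.7, 0), mix2)
  direct <- -tr2$Tu * 0.7 + sum(log(0.7 * 0.2) - 0.2 * tr2$tau_b)
  expect_equal(ll, direct, tolerance = 1e-12)

  expect_equal(log_likelihood(tr2, c(0, 0), mix2), -Inf)
  expect_error(log_likelihood(tr2, c(-1, 1), mix2), "non-negative")
})

test_that("log-likelihood is finite under extreme bound durations", {
  # tau * r_nc > 700: naive evaluation of D underflows; log-space must not
  mix <- std_mixture(r_c = 0.001, c_c = 0.5)
  tr <- binding_trace(tau_b = c(800, 0.5), tau_u = c(1, 1))
  expect_true(is.finite(log_likelihood(tr, c(0.5, 0.5), mix)))
  H <- ml_hessian(tr, c(0.5, 0.5), mix)
  expect_true(all(is.finite(H)))
})

test_that("interior ML optimum satisfies the total-on-rate identity and zero gradient", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  for (seed in 1:5) {
    tr <- sample_trace(mix, 2000, seed = seed)
    fit <- solve_ml(tr, mix)
    expect_false(fit$boundary)
    expect_true(fit$converged)
    # identity k_c c_c* + k_nc c_nc* = n / Tu holds exactly
    expect_equal(sum(mix$k * fit$c_hat), tr$n / tr$Tu, tolerance = 1e-12)
    # central finite-difference gradient vanishes at the optimum
    h <- 1e-6
    for (j in 1:2) {
      dc <- c(0, 0); dc[j] <- h
      g <- (log_likelihood(tr, fit$c_hat + dc, mix) -
            log_likelihood(tr, fit$c_hat - dc, mix)) / (2 * h)
      # scale: curvature ~ n, so gradient ~ n * |c - c*|
      expect_lt(abs(g) / tr$n, 1e-4)
    }
  }
})

test_that("solver agrees with exhaustive grid search along the constraint line", {
  # brute-force oracle: evaluate the log-likelihood on 10^4 points of the
  # constraint line and compare the argmax with the root-finder
  mix <- std_mixture(r_c = 0.2, c_c = 0.4)
  set.seed(42)
  seeds <- sample.int(1e6, 20)
  f_grid <- seq(0, 1, length.out = 1e4 + 1)
  for (s in seeds) {
    tr <- sample_trace(mix, 200, seed = s)
    S <- tr$n / tr$Tu
    ll <- vapply(f_grid, function(f)
      log_likelihood(tr, c(f * S / mix$k[1L], (1 - f) * S / mix$k[2L]), mix),
      numeric(1L))
    f_best <- f_grid[which.max(ll)]
    fit <- solve_ml(tr, mix)
    expect_lt(abs(fit$f - f_best), 1.5e-4)  # grid resolution 1e-4
  }
})

test_that("analytic Hessian matches central finite differences and is negative", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  tr <- sample_trace(mix, 500, seed = 17)
  cc <- c(0.45, 0.52)
  H <- ml_hessian(tr, cc, mix)
  expect_true(all(H <= 0))              # every entry a sum of negatives
  expect_equal(H[1L, 2L], H[2L, 1L])
  h <- 1e-4
  num <- matrix(NA_real_, 2L, 2L)
  for (a in 1:2) for (b in 1:2) {
    ea <- c(0, 0); ea[a] <- h
    eb <- c(0, 0); eb[b] <- h
    num[a, b] <- (log_likelihood(tr, cc + ea + eb, mix) -
                  log_likelihood(tr, cc + ea - eb, mix) -
                  log_likelihood(tr, cc - ea + eb, mix) +
                  log_likelihood(tr, cc - ea - eb, mix)) / (4 * h^2)
  }
  expect_equal(unname(H), num, tolerance = 1e-5)
  expect_error(ml_hessian(tr, c(0.5, 0), mix), "interior")
})

test_that("a trace with no non-cognate ligand yields a near-zero non-cognate estimate", {
  gen <- std_mixture(r_c = 0.05, c_c = 1)  # c_nc = 0
  model <- std_mixture(r_c = 0.05, c_c = 0.5)  # rates only; c ignored
  nc_est <- vapply(1:10, function(s) {
    tr <- sample_trace(gen, 3000, seed = 100 + s)
    solve_ml(tr, model)$c_hat[2L]
  }, numeric(1L))
  expect_true(all(nc_est < 0.02))
})

test_that("ML estimates are unbiased, Cramer-Rao consistent, and the two E definitions agree", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  n <- 1e4; nrep <- 500
  reps <- fit_replicates(mix, n, nrep, master_seed = 31)
  em <- error_metrics(reps$fits, mix)
  # unbiased to leading order: |mean - truth| < 3 ensemble standard errors
  for (j in 1:2)
    expect_lt(abs(em$mean_c_hat[j] - mix$c[j]), 3 * em$se_c_hat[j])
  # Cramer-Rao: ensemble variance >= mean inverse-Hessian variance - 3 se
  for (j in 1:2) {
    v_ens <- stats::var(reps$chat_ml[, j])
    se_v <- v_ens * sqrt(2 / (nrep - 1))
    expect_gt(v_ens, mean(reps$var_ml[, j]) - 3 * se_v)
    # posterior-variance and ensemble-variance E agree within 3 se
    se_E <- n * se_v / mix$c[j]^2
    expect_lt(abs(em$E_hessian[j] - em$E_ensemble[j]), 3 * se_E)
  }
  expect_equal(em$n_replicates, nrep)
})

test_that("E is asymmetric under concentration exchange at fixed r_c < r_nc", {
  # the cognate ligand can generate short events, but long non-cognate
  # events are exponentially unlikely, so swapping concentrations does not
  # swap the errors
  r_c <- 0.1; nrep <- 120; n <- 2000
  em_hi <- error_metrics(
    fit_replicates(std_mixture(r_c, c_c = 0.9), n, nrep, 53)$fits,
    std_mixture(r_c, c_c = 0.9))
  em_lo <- error_metrics(
    fit_replicates(std_mixture(r_c, c_c = 0.1), n, nrep, 53)$fits,
    std_mixture(r_c, c_c = 0.1))
  # E of the slow (cognate) ligand when it is rare differs from E of the
  # fast ligand when it is rare
  rel_gap <- abs(em_hi$E_hessian[2L] - em_lo$E_hessian[1L]) /
    em_lo$E_hessian[1L]
  expect_gt(rel_gap, 0.25)
})

test_that("nearly degenerate off-rates drive the estimate correlation to -1", {
  mix <- std_mixture(r_c = 0.95, c_c = 0.5)
  reps <- fit_replicates(mix, 5000, 60, master_seed = 61)
  em <- error_metrics(reps$fits, mix)
  expect_lt(em$rho_hessian, -0.97)
  expect_gt(em$E_hessian[1L], 50)
})

test_that("error_metrics handles edge cases", {
  mix <- std_mixture()
  tr <- sample_trace(mix, 1000, seed = 1)
  fit <- solve_ml(tr, mix, truth = mix)
  expect_warning(em <- error_metrics(list(fit), mix), "fewer than 2")
  expect_true(is.na(em$rho_ensemble))
  expect_false(anyNA(em$E_hessian))
})
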