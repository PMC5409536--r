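# Long-event threshold estimator: exact identities, analytic bias/variance
# against replicate simulations, and the optimal cutoff.

test_that("cutoff limits collapse to the expected closed forms", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  tr <- sample_trace(mix, 1000, seed = 2)
  # Tc = 0: every event is long, all mass attributed to the cognate ligand
  a0 <- approx_estimate(tr, 0, mix)
  expect_equal(a0$n_l, tr$n)
  expect_equal(unname(a0$c_hat[1L]), tr$n / (mix$k[1L] * tr$Tu))
  expect_equal(unname(a0$c_hat[2L]), 0)
  # Tc beyond the longest event: no long events at all
  a1 <- approx_estimate(tr, max(tr$tau_b) + 1, mix)
  expect_equal(a1$n_l, 0L)
  expect_equal(unname(a1$c_hat[1L]), 0)
  expect_equal(unname(a1$c_hat[2L]), tr$n / (mix$k[2L] * tr$Tu))
  # a tie counts as long
  trt <- binding_trace(tau_b = c(2, 1), tau_u = c(1, 1))
  expect_equal(approx_estimate(trt, 2, mix)$n_l, 1L)
})

test_that("the on-rate identity holds exactly for every trace and cutoff", {
  mix <- std_mixture(r_c = 0.2, c_c = 0.3)
  tr <- sample_trace(mix, 500, seed = 9)
  for (Tc in c(0, 0.5, 2, 5, 20)) {
    a <- approx_estimate(tr, Tc, mix)
    expect_equal(sum(mix$k * a$c_hat), tr$n / tr$Tu, tolerance = 1e-12)
  }
})

test_that("negative non-cognate estimates are flagged and optionally clipped", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  # few events, small cutoff with a large rescale makes n_l e^{rc Tc} > n
  tr <- binding_trace(tau_b = c(30, 40, 50), tau_u = c(1, 1, 1))
  a <- approx_estimate(tr, 20, mix)
  expect_true(a$negative_nc)
  expect_lt(a$c_hat[2L], 0)
  ac <- approx_estimate(tr, 20, mix, clip = TRUE)
  expect_equal(unname(ac$c_hat[2L]), 0)
})

test_that("replicate mean, variance and Poisson long-event counts match the analytic model", {
  mix <- std_mixture(r_c = 0.05, c_c = 0.5)
  n <- 1000; nrep <- 4000
  Tc <- 4  # validity regime: r_nc * Tc = 4 >= 3, r_c/r_nc = 0.05
  set.seed(71)
  seeds <- sample.int(.Machine$integer.max, nrep)
  Tc_rare <- 60  # r_c * Tc_rare = 3: long events are rare, mean(n_l) << n
  est <- matrix(NA_real_, nrep, 2L)
  n_l_rare <- integer(nrep)
  for (i in seq_len(nrep)) {
    tr <- sample_trace(mix, n, seed = seeds[i])
    a <- approx_estimate(tr, Tc, mix)
    est[i, ] <- a$c_hat
    n_l_rare[i] <- sum(tr$tau_b >= Tc_rare)
  }
  # mean matches c_c + (k_nc c_nc / k_c) e^{-(r_nc - r_c) Tc}
  m_pred <- analytic_bias_mean(mix, Tc)
  se <- stats::sd(est[, 1L]) / sqrt(nrep)
  expect_lt(abs(mean(est[, 1L]) - m_pred), 4 * se)
  # variance within 20%
  v_pred <- analytic_variance(mix, Tc, n)
  expect_lt(abs(stats::var(est[, 1L]) - v_pred) / v_pred, 0.20)
  # empirical loss (variance + squared bias) within 25% of the analytic loss
  L_emp <- mean((est[, 1L] - mix$c[1L])^2)
  L_pred <- approx_loss(mix, Tc, n)[["L_c"]]
  expect_lt(abs(L_emp - L_pred) / L_pred, 0.25)
  # in the rare regime (mean(n_l) << n) the long-event count is Poisson:
  # Fano factor near 1
  expect_lt(mean(n_l_rare) / n, 0.05)
  fano <- stats::var(n_l_rare) / mean(n_l_rare)
  expect_gt(fano, 0.8); expect_lt(fano, 1.2)
})

test_that("bias decreases and variance increases monotonically in the cutoff", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  Tcs <- seq(3, 10, by = 0.5)
  bias <- suppressWarnings(
    vapply(Tcs, function(Tc) analytic_bias_mean(mix, Tc), numeric(1L))) -
    mix$c[1L]
  vars <- vapply(Tcs, function(Tc) analytic_variance(mix, Tc, 1000),
                 numeric(1L))
  expect_true(all(diff(bias) < 0))
  expect_true(all(bias > 0))
  expect_true(all(diff(vars) > 0))
  # warns outside the validity regime
  expect_warning(analytic_bias_mean(mix, 1), "validity")
  # absent non-cognate ligand: no bias, variance is the pure Poisson term
  pure <- std_mixture(r_c = 0.1, c_c = 1)
  expect_equal(analytic_bias_mean(pure, 5), 1)
  expect_equal(analytic_variance(pure, 5, 1000), exp(0.1 * 5) / 1000)
})

test_that("closed-form optimal cutoff matches its structure and the numerical argmin", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.5)
  n <- 3000
  Tu <- n / mix$total_on_rate
  # doubling Tu shifts the optimum by exactly log(2) / (2 r_nc - r_c)
  d <- optimal_cutoff(mix, Tu = 2 * Tu) - optimal_cutoff(mix, Tu = Tu)
  expect_equal(d, log(2) / (2 * mix$r[2L] - mix$r[1L]), tolerance = 1e-12)
  # Tc* ~ 1/r_nc when r_nc >> r_c: slope -1 on log-log over a decade
  r_nc_grid <- 10^seq(1, 2, length.out = 5)
  tc <- vapply(r_nc_grid, function(rnc) {
    m <- two_ligand_mixture(k_c = 1, r_c = 0.01, c_c = 0.5,
                            k_nc = 1, r_nc = rnc, c_nc = 0.5)
    optimal_cutoff(m, Tu = 3000)
  }, numeric(1L))
  slope <- stats::coef(stats::lm(log(tc) ~ log(r_nc_grid)))[[2L]]
  expect_lt(abs(slope + 1), 0.15)
  # numerical argmin oracle: dense grid minimisation of the analytic loss
  for (r_c in c(0.05, 0.1)) {
    m <- std_mixture(r_c = r_c, c_c = 0.5)
    tc_star <- optimal_cutoff(m, n = n)
    grid <- seq(0.2 * tc_star, 3 * tc_star, length.out = 4000)
    # same approximation as the closed form: true c_c in the variance
    Lc <- vapply(grid, function(Tc) {
      bias <- (m$k[2L] * m$c[2L] / m$k[1L]) *
        exp(-(m$r[2L] - m$r[1L]) * Tc)
      v <- m$c[1L] * (m$c[1L] + m$k[2L] * m$c[2L] / m$k[1L]) *
        exp(m$r[1L] * Tc) / n
      v + bias^2
    }, numeric(1L))
    tc_num <- grid[which.min(Lc)]
    expect_lt(abs(tc_star - tc_num) / tc_num, 0.10)
    # the full analytic loss at Tc* is within a whisker of its grid minimum
    L_grid <- vapply(grid, function(Tc) approx_loss(m, Tc, n)[["L_c"]],
                     numeric(1L))
    expect_lte(approx_loss(m, tc_star, n)[["L_c"]], 1.02 * min(L_grid))
  }
  # degenerate argument: no finite positive optimum
  tiny <- std_mixture(r_c = 0.1, c_c = 1 - 1e-12)
  expect_error(optimal_cutoff(tiny, Tu = 0.1), "log argument")
})

test_that("reference cutoff is the optimum at unit reference on-rates", {
  mix <- std_mixture(r_c = 0.1, c_c = 0.9)
  n <- 3000
  ref <- set_concentrations(mix, c(0.5, 0.5))
  expect_equal(reference_cutoff(mix, n = n), optimal_cutoff(ref, n = n))
  # closed form at the reference point: log(n (r_nc/r_c - 1)) / (2 r_nc - r_c)
  expect_equal(reference_cutoff(mix, n = n),
               log(n * (1 / 0.1 - 1)) / (2 - 0.1), tolerance = 1e-12)
})

test_that("fixed reference cutoff keeps the threshold loss within a small factor of ML", {
  # order-unity loss ratios at moderate concentration ratios; the cognate
  # ratio worsens as the cognate ligand becomes rarer
  cfg <- sweep_config(r_ratio_grid = 0.1, c_ratio_grid = c(1/3, 1, 3),
                      n_events = 3000, n_replicates = 150, master_seed = 77)
  tab <- run_approx_comparison(cfg)
  expect_true(all(tab$ratio_c > 0.8 & tab$ratio_c < 2.0))
  expect_true(all(tab$ratio_nc > 0.8 & tab$ratio_nc < 2.0))
  expect_gt(tab$ratio_c[tab$c_ratio == 1/3],
            tab$ratio_c[tab$c_ratio == 3])
})
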