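test_that("generators are pure functions of their parameters and seed", {
  a <- gen_degradation_assay(seed = 7)
  b <- gen_degradation_assay(seed = 7)
  expect_identical(a, b)
  expect_false(identical(gen_degradation_assay(seed = 7),
                         gen_degradation_assay(seed = 8)))

  r1 <- gen_release_study(seed = 3)
  r2 <- gen_release_study(seed = 3)
  expect_identical(r1, r2)

  q1 <- gen_qcmd_trace(c(50, 100), noise_sd = 0.2, seed = 5)
  q2 <- gen_qcmd_trace(c(50, 100), noise_sd = 0.2, seed = 5)
  expect_identical(q1, q2)

  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_degradation_assay(seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless degradation assay reduces to an exact exponential", {
  tcs <- gen_degradation_assay(c0 = 400, k = 0.03, burst_fraction = 0,
                               cv = 0, n_replicates = 2, seed = 0)
  fit <- fit_first_order(tcs[[1]], window = c(8, 96))
  expect_lt(rel_err(fit$k, 0.03), 1e-10)
  expect_error(gen_degradation_assay(cv = -0.1), "non-negative")
  expect_error(gen_degradation_assay(burst_rate = 0.01), "exceed")
})

test_that("burst contaminates early samples but not the 8-96 h window", {
  tcs <- gen_degradation_assay(c0 = 500, k = rate_from_half_life(22.75),
                               burst_fraction = 0.3, burst_rate = 0.5,
                               cv = 0, n_replicates = 1, seed = 0)
  fit <- fit_first_order(tcs[[1]], window = c(8, 96))
  expect_lt(rel_err(fit$t_half, 22.75), 0.01)
})

test_that("half-life recovery from noisy assays is within 10% (seeds 0-9)", {
  truth <- 22.75
  for (seed in 0:9) {
    tcs <- gen_degradation_assay(c0 = 500, k = rate_from_half_life(truth),
                                 burst_fraction = 0.3, burst_rate = 0.5,
                                 cv = 0.10, n_replicates = 5, seed = seed)
    s <- summarize_fits(lapply(tcs, fit_first_order, window = c(8, 96)))
    expect_lt(rel_err(s$mean_t_half, truth), 0.10)
  }
})

test_that("noiseless release study round-trips the power-law parameters", {
  # k = 0: correction is the identity, recovery to float precision
  st0 <- gen_release_study(K = 0.12, n = 0.25, m_inf_ng = 12, k_true = 0,
                           cv = 0, n_replicates = 1, seed = 0)[[1]]
  corr0 <- degradation_correct(st0, k = 0)
  fit0 <- fit_power_law(corr0, m_infinity(corr0))
  expect_lt(rel_err(fit0$K, 0.12), 1e-10)
  expect_lt(rel_err(fit0$n, 0.25), 1e-10)

  # k > 0: correcting with the true rate undoes the attenuation
  k <- rate_from_half_life(22.75)
  st <- gen_release_study(K = 0.12, n = 0.25, m_inf_ng = 12, k_true = k,
                          cv = 0, n_replicates = 1, seed = 0)[[1]]
  corr <- degradation_correct(st, k = k)
  fit <- fit_power_law(corr, m_infinity(corr))
  expect_lt(rel_err(fit$K, 0.12), 1e-6)
  expect_lt(rel_err(fit$n, 0.25), 1e-6)
  # and M_inf reassembles exactly: final cumulative + wash = m_inf
  expect_equal(m_infinity(corr), 12, tolerance = 1e-9)

  expect_error(gen_release_study(K = 0.5, n = 0.5, sample_times = c(1, 96)),
               "infeasible")
})

test_that("noisy release study recovers the exponent within 0.05", {
  k <- rate_from_half_life(22.75)
  studies <- gen_release_study(K = 0.12, n = 0.25, m_inf_ng = 12, k_true = k,
                               cv = 0.15, n_replicates = 5, seed = 1)
  n_hat <- vapply(studies, function(st) {
    corr <- degradation_correct(st, k = k)
    fit_power_law(corr, m_infinity(corr))$n
  }, numeric(1))
  expect_lt(abs(mean(n_hat) - 0.25), 0.05)
})

test_that("recovered-parameter spread grows with the noise level", {
  k <- rate_from_half_life(22.75)
  sd_at_cv <- vapply(c(0, 0.05, 0.1, 0.2), function(cv) {
    th <- vapply(0:19, function(seed) {
      tcs <- gen_degradation_assay(k = k, cv = cv, n_replicates = 2,
                                   seed = seed)
      summarize_fits(lapply(tcs, fit_first_order))$mean_t_half
    }, numeric(1))
    stats::sd(th)
  }, numeric(1))
  expect_true(all(diff(sd_at_cv) > 0))
  expect_equal(sd_at_cv[1], 0, tolerance = 1e-9)
})

test_that("gaussian noise mode stays non-negative and perturbs the curve", {
  tcs <- gen_degradation_assay(cv = 0.5, n_replicates = 3, seed = 2,
                               noise = "gaussian")
  expect_true(all(vapply(tcs, function(tc) all(tc$conc_ng_ml >= 0),
                         logical(1))))
})
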