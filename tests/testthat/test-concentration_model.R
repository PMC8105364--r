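test_that("eluting simulation conserves mass when nothing degrades", {
  fit <- power_law_fit(K = 0.05, n = 0.3, m_inf_ng = 10, study_area_cm2 = 1)
  sys <- culture_system(1.9, 0.6)
  prof <- simulate_eluting(fit, sys, k = 0, t_end = 96, dt = 0.05)
  expected <- sys$surface_area_cm2 * predict_release(fit, prof$time_h) /
    sys$media_volume_ml
  idx <- expected > 0
  expect_lt(max(abs(prof$conc_ng_ml[idx] - expected[idx]) / expected[idx]),
            1e-9)
})

test_that("eluting simulation matches independent quadrature of the convolution", {
  fit <- power_law_fit(K = 0.05, n = 0.3, m_inf_ng = 10, study_area_cm2 = 1)
  sys <- culture_system(1.9, 0.6)
  k <- rate_from_half_life(22.75)
  prof <- simulate_eluting(fit, sys, k = k, t_end = 96, dt = 0.05)
  ts <- c(0.5, 1, 2, 4, 8, 16, 24, 48, 72, 96)
  oracle <- quadrature_concentration(ts, K = 0.05, n = 0.3, m_inf = 10,
                                     area = 1.9, volume = 0.6, k = k)
  expect_lt(max(abs(profile_value(prof, ts) - oracle)) / max(oracle), 1e-3)
})

test_that("eluting simulation converges under step halving", {
  fit <- power_law_fit(K = 0.05, n = 0.3, m_inf_ng = 10, study_area_cm2 = 1)
  k <- rate_from_half_life(22.75)
  p1 <- simulate_eluting(fit, culture_system(), k = k, dt = 0.05)
  p2 <- simulate_eluting(fit, culture_system(), k = k, dt = 0.025)
  ts <- seq(1, 96, by = 1)
  diff_rel <- max(abs(profile_value(p1, ts) - profile_value(p2, ts))) /
    max(profile_value(p2, ts))
  expect_lt(diff_rel, 1e-3)
})

test_that("eluting edge cases: no source, saturating release, decay to zero", {
  sys <- culture_system()
  k <- rate_from_half_life(22.75)
  tiny <- simulate_eluting(power_law_fit(K = 1e-300, n = 0.3, m_inf_ng = 10),
                           sys, k = k)
  expect_true(all(tiny$conc_ng_ml < 1e-290))
  # release saturates early (K t^n hits 1), then pure decay: profile -> 0
  sat <- simulate_eluting(power_law_fit(K = 0.5, n = 0.5, m_inf_ng = 5),
                          sys, k = 0.2, t_end = 200, dt = 0.05)
  expect_true(all(sat$conc_ng_ml >= 0))
  expect_lt(sat$conc_ng_ml[nrow(sat)], 1e-10 * max(sat$conc_ng_ml))
  expect_error(simulate_eluting(power_law_fit(0.1, 0.3, 10), sys, k = k,
                                dt = -1), "dt")
})

test_that("exogenous dosing reproduces the closed-form decay pointwise", {
  k <- rate_from_half_life(22.75)
  single <- simulate_exogenous(data.frame(time_h = 0, conc_ng_ml = 16),
                               k = k, t_end = 96)
  post <- single[-1, ] # drop the pre-dose row at t = 0
  expect_equal(post$conc_ng_ml,
               decay_concentration(16, k, post$time_h),
               tolerance = 1e-14)
})

test_that("exogenous profiles record pre/post dose values and superpose", {
  k <- rate_from_half_life(22.75)
  doses <- data.frame(time_h = c(0, 48), conc_ng_ml = c(16, 16))
  prof <- simulate_exogenous(doses, k = k, t_end = 96)
  expect_equal(profile_value(prof, 48, side = "pre"), 3.71,
               tolerance = 0.01 / 3.71)
  expect_equal(profile_value(prof, 48, side = "post"), 19.71,
               tolerance = 0.01 / 19.71)
  # superposition: dose schedules are additive under a linear ODE
  d1 <- data.frame(time_h = 0, conc_ng_ml = 16)
  d2 <- data.frame(time_h = 48, conc_ng_ml = 16)
  p1 <- simulate_exogenous(d1, k = k, t_end = 96)
  p2 <- simulate_exogenous(d2, k = k, t_end = 96)
  ts <- c(0, 7.3, 24, 47.9, 48, 60, 96)
  for (side in c("pre", "post")) {
    expect_equal(profile_value(prof, ts, side),
                 profile_value(p1, ts, side) + profile_value(p2, ts, side),
                 tolerance = 1e-12)
  }
})

test_that("exogenous dosing with k = 0 is a running-sum staircase", {
  doses <- data.frame(time_h = c(0, 10, 20), conc_ng_ml = c(1, 2, 3))
  prof <- simulate_exogenous(doses, k = 0, t_end = 30, dt = 1)
  expect_equal(profile_value(prof, 5), 1)
  expect_equal(profile_value(prof, 10, "pre"), 1)
  expect_equal(profile_value(prof, 10, "post"), 3)
  expect_equal(profile_value(prof, 25), 6)
  expect_error(
    simulate_exogenous(data.frame(time_h = c(10, 0), conc_ng_ml = c(1, 1)),
                       k = 0, t_end = 20),
    "sorted"
  )
})

test_that("profile_stats and profile_value read ranges and points", {
  k <- rate_from_half_life(22.75)
  prof <- simulate_exogenous(data.frame(time_h = 0, conc_ng_ml = 16),
                             k = k, t_end = 96)
  st <- profile_stats(prof, after = 0)
  expect_equal(st$max, 16)
  expect_identical(st$t_max, 0)
  expect_equal(st$min, decay_concentration(16, k, 96), tolerance = 1e-12)
  expect_error(profile_stats(prof, after = 96), "before the profile end")
  # linear interpolation between grid points
  flat <- simulate_exogenous(data.frame(time_h = 0, conc_ng_ml = 5),
                             k = 0, t_end = 10, dt = 1)
  expect_equal(profile_value(flat, 2.5), 5)
  expect_error(profile_value(flat, 11), "span")
})

test_that("condition_table reads pre-dose values per condition", {
  k <- rate_from_half_life(22.75)
  mk <- function(c0) {
    simulate_exogenous(data.frame(time_h = c(0, 48), conc_ng_ml = c(c0, c0)),
                       k = k, t_end = 96)
  }
  tab <- condition_table(list(`8 ng/mL` = mk(8), `4 ng/mL` = mk(4)),
                         read_times_h = c(48, 96))
  expect_equal(tab$t48_h, c(1.86, 0.93), tolerance = 0.02 / 0.93)
  expect_equal(tab$t96_h, c(2.28, 1.14), tolerance = 0.02 / 1.14)
  # full precision retained; print rounds
  expect_gt(abs(tab$t48_h[1] - round(tab$t48_h[1], 2)), 0)
  expect_output(print(tab), "1.85|1.86")

  zero <- simulate_exogenous(data.frame(time_h = 0, conc_ng_ml = 0),
                             k = k, t_end = 96)
  ztab <- condition_table(list(none = zero), 48)
  expect_identical(ztab$t48_h, 0)
  expect_error(condition_table(list(none = zero), 100), "span")
})

test_that("population doublings is log2 of the count ratio", {
  expect_equal(population_doublings(1000, 2000), 1.0)
  expect_equal(population_doublings(1000, 1000), 0.0)
  expect_equal(population_doublings(9387, 42560), 2.18, tolerance = 0.005)
  expect_error(population_doublings(0, 10), "positive")
})
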