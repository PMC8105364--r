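test_that("rate/half-life algebra matches the first-order definitions", {
  expect_equal(rate_from_half_life(22.75), 0.030468, tolerance = 1e-4)
  expect_equal(rate_from_half_life(log(2)), 1.0)
  # round trip
  expect_equal(rate_from_half_life(half_life_from_rate(0.05)), 0.05)
  expect_equal(half_life_from_rate(0), Inf)
  expect_error(rate_from_half_life(0), "positive")
  expect_error(rate_from_half_life(-1), "positive")
  expect_error(rate_from_half_life(Inf), "finite")
})

test_that("decay_concentration evaluates first-order decay", {
  k <- rate_from_half_life(22.75)
  expect_equal(decay_concentration(16, k, 48), 3.71, tolerance = 0.01 / 3.71)
  expect_equal(decay_concentration(100, k, 0), 100)
  expect_equal(decay_concentration(100, k, 22.75), 50)
  expect_error(decay_concentration(100, k, -1), "non-negative")
  expect_error(decay_concentration(100, -0.1, 1), "non-negative")
})

test_that("decay composes as a semigroup and halves at the half-life", {
  for (k in c(0, 0.01, 0.3)) {
    for (tt in list(c(3, 7), c(0.2, 90))) {
      two_step <- decay_concentration(
        decay_concentration(120, k, tt[1]), k, tt[2])
      expect_equal(two_step, decay_concentration(120, k, sum(tt)),
                   tolerance = 1e-12)
    }
  }
  k <- 0.04
  expect_equal(decay_concentration(7, k, half_life_from_rate(k)), 3.5)
})

test_that("timecourse constructor enforces its invariants", {
  expect_error(timecourse(c(1, 1, 2), c(3, 2, 1)), "strictly increasing")
  expect_error(timecourse(c(2, 1), c(3, 2)), "strictly increasing")
  expect_error(timecourse(c(1, 2), c(-1, 2)), "non-negative")
  expect_error(timecourse(c(1, NA), c(1, 2)), "finite")
  tc <- timecourse(c(1, 2), c(5, 4), condition = "PBS", replicate = "a")
  expect_s3_class(tc, "timecourse")
  expect_identical(attr(tc, "condition"), "PBS")
})

test_that("fit_first_order recovers k exactly from noiseless exponentials", {
  t <- c(8, 16, 24, 48, 72, 96)
  tc <- timecourse(t, 400 * exp(-0.03 * t))
  fit <- fit_first_order(tc, window = c(8, 96))
  expect_lt(rel_err(fit$k, 0.03), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$ln_N0, log(400), tolerance = 1e-8)
  expect_equal(fit$t_half * fit$k, log(2))
  expect_identical(fit$n_points, 6L)

  # any 2-point window also recovers exactly
  fit2 <- fit_first_order(tc, window = c(40, 80))
  expect_lt(rel_err(fit2$k, 0.03), 1e-10)
  expect_identical(fit2$n_points, 2L)
})

test_that("fit window excludes an early burst so the tail rate dominates", {
  # biexponential: fast burst on top of slow decay; fit from 8 h on
  t <- c(1, 2, 4, 8, 24, 48, 72, 96)
  conc <- 400 * (0.7 * exp(-0.03 * t) + 0.3 * exp(-0.5 * t))
  fit <- fit_first_order(timecourse(t, conc), window = c(8, 96))
  expect_lt(rel_err(fit$k, 0.03), 0.01)
  # fitting all points instead drags the rate upward
  fit_all <- fit_first_order(timecourse(t, conc), window = c(0, 96))
  expect_gt(fit_all$k, fit$k)
})

test_that("flat and growing data yield sentinels, not failures", {
  t <- c(8, 24, 48, 96)
  flat <- fit_first_order(timecourse(t, rep(20, 4)))
  expect_identical(flat$k, 0)
  expect_identical(flat$t_half, Inf)
  expect_identical(flat$r_squared, 0)

  expect_warning(
    grow <- fit_first_order(timecourse(t, 10 * exp(0.01 * t))),
    "growing"
  )
  expect_lt(grow$k, 0)
  expect_identical(grow$t_half, Inf)
  expect_identical(grow$quality_flag, "nonphysical_growth")
})

test_that("fit_first_order rejects unusable inputs", {
  expect_error(fit_first_order(timecourse(c(1, 100), c(5, 4))),
               "insufficient data")
  expect_error(fit_first_order(timecourse(c(8, 24), c(5, 0))),
               "log is undefined")
  expect_error(fit_first_order(timecourse(c(8, 24), c(5, 4)),
                               window = c(96, 8)), "t_min < t_max")
})

test_that("summarize_fits aggregates replicate half-lives", {
  mk <- function(th, rep_id = "r") {
    t <- c(8, 24, 48, 96)
    fit_first_order(timecourse(t, 100 * exp(-log(2) / th * t),
                               replicate = rep_id))
  }
  fits <- lapply(c(20, 24), mk)
  s <- summarize_fits(fits)
  expect_equal(s$mean_t_half, 22, tolerance = 1e-9)
  expect_equal(s$sd_t_half, sqrt(2) * 2, tolerance = 1e-9) # sample SD of {20,24}
  expect_identical(s$n_replicates, 2L)

  same <- summarize_fits(lapply(rep(20, 5), mk))
  expect_identical(same$sd_t_half, 0)
  expect_equal(same$mean_t_half, 20, tolerance = 1e-9)

  expect_error(summarize_fits(list()), "insufficient data")
  flat <- fit_first_order(timecourse(c(8, 24), c(5, 5), replicate = "bad"))
  expect_error(summarize_fits(list(mk(20), flat)), "bad")
})

test_that("fit_replicates offers per-replicate and mean-curve modes", {
  t <- c(8, 24, 48, 96)
  tcs <- lapply(1:3, function(i) {
    timecourse(t, (90 + 10 * i) * exp(-0.03 * t), replicate = paste0("r", i))
  })
  per <- fit_replicates(tcs)
  expect_length(per, 3)
  expect_true(all(vapply(per, function(f) rel_err(f$k, 0.03) < 1e-10,
                         logical(1))))
  mean_fit <- fit_replicates(tcs, method = "mean_curve")
  expect_s3_class(mean_fit, "first_order_fit")
  expect_lt(rel_err(mean_fit$k, 0.03), 1e-10)
})
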