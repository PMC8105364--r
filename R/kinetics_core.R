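# First-order degradation kinetics: rate/half-life algebra, decay evaluation,
# and log-linear fitting of immunoassay timecourses within a fit window that
# excludes the early non-equilibrium (burst) phase.

#' Construct a degradation timecourse
#'
#' A timecourse holds replicate-tagged (time, concentration) measurements from
#' a degradation assay, e.g. ELISA-detectable growth factor concentration
#' sampled from a well over several days.
#'
#' @param time_h Numeric vector of sampling times in hours, strictly
#'   increasing, all `>= 0`.
#' @param conc_ng_ml Numeric vector of concentrations in ng/mL, finite and
#'   non-negative, same length as `time_h`.
#' @param condition Condition label (character scalar).
#' @param replicate Replicate identifier (character scalar).
#'
#' @return An object of class `"timecourse"`: a data frame with columns
#'   `time_h` and `conc_ng_ml`, and attributes `condition` and `replicate`.
#' @export
#' @examples
#' tc <- timecourse(c(1, 8, 24, 96), 400 * exp(-0.03 * c(1, 8, 24, 96)))
#' fit_first_order(tc)
timecourse <- function(time_h, conc_ng_ml, condition = "unspecified",
                       replicate = "r1") {
  time_h <- as.numeric(time_h)
  conc_ng_ml <- as.numeric(conc_ng_ml)
  if (length(time_h) != length(conc_ng_ml)) {
    stop("`time_h` and `conc_ng_ml` must have the same length", call. = FALSE)
  }
  if (length(time_h) < 1L) {
    stop("a timecourse needs at least one sample", call. = FALSE)
  }
  if (anyNA(time_h) || any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("times must be finite, non-negative hours", call. = FALSE)
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("times must be strictly increasing within a replicate", call. = FALSE)
  }
  if (anyNA(conc_ng_ml) || any(!is.finite(conc_ng_ml)) || any(conc_ng_ml < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(time_h = time_h, conc_ng_ml = conc_ng_ml)
  attr(out, "condition") <- as.character(condition)
  attr(out, "replicate") <- as.character(replicate)
  class(out) <- c("timecourse", "data.frame")
  out
}

#' First-order rate constant from a half-life
#'
#' For pseudo-first-order decay `N(t) = N0 * exp(-k t)`, the rate constant and
#' half-life are related by `k = ln(2) / t_half`.
#'
#' @param t_half Half-life in hours, finite and `> 0`.
#' @return Rate constant in 1/hours.
#' @seealso [half_life_from_rate()]
#' @export
#' @examples
#' rate_from_half_life(22.75)
rate_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("`t_half` must be finite and positive", call. = FALSE)
  }
  log(2) / t_half
}

#' Half-life from a first-order rate constant
#'
#' Inverse of [rate_from_half_life()]. A rate of zero maps to an infinite
#' half-life.
#'
#' @param k Rate constant in 1/hours, finite and `>= 0`.
#' @return Half-life in hours (`Inf` when `k = 0`).
#' @export
half_life_from_rate <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be finite and non-negative", call. = FALSE)
  }
  ifelse(k == 0, Inf, log(2) / k)
}

#' Evaluate first-order exponential decay
#'
#' @param c0 Initial concentration in ng/mL, `>= 0`.
#' @param k Rate constant in 1/hours, `>= 0`.
#' @param t Time(s) in hours, `>= 0`; vectorized.
#' @return Concentration(s) `c0 * exp(-k t)` in ng/mL.
#' @export
#' @examples
#' decay_concentration(16, rate_from_half_life(22.75), 48) # ~3.71
decay_concentration <- function(c0, k, t) {
  if (!is.numeric(c0) || any(!is.finite(c0)) || any(c0 < 0)) {
    stop("`c0` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("`t` must be non-negative hours", call. = FALSE)
  }
  c0 * exp(-k * t)
}

#' Fit a first-order decay rate to one timecourse
#'
#' Ordinary least squares of `ln(concentration)` on time over the samples
#' falling inside the fit window (inclusive on both ends). The slope gives
#' `-k`; the default window of 8 to 96 hours excludes the early
#' non-equilibrium burst phase where decay is faster than first order.
#'
#' Growing (positive-slope) data is not an error: the fit reports `k < 0`
#' together with `quality_flag = "nonphysical_growth"` and an infinite
#' half-life sentinel, so that noisy, near-flat replicates can still be
#' audited rather than silently dropped.
#'
#' @param tc A [timecourse()].
#' @param window Length-2 numeric `(t_min, t_max)` in hours; samples with
#'   `t_min <= t <= t_max` enter the fit. Default `c(8, 96)`.
#' @return An object of class `"first_order_fit"`: a list with elements `k`
#'   (1/h), `t_half` (h; `Inf` when `k <= 0`), `ln_N0` (intercept),
#'   `r_squared`, `window`, `n_points`, `quality_flag` (`"ok"`, `"flat"`, or
#'   `"nonphysical_growth"`), `condition`, `replicate`.
#' @export
#' @examples
#' t <- c(8, 24, 48, 72, 96)
#' tc <- timecourse(t, 400 * exp(-0.03 * t))
#' fit <- fit_first_order(tc)
#' fit$k # 0.03
fit_first_order <- function(tc, window = c(8, 96)) {
  stopifnot(inherits(tc, "timecourse"))
  if (length(window) != 2L || !is.numeric(window) || any(!is.finite(window)) ||
      window[1] >= window[2]) {
    stop("`window` must be finite (t_min, t_max) with t_min < t_max",
         call. = FALSE)
  }
  inside <- tc$time_h >= window[1] & tc$time_h <= window[2]
  t_in <- tc$time_h[inside]
  c_in <- tc$conc_ng_ml[inside]
  if (length(t_in) < 2L) {
    stop("insufficient data: need at least 2 samples inside the fit window",
         call. = FALSE)
  }
  if (any(c_in <= 0)) {
    stop("non-positive concentration inside the fit window: log is undefined",
         call. = FALSE)
  }
  y <- log(c_in)
  fit <- stats::lm(y ~ t_in)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ss_tot
  k <- -slope
  flag <- "ok"
  if (abs(k) < .Machine$double.eps * max(1, abs(intercept))) {
    k <- 0
    flag <- "flat"
  } else if (k < 0) {
    flag <- "nonphysical_growth"
    warning("fitted slope is positive (growing concentration); ",
            "reporting k < 0 with an infinite half-life sentinel",
            call. = FALSE)
  }
  structure(
    list(
      k = k,
      t_half = if (k > 0) log(2) / k else Inf,
      ln_N0 = intercept,
      r_squared = r2,
      window = c(t_min = window[1], t_max = window[2]),
      n_points = length(t_in),
      quality_flag = flag,
      condition = attr(tc, "condition"),
      replicate = attr(tc, "replicate")
    ),
    class = "first_order_fit"
  )
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat("First-order degradation fit (", x$condition, "/", x$replicate, ")\n",
      sep = "")
  cat(sprintf("  k        = %.6g 1/h\n", x$k))
  cat(sprintf("  t_half   = %.4g h\n", x$t_half))
  cat(sprintf("  R^2      = %.4f over %d points in [%g, %g] h\n",
              x$r_squared, x$n_points, x$window[1], x$window[2]))
  if (x$quality_flag != "ok") cat("  flag     =", x$quality_flag, "\n")
  invisible(x)
}

#' Fit first-order decay per replicate or to the replicate mean
#'
#' The default (and recommended) mode fits each replicate's curve
#' independently and aggregation happens downstream via [summarize_fits()].
#' The `"mean_curve"` mode averages concentrations across replicates at each
#' shared time point and fits once; it exists for sensitivity comparison
#' only, since fitting the mean hides between-replicate variability.
#'
#' @param tcs List of [timecourse()] objects (same sampling grid required for
#'   `"mean_curve"`).
#' @param window Fit window, passed to [fit_first_order()].
#' @param method `"per_replicate"` (default) or `"mean_curve"`.
#' @return A list of `first_order_fit` objects (`"per_replicate"`), or a
#'   single fit (`"mean_curve"`).
#' @export
fit_replicates <- function(tcs, window = c(8, 96),
                           method = c("per_replicate", "mean_curve")) {
  method <- match.arg(method)
  if (!length(tcs)) stop("insufficient data: no timecourses given", call. = FALSE)
  stopifnot(all(vapply(tcs, inherits, logical(1), "timecourse")))
  if (method == "per_replicate") {
    return(lapply(tcs, fit_first_order, window = window))
  }
  grids <- lapply(tcs, `[[`, "time_h")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("`mean_curve` requires all replicates on the same sampling grid",
         call. = FALSE)
  }
  mean_conc <- rowMeans(vapply(tcs, `[[`, numeric(length(grids[[1]])),
                               "conc_ng_ml"))
  fit_first_order(
    timecourse(grids[[1]], mean_conc,
               condition = attr(tcs[[1]], "condition"),
               replicate = "mean_of_replicates"),
    window = window
  )
}

#' Summarize per-replicate first-order fits
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' replicate half-lives, plus the mean coefficient of determination. All
#' fits must have a finite half-life; an infinite sentinel (flat or growing
#' replicate) is an aggregation error that names the offending replicate.
#'
#' @param fits Non-empty list of `first_order_fit` objects.
#' @return An object of class `"fit_summary"`: list with `mean_t_half`,
#'   `sd_t_half` (0 when a single replicate), `mean_r_squared`,
#'   `n_replicates`, `condition`.
#' @export
summarize_fits <- function(fits) {
  if (!length(fits)) {
    stop("insufficient data: empty list of fits", call. = FALSE)
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "first_order_fit")))
  th <- vapply(fits, `[[`, numeric(1), "t_half")
  if (any(!is.finite(th))) {
    bad <- vapply(fits[!is.finite(th)], `[[`, character(1), "replicate")
    stop("cannot aggregate: infinite half-life in replicate(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      mean_t_half = mean(th),
      sd_t_half = if (length(th) > 1L) stats::sd(th) else 0,
      mean_r_squared = mean(vapply(fits, `[[`, numeric(1), "r_squared")),
      n_replicates = length(fits),
      condition = fits[[1]]$condition
    ),
    class = "fit_summary"
  )
}

#' @export
print.fit_summary <- function(x, ...) {
  cat("Half-life summary (", x$condition, "): ",
      sprintf("%.4g +/- %.4g h (n = %d, mean R^2 = %.3f)\n",
              x$mean_t_half, x$sd_t_half, x$n_replicates, x$mean_r_squared),
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.first_order_fit <- function(x, ...) {
  data.frame(
    condition = x$condition, replicate = x$replicate,
    k_per_h = x$k, t_half_h = x$t_half, ln_N0 = x$ln_N0,
    r_squared = x$r_squared, window_min_h = x$window[[1]],
    window_max_h = x$window[[2]], n_points = x$n_points,
    quality_flag = x$quality_flag,
    row.names = NULL
  )
}

#' @export
as.data.frame.fit_summary <- function(x, ...) {
  data.frame(
    condition = x$condition, mean_t_half_h = x$mean_t_half,
    sd_t_half_h = x$sd_t_half, mean_r_squared = x$mean_r_squared,
    n_replicates = x$n_replicates, row.names = NULL
  )
}
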