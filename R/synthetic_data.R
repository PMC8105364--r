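# Synthetic-data generators with the statistical structure the analysis
# modules assume: degradation assays with an early burst phase, release
# studies whose aliquots are attenuated by within-interval degradation, and
# QCM-D assembly traces. All generators are pure functions of their
# parameters and seed.

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# multiplicative lognormal noise with unit mean and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic degradation assays
#'
#' The true curve is a first-order decay superposed with a faster-decaying
#' burst component,
#' `c(t) = c0 * ((1 - b) exp(-k t) + b exp(-k_burst t))`,
#' emulating the early non-equilibrium phase of a reconstituted protein
#' before folding/unfolding equilibrium is reached. With the default burst
#' rate the burst is negligible past 8 h, so a fit window of (8, 96) h
#' isolates `k`. Observations carry multiplicative noise: lognormal with unit
#' mean and coefficient of variation `cv` by default (concentrations are
#' positive and immunoassay error scales roughly with the signal), or
#' additive Gaussian with standard deviation `cv * true` if requested.
#'
#' @param c0 Initial concentration in ng/mL (default 500, a typical spiked
#'   stock).
#' @param k True degradation rate in 1/hours (default corresponds to a
#'   half-life of 22.75 h).
#' @param burst_fraction Fraction of `c0` in the burst component, in `[0, 1)`
#'   (default 0.3).
#' @param burst_rate Burst decay rate in 1/hours, must exceed `k` (default
#'   0.5, i.e. burst half-life ~1.4 h).
#' @param times Sampling grid in hours (default `c(1, 2, 4, 8, 24, 48, 72,
#'   96)`: an early-dense grid starting after a 1-h incubation and ending at
#'   4 days).
#' @param n_replicates Number of replicate wells (default 5).
#' @param cv Noise coefficient of variation, `>= 0` (default 0.1).
#' @param seed RNG seed; identical seeds give identical output.
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param condition Condition label stamped on each replicate.
#' @return List of [timecourse()] objects, one per replicate, with the true
#'   parameters recorded in the `spec` attribute of the list.
#' @export
gen_degradation_assay <- function(c0 = 500, k = rate_from_half_life(22.75),
                                  burst_fraction = 0.3, burst_rate = 0.5,
                                  times = c(1, 2, 4, 8, 24, 48, 72, 96),
                                  n_replicates = 5, cv = 0.1, seed = 0,
                                  noise = c("lognormal", "gaussian"),
                                  condition = "synthetic") {
  noise <- match.arg(noise)
  if (!is.numeric(cv) || cv < 0) {
    stop("`cv` must be non-negative", call. = FALSE)
  }
  if (burst_fraction < 0 || burst_fraction >= 1) {
    stop("`burst_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (burst_rate <= k) {
    stop("`burst_rate` must exceed `k`", call. = FALSE)
  }
  true <- c0 * ((1 - burst_fraction) * exp(-k * times) +
                  burst_fraction * exp(-burst_rate * times))
  out <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    obs <- if (noise == "lognormal") {
      true * lognormal_noise(length(times), cv)
    } else {
      pmax(0, true + stats::rnorm(length(times), sd = cv * true))
    }
    timecourse(times, obs, condition = condition,
               replicate = paste0("rep", r))
  }))
  attr(out, "spec") <- list(c0 = c0, k = k, burst_fraction = burst_fraction,
                            burst_rate = burst_rate, times = times,
                            n_replicates = n_replicates, cv = cv, seed = seed,
                            noise = noise)
  out
}

#' Generate synthetic sampling-with-replacement release studies
#'
#' The true cumulative release follows the power law `R(t) = M_inf * K *
#' t^n`. Interval releases are differenced on the sampling grid; the measured
#' aliquot amount is the true interval release attenuated by within-interval
#' first-order degradation, `measured = true * (1 - exp(-k dt)) / (k dt)`,
#' times multiplicative noise. Aliquot concentration is amount / vial volume.
#' The terminal wash recovery is set to `M_inf - R(t_last)` (noiseless), so
#' the generated study is self-consistent with the definition of the total
#' releasable amount.
#'
#' @param K Power-law constant, must satisfy `K * max(sample_times)^n <= 1`.
#' @param n Power-law exponent (default 0.25, in the sub-diffusive regime
#'   typical of multilayer coatings).
#' @param m_inf_ng Total releasable amount in ng (default 12, a few ng/cm^2
#'   scale typical of adsorbed growth factor).
#' @param k_true Degradation rate during the study in 1/hours (default:
#'   half-life 22.75 h).
#' @param sample_times Sampling grid in hours (default `c(1, 4, 8, 24, 48,
#'   72, 96)`).
#' @param vial_volume_ml,substrate_area_cm2 Study geometry (defaults 1 mL,
#'   1 cm^2).
#' @param n_replicates,cv,seed As in [gen_degradation_assay()].
#' @param condition Condition label.
#' @return List of [release_study()] objects with the true parameters in the
#'   `spec` attribute.
#' @export
gen_release_study <- function(K = 0.12, n = 0.25, m_inf_ng = 12,
                              k_true = rate_from_half_life(22.75),
                              sample_times = c(1, 4, 8, 24, 48, 72, 96),
                              vial_volume_ml = 1, substrate_area_cm2 = 1,
                              n_replicates = 5, cv = 0.1, seed = 0,
                              condition = "synthetic") {
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  if (any(sample_times <= 0) || is.unsorted(sample_times, strictly = TRUE)) {
    stop("`sample_times` must be positive and strictly increasing",
         call. = FALSE)
  }
  t_last <- sample_times[length(sample_times)]
  if (K * t_last^n > 1) {
    stop("infeasible spec: K * t_last^n exceeds 1 (fractional release > 1)",
         call. = FALSE)
  }
  cum_true <- m_inf_ng * K * sample_times^n
  interval_true <- diff(c(0, cum_true))
  dt <- diff(c(0, sample_times))
  atten <- 1 / correction_factor(k_true, dt) # (1 - e^{-k dt}) / (k dt)
  wash <- m_inf_ng - cum_true[length(cum_true)]
  out <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    measured <- interval_true * atten *
      lognormal_noise(length(interval_true), cv)
    release_study(
      time_h = sample_times,
      aliquot_conc_ng_ml = measured / vial_volume_ml,
      vial_volume_ml = vial_volume_ml,
      substrate_area_cm2 = substrate_area_cm2,
      wash_recovery_ng = wash,
      condition = condition,
      replicate = paste0("rep", r)
    )
  }))
  attr(out, "spec") <- list(K = K, n = n, m_inf_ng = m_inf_ng,
                            k_true = k_true, sample_times = sample_times,
                            vial_volume_ml = vial_volume_ml,
                            substrate_area_cm2 = substrate_area_cm2,
                            n_replicates = n_replicates, cv = cv, seed = seed)
  out
}

#' Generate a synthetic QCM-D assembly trace
#'
#' Each layer consists of an adsorption phase during which the film mass
#' approaches its programmed plateau exponentially, followed by a wash phase
#' at exactly the plateau mass. Frequency shifts per overtone follow the
#' Sauerbrey relation `delta_f = -mass * n / C` plus white noise; dissipation
#' is generated proportional to the normalized frequency shift so the film
#' reads as rigid. Step annotations (adsorption and wash per layer) are
#' attached.
#'
#' @param step_masses Programmed end-of-layer areal masses in ng/cm^2 (may
#'   decrease: a stripping layer).
#' @param params [sauerbrey_params()] used for the forward map.
#' @param overtones Overtone numbers simulated (default odd 3 to 13).
#' @param noise_sd White-noise standard deviation on delta_f, in Hz, `>= 0`.
#' @param seed RNG seed.
#' @param adsorb_min,wash_min Phase durations in minutes (defaults 15 and
#'   10).
#' @param dt_s Sampling period in seconds (default 5).
#' @param tau_min Exponential approach time constant in minutes (default 2).
#' @param d_per_fnorm Dissipation generated per unit of `-delta_f/n`
#'   (default 1e-8 per Hz, i.e. well inside the rigid regime).
#' @return A [qcmd_trace()] with wash-phase annotations labelled
#'   `layer<i>_wash`.
#' @export
gen_qcmd_trace <- function(step_masses, params = sauerbrey_params(),
                           overtones = seq(3, 13, by = 2), noise_sd = 0,
                           seed = 0, adsorb_min = 15, wash_min = 10,
                           dt_s = 5, tau_min = 2, d_per_fnorm = 1e-8) {
  if (!is.numeric(step_masses) || !length(step_masses) ||
      any(!is.finite(step_masses))) {
    stop("`step_masses` must be finite", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  dt_min <- dt_s / 60
  n_layer <- length(step_masses)
  seg_min <- adsorb_min + wash_min
  times <- seq(0, n_layer * seg_min, by = dt_min)
  prev <- c(0, step_masses[-n_layer])
  mass_at <- function(t) {
    i <- pmin(n_layer, floor(t / seg_min) + 1L)
    tl <- t - (i - 1L) * seg_min
    target <- step_masses[i]
    start <- prev[i]
    in_wash <- tl >= adsorb_min | t >= n_layer * seg_min
    approach <- target + (start - target) * exp(-tl / tau_min)
    # plateau reached exactly during the wash phase
    ifelse(in_wash, target, approach)
  }
  mass <- mass_at(times)
  steps <- do.call(rbind, lapply(seq_len(n_layer), function(i) {
    base <- (i - 1) * seg_min
    data.frame(
      label = paste0("layer", i, c("_adsorption", "_wash")),
      start_min = c(base, base + adsorb_min),
      end_min = c(base + adsorb_min, base + seg_min),
      phase = c("adsorption", "wash")
    )
  }))
  long <- with_seed(seed, do.call(rbind, lapply(overtones, function(o) {
    f <- -mass * o / params$C +
      if (noise_sd > 0) stats::rnorm(length(mass), sd = noise_sd) else 0
    data.frame(time_min = times, overtone = o, delta_f_hz = f,
               delta_d = d_per_fnorm * pmax(0, -f / o))
  })))
  qcmd_trace(long$time_min, long$overtone, long$delta_f_hz, long$delta_d,
             steps = steps)
}
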