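# Sauerbrey analysis of QCM-D traces: areal mass from frequency shifts and
# per-layer adsorbed mass for layer-by-layer assembly experiments.
#
# The Sauerbrey relation for a rigid film is delta_m = -C * delta_f / n,
# where C is the mass-sensitivity constant of the crystal (17.7 ng/(cm^2 Hz)
# for 5 MHz sensors) and n the overtone number. A frequency drop therefore
# reports positive adsorbed mass.

#' Construct a QCM-D trace
#'
#' Long-format frequency/dissipation trace with step annotations marking the
#' adsorption and wash phases of a layer-by-layer assembly run.
#'
#' @param time_min Time in minutes (repeated per overtone), non-decreasing
#'   within each overtone.
#' @param overtone Odd overtone number (typically 3 to 13) for each row.
#' @param delta_f_hz Frequency shift in Hz.
#' @param delta_d Dissipation shift (absolute, i.e. a value of `1e-6`
#'   corresponds to one conventional "dissipation unit").
#' @param steps Data frame of annotations with columns `label`, `start_min`,
#'   `end_min`, and optionally `phase` (`"adsorption"` or `"wash"`); ordered,
#'   non-overlapping, inside the trace span.
#' @return Object of class `"qcmd_trace"`: the long data frame with a `steps`
#'   attribute.
#' @export
qcmd_trace <- function(time_min, overtone, delta_f_hz, delta_d, steps) {
  n <- length(time_min)
  if (length(overtone) != n || length(delta_f_hz) != n || length(delta_d) != n) {
    stop("trace columns must have equal length", call. = FALSE)
  }
  if (any(overtone %% 2 == 0) || any(overtone < 1)) {
    stop("overtone numbers must be odd and >= 1", call. = FALSE)
  }
  for (o in unique(overtone)) {
    if (is.unsorted(time_min[overtone == o])) {
      stop("times must be non-decreasing within each overtone", call. = FALSE)
    }
  }
  if (!is.data.frame(steps) ||
      !all(c("label", "start_min", "end_min") %in% names(steps))) {
    stop("`steps` needs columns label, start_min, end_min", call. = FALSE)
  }
  if (!"phase" %in% names(steps)) steps$phase <- NA_character_
  if (nrow(steps)) {
    if (any(steps$end_min <= steps$start_min)) {
      stop("each step must have end_min > start_min", call. = FALSE)
    }
    if (nrow(steps) > 1L &&
        any(steps$start_min[-1] < steps$end_min[-nrow(steps)])) {
      stop("step annotations must be ordered and non-overlapping",
           call. = FALSE)
    }
    if (min(steps$start_min) < min(time_min) ||
        max(steps$end_min) > max(time_min) + 1e-9) {
      stop("step annotation outside the trace span", call. = FALSE)
    }
  }
  out <- data.frame(time_min = time_min, overtone = overtone,
                    delta_f_hz = delta_f_hz, delta_d = delta_d)
  attr(out, "steps") <- steps
  class(out) <- c("qcmd_trace", "data.frame")
  out
}

#' Default Sauerbrey parameters
#'
#' @param C Mass-sensitivity constant in ng/(cm^2 Hz); 17.7 for 5 MHz
#'   crystals.
#' @param overtone Overtone used for mass calculation; the 3rd overtone is
#'   conventional as it best reflects the bulk of the film.
#' @return List with `C` and `overtone`.
#' @export
sauerbrey_params <- function(C = 17.7, overtone = 3) {
  if (!is.numeric(C) || !is.finite(C) || C <= 0) {
    stop("`C` must be positive", call. = FALSE)
  }
  if (!is.numeric(overtone) || overtone < 1 || overtone %% 2 == 0) {
    stop("`overtone` must be an odd integer >= 1", call. = FALSE)
  }
  list(C = C, overtone = as.integer(overtone))
}

#' Areal mass from a frequency shift (Sauerbrey)
#'
#' `delta_m = -C * delta_f / n`. Negative frequency shifts (adsorption) give
#' positive mass; positive shifts (stripping) give negative mass.
#'
#' @param delta_f_hz Frequency shift(s) in Hz; vectorized.
#' @param params [sauerbrey_params()].
#' @return Areal mass in ng/cm^2.
#' @export
#' @examples
#' sauerbrey_mass(-3) # 17.7 ng/cm^2 at the 3rd overtone
sauerbrey_mass <- function(delta_f_hz, params = sauerbrey_params()) {
  if (params$overtone < 1) stop("`overtone` must be >= 1", call. = FALSE)
  -params$C * delta_f_hz / params$overtone
}

#' Rigid-film validity check
#'
#' The Sauerbrey relation assumes a rigid film, diagnosed by a stable ratio
#' of dissipation change to normalized frequency change across overtones.
#' Over the given window this computes, per overtone, the mean
#' `delta_D / (-delta_f / n)` and reports the relative spread
#' (`(max - min) / mean`). The film is flagged rigid when the spread is below
#' `spread_threshold` and the mean ratio is below `ratio_threshold`. If all
#' overtones have near-zero frequency shift the ratio is indeterminate and
#' `rigid` is `NA`.
#'
#' This check is advisory only; no viscoelastic modeling is attempted.
#'
#' @param trace A [qcmd_trace()].
#' @param window Length-2 numeric window `(start_min, end_min)`.
#' @param spread_threshold Maximum relative spread across overtones
#'   (default 0.2).
#' @param ratio_threshold Maximum mean dissipation per normalized Hz
#'   (default 0.4e-6).
#' @return List with `rigid` (TRUE/FALSE/NA), `spread`, `mean_ratio`, and the
#'   per-overtone `ratios`.
#' @export
rigidity_check <- function(trace, window = range(trace$time_min),
                           spread_threshold = 0.2, ratio_threshold = 0.4e-6) {
  stopifnot(inherits(trace, "qcmd_trace"))
  sel <- trace$time_min >= window[1] & trace$time_min <= window[2]
  sub <- trace[sel, , drop = FALSE]
  overtones <- sort(unique(sub$overtone))
  if (length(overtones) < 2L) {
    stop("need at least 2 overtones inside the window", call. = FALSE)
  }
  f_norm <- vapply(overtones, function(o) {
    mean(-sub$delta_f_hz[sub$overtone == o] / o)
  }, numeric(1))
  d_mean <- vapply(overtones, function(o) {
    mean(sub$delta_d[sub$overtone == o])
  }, numeric(1))
  if (all(abs(f_norm) < 1e-9)) {
    warning("all overtones have ~zero frequency shift in the window: ",
            "rigidity indeterminate", call. = FALSE)
    return(list(rigid = NA, spread = NA_real_, mean_ratio = NA_real_,
                ratios = stats::setNames(rep(NA_real_, length(overtones)),
                                         overtones)))
  }
  ratios <- d_mean / f_norm
  spread <- (max(ratios) - min(ratios)) / mean(ratios)
  mean_ratio <- mean(ratios)
  list(rigid = abs(spread) <= spread_threshold && mean_ratio < ratio_threshold,
       spread = spread, mean_ratio = mean_ratio,
       ratios = stats::setNames(ratios, overtones))
}

#' Per-layer adsorbed mass from an annotated trace
#'
#' For each selected step the end-of-step areal mass is the Sauerbrey mass of
#' the chosen overtone's frequency shift averaged over the final `tail_s`
#' seconds of the step (post-wash convention, robust to noise); increments
#' are successive differences. A stripping step yields a negative increment.
#' Increments telescope to the final mass by construction.
#'
#' @param trace A [qcmd_trace()].
#' @param params [sauerbrey_params()].
#' @param tail_s Averaging window at the end of each step, in seconds
#'   (default 30).
#' @param steps Which annotated steps to read masses from. The default uses
#'   the steps flagged `phase == "wash"` (each wash ends a layer); if no
#'   phases are annotated, all steps are used.
#' @return Data frame of class `"layer_mass_profile"` with columns `label`,
#'   `end_min`, `mass_ng_cm2`, `increment_ng_cm2`.
#' @export
layer_masses <- function(trace, params = sauerbrey_params(), tail_s = 30,
                         steps = NULL) {
  stopifnot(inherits(trace, "qcmd_trace"))
  if (is.null(steps)) {
    steps <- attr(trace, "steps")
    if (any(!is.na(steps$phase)) && any(steps$phase == "wash", na.rm = TRUE)) {
      steps <- steps[!is.na(steps$phase) & steps$phase == "wash", , drop = FALSE]
    }
  }
  if (!nrow(steps)) stop("no steps to read masses from", call. = FALSE)
  ot <- trace$overtone == params$overtone
  if (!any(ot)) {
    stop("overtone ", params$overtone, " not present in trace", call. = FALSE)
  }
  t_o <- trace$time_min[ot]
  f_o <- trace$delta_f_hz[ot]
  mass <- vapply(seq_len(nrow(steps)), function(i) {
    w0 <- steps$end_min[i] - tail_s / 60
    sel <- t_o >= w0 - 1e-9 & t_o <= steps$end_min[i] + 1e-9
    if (!any(sel)) {
      stop("no samples in the final ", tail_s, " s of step '",
           steps$label[i], "'", call. = FALSE)
    }
    sauerbrey_mass(mean(f_o[sel]), params)
  }, numeric(1))
  out <- data.frame(
    label = steps$label,
    end_min = steps$end_min,
    mass_ng_cm2 = mass,
    increment_ng_cm2 = c(mass[1], diff(mass))
  )
  class(out) <- c("layer_mass_profile", "data.frame")
  out
}
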