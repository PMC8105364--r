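# Readers, writers, configuration, and the end-to-end pipeline runner.
# Canonical units everywhere: hours, ng/mL, mL, cm^2; columns carry unit
# suffixes and day-unit time columns are converted at the boundary.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(required, "time_h"), names(df))
  if ("time_h" %in% required && !"time_h" %in% names(df)) {
    if ("time_d" %in% names(df)) {
      df$time_h <- df$time_d * 24
      df$time_d <- NULL
      message("converted `time_d` to hours (x24) in ", basename(path))
    } else {
      missing <- c("time_h (or time_d)", missing)
    }
  }
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df[required[required %in% names(df)]])) {
    bad <- which(rowSums(is.na(df)) > 0)[1]
    stop("missing value in ", basename(path), " at data row ", bad,
         call. = FALSE)
  }
  df
}

#' Read degradation timecourses from CSV
#'
#' Expects columns `condition`, `replicate`, `time_h` (or `time_d`, converted
#' to hours), `conc_ng_ml`. Each (condition, replicate) pair becomes one
#' [timecourse()]; invariant violations (non-monotone times, negative
#' concentrations, missing values) are schema errors.
#'
#' @param path CSV file path.
#' @return Named list of [timecourse()] objects
#'   (`"<condition>/<replicate>"`).
#' @export
read_timecourse_csv <- function(path) {
  df <- read_checked_csv(path, c("condition", "replicate", "time_h",
                                 "conc_ng_ml"))
  key <- paste(df$condition, df$replicate, sep = "/")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    tryCatch(
      timecourse(g$time_h, g$conc_ng_ml, condition = g$condition[1],
                 replicate = g$replicate[1]),
      error = function(e) {
        stop("in ", basename(path), ", replicate ", g$condition[1], "/",
             g$replicate[1], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  out
}

#' Read release studies from CSV plus a study config
#'
#' The CSV holds columns `condition`, `replicate`, `time_h` (or `time_d`),
#' `aliquot_conc_ng_ml`; the study geometry (`vial_volume_ml`,
#' `substrate_area_cm2`, `wash_recovery_ng`) comes from a sidecar config: a
#' named list or a YAML/JSON file path.
#'
#' @param path CSV file path.
#' @param config Named list, or path to a YAML/JSON file, with elements
#'   `vial_volume_ml`, `substrate_area_cm2`, `wash_recovery_ng`.
#' @return Named list of [release_study()] objects.
#' @export
read_release_csv <- function(path, config) {
  if (is.character(config)) config <- read_run_config(config)
  needed <- c("vial_volume_ml", "substrate_area_cm2", "wash_recovery_ng")
  if (!is.list(config) || !all(needed %in% names(config))) {
    stop("`config` must provide ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df <- read_checked_csv(path, c("condition", "replicate", "time_h",
                                 "aliquot_conc_ng_ml"))
  key <- paste(df$condition, df$replicate, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    tryCatch(
      release_study(g$time_h, g$aliquot_conc_ng_ml,
                    vial_volume_ml = config$vial_volume_ml,
                    substrate_area_cm2 = config$substrate_area_cm2,
                    wash_recovery_ng = config$wash_recovery_ng,
                    condition = g$condition[1], replicate = g$replicate[1]),
      error = function(e) {
        stop("in ", basename(path), ", replicate ", g$condition[1], "/",
             g$replicate[1], ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path File path ending in `.yml`/`.yaml`/`.json`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

results_df <- function(object) {
  if (is.data.frame(object)) return(as.data.frame(object))
  if (inherits(object, c("first_order_fit", "fit_summary", "power_law_fit"))) {
    return(as.data.frame(object))
  }
  if (is.list(object) && length(object) &&
      all(vapply(object, inherits, logical(1),
                 c("first_order_fit", "power_law_fit")))) {
    return(do.call(rbind, lapply(object, as.data.frame)))
  }
  stop("don't know how to tabulate an object of class ",
       paste(class(object), collapse = "/"), call. = FALSE)
}

#' Write results with a JSON metadata sidecar
#'
#' Writes the tabular form of a result object to CSV at full double
#' precision, plus a `<path>.meta.json` sidecar recording the object class,
#' package version, timestamp, and any parameters carried in the object's
#' attributes (e.g. the correction rate of a corrected release or the dose
#' schedule of a profile). CSV written this way round-trips losslessly
#' through [utils::read.csv()].
#'
#' @param object A fit, summary, corrected release, profile, table, or list
#'   of fits.
#' @param path Output CSV path.
#' @return Invisibly, the paths written (`csv`, `meta`).
#' @export
write_results <- function(object, path) {
  df <- results_df(object)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  meta <- list(
    class = class(object)[1],
    package = "gfelute",
    version = as.character(utils::packageVersion("gfelute")),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  keep <- setdiff(names(attributes(object)),
                  c("names", "row.names", "class", "study"))
  params <- attributes(object)[keep]
  if (inherits(object, "corrected_release")) {
    st <- attr(object, "study")
    params$study <- st[c("vial_volume_ml", "substrate_area_cm2",
                         "wash_recovery_ng", "condition", "replicate")]
  }
  if (length(params)) meta$parameters <- params
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(list(csv = path, meta = meta_path))
}

#' Read a concentration profile written by [write_results()]
#'
#' @param path CSV path with columns `time_h`, `conc_ng_ml`.
#' @return A `"concentration_profile"`.
#' @export
read_profile_csv <- function(path) {
  df <- read_checked_csv(path, c("time_h", "conc_ng_ml"))
  new_profile(as.numeric(df$time_h), as.numeric(df$conc_ng_ml))
}

resolve_k <- function(block) {
  if (!is.null(block$k_per_h)) return(block$k_per_h)
  if (!is.null(block$half_life_h)) return(rate_from_half_life(block$half_life_h))
  rate_from_half_life(22.75)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages in dependency order — half-life fitting,
#' degradation-corrected release + power-law fitting, forward simulation, and
#' the dose table — writing each stage's artifacts (CSV + JSON sidecar) under
#' `output_dir` and logging the parameters used. Deterministic given the
#' config. Any stage error aborts with the stage name; artifacts of completed
#' stages are preserved.
#'
#' Recognized top-level keys (all stages optional, unknown keys rejected):
#' \describe{
#'   \item{output_dir}{Directory for artifacts (required).}
#'   \item{degradation}{`input` (timecourse CSV), `window` (default 8, 96).}
#'   \item{release}{`input` (release CSV), `vial_volume_ml`,
#'     `substrate_area_cm2`, `wash_recovery_ng`, plus `half_life_h` or
#'     `k_per_h` for the correction.}
#'   \item{simulate}{Named list of runs. Each run has `degradation`
#'     (`half_life_h`/`k_per_h`), `simulation` (`t_end_h`, `dt_h`), and
#'     either `doses` (list of `{time_h, conc_ng_ml}`) or `source`
#'     (`K`, `n`, `M_infinity_ng_per_cm2`, `study_area_cm2`) with `system`
#'     (`surface_area_cm2`, `media_volume_ml`).}
#'   \item{dose_table}{`read_times_h`: where to read every simulated
#'     profile (pre-dose convention).}
#' }
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Invisibly, a named list of in-memory stage results
#'   (`fits`, `summary`, `corrected`, `power_law`, `profiles`, `table`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  known <- c("output_dir", "degradation", "release", "simulate", "dose_table")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$output_dir)) stop("config needs `output_dir`", call. = FALSE)
  if (!is.null(config$simulate)) {
    for (nm in names(config$simulate)) {
      run <- config$simulate[[nm]]
      if (is.null(run$doses) && is.null(run$source)) {
        stop("simulate run '", nm, "': needs either `doses` or `source`",
             call. = FALSE)
      }
    }
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$degradation)) {
    results <- c(results, stage("degradation", {
      blk <- config$degradation
      window <- if (is.null(blk$window)) c(8, 96) else as.numeric(blk$window)
      tcs <- read_timecourse_csv(blk$input)
      message("[degradation] ", length(tcs), " replicate(s), window [",
              window[1], ", ", window[2], "] h")
      fits <- lapply(tcs, fit_first_order, window = window)
      write_results(fits, file.path(out_dir, "halflife_fits.csv"))
      by_cond <- split(fits, vapply(fits, `[[`, character(1), "condition"))
      summaries <- lapply(by_cond, summarize_fits)
      write_results(do.call(rbind, lapply(summaries, as.data.frame)),
                    file.path(out_dir, "halflife_summary.csv"))
      list(fits = fits, summary = summaries)
    }))
  }

  if (!is.null(config$release)) {
    results <- c(results, stage("release", {
      blk <- config$release
      k <- resolve_k(blk)
      studies <- read_release_csv(blk$input, blk)
      message("[release] ", length(studies), " replicate(s), correction k = ",
              signif(k, 6), " 1/h")
      corrected <- lapply(studies, degradation_correct, k = k)
      pl <- lapply(corrected, function(cr) fit_power_law(cr, m_infinity(cr)))
      corr_df <- do.call(rbind, Map(function(cr, nm) {
        cbind(replicate = nm, as.data.frame(cr))
      }, corrected, names(corrected)))
      write_results(corr_df, file.path(out_dir, "corrected_release.csv"))
      write_results(pl, file.path(out_dir, "powerlaw_fits.csv"))
      list(corrected = corrected, power_law = pl)
    }))
  }

  if (!is.null(config$simulate)) {
    results$profiles <- stage("simulate", {
      profiles <- list()
      for (nm in names(config$simulate)) {
        run <- config$simulate[[nm]]
        k <- resolve_k(run$degradation)
        sim <- run$simulation
        t_end <- if (is.null(sim$t_end_h)) 96 else sim$t_end_h
        if (!is.null(run$doses)) {
          doses <- do.call(rbind, lapply(run$doses, as.data.frame))
          dt <- if (is.null(sim$dt_h)) 0.1 else sim$dt_h
          message("[simulate:", nm, "] exogenous, ", nrow(doses),
                  " dose(s), k = ", signif(k, 6), " 1/h")
          prof <- simulate_exogenous(doses, k = k, t_end = t_end, dt = dt)
        } else {
          src <- run$source
          fit <- power_law_fit(src$K, src$n,
                               m_inf_ng = src$M_infinity_ng_per_cm2 *
                                 src$study_area_cm2,
                               study_area_cm2 = src$study_area_cm2,
                               condition = nm)
          sys <- if (is.null(run$system)) culture_system() else {
            culture_system(run$system$surface_area_cm2,
                           run$system$media_volume_ml)
          }
          dt <- if (is.null(sim$dt_h)) 0.05 else sim$dt_h
          message("[simulate:", nm, "] eluting, k = ", signif(k, 6),
                  " 1/h, dt = ", dt, " h")
          prof <- simulate_eluting(fit, sys, k = k, t_end = t_end, dt = dt)
        }
        safe_nm <- gsub("[^A-Za-z0-9._-]+", "_", nm)
        write_results(prof, file.path(out_dir, paste0("profile_", safe_nm, ".csv")))
        profiles[[nm]] <- prof
      }
      profiles
    })
  }

  if (!is.null(config$dose_table)) {
    results$table <- stage("dose_table", {
      if (is.null(results$profiles)) {
        stop("dose_table requires a simulate stage", call. = FALSE)
      }
      rt <- as.numeric(config$dose_table$read_times_h)
      tab <- condition_table(results$profiles, rt)
      write_results(tab, file.path(out_dir, "dose_table.csv"))
      tab
    })
  }

  invisible(results)
}
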