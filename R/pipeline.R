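.default_config <- function() {
  list(
    seed = 1L,
    generator = list(
      duration = 3, stim_window = c(1, 2), baseline_rate = 1,
      stim_rate = 3, n_us = 3,
      intra_burst_isi_range_ms = c(4, 8),
      pause_dist = list(family = "gamma", median_ms = 104, shape = 3),
      calcium = list(amp_per_us = 0.05, lag_mean_ms = 50,
                     lag_sd_ms = 10, tau_on = 0.15, tau_off = 2,
                     noise_sd = 0.005, bleach_rate = 0.02,
                     sample_rate = 100)
    ),
    analysis = list(
      isi_burst_max_ms = 9, isi_pause_min_ms = 20,
      rate_window_ms = 100, rate_step_ms = 10,
      min_peak_rate_hz = 25, min_trough_fraction = 0.5,
      schmitt_high_k = 4, schmitt_low_k = 1,
      tau_on_bounds = c(0.05, 0.5), tau_off_bounds = c(1.5, 10),
      grid_px = 34
    )
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Reads a YAML configuration, fills unspecified keys with package
#' defaults, and validates the analysis thresholds. The schema mirrors
#' the analysis parameters: a `generator` block (trial timing, rates,
#' burst count, pause distribution, calcium settings), an `analysis`
#' block (ISI thresholds in ms, rate window/step, peak and Schmitt
#' thresholds, fit bounds, grid pitch) and a `seed`. ISI thresholds are
#' configured in milliseconds and converted at the analysis boundary;
#' all serialized times are in seconds.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return config list with attribute `"hash"` (md5 of the normalized
#'   YAML, used as provenance).
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) cfg <- .merge_config(cfg, yaml::read_yaml(path))
  an <- cfg$analysis
  if (any(unlist(an[c("isi_burst_max_ms", "isi_pause_min_ms",
                      "rate_window_ms", "rate_step_ms",
                      "min_peak_rate_hz")]) <= 0))
    stop("analysis thresholds must be positive")
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  cfg
}

.gen_params_from_config <- function(g) {
  trialGenParams(
    duration = g$duration, stimWindow = as.numeric(g$stim_window),
    baselineRate = g$baseline_rate, stimRate = g$stim_rate,
    nUS = g$n_us,
    intraBurstIsiRangeMs = as.numeric(g$intra_burst_isi_range_ms),
    pauseDist = g$pause_dist
  )
}

.ca_params_from_config <- function(cc) {
  caGenParams(ampPerUS = cc$amp_per_us, lagMeanMs = cc$lag_mean_ms,
              lagSdMs = cc$lag_sd_ms, tauOn = cc$tau_on,
              tauOff = cc$tau_off, noiseSd = cc$noise_sd,
              bleachRate = cc$bleach_rate, sampleRate = cc$sample_rate)
}

#' Run one simulated (or supplied) trial through the analysis stages
#'
#' Executes the spike stage (US detection, pauses, rate peaks) and,
#' when a calcium trace is present or simulated, the calcium stage
#' (transient detection, model fit, onset lag). Deterministic given the
#' config and seed; every record carries provenance (config hash,
#' seed).
#'
#' @param config list from [readRunConfig()].
#' @param inputs optional list with `train` ([SpikeTrain-class]) and/or
#'   `trace` (dF/F0 [FluorTrace-class]); when NULL both are simulated
#'   from the config.
#' @param seed integer seed for the simulated inputs (defaults to
#'   `config$seed`).
#' @param trialId identifier.
#' @return list (TrialRecord): `train`, `trace`, `metrics` (one-row
#'   data.frame), `events`, `fit` (or NULL), `provenance`.
#' @export
runTrial <- function(config = readRunConfig(), inputs = NULL,
                     seed = NULL, trialId = "trial") {
  if (is.null(seed)) seed <- config$seed
  an <- config$analysis
  simulated <- is.null(inputs)
  if (simulated) {
    sim <- simulateSpikeTrial(.gen_params_from_config(config$generator),
                              seed = seed, trialId = trialId)
    ca <- simulateCalciumTrace(sim,
                               .ca_params_from_config(
                                 config$generator$calcium),
                               seed = seed + 500000L)
    inputs <- list(train = sim$train, trace = ca$trace)
  }
  train <- inputs$train
  ev <- detectUS(train, an$isi_burst_max_ms, an$isi_pause_min_ms)
  pauses <- pausePeriods(ev, train)
  fr <- firingRateTrace(train, an$rate_window_ms, an$rate_step_ms)
  metrics <- data.frame(
    trial_id = trialId(train),
    us_count = nrow(ev),
    peak_count = countRatePeaks(fr, an$min_peak_rate_hz,
                                an$min_trough_fraction,
                                window = stimWindow(train)),
    max_rate_hz = max(fr$rate),
    median_pause_ms = if (length(pauses)) stats::median(pauses)
                      else NA_real_,
    f_peak = NA_real_, onset_lag_s = NA_real_
  )
  fit <- NULL
  if (!is.null(inputs$trace)) {
    trace <- inputs$trace
    if (trace@unit == "raw") trace <- computeDFF(trace)
    metrics$f_peak <- peakAmplitude(trace)
    tev <- tryCatch(
      detectTransients(trace, an$schmitt_high_k, an$schmitt_low_k),
      error = function(e) NULL)
    if (!is.null(tev) && nrow(tev) && nrow(ev)) {
      fit <- tryCatch(
        fitTransient(trace,
                     window = c(max(0, tev$onset_time[1L] - 0.5),
                                stimWindow(trace)[2]),
                     nComponents = max(1L, nrow(ev)),
                     tauOnBounds = as.numeric(an$tau_on_bounds),
                     tauOffBounds = as.numeric(an$tau_off_bounds)),
        error = function(e) NULL)
      if (!is.null(fit))
        metrics$onset_lag_s <- onsetLag(fit, ev)
    }
  }
  list(train = train, trace = inputs$trace, metrics = metrics,
       events = ev, fit = fit,
       provenance = list(config_hash = attr(config, "hash"),
                         seed = if (simulated) seed else NA_integer_,
                         package_version =
                           as.character(utils::packageVersion("nociburst"))))
}

#' Run a multi-cohort simulation and comparison
#'
#' Simulates `nTrials` trials per cohort (each cohort may override any
#' generator key, e.g. a shortened pause median for a knockdown
#' cohort), computes per-trial spike/calcium metrics, and compares the
#' named metrics across cohorts with the configured test and
#' correction.
#'
#' @param config list from [readRunConfig()].
#' @param cohorts named list of generator override lists (possibly
#'   empty lists for the control settings).
#' @param nTrials trials per cohort (scalar or vector matching
#'   `cohorts`).
#' @param metrics character vector of metric columns to compare
#'   (default `"median_pause_ms"` and `"us_count"`).
#' @param test,correction see [runComparison()].
#' @param seed base seed (defaults to `config$seed`).
#' @param outDir optional directory: writes `metrics.csv`,
#'   `comparisons.csv` and `summary.json`.
#' @return list with `metrics` (data.frame with `cohort` column),
#'   `comparisons` (one block per metric), `provenance`.
#' @export
runCohort <- function(config = readRunConfig(), cohorts, nTrials = 20,
                      metrics = c("median_pause_ms", "us_count"),
                      test = "wilcoxon_rank_sum",
                      correction = "holm", seed = NULL, outDir = NULL) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2L,
            !is.null(names(cohorts)))
  if (any(vapply(cohorts, function(x) !is.list(x), TRUE)))
    stop("each cohort must be a (possibly empty) list of generator overrides")
  if (length(nTrials) == 1L) nTrials <- rep(nTrials, length(cohorts))
  if (any(nTrials < 1L)) stop("empty cohort configured")
  if (is.null(seed)) seed <- config$seed

  all_rows <- list()
  for (ci in seq_along(cohorts)) {
    gcfg <- .merge_config(config$generator, cohorts[[ci]])
    ccfg <- config
    ccfg$generator <- gcfg
    for (j in seq_len(nTrials[ci])) {
      rec <- runTrial(ccfg, seed = seed + ci * 10000L + j,
                      trialId = sprintf("%s_%03d", names(cohorts)[ci], j))
      row <- rec$metrics
      row$cohort <- names(cohorts)[ci]
      all_rows[[length(all_rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, all_rows)

  comp <- list()
  for (m in metrics) {
    groups <- lapply(split(tab[[m]], tab$cohort), function(v)
      v[is.finite(v)])
    groups <- groups[names(cohorts)]  # preserve configured order
    if (any(vapply(groups, length, 1L) < 2L)) next
    res <- runComparison(groups, test = test, correction = correction)
    res$metric <- m
    comp[[length(comp) + 1L]] <- res
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else NULL

  out <- list(metrics = tab, comparisons = comparisons,
              provenance = list(config_hash = attr(config, "hash"),
                                seed = seed,
                                package_version = as.character(
                                  utils::packageVersion("nociburst"))))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(provenance = out$provenance,
           cohorts = lapply(split(tab, tab$cohort), function(d)
             list(n = nrow(d),
                  median_pause_ms =
                    stats::median(d$median_pause_ms, na.rm = TRUE),
                  mean_us_count = mean(d$us_count)))),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
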