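#' Parameters for the synthetic calcium-trace generator
#'
#' Defaults: each US contributes a 5% dF/F0 step, calcium onsets
#' precede the first spike of their burst by a lag drawn from
#' N(50 ms, 10 ms) truncated at 0, rise/decay time constants 0.15 s /
#' 2 s (within the fitting bounds of 0.05-0.5 s and 1.5-10 s), 0.5%
#' dF/F0 Gaussian noise (chosen so a single-US step, whose model peak
#' is 0.76 * ampPerUS = 3.8% dF/F0, stands 7.5 baseline SDs above the
#' noise and is reliably detected at the 4-SD Schmitt threshold), a
#' linear photobleaching decline of 2% per second, and 100-Hz sampling.
#'
#' @param ampPerUS dF/F0 step contributed by each US.
#' @param lagMeanMs,lagSdMs onset-lead distribution (ms), truncated
#'   at 0.
#' @param tauOn,tauOff model time constants, s.
#' @param noiseSd Gaussian noise SD (dF/F0 fraction).
#' @param bleachRate linear decline, dF/F0 fraction per second.
#' @param sampleRate sampling rate, Hz (>= 100).
#' @return validated list of class "CaGenParams".
#' @export
caGenParams <- function(ampPerUS = 0.05, lagMeanMs = 50, lagSdMs = 10,
                        tauOn = 0.15, tauOff = 2, noiseSd = 0.005,
                        bleachRate = 0.02, sampleRate = 100) {
  stopifnot(ampPerUS >= 0, lagMeanMs >= 0, lagSdMs >= 0,
            tauOn > 0, tauOff > 0, noiseSd >= 0, bleachRate >= 0,
            sampleRate >= 100)
  if (tauOn < 0.05 || tauOn > 0.5 || tauOff < 1.5 || tauOff > 10)
    warning("time constants outside the standard fit bounds ",
            "(tauOn 0.05-0.5 s, tauOff 1.5-10 s)")
  structure(list(ampPerUS = ampPerUS, lagMeanMs = lagMeanMs,
                 lagSdMs = lagSdMs, tauOn = tauOn, tauOff = tauOff,
                 noiseSd = noiseSd, bleachRate = bleachRate,
                 sampleRate = sampleRate),
            class = "CaGenParams")
}

.rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
  }
  out
}

#' Simulate a calcium trace for a spike trial
#'
#' Builds the dF/F0 trace implied by a spike trial's ground truth: one
#' stepwise double-exponential component per embedded burst, with onset
#' t0_k = (first spike of burst k) - lag_k and amplitude `ampPerUS`,
#' plus a linear photobleaching decline over the whole recording and
#' additive Gaussian noise. Onsets and amplitude steps are written
#' back into the returned truth. With `output = "raw"` the trace is
#' returned in fluorescence counts, F(t) = f0Level * (1 + dff(t)), for
#' exercising [computeDFF()].
#'
#' @param sim result of [simulateSpikeTrial()] (list with `train` and
#'   `truth`).
#' @param params a [caGenParams()] list.
#' @param seed optional integer seed.
#' @param output "dff" (default) or "raw".
#' @param f0Level baseline fluorescence in counts for raw output.
#' @param postS recording continues this long after the stimulus ends
#'   (default 6 s), so the slow transient tail decays within the trace
#'   and the bleaching trend is identifiable from event-free samples.
#' @return list with `trace` ([FluorTrace-class]) and the updated
#'   `truth` (fields `true_onsets_s`, `true_amplitude_steps`).
#' @export
simulateCalciumTrace <- function(sim, params = caGenParams(), seed = NULL,
                                 output = c("dff", "raw"),
                                 f0Level = 500, postS = 6) {
  output <- match.arg(output)
  stopifnot(inherits(params, "CaGenParams"), is.list(sim),
            !is.null(sim$train), !is.null(sim$truth))
  train <- sim$train
  truth <- sim$truth
  gen <- function() {
    dur <- max(c(spikeTimes(train), stimWindow(train)[2])) + postS
    tt <- seq(0, dur, by = 1 / params$sampleRate)
    nB <- length(truth$burst_first_spike_s)
    clean <- numeric(length(tt))
    onsets <- numeric(0)
    steps <- numeric(0)
    if (nB > 0L) {
      lags <- .rtrunc_norm_pos(nB, params$lagMeanMs, params$lagSdMs) / 1000
      onsets <- truth$burst_first_spike_s - lags
      steps <- rep(params$ampPerUS, nB)
      for (k in seq_len(nB))
        clean <- clean + caTransientModel(tt, steps[k], onsets[k],
                                          params$tauOn, params$tauOff)
    }
    sw <- stimWindow(train)
    # continuous excitation illumination: linear decline over the
    # whole recording
    bleach <- -params$bleachRate * tt
    dff <- clean + bleach + stats::rnorm(length(tt), 0, params$noiseSd)
    vals <- if (output == "dff") dff else f0Level * (1 + dff)
    truth$true_onsets_s <- onsets
    truth$true_amplitude_steps <- steps
    list(
      trace = FluorTrace(tt, vals, baselineWindow = c(0, sw[1]),
                         stimWindow = sw,
                         unit = if (output == "dff") "dff" else "raw"),
      truth = truth
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a SuperClomeleon YFP/CFP channel pair
#'
#' Emulates a stimulus-evoked chloride drop: the background-subtracted
#' YFP signal rises during the stimulus by up to `clDropFraction` of
#' its baseline (Cl- unquenching of YFP) along a saturating
#' exponential with time constant `tauOn`, recovers exponentially with
#' `tauOff` after the stimulus ends, the CFP signal stays flat, and
#' both channels share a common additive background level. The
#' ground-truth peak ratio change is returned alongside.
#'
#' @param clDropFraction fractional YFP rise at the response peak
#'   (>= 0).
#' @param noiseSd per-channel Gaussian noise SD, in counts.
#' @param seed optional integer seed.
#' @param duration,stimWindow trial timing, s.
#' @param sampleRate frames per second (default 30).
#' @param yfp0,cfp0,background baseline region-mean count levels.
#' @param tauOn,tauOff response time constants, s.
#' @return list with `frames` ([FretFrameSet-class]) and
#'   `truth = list(delta_r_peak)`.
#' @export
simulateFretPair <- function(clDropFraction, noiseSd = 0, seed = NULL,
                             duration = 3, stimWindow = c(1, 2),
                             sampleRate = 30, yfp0 = 200, cfp0 = 150,
                             background = 100, tauOn = 0.15,
                             tauOff = 2) {
  stopifnot(clDropFraction >= 0, noiseSd >= 0)
  gen <- function() {
    tt <- seq(0, duration, by = 1 / sampleRate)
    # saturating rise during the stimulus, exponential recovery after
    profile <- numeric(length(tt))
    up <- tt > stimWindow[1] & tt <= stimWindow[2]
    profile[up] <- 1 - exp(-(tt[up] - stimWindow[1]) / tauOn)
    peak_end <- 1 - exp(-(stimWindow[2] - stimWindow[1]) / tauOn)
    post <- tt > stimWindow[2]
    profile[post] <- peak_end * exp(-(tt[post] - stimWindow[2]) / tauOff)
    yfp_cell <- background + yfp0 * (1 + clDropFraction * profile) +
      stats::rnorm(length(tt), 0, noiseSd)
    cfp_cell <- background + cfp0 + stats::rnorm(length(tt), 0, noiseSd)
    yfp_bg <- background + stats::rnorm(length(tt), 0, noiseSd)
    cfp_bg <- background + stats::rnorm(length(tt), 0, noiseSd)
    frames <- FretFrameSet(tt, yfp_cell, yfp_bg, cfp_cell, cfp_bg,
                           baselineWindow = c(0, stimWindow[1]),
                           stimWindow = stimWindow)
    r0 <- yfp0 / cfp0
    keep <- tt >= stimWindow[1] & tt <= stimWindow[2]
    truth <- list(delta_r_peak =
                    r0 * clDropFraction * max(profile[keep]))
    list(frames = frames, truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
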