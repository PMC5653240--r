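#' Normalize a raw fluorescence trace to dF/F0
#'
#' dF/F0 = (F_n - F0) / F0 with F0 the mean fluorescence over a short
#' window immediately before stimulus onset (default: the final 100 ms
#' of the baseline window). The slow fluorescence decline during
#' irradiation (photobleaching) can be removed before normalization by
#' fitting a linear or exponential decay to samples outside detected
#' events and subtracting it.
#'
#' @param raw a raw-unit [FluorTrace-class].
#' @param decayModel "linear" (default), "none" or "exponential".
#' @param f0Window optional (start, end) s for F0; default is the last
#'   `f0SpanS` seconds of the baseline window.
#' @param f0SpanS length of the default F0 window, s (default 0.1).
#' @param highK,lowK Schmitt thresholds used to exclude event samples
#'   from the decay fit (see [detectTransients()]).
#' @return a [FluorTrace-class] with unit "dff".
#' @export
computeDFF <- function(raw, decayModel = c("linear", "none", "exponential"),
                       f0Window = NULL, f0SpanS = 0.1,
                       highK = 4, lowK = 1) {
  decayModel <- match.arg(decayModel)
  stopifnot(is(raw, "FluorTrace"))
  tt <- traceTime(raw)
  yy <- traceValues(raw)
  bw <- baselineWindow(raw)
  if (is.null(f0Window)) f0Window <- c(bw[2] - f0SpanS, bw[2])
  # right-open: the sample at stimulus onset is not "before" it
  in_f0 <- tt >= f0Window[1] & tt < f0Window[2] - 1e-12
  if (sum(in_f0) < 2L) stop("F0 window contains fewer than 2 samples")
  f0 <- mean(yy[in_f0])
  if (f0 <= 0) stop("F0 must be positive")
  dff <- (yy - f0) / f0
  out <- FluorTrace(tt, dff, baselineWindow = bw,
                    stimWindow = stimWindow(raw), unit = "dff")

  if (decayModel != "none")
    out <- subtractDecay(out, decayModel = decayModel,
                         anchorWindow = f0Window,
                         highK = highK, lowK = lowK)
  out
}

#' Subtract a slow fluorescence decay from a dF/F0 trace
#'
#' Fits a linear or exponential decline to samples outside detected
#' transient events (Schmitt trigger on the uncorrected trace),
#' subtracts it, and re-anchors the trace so the anchor window (the F0
#' window by default) averages zero. Used internally by [computeDFF()]
#' and applicable directly to traces already in dF/F0 or ratio units.
#'
#' @param trace a [FluorTrace-class] (unit "dff" or "dr").
#' @param decayModel "linear" (default) or "exponential".
#' @param anchorWindow (start, end) s re-zeroed after subtraction;
#'   default is the final 100 ms of the baseline window.
#' @param highK,lowK Schmitt thresholds used to exclude event samples
#'   from the trend fit.
#' @param padS exclusion padding around each detected event, s: the
#'   slow sub-threshold tail of a transient would otherwise bias the
#'   trend (default 0.1 s before onset, `padS` after offset).
#' @return the corrected [FluorTrace-class].
#' @export
subtractDecay <- function(trace, decayModel = c("linear", "exponential"),
                          anchorWindow = NULL, highK = 4, lowK = 1,
                          padS = 1) {
  decayModel <- match.arg(decayModel)
  stopifnot(is(trace, "FluorTrace"))
  tt <- traceTime(trace)
  yy <- traceValues(trace)
  bw <- baselineWindow(trace)
  if (is.null(anchorWindow)) anchorWindow <- c(bw[2] - 0.1, bw[2])
  anchor <- tt >= anchorWindow[1] & tt <= anchorWindow[2]
  ev <- tryCatch(detectTransients(trace, highK = highK, lowK = lowK),
                 error = function(e) NULL)
  excl <- rep(FALSE, length(tt))
  if (!is.null(ev) && nrow(ev))
    for (k in seq_len(nrow(ev)))
      excl[tt >= ev$onset_time[k] - 0.1 &
           tt <= ev$offset_time[k] + padS] <- TRUE
  use <- !excl
  if (sum(use) < 3L || !any(anchor)) return(trace)
  trend <- switch(decayModel,
    linear = {
      fit <- stats::lm(y ~ t, data = data.frame(t = tt[use], y = yy[use]))
      stats::predict(fit, newdata = data.frame(t = tt))
    },
    exponential = {
      df <- data.frame(t = tt[use], y = yy[use])
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ c0 + a * exp(-k * t), data = df,
                          start = list(c0 = 0,
                                       a = max(df$y) - min(df$y),
                                       k = 0.1)),
        error = function(e) NULL)
      if (is.null(fit)) {
        lf <- stats::lm(y ~ t, data = df)
        stats::predict(lf, newdata = data.frame(t = tt))
      } else {
        stats::predict(fit, newdata = data.frame(t = tt))
      }
    })
  corrected <- yy - trend
  corrected <- corrected - mean(corrected[anchor])
  FluorTrace(tt, corrected, baselineWindow = bw,
             stimWindow = stimWindow(trace), unit = trace@unit)
}

#' Schmitt-trigger detection of fluorescence transients
#'
#' Dual-threshold (hysteresis) event detection: an event opens when the
#' trace stays at least `highK` baseline SDs above the baseline mean for
#' `minOpenSamples` consecutive samples, and closes when it falls below
#' `lowK` SDs. While an event is open it cannot re-trigger. Baseline
#' mean and SD are estimated from the trace's baseline window. The
#' two-sample opening requirement rejects single-sample noise
#' excursions, which are uncorrelated at the sampling rates used here,
#' while real transients (rise time constant >= 50 ms) stay above
#' threshold for many samples.
#'
#' @param trace a dF/F0 or dR [FluorTrace-class].
#' @param highK opening threshold in baseline SDs (default 4).
#' @param lowK closing threshold in baseline SDs (default 1).
#' @param minOpenSamples consecutive super-threshold samples required to
#'   open an event (default 2).
#' @param baselineSD optional explicit SD override (required when the
#'   baseline has zero variance, e.g. noiseless synthetic traces).
#' @return data.frame with one row per event: `onset_idx`, `offset_idx`,
#'   `onset_time`, `offset_time`, `peak` (max value over the event).
#' @export
detectTransients <- function(trace, highK = 4, lowK = 1,
                             minOpenSamples = 2L, baselineSD = NULL) {
  stopifnot(is(trace, "FluorTrace"), highK > lowK)
  tt <- traceTime(trace)
  yy <- traceValues(trace)
  bw <- baselineWindow(trace)
  # right-open: the sample at the window's end belongs to the stimulus
  base <- yy[tt >= bw[1] & tt < bw[2] - 1e-12]
  if (length(base) < 3L) stop("baseline window contains too few samples")
  mu <- mean(base)
  sdv <- if (is.null(baselineSD)) stats::sd(base) else baselineSD
  if (!is.finite(sdv) || sdv <= 0)
    stop("baseline SD is zero; pass an explicit baselineSD override")
  hi <- mu + highK * sdv
  lo <- mu + lowK * sdv

  above <- yy >= hi
  n <- length(yy)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      run_end <- i
      while (run_end < n && above[run_end + 1L]) run_end <- run_end + 1L
      if (run_end - i + 1L >= minOpenSamples) {
        onset <- i
        j <- run_end
        while (j < n && yy[j + 1L] >= lo) j <- j + 1L  # hysteresis close
        out[[length(out) + 1L]] <- c(onset, j)
        i <- j + 1L
      } else {
        i <- run_end + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(onset_idx = integer(0), offset_idx = integer(0),
                      onset_time = numeric(0), offset_time = numeric(0),
                      peak = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(
    onset_idx = m[, 1L], offset_idx = m[, 2L],
    onset_time = tt[m[, 1L]], offset_time = tt[m[, 2L]],
    peak = vapply(seq_len(nrow(m)),
                  function(k) max(yy[m[k, 1L]:m[k, 2L]]), 1)
  )
}

#' Peak fluorescence change during the stimulus epoch
#'
#' F_peak (or dR_peak for ratiometric traces): the maximum of the trace
#' over the stimulus window.
#'
#' @param trace a dF/F0 or dR [FluorTrace-class].
#' @return numeric peak value.
#' @export
peakAmplitude <- function(trace) {
  stopifnot(is(trace, "FluorTrace"))
  sw <- stimWindow(trace)
  keep <- traceTime(trace) >= sw[1] & traceTime(trace) <= sw[2]
  if (!any(keep)) stop("stimulus window contains no samples")
  max(traceValues(trace)[keep])
}

#' Align traces at the first-US end timings
#'
#' Shifts each trial's fluorescence trace so that the last spike of its
#' first US maps to time 0, interpolates the shifted traces onto a
#' common grid, and computes the ensemble mean. Aligning at the burst
#' end removes trial-to-trial jitter in burst timing and sharpens the
#' mean onset. Trials without a US are skipped with a message.
#'
#' @param trials list of `list(trace = FluorTrace, train = SpikeTrain)`.
#' @param isiBurstMaxMs,isiPauseMinMs US detector thresholds (ms).
#' @return list with `aligned` (list of data.frames time/value on the
#'   shifted axis), `grid`, `mean` (ensemble mean on `grid`), `shifts`,
#'   and `skipped` (trial ids without a US).
#' @export
alignAtFirstUSEnd <- function(trials, isiBurstMaxMs = 9,
                              isiPauseMinMs = 20) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  aligned <- list()
  shifts <- numeric(0)
  skipped <- character(0)
  for (tr in trials) {
    ev <- detectUS(tr$train, isiBurstMaxMs, isiPauseMinMs)
    if (!nrow(ev)) {
      skipped <- c(skipped, trialId(tr$train))
      message("trial '", trialId(tr$train), "' has no US; skipped")
      next
    }
    shift <- ev$t3[1L]
    aligned[[length(aligned) + 1L]] <-
      data.frame(time = traceTime(tr$trace) - shift,
                 value = traceValues(tr$trace))
    shifts <- c(shifts, shift)
  }
  if (!length(aligned)) stop("no trial contains a US")
  dt <- stats::median(diff(aligned[[1L]]$time))
  lo <- max(vapply(aligned, function(a) min(a$time), 1))
  hi <- min(vapply(aligned, function(a) max(a$time), 1))
  grid <- seq(lo, hi, by = dt)
  mat <- vapply(aligned, function(a)
    stats::approx(a$time, a$value, xout = grid)$y, numeric(length(grid)))
  list(aligned = aligned, grid = grid,
       mean = rowMeans(as.matrix(mat)), shifts = shifts, skipped = skipped)
}

#' Peak amplitude versus US count across trials
#'
#' Per-trial pairs of total US number and F_peak, with the Spearman rank
#' correlation (monotone association) and a least-squares line.
#'
#' @param trials list of `list(trace = FluorTrace, train = SpikeTrain)`;
#'   traces must be in dF/F0 (or dR) units.
#' @param isiBurstMaxMs,isiPauseMinMs US detector thresholds (ms).
#' @return list with `table` (data.frame trial_id, us_count, f_peak),
#'   `rho`, `p`, and `line` (intercept, slope), or `rho = NA` with a
#'   `degenerate` flag when all US counts are equal.
#' @export
amplitudeVsUSCount <- function(trials, isiBurstMaxMs = 9,
                               isiPauseMinMs = 20) {
  stopifnot(is.list(trials), length(trials) >= 3L)
  tab <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(
      trial_id = trialId(tr$train),
      us_count = nrow(detectUS(tr$train, isiBurstMaxMs, isiPauseMinMs)),
      f_peak = peakAmplitude(tr$trace)
    )
  }))
  if (length(unique(tab$us_count)) < 2L)
    return(list(table = tab, rho = NA_real_, p = NA_real_, line = NULL,
                degenerate = TRUE))
  sp <- spearmanAssoc(tab$us_count, tab$f_peak)
  fit <- stats::lm(f_peak ~ us_count, data = tab)
  list(table = tab, rho = sp$rho, p = sp$p,
       line = stats::coef(fit), degenerate = FALSE)
}
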