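#' Detect unconventional spikes (three-spike bursts with a pause)
#'
#' An unconventional spike (US) is the signature of burst-and-pause firing
#' in Class IV nociceptors: within four sequential spikes, the first and
#' second interspike intervals (ISIs) are both shorter than
#' `isiBurstMaxMs` and the third ISI is longer than `isiPauseMinMs`.
#' The first three spikes of a matching quadruple form the US; the third
#' ISI is the pause that follows it. Both comparisons are strict.
#'
#' The train is scanned left to right; when a quadruple matches, the scan
#' resumes at the spike after the matched triple, so USs never share
#' spikes (greedy resolution).
#'
#' @param train a [SpikeTrain-class].
#' @param isiBurstMaxMs upper bound (exclusive) on the two intra-burst
#'   ISIs, milliseconds. Default 9 ms.
#' @param isiPauseMinMs lower bound (exclusive) on the ISI that follows
#'   the burst, milliseconds. Default 20 ms.
#' @return data.frame with one row per US: spike indices `i1,i2,i3`,
#'   times `t1,t2,t3` (s), the two intra-burst ISIs and the following
#'   ISI in ms. Zero rows when fewer than 4 spikes.
#' @examples
#' st <- SpikeTrain(c(0.100, 0.108, 0.116, 0.140), stimWindow = c(0, 1))
#' detectUS(st)
#' @export
detectUS <- function(train, isiBurstMaxMs = 9, isiPauseMinMs = 20) {
  stopifnot(is(train, "SpikeTrain"),
            isiBurstMaxMs > 0, isiPauseMinMs > 0)
  t <- spikeTimes(train)
  empty <- data.frame(i1 = integer(0), i2 = integer(0), i3 = integer(0),
                      t1 = numeric(0), t2 = numeric(0), t3 = numeric(0),
                      isi1_ms = numeric(0), isi2_ms = numeric(0),
                      following_isi_ms = numeric(0))
  n <- length(t)
  if (n < 4L) return(empty)
  if (is.unsorted(t, strictly = TRUE))
    stop("spike times must be strictly increasing")
  isi_ms <- diff(t) * 1000
  # strict comparisons with a 1e-9 ms guard so an ISI exactly at a
  # threshold is never misclassified by floating-point representation
  eps <- 1e-9
  out <- vector("list", 0L)
  i <- 1L
  while (i <= n - 3L) {
    if (isi_ms[i] < isiBurstMaxMs - eps &&
        isi_ms[i + 1L] < isiBurstMaxMs - eps &&
        isi_ms[i + 2L] > isiPauseMinMs + eps) {
      out[[length(out) + 1L]] <- c(i, i + 1L, i + 2L)
      i <- i + 3L  # resume after the matched triple
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  idx <- do.call(rbind, out)
  data.frame(
    i1 = idx[, 1L], i2 = idx[, 2L], i3 = idx[, 3L],
    t1 = t[idx[, 1L]], t2 = t[idx[, 2L]], t3 = t[idx[, 3L]],
    isi1_ms = isi_ms[idx[, 1L]], isi2_ms = isi_ms[idx[, 2L]],
    following_isi_ms = isi_ms[idx[, 3L]]
  )
}

#' Pause periods of detected unconventional spikes
#'
#' The pause of a US is the interval from its last spike to the next
#' spike (the defining quadruple's third ISI). USs that occurred around
#' the shutdown of the stimulus are excluded: a US whose last spike has
#' no further spike within the stimulus window — either because no later
#' spike exists or because the next spike falls after the stimulus end —
#' has an undefined pause and contributes nothing.
#'
#' @param events data.frame from [detectUS()] on the same train.
#' @param train the [SpikeTrain-class] the events came from.
#' @return numeric vector of pause durations in milliseconds (possibly
#'   shorter than `nrow(events)`).
#' @examples
#' st <- SpikeTrain(c(0.100, 0.108, 0.116, 0.220), stimWindow = c(0, 1))
#' pausePeriods(detectUS(st), st)  # 104 ms
#' @export
pausePeriods <- function(events, train) {
  stopifnot(is(train, "SpikeTrain"), is.data.frame(events))
  if (!nrow(events)) return(numeric(0))
  t <- spikeTimes(train)
  if (max(events$i3) + 1L > length(t) + 1L ||
      any(abs(t[events$i3] - events$t3) > 1e-9))
    stop("events do not match the supplied train")
  stim_end <- stimWindow(train)[2]
  out <- numeric(0)
  for (k in seq_len(nrow(events))) {
    i3 <- events$i3[k]
    if (i3 + 1L > length(t)) next           # no further spike at all
    nxt <- t[i3 + 1L]
    if (nxt > stim_end) next                # next spike after stimulus end
    out <- c(out, (nxt - t[i3]) * 1000)
  }
  out
}

#' ISI time course around the first US (or the minimum ISI)
#'
#' Tabulates interspike intervals at ordinal positions X in -8..2 around
#' a reference ISI for each trial. For trials with a US, ISI_0 is the ISI
#' terminating at the first US's last spike, ISI_1 is that US's pause,
#' and negative X counts backward through the ISIs preceding the US:
#' ISI_-1 is the ISI terminating at the US's first spike. For trials
#' without a US, a window of 11 consecutive ISIs is positioned so the
#' trial's minimum ISI sits at X = 0 (a documented convention, flagged in
#' the result's `"window_convention"` attribute). Positions outside the
#' trial are NA.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param isiBurstMaxMs,isiPauseMinMs US detector thresholds (ms).
#' @return data.frame with columns `trial_id`, `group` ("US"/"non-US"),
#'   `X` (-8..2) and `isi_ms`.
#' @export
isiTimeCourse <- function(trains, isiBurstMaxMs = 9, isiPauseMinMs = 20) {
  stopifnot(is.list(trains))
  xs <- -8:2
  rows <- lapply(trains, function(tr) {
    t <- spikeTimes(tr)
    isi <- diff(t) * 1000
    ev <- detectUS(tr, isiBurstMaxMs, isiPauseMinMs)
    if (nrow(ev)) {
      # X = 0: ISI ending at the first US's last spike (isi index i2);
      # X >= 1: pause and onward (from isi index i3); X <= -1: ISIs
      # preceding the US, anchored at its first spike (isi index i1 + X)
      j <- ifelse(xs >= 1L, ev$i3[1L] + xs - 1L,
                  ifelse(xs == 0L, ev$i2[1L], ev$i1[1L] + xs))
      grp <- "US"
    } else {
      if (!length(isi)) return(NULL)
      j <- which.min(isi) + xs
      grp <- "non-US"
    }
    vals <- ifelse(j >= 1L & j <= length(isi), isi[pmax(j, 1L)], NA_real_)
    data.frame(trial_id = trialId(tr), group = grp, X = xs, isi_ms = vals)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trial_id = character(0), group = character(0),
                      X = integer(0), isi_ms = numeric(0))
  attr(out, "window_convention") <-
    "non-US trials: 11-ISI window placed with the minimum ISI at X=0"
  out
}

#' Firing-rate trace by centered boxcar
#'
#' Spike count in a centered window of `windowMs`, divided by the window
#' length, evaluated every `stepMs` on a uniform grid covering the trial
#' (from 0 to the later of the last spike and the stimulus end).
#'
#' @param train a [SpikeTrain-class].
#' @param windowMs boxcar width, ms (default 100).
#' @param stepMs grid step, ms (default 10).
#' @return list with `time` (s), `rate` (Hz), `windowMs`, `stepMs` and
#'   the train's `stimWindow`.
#' @export
firingRateTrace <- function(train, windowMs = 100, stepMs = 10) {
  stopifnot(is(train, "SpikeTrain"), windowMs > stepMs, stepMs > 0)
  t <- spikeTimes(train)
  w <- windowMs / 1000
  t_end <- max(c(t, stimWindow(train)[2]))
  grid <- seq(0, t_end, by = stepMs / 1000)
  if (length(t)) {
    # count spikes in [g - w/2, g + w/2)
    cnt <- findInterval(grid + w / 2 - 1e-12, t) -
           findInterval(grid - w / 2 - 1e-12, t)
    rate <- cnt / w
  } else {
    rate <- numeric(length(grid))
  }
  list(time = grid, rate = rate, windowMs = windowMs, stepMs = stepMs,
       stimWindow = stimWindow(train))
}

#' Count peaks of a firing-rate trace
#'
#' Counts local maxima of the firing-rate trace that reach at least
#' `minPeakRateHz` and are separated from their neighbours by troughs
#' falling below `minTroughFraction` times the smaller of the two
#' flanking peaks ("peak number of firing-rate fluctuations"). Peaks not
#' separated by a qualifying trough are merged and counted once.
#'
#' @param trace result of [firingRateTrace()].
#' @param minPeakRateHz minimum peak height, Hz. The default (25 Hz) sits
#'   between the rate contributed by a single background spike in the
#'   100-ms boxcar (10 Hz) and that of a 3-spike burst (30 Hz).
#' @param minTroughFraction trough criterion in (0, 1), default 0.5.
#' @param window optional (start, end) s restricting the count (e.g. the
#'   stimulus window, the epoch over which the metric is defined).
#' @return integer peak count.
#' @export
countRatePeaks <- function(trace, minPeakRateHz = 25,
                           minTroughFraction = 0.5, window = NULL) {
  stopifnot(minPeakRateHz > 0,
            minTroughFraction > 0, minTroughFraction < 1)
  r <- trace$rate
  tt <- trace$time
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    r <- r[keep]
  }
  n <- length(r)
  if (n < 3L || all(r <= 0)) return(0L)
  # local maxima (plateau-aware: first sample of a plateau counts)
  cand <- which(diff(sign(diff(c(-Inf, r, -Inf)))) < 0)
  cand <- cand[r[cand] >= minPeakRateHz]
  if (!length(cand)) return(0L)
  kept <- cand[1L]
  for (p in cand[-1L]) {
    last <- kept[length(kept)]
    trough <- min(r[last:p])
    if (trough < minTroughFraction * min(r[last], r[p])) {
      kept <- c(kept, p)
    } else if (r[p] > r[last]) {
      kept[length(kept)] <- p  # merge: keep the higher summit
    }
  }
  length(kept)
}

#' Spontaneous firing rate before the stimulus
#'
#' Spike count in the pre-stimulus epoch divided by its duration.
#'
#' @param train a [SpikeTrain-class] with `stimWindow[1] > 0`.
#' @return rate in Hz.
#' @export
spontaneousRate <- function(train) {
  stopifnot(is(train, "SpikeTrain"))
  t0 <- stimWindow(train)[1]
  if (t0 <= 0) stop("pre-stimulus epoch has zero length")
  sum(spikeTimes(train) < t0) / t0
}

#' Classify trials by the presence of unconventional spikes
#'
#' A trial is labeled with-US iff [detectUS()] returns at least one
#' event.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param isiBurstMaxMs,isiPauseMinMs detector thresholds (ms).
#' @return data.frame with columns `trial_id`, `us_count`, `has_us`.
#' @export
classifyTrials <- function(trains, isiBurstMaxMs = 9, isiPauseMinMs = 20) {
  stopifnot(is.list(trains))
  us <- vapply(trains, function(tr)
    nrow(detectUS(tr, isiBurstMaxMs, isiPauseMinMs)), 1L)
  data.frame(
    trial_id = vapply(trains, trialId, character(1)),
    us_count = us,
    has_us = us >= 1L
  )
}

#' Per-trial spike metrics table
#'
#' Convenience summary used by the cohort pipeline: US count, number of
#' firing-rate peaks in the stimulus window, maximum firing rate, median
#' pause, and spontaneous rate for each trial.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param isiBurstMaxMs,isiPauseMinMs,rateWindowMs,rateStepMs,minPeakRateHz,minTroughFraction
#'   analysis parameters, see the individual functions.
#' @return data.frame, one row per trial.
#' @export
spikeMetrics <- function(trains, isiBurstMaxMs = 9, isiPauseMinMs = 20,
                         rateWindowMs = 100, rateStepMs = 10,
                         minPeakRateHz = 25, minTroughFraction = 0.5) {
  rows <- lapply(trains, function(tr) {
    ev <- detectUS(tr, isiBurstMaxMs, isiPauseMinMs)
    pauses <- pausePeriods(ev, tr)
    fr <- firingRateTrace(tr, rateWindowMs, rateStepMs)
    data.frame(
      trial_id = trialId(tr),
      us_count = nrow(ev),
      peak_count = countRatePeaks(fr, minPeakRateHz, minTroughFraction,
                                  window = stimWindow(tr)),
      max_rate_hz = max(fr$rate),
      median_pause_ms = if (length(pauses)) stats::median(pauses) else NA_real_,
      n_pauses = length(pauses),
      spont_rate_hz = if (stimWindow(tr)[1] > 0) spontaneousRate(tr)
                      else NA_real_
    )
  })
  do.call(rbind, rows)
}
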