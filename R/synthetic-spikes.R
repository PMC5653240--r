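#' Parameters for the synthetic spike-trial generator
#'
#' Bundles and validates the settings of [simulateSpikeTrial()]. The
#' defaults describe a 3-s trial with a 1-s stimulus (1-2 s), sparse
#' spontaneous firing (1 Hz), moderate non-burst background firing
#' during the stimulus (3 Hz; the burst motifs carry the
#' high-frequency content), three embedded 3-spike bursts with
#' intra-burst ISIs of 4-8 ms, and gamma-distributed pauses with a
#' median of 104 ms (shape 3) — the control-genotype pause regime.
#'
#' @param duration trial length, s.
#' @param stimWindow (start, end) s; must lie within the trial.
#' @param baselineRate spontaneous rate outside the stimulus, Hz.
#' @param stimRate non-burst background rate inside the stimulus, Hz.
#' @param nUS number of embedded burst motifs.
#' @param intraBurstIsiRangeMs (low, high) ms for the two intra-burst
#'   ISIs; high must stay below the 9-ms detector bound.
#' @param pauseDist list(family = "gamma"|"lognormal",
#'   median_ms, shape); the median must exceed the 20-ms pause bound.
#'   For the lognormal family `shape` is sdlog.
#' @param suppress suppress background spikes through each burst span
#'   and its pause (default TRUE; FALSE gives the "leaky" mode used for
#'   robustness checks).
#' @return validated list of class "TrialGenParams".
#' @export
trialGenParams <- function(duration = 3, stimWindow = c(1, 2),
                           baselineRate = 1, stimRate = 3, nUS = 3,
                           intraBurstIsiRangeMs = c(4, 8),
                           pauseDist = list(family = "gamma",
                                            median_ms = 104, shape = 3),
                           suppress = TRUE) {
  stopifnot(duration > 0, length(stimWindow) == 2L,
            stimWindow[1] >= 0, stimWindow[2] <= duration,
            stimWindow[1] < stimWindow[2],
            baselineRate >= 0, stimRate >= 0, nUS >= 0,
            length(intraBurstIsiRangeMs) == 2L,
            intraBurstIsiRangeMs[1] > 0,
            intraBurstIsiRangeMs[1] <= intraBurstIsiRangeMs[2])
  if (intraBurstIsiRangeMs[2] >= 9)
    stop("intra-burst ISI upper bound must stay below 9 ms")
  stopifnot(pauseDist$family %in% c("gamma", "lognormal"),
            pauseDist$median_ms > 20, pauseDist$shape > 0)
  structure(list(duration = duration, stimWindow = stimWindow,
                 baselineRate = baselineRate, stimRate = stimRate,
                 nUS = as.integer(nUS),
                 intraBurstIsiRangeMs = intraBurstIsiRangeMs,
                 pauseDist = pauseDist, suppress = isTRUE(suppress)),
            class = "TrialGenParams")
}

.draw_pause_ms <- function(n, pd) {
  draw <- function(m) {
    if (pd$family == "gamma") {
      # scale chosen so the distribution median equals median_ms
      scale <- pd$median_ms / stats::qgamma(0.5, shape = pd$shape)
      stats::rgamma(m, shape = pd$shape, scale = scale)
    } else {
      stats::rlnorm(m, meanlog = log(pd$median_ms), sdlog = pd$shape)
    }
  }
  # embedded pauses must satisfy the detector's > 20 ms predicate, so
  # the distribution is truncated just above the bound (median_ms is
  # the nominal untruncated median)
  out <- draw(n)
  bad <- out <= 20.01
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out <= 20.01
  }
  out
}

.poisson_times <- function(rate, from, to) {
  if (rate <= 0 || to <= from) return(numeric(0))
  n <- stats::rpois(1L, rate * (to - from))
  sort(stats::runif(n, from, to))
}

#' Simulate one spike trial with embedded burst-and-pause motifs
#'
#' Generates a homogeneous-Poisson background (baseline rate outside
#' the stimulus window, stimulus rate inside) and inserts `nUS` burst
#' motifs — three spikes with intra-burst ISIs drawn from the
#' configured range, followed by a pause drawn from the pause
#' distribution and terminated by a resumption spike at exactly the
#' pause end (when it falls inside the stimulus window). Background
#' spikes are suppressed through each burst span and its pause by
#' default, so embedded pauses are exactly recoverable; `suppress =
#' FALSE` gives a leaky variant. Spikes are sorted and duplicate-free.
#'
#' @param params a [trialGenParams()] list.
#' @param seed integer seed (optional; the generator is
#'   bit-reproducible for a fixed seed).
#' @param trialId identifier for the resulting train.
#' @return list with `train` ([SpikeTrain-class]) and `truth`, a list
#'   holding `us_spike_indices` (list of index triples into the final
#'   train), `burst_first_spike_s`, `burst_last_spike_s`,
#'   `true_pauses_ms`, and placeholders (`true_onsets_s`,
#'   `true_amplitude_steps`) filled by [simulateCalciumTrace()].
#' @examples
#' sim <- simulateSpikeTrial(trialGenParams(nUS = 2), seed = 1)
#' detectUS(sim$train)
#' @export
simulateSpikeTrial <- function(params = trialGenParams(), seed = NULL,
                               trialId = "sim") {
  stopifnot(inherits(params, "TrialGenParams"))
  gen <- function() {
    sw <- params$stimWindow
    stim_len <- sw[2] - sw[1]
    nUS <- params$nUS

    bursts <- list()
    if (nUS > 0L) {
      isis <- matrix(stats::runif(2L * nUS,
                                  params$intraBurstIsiRangeMs[1],
                                  params$intraBurstIsiRangeMs[2]) / 1000,
                     nrow = nUS)
      pauses <- .draw_pause_ms(nUS, params$pauseDist) / 1000
      spans <- rowSums(isis) + pauses
      free <- stim_len - sum(spans)
      if (free <= 0)
        stop("burst placement infeasible: total burst+pause time (",
             signif(sum(spans), 3), " s) exceeds the stimulus window (",
             signif(stim_len, 3), " s)")
      # motifs are kept apart by a minimum gap (one 100-ms rate-analysis
      # window when room allows) so adjacent bursts remain resolvable as
      # separate firing-rate fluctuations, as in recorded trains where
      # bursts are spread across the stimulus
      min_gap <- min(0.1, free / (2 * nUS + 2))
      slack <- free - nUS * min_gap
      gaps <- diff(c(0, sort(stats::runif(nUS)), 1))[seq_len(nUS)] *
        slack + min_gap
      start <- sw[1]
      for (k in seq_len(nUS)) {
        s1 <- start + gaps[k]
        t3 <- s1 + isis[k, 1L] + isis[k, 2L]
        bursts[[k]] <- list(
          spikes = c(s1, s1 + isis[k, 1L], t3),
          pause_s = pauses[k],
          resume = t3 + pauses[k]
        )
        start <- bursts[[k]]$resume
      }
    }

    bg <- c(.poisson_times(params$baselineRate, 0, sw[1]),
            .poisson_times(params$stimRate, sw[1], sw[2]),
            .poisson_times(params$baselineRate, sw[2], params$duration))
    if (params$suppress && length(bursts)) {
      for (b in bursts)
        bg <- bg[bg < b$spikes[1L] | bg > b$resume]
    }
    burst_spikes <- unlist(lapply(bursts, function(b)
      c(b$spikes, if (b$resume <= sw[2]) b$resume)))
    times <- sort(unique(c(bg, burst_spikes)))

    idx_of <- function(x) match(x, times)
    truth <- list(
      us_spike_indices = lapply(bursts, function(b) idx_of(b$spikes)),
      burst_first_spike_s = vapply(bursts, function(b) b$spikes[1L], 1),
      burst_last_spike_s = vapply(bursts, function(b) b$spikes[3L], 1),
      true_pauses_ms = vapply(bursts, function(b) b$pause_s * 1000, 1),
      true_onsets_s = numeric(0),
      true_amplitude_steps = numeric(0)
    )
    list(train = SpikeTrain(times, stimWindow = sw, trialId = trialId),
         truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a behavioral cohort with censored non-responders
#'
#' Draws response latencies from a lognormal distribution with the
#' given median, flags animals as non-responders (NR) either at random
#' with probability `nonresponseProb` or when the drawn latency exceeds
#' the observation window.
#'
#' @param n number of animals.
#' @param medianS latency median, s.
#' @param sdlog lognormal shape (default 0.4).
#' @param nonresponseProb probability of an unconditional NR
#'   (default 0.1).
#' @param windowS observation window, s (default 5).
#' @param seed optional integer seed.
#' @param group group label.
#' @return data.frame with columns `animal_id`, `group`, `latency_s`
#'   (NA for unconditional NRs), `nr`.
#' @export
simulateBehaviorCohort <- function(n, medianS, sdlog = 0.4,
                                   nonresponseProb = 0.1, windowS = 5,
                                   seed = NULL, group = "cohort") {
  stopifnot(n >= 1L, medianS > 0, windowS > 0,
            nonresponseProb >= 0, nonresponseProb <= 1)
  gen <- function() {
    lat <- stats::rlnorm(n, meanlog = log(medianS), sdlog = sdlog)
    hard_nr <- stats::runif(n) < nonresponseProb
    nr <- hard_nr | lat > windowS
    data.frame(
      animal_id = sprintf("%s_%03d", group, seq_len(n)),
      group = group,
      latency_s = ifelse(hard_nr, NA_real_, lat),
      nr = nr
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
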