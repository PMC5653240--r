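# Independent oracles and small fixture builders used across the suite.

# Brute-force US oracle: tests every sequential quadruple independently,
# then applies greedy left-to-right selection (next match must start
# after the previously matched triple). Kept deliberately simple and
# separate from the package's scanning implementation.
oracle_us_starts <- function(times, burst_max_ms = 9, pause_min_ms = 20) {
  n <- length(times)
  if (n < 4L) return(integer(0))
  matches <- integer(0)
  for (i in seq_len(n - 3L)) {
    d1 <- (times[i + 1L] - times[i]) * 1000
    d2 <- (times[i + 2L] - times[i + 1L]) * 1000
    d3 <- (times[i + 3L] - times[i + 2L]) * 1000
    if (d1 < burst_max_ms - 1e-9 && d2 < burst_max_ms - 1e-9 &&
        d3 > pause_min_ms + 1e-9)
      matches <- c(matches, i)
  }
  sel <- integer(0)
  last_end <- 0L
  for (i in matches) {
    if (i > last_end) {
      sel <- c(sel, i)
      last_end <- i + 2L
    }
  }
  sel
}

# Random spike train with a realistic mix of tight and loose ISIs so
# quadruple matches are common.
random_train <- function(seed, n = 40) {
  withr::with_seed(seed, {
    rates <- sample(c(30, 80, 200), n, replace = TRUE)
    times <- cumsum(stats::rexp(n, rates))
    SpikeTrain(times, stimWindow = c(0, max(times) + 0.1),
               trialId = paste0("rnd", seed))
  })
}

# Exhaustive grid-search oracle for the transient fit: for each grid
# point the amplitude is solved in closed form (linear least squares),
# and the lowest-RSS grid point wins.
oracle_grid_fit <- function(tt, yy,
                            t0_grid = seq(0.5, 2, by = 0.01),
                            tau_on_grid = c(0.05, 0.1, 0.15, 0.2, 0.3),
                            tau_off_grid = c(1.5, 2, 2.5, 3)) {
  best <- list(rss = Inf)
  for (ton in tau_on_grid) {
    for (toff in tau_off_grid) {
      for (t0 in t0_grid) {
        b <- caTransientModel(tt, 1, t0, ton, toff)
        denom <- sum(b^2)
        if (denom == 0) next
        A <- max(sum(b * yy) / denom, 0)
        rss <- sum((yy - A * b)^2)
        if (rss < best$rss)
          best <- list(rss = rss, t0 = t0, tau_on = ton,
                       tau_off = toff, A = A)
      }
    }
  }
  best
}

# Single-component noisy fixture used by the fit-recovery tests.
noisy_transient_trace <- function(seed, A = 0.1, t0 = 1.0,
                                  tau_on = 0.1, tau_off = 2.0,
                                  noise_sd = 0.2 * A, fs = 100,
                                  duration = 6) {
  withr::with_seed(seed, {
    tt <- seq(0, duration, by = 1 / fs)
    yy <- caTransientModel(tt, A, t0, tau_on, tau_off) +
      stats::rnorm(length(tt), 0, noise_sd)
    FluorTrace(tt, yy, baselineWindow = c(0, t0 - 0.05),
               stimWindow = c(t0 - 0.05, duration), unit = "dff")
  })
}

# Spike train built directly from ISIs in ms (first spike at start_ms).
train_from_isis_ms <- function(isis_ms, start_ms = 100, stim_end_s = 1) {
  times <- cumsum(c(start_ms, isis_ms)) / 1000
  SpikeTrain(times, stimWindow = c(0, stim_end_s))
}

# Per-square occupancy vector (row-block x col-block grid), used for
# square-level agreement between a predicted mask and ground truth.
square_occupancy <- function(mask, g = 34L) {
  nr <- ceiling(nrow(mask) / g)
  nc <- ceiling(ncol(mask) / g)
  occ <- matrix(FALSE, nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx))
    occ[unique(cbind((idx[, 1] - 1) %/% g + 1,
                     (idx[, 2] - 1) %/% g + 1))] <- TRUE
  as.vector(occ)
}
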