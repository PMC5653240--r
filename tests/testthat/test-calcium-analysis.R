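make_trace <- function(values, fs = 100, base_end = 1,
                       stim = c(1, 2), unit = "raw") {
  tt <- seq(0, by = 1 / fs, length.out = length(values))
  FluorTrace(tt, values, baselineWindow = c(0, base_end),
             stimWindow = stim, unit = unit)
}

test_that("dF/F0 normalization and its invariances", {
  # constant trace maps to identically zero
  tr <- make_trace(rep(500, 400))
  dff <- computeDFF(tr, decayModel = "none")
  expect_true(all(traceValues(dff) == 0))

  # F0 = 100, sample at 150 -> 50%
  v <- c(rep(100, 100), rep(150, 300))
  expect_equal(max(traceValues(computeDFF(make_trace(v),
                                          decayModel = "none"))), 0.5)

  # invariant to positive rescaling of the raw trace
  raw <- withr::with_seed(1, rep(200, 400) + rnorm(400, 0, 2) +
                            c(rep(0, 150), rep(30, 250)))
  d1 <- computeDFF(make_trace(raw), decayModel = "none")
  d2 <- computeDFF(make_trace(raw * 7.3), decayModel = "none")
  expect_equal(traceValues(d1), traceValues(d2), tolerance = 1e-12)

  # errors on invalid baselines
  expect_error(computeDFF(make_trace(rep(-5, 400)), "none"), "positive")

  # bleach-only raw trace: decay correction flattens it
  sim <- simulateSpikeTrial(trialGenParams(nUS = 0), seed = 2)
  ca <- simulateCalciumTrace(sim, caGenParams(noiseSd = 0.005),
                             seed = 2, output = "raw")
  corrected <- computeDFF(ca$trace, decayModel = "linear")
  expect_lt(mean(abs(traceValues(corrected))), 0.005)
})

test_that("Schmitt trigger opens high, closes low, never overlaps", {
  # clean step of 10 baseline SDs: one event at the crossing sample
  withr::with_seed(3, {
    v <- c(rnorm(100, 0, 0.01), rep(0.1, 100), rnorm(100, 0, 0.01))
  })
  tr <- make_trace(v, unit = "dff")
  ev <- detectTransients(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_idx, 101L)
  expect_equal(ev$peak, max(v[101:200]))

  # two separated transients: two ordered, non-overlapping events
  v2 <- c(rnorm(100, 0, 0.01), rep(0.1, 50), rnorm(80, 0, 0.01),
          rep(0.08, 50), rnorm(60, 0, 0.01))
  ev2 <- detectTransients(make_trace(v2, unit = "dff"))
  expect_equal(nrow(ev2), 2L)
  expect_true(all(ev2$onset_idx < ev2$offset_idx))
  expect_true(ev2$offset_idx[1] < ev2$onset_idx[2])

  # zero-variance baseline: explicit override required
  flat <- make_trace(c(rep(0, 100), rep(1, 50), rep(0, 50)),
                     unit = "dff")
  expect_error(detectTransients(flat), "baselineSD")
  ev3 <- detectTransients(flat, baselineSD = 0.01)
  expect_equal(nrow(ev3), 1L)
})

test_that("transient fit recovers its own model exactly and matches the
           closed-form peak location", {
  tt <- seq(0, 6, by = 0.01)
  y <- caTransientModel(tt, 0.1, 1.0, 0.1, 2.0)
  trc <- FluorTrace(tt, y, baselineWindow = c(0, 1),
                    stimWindow = c(1, 2), unit = "dff")
  fit <- fitTransient(trc, window = c(0.5, 6), nComponents = 1,
                      t0Inits = 1.1)
  expect_equal(fit@components$t0, 1.0, tolerance = 1e-3)
  expect_equal(fit@components$A, 0.1, tolerance = 1e-3)
  expect_equal(fit@tauOn, 0.1, tolerance = 1e-3)
  expect_equal(fit@tauOff, 2.0, tolerance = 1e-3)

  # fitted-model peak equals t0 + tauOn log(1 + tauOff/tauOn) within
  # one sample
  model_peak <- caTransientPeakTime(fit@components$t0, fit@tauOn,
                                    fit@tauOff)
  grid_peak <- tt[which.max(caTransientModel(tt, fit@components$A,
                                             fit@components$t0,
                                             fit@tauOn, fit@tauOff))]
  expect_lt(abs(model_peak - grid_peak), 0.01 + 1e-9)
  expect_equal(model_peak, caTransientPeakTime(1, 0.1, 2),
               tolerance = 1e-2)
})

test_that("model is exactly zero before onset", {
  tt <- seq(-1, 5, by = 0.01)
  y <- caTransientModel(tt, 0.2, 1.5, 0.1, 2)
  expect_true(all(y[tt <= 1.5] == 0))
  expect_true(all(y[tt > 1.51] > 0))
})

test_that("fit RSS never increases with added components", {
  sim <- simulateSpikeTrial(trialGenParams(), seed = 31)
  ca <- simulateCalciumTrace(sim, caGenParams(), seed = 31)
  trc <- subtractDecay(ca$trace)
  rss <- vapply(1:3, function(K)
    fitTransient(trc, window = c(0.8, 8), nComponents = K)@rss, 1)
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("noisy-fit onset recovery matches the grid-search oracle", {
  lm_err <- numeric(0)
  agree <- numeric(0)
  for (i in 1:50) {
    trc <- noisy_transient_trace(20000 + i)
    fit <- fitTransient(trc, window = c(0.5, 6), nComponents = 1,
                        t0Inits = seq(0.6, 2, by = 0.35))
    orc <- oracle_grid_fit(traceTime(trc), traceValues(trc))
    lm_err <- c(lm_err, abs(fit@components$t0 - 1.0))
    agree <- c(agree, abs(fit@components$t0 - orc$t0))
  }
  expect_lte(median(lm_err), 0.020)
  expect_lte(median(agree), 0.020)
})

test_that("onset lag conventions", {
  ev <- data.frame(i1 = 1, i2 = 2, i3 = 3, t1 = 1.00, t2 = 1.006,
                   t3 = 1.012, isi1_ms = 6, isi2_ms = 6,
                   following_isi_ms = 100)
  fit <- new("TransientFit",
             components = data.frame(t0 = 0.95, A = 0.1),
             tauOn = 0.1, tauOff = 2, rss = 0, nComponents = 1L,
             atBound = FALSE, converged = TRUE)
  expect_equal(onsetLag(fit, ev), -0.05)
  expect_equal(onsetLag(fit, ev, reference = "last_spike"),
               0.95 - 1.012)
  fit0 <- fit; fit0@components$t0 <- 1.00
  expect_equal(onsetLag(fit0, ev), 0)
  expect_error(onsetLag(fit, ev[0, ]), "undefined")
})

test_that("alignment at the first-US end removes onset jitter", {
  sims <- lapply(1:8, function(i) {
    s <- simulateSpikeTrial(trialGenParams(nUS = 1), seed = 800 + i)
    cc <- simulateCalciumTrace(s, caGenParams(noiseSd = 0.002),
                               seed = 800 + i)
    list(train = s$train, trace = cc$trace)
  })
  al <- alignAtFirstUSEnd(sims)
  expect_length(al$aligned, 8L)

  # identical trials at different offsets align exactly
  s1 <- sims[[1]]
  shift <- 0.3
  s2 <- list(train = SpikeTrain(spikeTimes(s1$train) + shift,
                                stimWindow = stimWindow(s1$train) + shift),
             trace = FluorTrace(traceTime(s1$trace) + shift,
                                traceValues(s1$trace),
                                baselineWindow =
                                  baselineWindow(s1$trace) + shift,
                                stimWindow = stimWindow(s1$trace) + shift,
                                unit = "dff"))
  al2 <- alignAtFirstUSEnd(list(s1, s2))
  expect_equal(al2$aligned[[1]]$value, al2$aligned[[2]]$value)
  expect_equal(al2$shifts[2] - al2$shifts[1], shift, tolerance = 1e-9)

  # aligned ensemble rises faster around 0 than an unaligned average
  grid <- al$grid
  rise_aligned <- mean(diff(al$mean[grid > -0.1 & grid < 0.3]))
  unaligned <- rowMeans(vapply(sims, function(x)
    traceValues(x$trace)[1:600], numeric(600)))
  tt <- traceTime(sims[[1]]$trace)[1:600]
  rise_unaligned <- mean(diff(unaligned[tt > 1.2 & tt < 1.6]))
  expect_gt(rise_aligned, rise_unaligned)

  # trials without USs are skipped
  no_us <- simulateSpikeTrial(trialGenParams(nUS = 0), seed = 1)
  ca_no <- simulateCalciumTrace(no_us, caGenParams(), seed = 1)
  expect_message(
    al3 <- alignAtFirstUSEnd(c(sims[1:2],
                               list(list(train = no_us$train,
                                         trace = ca_no$trace)))),
    "skipped")
  expect_length(al3$aligned, 2L)
})

test_that("amplitude-US association is detected when coupled and absent
           when decoupled", {
  trials <- lapply(1:25, function(i) {
    n <- 1L + (i - 1L) %% 5L
    s <- simulateSpikeTrial(trialGenParams(nUS = n), seed = 900 + i)
    cc <- simulateCalciumTrace(s, caGenParams(), seed = 900 + i)
    list(train = s$train, trace = subtractDecay(cc$trace))
  })
  res <- amplitudeVsUSCount(trials)
  expect_gt(res$rho, 0.7)
  expect_lt(res$p, 0.01)
  expect_gt(res$line["us_count"], 0)

  # perfectly monotone pairs
  tab <- spearmanAssoc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tab$rho, 1)

  # degenerate: all trials share one US count
  same <- trials[c(1, 6, 11)]  # all n = 1
  res2 <- amplitudeVsUSCount(same)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$rho))
})
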