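test_that("US detection applies the ISI thresholds strictly", {
  # two 8-ms ISIs followed by 24 ms: one US
  st <- SpikeTrain(c(0.100, 0.108, 0.116, 0.140), stimWindow = c(0, 1))
  ev <- detectUS(st)
  expect_equal(nrow(ev), 1L)
  expect_equal(unlist(ev[1, c("i1", "i2", "i3")], use.names = FALSE),
               1:3)
  expect_equal(ev$following_isi_ms, 24)

  # first ISI exactly 9 ms: not a US (strict inequality)
  expect_equal(nrow(detectUS(
    SpikeTrain(c(0.100, 0.109, 0.116, 0.140), stimWindow = c(0, 1)))), 0L)
  # third ISI exactly 20 ms: not a US
  expect_equal(nrow(detectUS(
    SpikeTrain(c(0.100, 0.108, 0.116, 0.136), stimWindow = c(0, 1)))), 0L)

  # fewer than 4 spikes: empty result
  expect_equal(nrow(detectUS(
    SpikeTrain(c(0.1, 0.108, 0.116), stimWindow = c(0, 1)))), 0L)
  # unsorted input rejected at construction
  expect_error(SpikeTrain(c(0.2, 0.1), stimWindow = c(0, 1)),
               "increasing")
})

test_that("US detection matches the brute-force oracle on random trains", {
  for (seed in 1:200) {
    tr <- random_train(seed)
    got <- detectUS(tr)$i1
    want <- oracle_us_starts(spikeTimes(tr))
    expect_identical(as.integer(got), as.integer(want),
                     info = paste("seed", seed))
  }
})

test_that("detector is translation-invariant and monotone under insertion", {
  for (seed in c(3, 17, 42)) {
    tr <- random_train(seed)
    shifted <- SpikeTrain(spikeTimes(tr) + 5,
                          stimWindow = stimWindow(tr) + 5)
    e1 <- detectUS(tr); e2 <- detectUS(shifted)
    expect_equal(e2$i1, e1$i1)
    expect_equal(e2$t1, e1$t1 + 5)
  }
  # inserting a qualifying burst into a quiet gap adds exactly one US
  base <- SpikeTrain(c(0.1, 0.5, 2.0, 2.5), stimWindow = c(0, 3))
  n0 <- nrow(detectUS(base))
  with_burst <- SpikeTrain(sort(c(spikeTimes(base), 1.0, 1.006, 1.012)),
                           stimWindow = c(0, 3))
  expect_gte(nrow(detectUS(with_burst)), n0 + 1L)
})

test_that("returned events always satisfy their ISI predicates", {
  for (seed in 1:50) {
    tr <- random_train(seed)
    ev <- detectUS(tr)
    if (nrow(ev)) {
      expect_true(all(ev$isi1_ms < 9))
      expect_true(all(ev$isi2_ms < 9))
      expect_true(all(ev$following_isi_ms > 20))
    }
  }
})

test_that("pause periods follow the last US spike and honour the
           stimulus-shutdown exclusion", {
  st <- SpikeTrain(c(0.100, 0.108, 0.116, 0.220), stimWindow = c(0, 1))
  expect_equal(pausePeriods(detectUS(st), st), 104)

  # US near stimulus end with no further spike inside the window:
  # detected (4th spike exists) but pause excluded
  st2 <- SpikeTrain(c(0.900, 0.906, 0.912, 1.100), stimWindow = c(0, 1))
  ev2 <- detectUS(st2)
  expect_equal(nrow(ev2), 1L)
  expect_length(pausePeriods(ev2, st2), 0L)

  # only three spikes at the end: no US, no pause
  st3 <- SpikeTrain(c(0.900, 0.906, 0.912), stimWindow = c(0, 1))
  expect_length(pausePeriods(detectUS(st3), st3), 0L)

  # empty event list
  expect_length(pausePeriods(detectUS(
    SpikeTrain(c(0.1, 0.5), stimWindow = c(0, 1))), st), 0L)

  # mismatched train rejected
  expect_error(pausePeriods(detectUS(st), st2), "match")

  # all defined pauses exceed the 20-ms bound by construction
  for (seed in 1:30) {
    tr <- random_train(seed)
    p <- pausePeriods(detectUS(tr), tr)
    if (length(p)) expect_true(all(p > 20))
  }
})

test_that("ISI time course indexes around the first US / minimum ISI", {
  tr <- train_from_isis_ms(c(20, 8, 8, 104, 80), start_ms = 80)
  tc <- isiTimeCourse(list(tr))
  expect_equal(tc$group[1], "US")
  get <- function(x) tc$isi_ms[tc$X == x]
  expect_equal(get(-1), 20)
  expect_equal(get(0), 8)
  expect_equal(get(1), 104)
  expect_equal(get(2), 80)
  expect_true(is.na(get(-8)))

  # non-US trial: minimum ISI sits at X = 0
  tr2 <- SpikeTrain(cumsum(c(0.1, 0.05, 0.04, 0.03, 0.06, 0.08)),
                    stimWindow = c(0, 1))
  tc2 <- isiTimeCourse(list(tr2))
  expect_equal(tc2$group[1], "non-US")
  expect_equal(tc2$isi_ms[tc2$X == 0], 30)
  expect_equal(attr(tc2, "window_convention"),
               "non-US trials: 11-ISI window placed with the minimum ISI at X=0")
})

test_that("ISIs shorten before the pause in a synthetic US cohort", {
  tcs <- lapply(1:30, function(i) {
    sim <- simulateSpikeTrial(trialGenParams(), seed = 4000 + i)
    sim$train
  })
  tc <- isiTimeCourse(tcs)
  us <- tc[tc$group == "US", ]
  m0 <- mean(us$isi_ms[us$X == 0], na.rm = TRUE)
  m3 <- mean(us$isi_ms[us$X == -3], na.rm = TRUE)
  expect_lt(m0, m3)
})

test_that("firing-rate trace conserves spike count and hits plateaus", {
  # empty train: all-zero trace
  fr0 <- firingRateTrace(SpikeTrain(numeric(0), stimWindow = c(0, 1)))
  expect_true(all(fr0$rate == 0))

  # regular 10-ms ISIs: 100-Hz plateau away from the edges
  tr <- SpikeTrain(seq(0.2, 1.2, by = 0.01), stimWindow = c(0, 2))
  fr <- firingRateTrace(tr)
  mid <- fr$rate[fr$time > 0.4 & fr$time < 1.0]
  expect_true(all(abs(mid - 100) <= 10))

  # integral of the rate approximates the spike count
  tr2 <- random_train(9)
  fr2 <- firingRateTrace(tr2)
  integral <- sum(fr2$rate) * fr2$stepMs / 1000
  expect_equal(integral, nSpikes(tr2), tolerance = 0.1)
})

test_that("rate-peak counting separates bursts by troughs", {
  flat <- list(time = seq(0, 1, 0.01), rate = rep(0, 101))
  expect_equal(countRatePeaks(flat), 0L)

  # two bursts separated by silence
  tr <- SpikeTrain(c(seq(0.3, 0.33, 0.008), seq(0.8, 0.83, 0.008)),
                   stimWindow = c(0, 1.5))
  fr <- firingRateTrace(tr)
  expect_equal(countRatePeaks(fr), 2L)

  # generated trains: peak count equals the embedded burst count in
  # most seeded trials at default thresholds
  hits <- vapply(1:60, function(i) {
    sim <- simulateSpikeTrial(trialGenParams(), seed = 7000 + i)
    fr <- firingRateTrace(sim$train)
    countRatePeaks(fr, window = stimWindow(sim$train)) == 3L
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("spontaneous rate uses the pre-stimulus epoch", {
  tr <- SpikeTrain(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.5), stimWindow = c(1, 2))
  expect_equal(spontaneousRate(tr), 5)
  expect_equal(spontaneousRate(
    SpikeTrain(c(1.5), stimWindow = c(1, 2))), 0)
  expect_error(spontaneousRate(
    SpikeTrain(c(0.5), stimWindow = c(0, 1))), "zero length")

  # Poisson recovery at 3 Hz
  est <- vapply(1:300, function(i) {
    sim <- simulateSpikeTrial(
      trialGenParams(baselineRate = 3, nUS = 0), seed = 5000 + i)
    spontaneousRate(sim$train)
  }, 1)
  expect_equal(mean(est), 3, tolerance = 0.15)
})

test_that("trial classification flags US trials", {
  sim <- simulateSpikeTrial(trialGenParams(nUS = 1), seed = 11)
  cls <- classifyTrials(list(sim$train))
  expect_true(cls$has_us)

  # burst-free Poisson trains at 5 Hz are rarely misclassified
  fp <- vapply(1:200, function(i) {
    sim <- simulateSpikeTrial(
      trialGenParams(nUS = 0, baselineRate = 5, stimRate = 5),
      seed = 6000 + i)
    classifyTrials(list(sim$train))$has_us
  }, TRUE)
  expect_lte(mean(fp), 0.05)

  expect_false(classifyTrials(
    list(SpikeTrain(numeric(0), stimWindow = c(0, 1))))$has_us)
})
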