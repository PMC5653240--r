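test_that("comparison wrapper applies the named test and correction", {
  withr::with_seed(1, {
    g <- list(ctrl = rnorm(12), a = rnorm(12, 1.5), b = rnorm(12, 0.2))
  })
  res <- runComparison(g, test = "student_t", correction = "holm")
  expect_equal(nrow(res), 2L)
  expect_equal(res$contrast, c("ctrl vs a", "ctrl vs b"))
  expect_true(all(res$adjusted_p >= res$raw_p))

  # identical groups: rank-sum p near 1
  same <- list(x = 1:10 + 0.5, y = 1:10 + 0.5)
  p <- runComparison(same, test = "wilcoxon_rank_sum")$raw_p
  expect_gt(p, 0.9)

  # wrapper agrees with the underlying base test
  direct <- stats::t.test(g$ctrl, g$a, var.equal = TRUE)$p.value
  expect_equal(res$raw_p[1], direct)

  # paired tests demand equal lengths
  expect_error(runComparison(list(a = 1:5, b = 1:6), test = "paired_t"),
               "equal lengths")
})

test_that("Holm step-down matches its definition and dominates Bonferroni", {
  # hand computation: raw p (0.01, 0.04), m = 2 -> adjusted (0.02, 0.04)
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  withr::with_seed(2, {
    g <- list(ctrl = rnorm(10), a = rnorm(10, 1), b = rnorm(10, 2),
              c = rnorm(10, 0.5))
  })
  h <- runComparison(g, "student_t", "holm")$adjusted_p
  b <- runComparison(g, "student_t", "bonferroni")$adjusted_p
  raw <- runComparison(g, "student_t", "none")$adjusted_p
  expect_true(all(h <= b + 1e-15))
  expect_true(all(h >= raw - 1e-15))
  # manual step-down on the same raw p-values
  o <- order(raw)
  manual <- pmin(cummax((length(raw) - seq_along(raw) + 1L) *
                          raw[o]), 1)[order(o)]
  expect_equal(h, manual)
})

test_that("Wilcoxon wrapper holds its nominal type-I error", {
  rej <- withr::with_seed(7, {
    vapply(1:2000, function(i) {
      x <- rnorm(20); y <- rnorm(20)
      runComparison(list(a = x, b = y),
                    test = "wilcoxon_rank_sum")$raw_p < 0.05
    }, TRUE)
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Spearman association matches brute-force midranks", {
  expect_equal(spearmanAssoc(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearmanAssoc(1:8, -(1:8))$rho, -1)
  # ties-heavy samples against direct rank correlation
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- sample(1:4, 15, replace = TRUE)
      y <- sample(1:5, 15, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(spearmanAssoc(x, y)$rho, cor(rank(x), rank(y)),
                   tolerance = 1e-12)
    }
  })
  expect_true(spearmanAssoc(rep(1, 5), 1:5)$degenerate)
})

test_that("Clopper-Pearson interval inverts the binomial tails", {
  # k = 0: lower bound 0, upper solves P(X = 0 | p) = alpha/2
  ci <- clopperPearsonCI(0, 10)
  expect_equal(ci[["lower"]], 0)
  expect_equal((1 - ci[["upper"]])^10, 0.025, tolerance = 1e-9)

  # generic k: bounds solve the tail equations (brute-force check)
  ci2 <- clopperPearsonCI(7, 24)
  expect_equal(sum(dbinom(7:24, 24, ci2[["lower"]])), 0.025,
               tolerance = 1e-6)
  expect_equal(sum(dbinom(0:7, 24, ci2[["upper"]])), 0.025,
               tolerance = 1e-6)

  # interval always contains k/n
  for (k in 0:12) {
    ci3 <- clopperPearsonCI(k, 12)
    expect_lte(ci3[["lower"]], k / 12)
    expect_gte(ci3[["upper"]], k / 12)
  }

  # empirical coverage at p = 0.3, n = 24 meets the nominal level
  cover <- withr::with_seed(5, {
    k <- rbinom(5000, 24, 0.3)
    lo <- ifelse(k == 0, 0, qbeta(0.025, k, 24 - k + 1))
    hi <- ifelse(k == 24, 1, qbeta(0.975, k + 1, 24 - k))
    mean(lo <= 0.3 & 0.3 <= hi)
  })
  expect_gte(cover, 0.95)
})

test_that("response rate counts NR in the denominator only", {
  tab <- data.frame(latency_s = c(1.2, 3.5, NA, 6.0),
                    nr = c(FALSE, FALSE, TRUE, FALSE))
  rr <- responseRate(tab, windowS = 5)
  expect_equal(rr$k, 2L)
  expect_equal(rr$n, 4L)
  expect_equal(rr$fraction, 0.5)
  expect_equal(rr$ci, clopperPearsonCI(2, 4))
  expect_error(responseRate(tab[0, ]))
})

test_that("latency comparisons support responder-only and censored modes", {
  withr::with_seed(3, {
    a <- simulateBehaviorCohort(30, 3.8, group = "ctrl")
    b <- simulateBehaviorCohort(30, 1.8, group = "kd")
  })
  res <- latencyCompare(list(ctrl = a, kd = b))
  expect_equal(nrow(res), 1L)
  expect_lt(res$raw_p, 0.05)

  cens <- latencyCompare(list(ctrl = a, kd = b), mode = "censored")
  expect_equal(cens$n1, 30L)  # all animals enter as ties at the window

  # identical sets: no rejection
  same <- latencyCompare(list(a = a, b = a))
  expect_gt(same$adjusted_p, 0.9)

  # three groups: three contrasts, Holm over m = 3
  withr::with_seed(4, {
    c3 <- simulateBehaviorCohort(30, 4.8, group = "c3")
  })
  res3 <- latencyCompare(list(ctrl = a, kd = b, c3 = c3))
  expect_equal(nrow(res3), 3L)
  o <- order(res3$raw_p)
  manual <- pmin(cummax((3:1) * res3$raw_p[o]), 1)[order(o)]
  expect_equal(res3$adjusted_p, manual)
})

test_that("Fisher exact comparisons match hypergeometric enumeration", {
  balanced <- list(c1 = matrix(c(5, 5, 5, 5), 2))
  expect_equal(fisherRateCompare(balanced)$raw_p, 1)

  # extreme table: two-sided p from exhaustive enumeration of tables
  # with the same margins
  m <- matrix(c(10, 0, 0, 10), 2)
  p_pkg <- fisherRateCompare(list(x = m))$raw_p
  # enumerate k successes in row 1 given margins (10, 10, 10)
  probs <- dhyper(0:10, 10, 10, 10)
  p_manual <- sum(probs[probs <= probs[11] * (1 + 1e-7)])
  expect_equal(p_pkg, p_manual, tolerance = 1e-9)

  # duplicated contrasts share the adjusted p
  dup <- fisherRateCompare(list(a = m, b = m))
  expect_equal(dup$adjusted_p[1], dup$adjusted_p[2])

  # zero-margin table flagged with p = 1
  zm <- fisherRateCompare(list(z = matrix(c(0, 0, 3, 4), 2,
                                          byrow = TRUE)))
  expect_true(zm$zero_margin)
  expect_equal(zm$raw_p, 1)
})
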