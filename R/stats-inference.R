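.test_names <- c("student_t", "welch_t", "paired_t", "wilcoxon_rank_sum",
                 "wilcoxon_signed_rank", "fisher_exact", "spearman")

.apply_one_test <- function(x, y, test) {
  switch(test,
    student_t = stats::t.test(x, y, var.equal = TRUE),
    welch_t = stats::t.test(x, y, var.equal = FALSE),
    paired_t = stats::t.test(x, y, paired = TRUE),
    wilcoxon_rank_sum = suppressWarnings(stats::wilcox.test(x, y)),
    wilcoxon_signed_rank =
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)),
    stop("unsupported test: ", test))
}

#' Run a family of two-group comparisons with correction
#'
#' Applies one of the named two-sample tests to each contrast of a
#' comparison family and adjusts the p-values family-wise. All tests are
#' two-sided. By default every non-first group is contrasted against the
#' first (the "versus control" layout of a screen panel).
#'
#' @param groups named list of numeric vectors.
#' @param test one of "student_t", "welch_t", "paired_t",
#'   "wilcoxon_rank_sum", "wilcoxon_signed_rank".
#' @param correction "none", "bonferroni" or "holm".
#' @param contrasts optional list of character pairs naming the groups
#'   of each contrast.
#' @return data.frame with columns `contrast`, `statistic`, `raw_p`,
#'   `adjusted_p`, `n1`, `n2`.
#' @examples
#' g <- list(ctrl = rnorm(10), kd = rnorm(10, 2))
#' runComparison(g, test = "wilcoxon_rank_sum", correction = "holm")
#' @export
runComparison <- function(groups, test = "student_t",
                          correction = c("none", "bonferroni", "holm"),
                          contrasts = NULL) {
  correction <- match.arg(correction)
  test <- match.arg(test, .test_names)
  stopifnot(is.list(groups), length(groups) >= 2L,
            !is.null(names(groups)))
  if (is.null(contrasts))
    contrasts <- lapply(names(groups)[-1L],
                        function(g) c(names(groups)[1L], g))
  rows <- lapply(contrasts, function(ct) {
    x <- groups[[ct[1L]]]; y <- groups[[ct[2L]]]
    if (is.null(x) || is.null(y))
      stop("contrast references unknown group: ",
           paste(ct, collapse = " vs "))
    if (test %in% c("paired_t", "wilcoxon_signed_rank") &&
        length(x) != length(y))
      stop("paired test requires equal lengths in contrast ",
           paste(ct, collapse = " vs "))
    ht <- .apply_one_test(x, y, test)
    data.frame(contrast = paste(ct, collapse = " vs "),
               statistic = unname(ht$statistic),
               raw_p = ht$p.value,
               n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = correction)
  out[, c("contrast", "statistic", "raw_p", "adjusted_p", "n1", "n2")]
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties, p-value from [stats::cor.test()]
#' (exact for small untied samples, t-approximation otherwise). The
#' coefficient itself is always the Pearson correlation of the midranks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n` and a `degenerate` flag (TRUE when
#'   either vector is constant, in which case rho is NA).
#' @export
spearmanAssoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 10L))
  list(rho = rho, p = ct$p.value, n = length(x), degenerate = FALSE)
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion by beta-quantile
#' inversion of the binomial tails.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric c(lower, upper).
#' @export
clopperPearsonCI <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  a <- 1 - conf
  lower <- if (k == 0L) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Behavioral response rate with Clopper-Pearson CI
#'
#' A responder is an animal whose latency does not exceed the
#' observation window; non-responders (NR flag, or latency beyond the
#' window) count in the denominator only.
#'
#' @param table data.frame with columns `latency_s` and logical `nr`
#'   (non-responder flag); NA latency with `nr = TRUE` is allowed.
#' @param windowS observation window, s (default 5).
#' @param conf confidence level (default 0.95).
#' @return list with `k`, `n`, `fraction`, `ci` (Clopper-Pearson).
#' @examples
#' tab <- data.frame(latency_s = c(1.2, 3.5, NA, 6.0),
#'                   nr = c(FALSE, FALSE, TRUE, FALSE))
#' responseRate(tab, windowS = 5)  # 2/4 = 50%
#' @export
responseRate <- function(table, windowS = 5, conf = 0.95) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("latency_s", "nr") %in% names(table)))
  resp <- !table$nr & !is.na(table$latency_s) & table$latency_s <= windowS
  k <- sum(resp)
  n <- nrow(table)
  list(k = k, n = n, fraction = k / n,
       ci = clopperPearsonCI(k, n, conf))
}

#' Pairwise latency comparisons across behavioral groups
#'
#' Wilcoxon rank-sum tests on response latencies for every pair of
#' groups, with family-wise correction. By default only responders
#' enter the tests (non-responders are excluded from latency but remain
#' in response-rate denominators); the censored mode instead scores
#' non-responders as ties at the window bound.
#'
#' @param tables named list of behavior data.frames (columns
#'   `latency_s`, `nr`).
#' @param windowS observation window, s.
#' @param correction p-adjustment method (default "holm").
#' @param mode "responders" (default) or "censored".
#' @return data.frame of pairwise results (`contrast`, `statistic`,
#'   `raw_p`, `adjusted_p`, `n1`, `n2`); contrasts where a group has no
#'   responders are skipped with a warning in responders mode.
#' @export
latencyCompare <- function(tables, windowS = 5,
                           correction = c("holm", "bonferroni", "none"),
                           mode = c("responders", "censored")) {
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  stopifnot(is.list(tables), length(tables) >= 2L, !is.null(names(tables)))
  lat <- lapply(tables, function(tb) {
    resp <- !tb$nr & !is.na(tb$latency_s) & tb$latency_s <= windowS
    if (mode == "responders") tb$latency_s[resp]
    else ifelse(resp, tb$latency_s, windowS)
  })
  pairs <- utils::combn(names(tables), 2L, simplify = FALSE)
  rows <- list()
  for (ct in pairs) {
    x <- lat[[ct[1L]]]; y <- lat[[ct[2L]]]
    if (mode == "responders" && (length(x) < 2L || length(y) < 2L)) {
      warning("contrast ", paste(ct, collapse = " vs "),
              " skipped: a group has fewer than 2 responders")
      next
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    rows[[length(rows) + 1L]] <-
      data.frame(contrast = paste(ct, collapse = " vs "),
                 statistic = unname(ht$statistic), raw_p = ht$p.value,
                 n1 = length(x), n2 = length(y))
  }
  if (!length(rows))
    return(data.frame(contrast = character(0), statistic = numeric(0),
                      raw_p = numeric(0), adjusted_p = numeric(0),
                      n1 = integer(0), n2 = integer(0)))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = correction)
  out[, c("contrast", "statistic", "raw_p", "adjusted_p", "n1", "n2")]
}

#' Fisher's exact tests on 2x2 response-count tables
#'
#' Two-sided exact test per contrast with family-wise correction
#' (response-rate comparisons across genotypes). A table with a zero
#' margin carries no information; its p is reported as 1 with a flag.
#'
#' @param tables named list of 2x2 integer matrices.
#' @param correction p-adjustment method (default "holm").
#' @return data.frame (`contrast`, `raw_p`, `adjusted_p`,
#'   `zero_margin`).
#' @export
fisherRateCompare <- function(tables,
                              correction = c("holm", "bonferroni",
                                             "none")) {
  correction <- match.arg(correction)
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  rows <- lapply(names(tables), function(nm) {
    m <- tables[[nm]]
    stopifnot(is.matrix(m), all(dim(m) == 2L), all(m >= 0),
              all(m == round(m)))
    zero_margin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
    p <- if (zero_margin) 1 else stats::fisher.test(m)$p.value
    data.frame(contrast = nm, raw_p = p, zero_margin = zero_margin)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = correction)
  out[, c("contrast", "raw_p", "adjusted_p", "zero_margin")]
}
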