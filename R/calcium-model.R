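#' Double-exponential calcium transient model
#'
#' The parametric form used for dendritic Ca2+ transients:
#' \deqn{f(t) = A (1 - e^{-(t - t_0)/\tau_{on}}) e^{-(t - t_0)/\tau_{off}}}
#' for t > t0 and exactly 0 for t <= t0. `t0` is the transient onset,
#' `tauOn` the rise time constant, `tauOff` the decay time constant and
#' `A` an amplitude scale.
#'
#' @param t numeric time vector (s).
#' @param A amplitude scale (dF/F0 fraction).
#' @param t0 onset time (s).
#' @param tauOn,tauOff rise / decay time constants (s).
#' @return numeric vector, same length as `t`.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' y <- caTransientModel(t, A = 0.1, t0 = 1, tauOn = 0.1, tauOff = 2)
#' # the peak sits at t0 + tauOn * log(1 + tauOff/tauOn)
#' t[which.max(y)]
#' @export
caTransientModel <- function(t, A, t0, tauOn, tauOff) {
  s <- t - t0
  out <- numeric(length(t))
  up <- s > 0
  out[up] <- A * (1 - exp(-s[up] / tauOn)) * exp(-s[up] / tauOff)
  out
}

#' Peak time of the transient model
#'
#' Closed-form location of the model maximum:
#' t0 + tauOn * log(1 + tauOff / tauOn).
#'
#' @inheritParams caTransientModel
#' @return peak time (s).
#' @export
caTransientPeakTime <- function(t0, tauOn, tauOff) {
  t0 + tauOn * log(1 + tauOff / tauOn)
}

# sum of components with shared taus; comp = data.frame(t0, A)
.caModelSum <- function(t, comp, tauOn, tauOff) {
  y <- numeric(length(t))
  for (k in seq_len(nrow(comp)))
    y <- y + caTransientModel(t, comp$A[k], comp$t0[k], tauOn, tauOff)
  y
}

#' Fit a stepwise transient model to a trace segment
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) fit of a sum of
#' `nComponents` transient-model terms to a dF/F0 trace segment. Each
#' component has its own onset `t0` and amplitude `A >= 0`; the rise and
#' decay time constants are shared across components (per-component time
#' constants would be poorly constrained on stepwise transients whose
#' steps share kinetics). Time constants are bounded to
#' `tauOnBounds` = 0.05-0.5 s and `tauOffBounds` = 1.5-10 s by default.
#'
#' Manual per-trial tuning of the time constants is replaced by
#' multi-start bounded optimization: each supplied `t0Inits` value is
#' tried together with starts shifted by one rise time constant either
#' way, and the lowest-RSS solution is returned. For `nComponents > 1`
#' the fit is warm-started from the (K-1)-component solution with a
#' small extra component at the largest residual, which guarantees the
#' RSS never increases with added components.
#'
#' Before fitting, a baseline offset (mean of the samples preceding the
#' earliest onset candidate, fallback: first 100 ms of the segment) is
#' subtracted from the segment.
#'
#' @param trace a dF/F0 [FluorTrace-class].
#' @param window (start, end) s segment containing the event(s).
#' @param nComponents number of stepwise components (>= 1).
#' @param t0Inits numeric vector of onset initializations (s). Default:
#'   Schmitt-trigger event onsets detected in the window, falling back
#'   to an even grid.
#' @param tauOnBounds,tauOffBounds fit bounds (s).
#' @param tauOnInit,tauOffInit starting values (s).
#' @param drift when TRUE (default) a linear nuisance term c + b*t is
#'   fitted alongside the transient components, absorbing any residual
#'   photobleaching trend left by the decay correction; both
#'   coefficients are zero on drift-free input.
#' @return a [TransientFit-class].
#' @export
fitTransient <- function(trace, window = NULL, nComponents = 1L,
                         t0Inits = NULL,
                         tauOnBounds = c(0.05, 0.5),
                         tauOffBounds = c(1.5, 10),
                         tauOnInit = 0.15, tauOffInit = 2.5,
                         drift = TRUE) {
  stopifnot(is(trace, "FluorTrace"), nComponents >= 1L)
  if (is.null(window)) window <- range(traceTime(trace))
  keep <- traceTime(trace) >= window[1] & traceTime(trace) <= window[2]
  tt <- traceTime(trace)[keep]
  yy <- traceValues(trace)[keep]
  if (length(tt) < 10L) stop("fit window contains too few samples")
  dt <- stats::median(diff(tt))

  if (is.null(t0Inits)) {
    ev <- tryCatch(detectTransients(trace), error = function(e) NULL)
    if (!is.null(ev) && nrow(ev)) {
      cand <- ev$onset_time[ev$onset_time >= window[1] &
                            ev$onset_time <= window[2]]
      if (length(cand)) t0Inits <- cand
    }
    if (is.null(t0Inits))
      t0Inits <- seq(window[1], window[2] - 5 * dt,
                     length.out = max(nComponents, 3L))
  }

  # baseline offset: early segment samples that certainly precede the
  # first onset candidate (capped at the first 100 ms of the segment so
  # the rising edge never leaks into the offset estimate)
  pre <- tt < min(min(t0Inits) - 2 * dt, window[1] + 0.1)
  offset <- if (sum(pre) >= 2L) mean(yy[pre])
            else mean(yy[seq_len(2L)])
  yy <- yy - offset

  lo_t0 <- window[1] - 0.5
  hi_t0 <- window[2]
  t_mid <- mean(range(tt))
  nd <- if (drift) 2L else 0L   # trailing nuisance params (c, b)
  resid_fun <- function(par, K) {
    A <- par[seq_len(K)]
    t0 <- par[K + seq_len(K)]
    tauOn <- par[2 * K + 1L]
    tauOff <- par[2 * K + 2L]
    base <- if (drift) par[2 * K + 3L] + par[2 * K + 4L] * (tt - t_mid)
            else 0
    yy - base - .caModelSum(tt, data.frame(t0 = t0, A = A), tauOn, tauOff)
  }
  run_lm <- function(start, K) {
    lower <- c(rep(0, K), rep(lo_t0, K), tauOnBounds[1], tauOffBounds[1],
               rep(-Inf, nd))
    upper <- c(rep(Inf, K), rep(hi_t0, K), tauOnBounds[2], tauOffBounds[2],
               rep(Inf, nd))
    tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun, K = K,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  best_of <- function(starts, K) {
    best <- NULL
    for (s in starts) {
      fit <- run_lm(s, K)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
    best
  }
  a_init <- max(max(yy), 1e-6) / 0.8

  fit_K <- function(K, warm = NULL) {
    starts <- list()
    if (K == 1L) {
      for (t0i in t0Inits)
        for (shift in c(-tauOnInit, 0, tauOnInit)) {
          t0s <- min(max(t0i + shift, lo_t0), hi_t0 - dt)
          starts[[length(starts) + 1L]] <-
            c(a_init, t0s, tauOnInit, tauOffInit, rep(0, nd))
        }
    } else {
      # warm starts from the (K-1)-component solution: the residual peak
      # marks the missing step, whose onset precedes it by about the
      # model's rise-to-peak time
      w <- warm
      res <- yy - .caModelSum(tt, w$comp, w$tauOn, w$tauOff) -
        (if (drift) w$nuis[1L] + w$nuis[2L] * (tt - t_mid) else 0)
      t_pk <- tt[which.max(res)]
      clamp <- function(x) min(max(x, lo_t0), hi_t0 - dt)
      lead <- w$tauOn * log(1 + w$tauOff / w$tauOn)
      # zero-amplitude start reproduces the (K-1) fit exactly, so the
      # K-component RSS can never exceed it
      starts[[1L]] <- c(w$comp$A, 1e-8, w$comp$t0, clamp(t_pk - lead),
                        w$tauOn, w$tauOff, w$nuis)
      starts[[2L]] <- c(w$comp$A, max(max(res), 1e-6),
                        w$comp$t0, clamp(t_pk - lead), w$tauOn, w$tauOff,
                        w$nuis)
      starts[[3L]] <- c(w$comp$A, max(max(res), 1e-6),
                        w$comp$t0, clamp(t_pk - 2 * w$tauOn),
                        w$tauOn, w$tauOff, w$nuis)
      # plus a fresh start spread over the inits
      grid <- if (length(t0Inits) >= K) utils::head(sort(t0Inits), K)
              else seq(window[1], window[2] - 5 * dt, length.out = K)
      starts[[4L]] <- c(rep(a_init / K, K), grid, tauOnInit, tauOffInit,
                        rep(0, nd))
    }
    best_of(starts, K)
  }

  warm <- NULL
  best <- NULL
  for (K in seq_len(nComponents)) {
    best <- fit_K(K, warm)
    if (is.null(best))
      stop("transient fit failed to converge for all starts")
    p <- best$fit$par
    comp <- data.frame(t0 = p[K + seq_len(K)], A = p[seq_len(K)])
    warm <- list(comp = comp, tauOn = p[2 * K + 1L],
                 tauOff = p[2 * K + 2L],
                 nuis = if (drift) p[2 * K + 3:4] else numeric(0))
  }
  K <- nComponents
  p <- best$fit$par
  comp <- data.frame(t0 = p[K + seq_len(K)], A = pmax(p[seq_len(K)], 0))
  comp <- comp[order(comp$t0), , drop = FALSE]
  rownames(comp) <- NULL
  tauOn <- p[2 * K + 1L]
  tauOff <- p[2 * K + 2L]
  eps <- 1e-8
  at_bound <- tauOn <= tauOnBounds[1] + eps | tauOn >= tauOnBounds[2] - eps |
    tauOff <= tauOffBounds[1] + eps | tauOff >= tauOffBounds[2] - eps
  new("TransientFit", components = comp, tauOn = tauOn, tauOff = tauOff,
      rss = best$rss, nComponents = as.integer(K),
      atBound = at_bound, converged = best$fit$info %in% 1:4)
}

#' Onset lag of a calcium transient relative to the first US
#'
#' Temporal difference Dt = t0 - (reference spike time of the first US).
#' Negative values mean the calcium onset precedes the spike reference.
#' The reference defaults to the first spike of the US; the last spike
#' (the burst end used for trace alignment) is available as an
#' alternative since either convention is defensible.
#'
#' @param fit a [TransientFit-class] (first component used).
#' @param events data.frame from [detectUS()] for the same trial.
#' @param reference "first_spike" (default) or "last_spike".
#' @return Dt in seconds.
#' @export
onsetLag <- function(fit, events, reference = c("first_spike", "last_spike")) {
  reference <- match.arg(reference)
  stopifnot(is(fit, "TransientFit"))
  if (!is.data.frame(events) || !nrow(events))
    stop("no US event supplied: onset lag is undefined")
  ref <- if (reference == "first_spike") events$t1[1L] else events$t3[1L]
  fit@components$t0[1L] - ref
}
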