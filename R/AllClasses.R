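#' @import methods
NULL

#' SpikeTrain: spike times for one trial
#'
#' Ordered spike times (seconds) recorded from one neuron in one trial,
#' together with the stimulus window during which the thermal (IR-laser)
#' stimulus was applied. All downstream spike metrics — unconventional-spike
#' detection, pause periods, firing-rate traces — consume this container.
#'
#' @slot times numeric, strictly increasing spike times in seconds.
#' @slot stimWindow numeric length 2, stimulus (start, end) in seconds.
#' @slot trialId character scalar identifier.
#'
#' @seealso [SpikeTrain()] for the constructor, [detectUS()].
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    times = "numeric",
    stimWindow = "numeric",
    trialId = "character"
  ),
  prototype(times = numeric(0), stimWindow = c(0, 1), trialId = "trial")
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@stimWindow) != 2L || any(!is.finite(object@stimWindow)))
    msg <- c(msg, "stimWindow must be two finite numbers (start, end)")
  else if (object@stimWindow[1] >= object@stimWindow[2])
    msg <- c(msg, "stimWindow start must precede end")
  if (length(object@times)) {
    if (any(!is.finite(object@times)))
      msg <- c(msg, "spike times must be finite")
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "spike times must be strictly increasing")
  }
  if (length(object@trialId) != 1L)
    msg <- c(msg, "trialId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times numeric vector of spike times in seconds (sorted, no
#'   duplicates).
#' @param stimWindow numeric length 2, stimulus (start, end) in seconds.
#' @param trialId identifier string.
#' @return A [SpikeTrain-class] object.
#' @examples
#' st <- SpikeTrain(c(0.10, 0.108, 0.116, 0.14), stimWindow = c(0, 1))
#' nSpikes(st)
#' @export
SpikeTrain <- function(times, stimWindow = c(0, 1), trialId = "trial") {
  new("SpikeTrain", times = as.numeric(times),
      stimWindow = as.numeric(stimWindow), trialId = as.character(trialId))
}

#' FluorTrace: uniformly sampled fluorescence time series
#'
#' One fluorescence trace (raw counts, dF/F0 fraction, or a FRET ratio)
#' on a uniform time grid, carrying the baseline (pre-stimulus) window used
#' for F0 / noise-SD estimation and the stimulus window.
#'
#' @slot time numeric, uniform time grid in seconds.
#' @slot values numeric, same length as time.
#' @slot baselineWindow numeric length 2, pre-stimulus (start, end) s.
#' @slot stimWindow numeric length 2, stimulus (start, end) s.
#' @slot unit character, one of "raw", "dff", "ratio", "dr".
#'
#' @exportClass FluorTrace
setClass("FluorTrace",
  representation(
    time = "numeric",
    values = "numeric",
    baselineWindow = "numeric",
    stimWindow = "numeric",
    unit = "character"
  ),
  prototype(unit = "raw")
)

setValidity("FluorTrace", function(object) {
  msg <- character(0)
  if (length(object@time) != length(object@values))
    msg <- c(msg, "time and values must have equal length")
  if (length(object@time) >= 3L) {
    dt <- diff(object@time)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
      msg <- c(msg, "time grid must be uniform and increasing")
  }
  for (w in list(object@baselineWindow, object@stimWindow))
    if (length(w) != 2L || w[1] >= w[2])
      msg <- c(msg, "windows must be (start, end) with start < end")
  if (length(object@baselineWindow) == 2L && length(object@stimWindow) == 2L &&
      object@baselineWindow[2] > object@stimWindow[1] + 1e-9)
    msg <- c(msg, "baselineWindow must precede stimWindow")
  if (!object@unit %in% c("raw", "dff", "ratio", "dr"))
    msg <- c(msg, "unit must be one of raw, dff, ratio, dr")
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a FluorTrace
#'
#' @param time uniform time grid (seconds).
#' @param values fluorescence values (same length as `time`).
#' @param baselineWindow pre-stimulus (start, end) s used for F0 and
#'   baseline-SD estimation.
#' @param stimWindow stimulus (start, end) s.
#' @param unit "raw" counts, "dff" (dF/F0), "ratio" (FRET ratio) or
#'   "dr" (baseline-subtracted ratio).
#' @return A [FluorTrace-class] object.
#' @export
FluorTrace <- function(time, values, baselineWindow = c(0, 1),
                       stimWindow = c(1, 2), unit = "raw") {
  new("FluorTrace", time = as.numeric(time), values = as.numeric(values),
      baselineWindow = as.numeric(baselineWindow),
      stimWindow = as.numeric(stimWindow), unit = unit)
}

#' FretFrameSet: paired YFP/CFP frames with cell and background regions
#'
#' Per-frame mean intensities of the outlined cellular region ("unmasked")
#' and of a background region ("masked") for the YFP and CFP channels of a
#' SuperClomeleon recording, on a shared time grid. Region means (not sums)
#' are stored so the values are region-size invariant.
#'
#' @slot time numeric, shared time grid (s).
#' @slot yfpCell,yfpBg,cfpCell,cfpBg numeric, per-frame region means.
#' @slot baselineWindow,stimWindow numeric length 2 (s).
#' @exportClass FretFrameSet
setClass("FretFrameSet",
  representation(
    time = "numeric",
    yfpCell = "numeric", yfpBg = "numeric",
    cfpCell = "numeric", cfpBg = "numeric",
    baselineWindow = "numeric", stimWindow = "numeric"
  )
)

setValidity("FretFrameSet", function(object) {
  n <- length(object@time)
  if (any(vapply(list(object@yfpCell, object@yfpBg, object@cfpCell,
                      object@cfpBg), length, 1L) != n))
    return("all channel vectors must match the time grid length")
  TRUE
})

#' Construct a FretFrameSet
#'
#' @param time shared time grid (s).
#' @param yfpCell,yfpBg,cfpCell,cfpBg per-frame region-mean intensities of
#'   the cellular and background regions in each channel.
#' @param baselineWindow,stimWindow (start, end) s.
#' @return A [FretFrameSet-class] object.
#' @export
FretFrameSet <- function(time, yfpCell, yfpBg, cfpCell, cfpBg,
                         baselineWindow = c(0, 1), stimWindow = c(1, 2)) {
  new("FretFrameSet", time = as.numeric(time),
      yfpCell = as.numeric(yfpCell), yfpBg = as.numeric(yfpBg),
      cfpCell = as.numeric(cfpCell), cfpBg = as.numeric(cfpBg),
      baselineWindow = as.numeric(baselineWindow),
      stimWindow = as.numeric(stimWindow))
}

#' TransientFit: fitted parameters of a stepwise calcium transient
#'
#' Result of fitting a sum of double-exponential rise-and-decay components
#' to one dF/F0 trace segment: per-component onset `t0` and amplitude `A`,
#' time constants `tauOn` / `tauOff` shared across components by default,
#' and the residual sum of squares.
#'
#' @slot components data.frame with columns `t0` (s) and `A` (dF/F0
#'   fraction), one row per component, sorted by t0.
#' @slot tauOn,tauOff numeric time constants (s).
#' @slot rss residual sum of squares.
#' @slot nComponents integer.
#' @slot atBound logical, TRUE when any parameter sits at a fit bound.
#' @slot converged logical.
#' @exportClass TransientFit
setClass("TransientFit",
  representation(
    components = "data.frame",
    tauOn = "numeric", tauOff = "numeric",
    rss = "numeric", nComponents = "integer",
    atBound = "logical", converged = "logical"
  )
)

setValidity("TransientFit", function(object) {
  msg <- character(0)
  if (!all(c("t0", "A") %in% names(object@components)))
    msg <- c(msg, "components must have columns t0 and A")
  else {
    if (nrow(object@components) != object@nComponents)
      msg <- c(msg, "nComponents must match component rows")
    if (any(object@components$A < -1e-12))
      msg <- c(msg, "amplitudes must be nonnegative")
    if (is.unsorted(object@components$t0))
      msg <- c(msg, "components must be sorted by t0")
  }
  if (object@tauOn <= 0 || object@tauOff <= 0)
    msg <- c(msg, "time constants must be positive")
  if (length(msg)) msg else TRUE
})

#' CoverageResult: dendritic coverage score of one arbor image
#'
#' Binarized dendrite mask plus the count of grid squares (default
#' 34 x 34 px, i.e. 14 x 14 um at the calibrated pixel pitch) that contain
#' at least one foreground pixel.
#'
#' @slot mask logical matrix (foreground = dendrite).
#' @slot gridPx integer grid pitch in pixels.
#' @slot occupiedSquares,totalSquares integer counts.
#' @exportClass CoverageResult
setClass("CoverageResult",
  representation(
    mask = "matrix",
    gridPx = "integer",
    occupiedSquares = "integer",
    totalSquares = "integer"
  )
)

setValidity("CoverageResult", function(object) {
  msg <- character(0)
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (object@occupiedSquares < 0L ||
      object@occupiedSquares > object@totalSquares)
    msg <- c(msg, "occupiedSquares must lie in [0, totalSquares]")
  expected <- as.integer(ceiling(nrow(object@mask) / object@gridPx) *
                         ceiling(ncol(object@mask) / object@gridPx))
  if (object@totalSquares != expected)
    msg <- c(msg, "totalSquares inconsistent with mask dimensions and gridPx")
  if (length(msg)) msg else TRUE
})
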