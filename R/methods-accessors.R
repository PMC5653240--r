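#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @rdname accessors
#' @export
setMethod("stimWindow", "SpikeTrain", function(x) x@stimWindow)

#' @rdname accessors
#' @export
setMethod("stimWindow", "FluorTrace", function(x) x@stimWindow)

#' @rdname accessors
#' @export
setMethod("stimWindow", "FretFrameSet", function(x) x@stimWindow)

#' @rdname accessors
#' @export
setMethod("baselineWindow", "FluorTrace", function(x) x@baselineWindow)

#' @rdname accessors
#' @export
setMethod("baselineWindow", "FretFrameSet", function(x) x@baselineWindow)

#' @rdname accessors
#' @export
setMethod("trialId", "SpikeTrain", function(x) x@trialId)

#' @rdname accessors
#' @export
setMethod("traceTime", "FluorTrace", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("traceValues", "FluorTrace", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleRate", "FluorTrace", function(x) {
  if (length(x@time) < 2L) return(NA_real_)
  1 / stats::median(diff(x@time))
})

#' @rdname accessors
#' @export
setMethod("coverageFraction", "CoverageResult", function(x)
  x@occupiedSquares / x@totalSquares)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes, stimulus %.3g-%.3g s\n",
              object@trialId, length(object@times),
              object@stimWindow[1], object@stimWindow[2]))
})

setMethod("show", "FluorTrace", function(object) {
  cat(sprintf(
    "FluorTrace [%s]: %d samples @ %.4g Hz, %.3g-%.3g s (stim %.3g-%.3g s)\n",
    object@unit, length(object@time), sampleRate(object),
    if (length(object@time)) object@time[1] else NA,
    if (length(object@time)) object@time[length(object@time)] else NA,
    object@stimWindow[1], object@stimWindow[2]))
})

setMethod("show", "FretFrameSet", function(object) {
  cat(sprintf("FretFrameSet: %d frames, stim %.3g-%.3g s\n",
              length(object@time), object@stimWindow[1],
              object@stimWindow[2]))
})

setMethod("show", "TransientFit", function(object) {
  cat(sprintf(
    "TransientFit: %d component(s), tauOn=%.3g s, tauOff=%.3g s, rss=%.4g%s\n",
    object@nComponents, object@tauOn, object@tauOff, object@rss,
    if (object@atBound) " [at bound]" else ""))
  for (k in seq_len(nrow(object@components)))
    cat(sprintf("  t0=%.4g s  A=%.4g\n",
                object@components$t0[k], object@components$A[k]))
})

setMethod("show", "CoverageResult", function(object) {
  cat(sprintf(
    "CoverageResult: %d/%d grid squares occupied (%.1f%%), grid %d px\n",
    object@occupiedSquares, object@totalSquares,
    100 * coverageFraction(object), object@gridPx))
})
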