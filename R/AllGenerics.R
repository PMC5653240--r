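#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: spike times,
#' spike count, stimulus / baseline windows, trace time grid and values,
#' sampling rate, and trial identifier.
#'
#' @param x an object of one of the package classes.
#' @return The corresponding slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("stimWindow", function(x) standardGeneric("stimWindow"))

#' @rdname accessors
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))

#' @rdname accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))

#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("coverageFraction", function(x) standardGeneric("coverageFraction"))
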