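#' SuperClomeleon FRET ratio
#'
#' Per-frame ratio of background-subtracted YFP over background-
#' subtracted CFP:
#' ratio = (YFP_unmasked - YFP_masked) / (CFP_unmasked - CFP_masked),
#' where "unmasked" is the outlined cellular region and "masked" the
#' background region. Because SuperClomeleon's YFP is quenched by Cl-
#' binding, a ratio increase reflects a fall in intracellular Cl-; the
#' function itself only reports ratios.
#'
#' @param frames a [FretFrameSet-class].
#' @return a [FluorTrace-class] with unit "ratio".
#' @examples
#' fs <- FretFrameSet(time = 0:4 / 10, yfpCell = rep(200, 5),
#'                    yfpBg = rep(100, 5), cfpCell = rep(150, 5),
#'                    cfpBg = rep(100, 5),
#'                    baselineWindow = c(0, 0.2), stimWindow = c(0.2, 0.4))
#' traceValues(fretRatio(fs))  # 2 at every frame
#' @export
fretRatio <- function(frames) {
  stopifnot(is(frames, "FretFrameSet"))
  cfp <- frames@cfpCell - frames@cfpBg
  bad <- which(cfp <= 0)
  if (length(bad))
    stop("non-positive background-subtracted CFP at frame(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  yfp <- frames@yfpCell - frames@yfpBg
  FluorTrace(frames@time, yfp / cfp,
             baselineWindow = frames@baselineWindow,
             stimWindow = frames@stimWindow, unit = "ratio")
}

#' Baseline-subtracted ratio change and its peak
#'
#' dR = ratio - baseline mean; dR_peak is the maximum of dR over the
#' stimulus epoch.
#'
#' @param ratioTrace a ratio [FluorTrace-class] (from [fretRatio()]).
#' @param baselineWindow optional (start, end) s override; defaults to
#'   the trace's own baseline window.
#' @return list with `trace` (a "dr" [FluorTrace-class]) and `peak`
#'   (dR_peak).
#' @export
deltaR <- function(ratioTrace, baselineWindow = NULL) {
  stopifnot(is(ratioTrace, "FluorTrace"))
  if (is.null(baselineWindow)) baselineWindow <- ratioTrace@baselineWindow
  tt <- traceTime(ratioTrace)
  in_base <- tt >= baselineWindow[1] & tt <= baselineWindow[2]
  if (!any(in_base)) stop("baseline window contains no samples")
  dr <- traceValues(ratioTrace) - mean(traceValues(ratioTrace)[in_base])
  trace <- FluorTrace(tt, dr, baselineWindow = baselineWindow,
                      stimWindow = stimWindow(ratioTrace), unit = "dr")
  list(trace = trace, peak = peakAmplitude(trace))
}
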