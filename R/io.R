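#' Read and write spike-time CSV files
#'
#' Spike CSV format: columns `trial_id`, `spike_time_s`, one row per
#' spike. The stimulus window is supplied separately (it is an
#' acquisition setting, not per-spike data).
#'
#' @param path CSV file path.
#' @param stimWindow (start, end) s applied to every trial.
#' @return `readSpikeCsv`: named list of [SpikeTrain-class], one per
#'   trial_id; `writeSpikeCsv`: the path, invisibly.
#' @export
readSpikeCsv <- function(path, stimWindow = c(1, 2)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "spike_time_s") %in% names(df)))
  ids <- unique(df$trial_id)
  out <- lapply(ids, function(id)
    SpikeTrain(sort(df$spike_time_s[df$trial_id == id]),
               stimWindow = stimWindow, trialId = id))
  names(out) <- ids
  out
}

#' @rdname readSpikeCsv
#' @param trains list of [SpikeTrain-class] objects.
#' @export
writeSpikeCsv <- function(trains, path) {
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(trial_id = trialId(tr), spike_time_s = spikeTimes(tr))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write fluorescence-trace CSV files
#'
#' Trace CSV format: columns `time_s`, `value`.
#'
#' @param path CSV file path.
#' @param baselineWindow,stimWindow (start, end) s metadata for the
#'   resulting trace.
#' @param unit trace unit, see [FluorTrace()].
#' @return `readTraceCsv`: a [FluorTrace-class]; `writeTraceCsv`: the
#'   path, invisibly.
#' @export
readTraceCsv <- function(path, baselineWindow = c(0, 1),
                         stimWindow = c(1, 2), unit = "dff") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  FluorTrace(df$time_s, df$value, baselineWindow = baselineWindow,
             stimWindow = stimWindow, unit = unit)
}

#' @rdname readTraceCsv
#' @param trace a [FluorTrace-class].
#' @export
writeTraceCsv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = traceTime(trace),
                              value = traceValues(trace)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write FRET channel-pair CSV files
#'
#' Format: columns `time_s`, `yfp_cell`, `yfp_bg`, `cfp_cell`,
#' `cfp_bg`.
#'
#' @param path CSV file path.
#' @param baselineWindow,stimWindow (start, end) s metadata.
#' @return `readFretCsv`: a [FretFrameSet-class]; `writeFretCsv`: the
#'   path, invisibly.
#' @export
readFretCsv <- function(path, baselineWindow = c(0, 1),
                        stimWindow = c(1, 2)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "yfp_cell", "yfp_bg", "cfp_cell", "cfp_bg")
  stopifnot(all(need %in% names(df)))
  FretFrameSet(df$time_s, df$yfp_cell, df$yfp_bg, df$cfp_cell,
               df$cfp_bg, baselineWindow = baselineWindow,
               stimWindow = stimWindow)
}

#' @rdname readFretCsv
#' @param frames a [FretFrameSet-class].
#' @export
writeFretCsv <- function(frames, path) {
  utils::write.csv(data.frame(time_s = frames@time,
                              yfp_cell = frames@yfpCell,
                              yfp_bg = frames@yfpBg,
                              cfp_cell = frames@cfpCell,
                              cfp_bg = frames@cfpBg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write grayscale arbor images as TIFF
#'
#' Images are stored as 16-bit grayscale TIFF; in R they are plain
#' numeric matrices on the 0-1 scale.
#'
#' @param path TIFF file path.
#' @return `readArborTiff`: numeric matrix in 0-1; `writeArborTiff`:
#'   the path, invisibly.
#' @export
readArborTiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  as.matrix(img)
}

#' @rdname readArborTiff
#' @param img numeric matrix with values in 0-1.
#' @export
writeArborTiff <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 1))
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
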