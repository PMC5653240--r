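#' Render a synthetic dendritic arbor image
#'
#' Draws a random recursive branching tree as bright thin curves on a
#' noisy dark background, emulating an inverted-contrast maximum-
#' projection micrograph of a dendritic arborization neuron. The
#' noiseless ink mask provides the ground-truth grid coverage.
#'
#' @param sizePx image side length in pixels; should be divisible by
#'   the grid pitch (default 340 = 10 x 34).
#' @param nBranches number of branch segments to grow (0 gives a blank
#'   image).
#' @param lineWidthPx rendered line width, pixels (default 2).
#' @param noiseSd background Gaussian noise SD on the 0-1 intensity
#'   scale (default 0.05).
#' @param seed optional integer seed.
#' @param gridPx grid pitch used for the ground-truth coverage count.
#' @param inkLevel,bgLevel line and background intensities (0-1).
#' @return list with `image` (numeric matrix in 0-1), `inkMask`
#'   (logical, the noiseless rendering), and `truth = list(
#'   coverage_squares, total_squares)`.
#' @export
simulateArbor <- function(sizePx = 340L, nBranches = 30L,
                          lineWidthPx = 2L, noiseSd = 0.05, seed = NULL,
                          gridPx = 34L, inkLevel = 0.8, bgLevel = 0.1) {
  stopifnot(sizePx >= gridPx, nBranches >= 0L, lineWidthPx >= 1L,
            noiseSd >= 0)
  if (sizePx %% gridPx != 0L)
    stop("sizePx must be divisible by the grid pitch (", gridPx, ")")
  gen <- function() {
    ink <- matrix(FALSE, sizePx, sizePx)
    draw_segment <- function(p0, p1) {
      len <- sqrt(sum((p1 - p0)^2))
      if (len < 1) return(invisible())
      tseq <- seq(0, 1, by = 0.5 / len)
      xs <- round(p0[1L] + tseq * (p1[1L] - p0[1L]))
      ys <- round(p0[2L] + tseq * (p1[2L] - p0[2L]))
      ok <- xs >= 1 & xs <= sizePx & ys >= 1 & ys <= sizePx
      ink[cbind(xs[ok], ys[ok])] <<- TRUE
    }
    if (nBranches > 0L) {
      # queue of growing tips: position, direction, remaining depth
      tips <- list(list(p = c(sizePx / 2, sizePx / 2),
                        ang = stats::runif(1, 0, 2 * pi)))
      drawn <- 0L
      while (drawn < nBranches && length(tips)) {
        i <- sample.int(length(tips), 1L)
        tip <- tips[[i]]
        tips[[i]] <- NULL
        len <- stats::runif(1, 0.08, 0.25) * sizePx
        ang <- tip$ang + stats::rnorm(1, 0, 0.3)
        p1 <- tip$p + len * c(cos(ang), sin(ang))
        draw_segment(tip$p, p1)
        drawn <- drawn + 1L
        p1c <- pmin(pmax(p1, 1), sizePx)
        # bifurcate with divergent daughter directions
        for (dang in c(-1, 1) * stats::runif(1, 0.3, 0.9))
          tips[[length(tips) + 1L]] <- list(p = p1c, ang = ang + dang)
      }
    }
    if (any(ink) && lineWidthPx > 1L) {
      brush <- EBImage::makeBrush(
        2L * (as.integer(lineWidthPx) %/% 2L) + 1L, shape = "disc")
      ink <- EBImage::dilate(EBImage::Image(ink * 1), brush) > 0.5
      ink <- matrix(as.logical(ink), sizePx, sizePx)
    }
    img <- matrix(bgLevel, sizePx, sizePx)
    img[ink] <- inkLevel
    img <- img + stats::rnorm(sizePx^2, 0, noiseSd)
    img <- pmin(pmax(img, 0), 1)
    cov <- coverageScore(ink, gridPx = gridPx)
    list(image = img, inkMask = ink,
         truth = list(coverage_squares = cov@occupiedSquares,
                      total_squares = cov@totalSquares))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
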