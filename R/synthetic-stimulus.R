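#' Generate a binary checkerboard stimulus movie
#'
#' Draws every checker of every frame independently and equiprobably from
#' \{-1, +1\}. The movie is fully determined by `seed` and its
#' dimensions, so it can be stored as a descriptor and regenerated
#' bit-exactly (see [writeStimulusDescriptor()]).
#'
#' @param seed integer RNG seed.
#' @param frames number of frames (>= 1).
#' @param gridRows,gridCols checkers per side (>= 1).
#' @param frameRateHz frame rate in frames/s (default 60, i.e. a
#'   16.67 ms frame interval).
#' @param checkerSizeUm checker edge length in micrometers (metadata
#'   only; default 100).
#' @return a [StimulusMovie].
#' @export
#' @examples
#' stim <- makeCheckerboard(1, frames = 120, gridRows = 19, gridCols = 19)
#' stim
makeCheckerboard <- function(seed, frames, gridRows = 19, gridCols = 19,
                             frameRateHz = 60, checkerSizeUm = 100) {
  frames <- checkPositiveCount(frames, "frames")
  gridRows <- checkPositiveCount(gridRows, "gridRows")
  gridCols <- checkPositiveCount(gridCols, "gridCols")
  if (frameRateHz <= 0) stop("'frameRateHz' must be positive", call. = FALSE)
  seed <- asSeed(seed)
  vals <- withSeed(seed, {
    n <- as.double(frames) * gridRows * gridCols
    array(sample(c(-1L, 1L), n, replace = TRUE),
          dim = c(frames, gridRows, gridCols))
  })
  new("StimulusMovie", values = vals, frameRateHz = frameRateHz,
      checkerSizeUm = checkerSizeUm, seed = seed)
}

## Flatten to a frames x (rows*cols) matrix (row-major pixel order is
## irrelevant as long as it is consistent; column-major as in R arrays).
stimAsMatrix <- function(stim) {
  d <- dim(stim@values)
  dim(stim@values) <- c(d[1L], d[2L] * d[3L])
  m <- stim@values
  m
}
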