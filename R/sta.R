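#' Compute the spike-triggered average spatiotemporal volume
#'
#' For each pre-spike lag k (1..`nLags` frames), averages the stimulus
#' frame displayed k frames before each spike's frame and subtracts the
#' stimulus mean. Spikes are assigned to frames by `floor(t * fps)`;
#' spikes occurring before `nLags` stimulus frames have elapsed (or after
#' the last frame) are excluded from the average and counted in the
#' volume's `nSpikesExcluded` slot. The stimulus mean defaults to the
#' theoretical value 0 of the +/-1 checkerboard rather than the
#' empirical frame average, which is unbiased and exact.
#'
#' @param stim a [StimulusMovie].
#' @param spikes a [SpikeTrain] recorded during `stim`.
#' @param nLags number of pre-spike lag frames (default 18; at 60 fps
#'   this spans the standard 300 ms window).
#' @param stimMean value subtracted from the average (default 0).
#' @return an [STAVolume] with dimensions `nLags x rows x cols`.
#' @export
#' @examples
#' stim <- makeCheckerboard(1, frames = 600)
#' spk <- new("SpikeTrain", cellId = "u1",
#'            times = sort(runif(200, 0, 10)), duration = 10)
#' computeSTA(stim, spk)
computeSTA <- function(stim, spikes, nLags = 18, stimMean = 0) {
  stopifnot(is(stim, "StimulusMovie"), is(spikes, "SpikeTrain"))
  nLags <- checkPositiveCount(nLags, "nLags")
  nf <- nFrames(stim)
  if (nLags >= nf) stop("'nLags' must be smaller than the frame count",
                        call. = FALSE)
  fps <- frameRateHz(stim)
  frameIdx <- floor(spikeTimes(spikes) * fps) + 1L
  usable <- frameIdx > nLags & frameIdx <= nf
  nUsed <- sum(usable)
  nExcluded <- length(frameIdx) - nUsed
  if (nUsed == 0L) {
    stopWithClass("retimea_no_spikes",
                  "cell '%s': no usable spikes for the STA", cellId(spikes))
  }
  f <- frameIdx[usable]
  d <- gridDims(stim)
  m <- stimAsMatrix(stim)
  vals <- array(0, dim = c(nLags, d[1], d[2]))
  for (k in seq_len(nLags)) {
    vals[k, , ] <- colMeans(m[f - k, , drop = FALSE]) - stimMean
  }
  new("STAVolume", cellId = cellId(spikes), values = vals,
      frameRateHz = fps, nSpikesUsed = as.integer(nUsed),
      nSpikesExcluded = as.integer(nExcluded))
}

#' Locate the maximal-deviation pixel of an STA volume
#'
#' Returns the coordinate of the largest absolute value over the whole
#' spatiotemporal volume (sign-blind: an OFF cell's negative trough wins
#' over a weaker positive value). Exact ties are broken by earliest lag,
#' then row-major order within the frame.
#'
#' @param sta an [STAVolume].
#' @return list with `lag`, `row`, `col`, `value` (signed) and
#'   `degenerate` (TRUE when the volume is identically zero, in which
#'   case the coordinate is the tie-break default).
#' @export
findPeak <- function(sta) {
  stopifnot(is(sta, "STAVolume"))
  v <- staArray(sta)
  a <- abs(v)
  mx <- max(a)
  hits <- which(a == mx, arr.ind = TRUE)
  # order candidates by (lag, row, col) to enforce the tie-break
  o <- order(hits[, 1], hits[, 2], hits[, 3])
  h <- hits[o[1], ]
  list(lag = unname(h[1]), row = unname(h[2]), col = unname(h[3]),
       value = v[h[1], h[2], h[3]], degenerate = mx == 0)
}

## Noise SD of the STA estimated from the pixel values of the two
## longest-lag frames, where the kernel of a physiological cell has
## decayed to baseline.
staNoiseSd <- function(sta, nNoiseLags = 2L) {
  v <- staArray(sta)
  nl <- dim(v)[1L]
  keep <- seq.int(max(1L, nl - nNoiseLags + 1L), nl)
  sd(as.numeric(v[keep, , , drop = FALSE]))
}
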