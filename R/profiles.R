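#' Extract the temporal profile at the receptive-field center
#'
#' Reads, for every lag frame of the STA volume, the value of the pixel
#' at the (rounded) fitted receptive-field center. When the Gaussian fit
#' did not converge the maximal-deviation pixel is used instead.
#' Latencies are expressed as positive milliseconds before the spike
#' (time zero = spike occurrence).
#'
#' @param sta an [STAVolume].
#' @param fit the corresponding [RFFit]. Profiles are normally extracted
#'   only for valid fits, but extraction itself does not require
#'   validity.
#' @return a [TemporalProfile] (spline fields empty until
#'   [splineRefine()]).
#' @export
extractProfile <- function(sta, fit) {
  stopifnot(is(sta, "STAVolume"), is(fit, "RFFit"))
  d <- gridDims(sta)
  ctr <- if (fit@converged && all(is.finite(fit@center))) {
    as.integer(round(fit@center))
  } else {
    fit@peakPixel
  }
  if (ctr[1] < 1L || ctr[1] > d[1] || ctr[2] < 1L || ctr[2] > d[2]) {
    stop("receptive-field center lies outside the stimulus grid",
         call. = FALSE)
  }
  vals <- staArray(sta)[, ctr[1], ctr[2]]
  lagMs <- lagTimesMs(sta)
  flags <- character(0)
  if (all(vals == 0)) flags <- "degenerate"
  iPk <- which.max(abs(vals))
  pol <- if (vals[iPk] >= 0) 1L else -1L
  new("TemporalProfile", cellId = cellId(sta),
      lagTimesMs = lagMs, values = vals,
      splineTimesMs = numeric(0), splineValues = numeric(0),
      timeToPeakMs = lagMs[iPk],
      timeToZeroCrossMs = NA_real_,
      polarity = pol, flags = flags)
}

#' Refine a temporal profile by cubic-spline interpolation
#'
#' Interpolates the frame-resolution profile with a cubic spline
#' evaluated on a 1 ms grid (the grid always includes the original
#' sample times, so a peak lying exactly on a sample is preserved), and
#' recomputes the time-to-peak and the zero crossing from the spline.
#' The zero crossing is the first sign change encountered moving from
#' the peak toward the spike; kernels whose opposing lobe lies on the
#' far side of the peak have no such crossing and `NA` is recorded.
#' With fewer than 4 samples no spline is fitted and the
#' frame-resolution peak is kept, flagged `"frame_resolution"`.
#'
#' @param profile a [TemporalProfile].
#' @param resolutionMs spline evaluation step in ms (default 1).
#' @return the profile with spline fields, `timeToPeakMs`,
#'   `timeToZeroCrossMs` and `polarity` filled.
#' @export
splineRefine <- function(profile, resolutionMs = 1) {
  stopifnot(is(profile, "TemporalProfile"))
  x <- profile@lagTimesMs
  y <- profile@values
  if (length(x) < 4L) {
    warning("fewer than 4 samples: keeping the frame-resolution peak")
    profile@flags <- unique(c(profile@flags, "frame_resolution"))
    return(profile)
  }
  sf <- splinefun(x, y, method = "fmm")
  grid <- sort(unique(c(seq(min(x), max(x), by = resolutionMs), x)))
  gv <- sf(grid)
  iPk <- which.max(abs(gv))
  ttp <- grid[iPk]
  pol <- if (gv[iPk] >= 0) 1L else -1L
  # scan from the peak toward the spike (decreasing lag) for the first
  # sign change; linear interpolation between grid neighbours
  ttzc <- NA_real_
  if (iPk > 1L) {
    below <- rev(seq_len(iPk - 1L))  # indices from peak toward the spike
    sPk <- sign(gv[iPk])
    for (i in below) {
      if (gv[i] == 0) { ttzc <- grid[i]; break }
      if (sign(gv[i]) != sPk) {
        # crossing between grid[i] and grid[i + 1]
        x1 <- grid[i]; x2 <- grid[i + 1L]
        y1 <- gv[i]; y2 <- gv[i + 1L]
        ttzc <- x1 + (0 - y1) / (y2 - y1) * (x2 - x1)
        break
      }
    }
  }
  profile@splineTimesMs <- grid
  profile@splineValues <- gv
  profile@timeToPeakMs <- ttp
  profile@timeToZeroCrossMs <- ttzc
  profile@polarity <- pol
  profile
}
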