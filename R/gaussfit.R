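#' Fit an axis-aligned 2D Gaussian to a spatial STA frame
#'
#' Least-squares fit of
#' `amplitude * exp(-((r - r0)^2 / (2 sr^2) + (c - c0)^2 / (2 sc^2))) + offset`
#' to a single lag frame, initialised at the maximal-deviation pixel.
#' Fitting uses Levenberg-Marquardt (\pkg{minpack.lm}); non-convergence
#' (e.g. on a flat or pure-noise frame) is reported in the result, not
#' raised as an error.
#'
#' @param frame numeric matrix (>= 3x3), typically the peak-lag frame of
#'   an [STAVolume].
#' @param init integer `(row, col)` starting center, typically the peak
#'   pixel.
#' @return list with `center` (fractional `(row, col)`), `sigmas`,
#'   `amplitude`, `offset`, `rss` and `converged`.
#' @export
#' @examples
#' g <- outer(1:15, 1:15, function(r, c)
#'   0.8 * exp(-((r - 7.25)^2 + (c - 4.5)^2) / (2 * 1.5^2)))
#' fitGaussian2D(g, c(7, 4))$center
fitGaussian2D <- function(frame, init) {
  if (!is.matrix(frame) || any(dim(frame) < 3L)) {
    stop("'frame' must be a matrix of at least 3x3", call. = FALSE)
  }
  if (any(!is.finite(frame))) stop("'frame' must be finite", call. = FALSE)
  if (init[1] < 1 || init[1] > nrow(frame) ||
      init[2] < 1 || init[2] > ncol(frame)) {
    stop("'init' must lie inside the frame", call. = FALSE)
  }
  nr <- nrow(frame); nc <- ncol(frame)
  dat <- data.frame(
    r = rep(seq_len(nr), times = nc),
    c = rep(seq_len(nc), each = nr),
    z = as.numeric(frame)
  )
  off0 <- median(dat$z)
  amp0 <- frame[init[1], init[2]] - off0
  failed <- list(center = c(NA_real_, NA_real_),
                 sigmas = c(NA_real_, NA_real_),
                 amplitude = NA_real_, offset = NA_real_,
                 rss = NA_real_, converged = FALSE)
  if (abs(amp0) < .Machine$double.eps^0.5) return(failed)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((r - r0)^2 / (2 * sr^2) + (c - c0)^2 / (2 * sc^2))) + off,
      data = dat,
      start = list(A = amp0, r0 = init[1], c0 = init[2],
                   sr = 1.5, sc = 1.5, off = off0),
      lower = c(A = -Inf, r0 = 0.5, c0 = 0.5, sr = 0.05, sc = 0.05,
                off = -Inf),
      upper = c(A = Inf, r0 = nr + 0.5, c0 = nc + 0.5, sr = 2 * nr,
                sc = 2 * nc, off = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  conv <- is.finite(rss) && all(is.finite(cf))
  list(center = unname(cf[c("r0", "c0")]),
       sigmas = abs(unname(cf[c("sr", "sc")])),
       amplitude = unname(cf["A"]), offset = unname(cf["off"]),
       rss = rss, converged = conv)
}

#' Decide whether a fitted receptive field is real
#'
#' A receptive field is accepted when (i) the peak deviation, expressed
#' in units of the noise SD estimated from the two longest-lag frames,
#' reaches the z threshold (inclusive), and (ii) the 2D Gaussian fit
#' converged with both sigmas inside `sigmaRange`. Because the peak is
#' the maximum over all `nLags x rows x cols` pixels of the volume, the
#' default threshold controls the family-wise false-positive rate at
#' `alpha` by a Bonferroni bound over the volume size,
#' `zMin = qnorm(1 - alpha / (2 * nPixels))` (about 4.8 for the default
#' 18 x 19 x 19 volume); pass `zMin` explicitly to use a fixed cutoff.
#'
#' @param fit an [RFFit] (or the list returned by [fitGaussian2D()]
#'   augmented with `peakValue`).
#' @param sta the [STAVolume] the fit was computed from.
#' @param zMin fixed z threshold; when `NULL` (default) derived from
#'   `alpha` and the volume size.
#' @param alpha family-wise false-positive rate used to derive the
#'   default threshold (default 0.01).
#' @param sigmaRange admissible Gaussian SD range in checkers (default
#'   0.3 to half the larger grid side).
#' @return logical: is the receptive field valid. The applied threshold
#'   and z score are attached as attributes `zMin` and `peakZ`.
#' @export
validateRF <- function(fit, sta, zMin = NULL, alpha = 0.01,
                       sigmaRange = NULL) {
  stopifnot(is(sta, "STAVolume"))
  d <- dim(staArray(sta))
  if (is.null(sigmaRange)) sigmaRange <- c(0.3, max(d[2:3]) / 2)
  if (is.null(zMin)) zMin <- qnorm(1 - alpha / (2 * prod(d)))
  if (is(fit, "RFFit")) {
    peakValue <- fit@peakValue
    sigmas <- fit@sigmas
    converged <- fit@converged
  } else {
    peakValue <- fit$peakValue
    sigmas <- fit$sigmas
    converged <- isTRUE(fit$converged)
  }
  noiseSd <- staNoiseSd(sta)
  z <- if (is.finite(noiseSd) && noiseSd > 0) abs(peakValue) / noiseSd
       else Inf
  ok <- z >= zMin && converged && all(is.finite(sigmas)) &&
    all(sigmas >= sigmaRange[1] & sigmas <= sigmaRange[2])
  structure(ok, peakZ = z, zMin = zMin)
}

#' Locate, fit and validate the receptive field of one STA volume
#'
#' Convenience wrapper running [findPeak()], [fitGaussian2D()] on the
#' peak-lag frame and [validateRF()], returning a complete [RFFit].
#'
#' @inheritParams validateRF
#' @param sta an [STAVolume].
#' @return an [RFFit].
#' @export
#' @examples
#' stim <- makeCheckerboard(1, frames = 3000)
#' cell <- new("GroundTruthCell", cellId = "c1", polarity = -1L,
#'             center = c(9, 12), sigma = 1, peakLatencyMs = 48,
#'             baseRateHz = 8, gain = 6, condition = "control")
#' sta <- computeSTA(stim, simulateLNCell(cell, stim, seed = 3))
#' fitRF(sta)
fitRF <- function(sta, zMin = NULL, alpha = 0.01, sigmaRange = NULL) {
  pk <- findPeak(sta)
  flags <- character(0)
  if (pk$degenerate) flags <- "degenerate"
  frame <- staArray(sta)[pk$lag, , ]
  gf <- if (pk$degenerate) {
    list(center = c(NA_real_, NA_real_), sigmas = c(NA_real_, NA_real_),
         amplitude = NA_real_, offset = NA_real_, rss = NA_real_,
         converged = FALSE)
  } else {
    fitGaussian2D(frame, c(pk$row, pk$col))
  }
  fit <- new("RFFit", cellId = cellId(sta),
             peakLag = as.integer(pk$lag),
             peakPixel = as.integer(c(pk$row, pk$col)),
             peakValue = pk$value,
             center = gf$center, sigmas = gf$sigmas,
             amplitude = gf$amplitude, offset = gf$offset, rss = gf$rss,
             converged = gf$converged, peakZ = NA_real_, valid = FALSE,
             flags = flags)
  v <- validateRF(fit, sta, zMin = zMin, alpha = alpha,
                  sigmaRange = sigmaRange)
  fit@peakZ <- attr(v, "peakZ")
  fit@valid <- as.logical(v) && !pk$degenerate
  fit
}
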