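## Build a minimal STA volume + fit around a given center-pixel series.
volumeWithSeries <- function(series, center = c(5, 5), dims = c(9, 9)) {
  v <- array(0, dim = c(length(series), dims[1], dims[2]))
  v[, center[1], center[2]] <- series
  sta <- new("STAVolume", cellId = "x", values = v, frameRateHz = 60,
             nSpikesUsed = 100L, nSpikesExcluded = 0L)
  fit <- new("RFFit", cellId = "x", peakLag = 1L,
             peakPixel = as.integer(center),
             peakValue = series[which.max(abs(series))],
             center = as.numeric(center), sigmas = c(1, 1),
             amplitude = 1, offset = 0, rss = 0, converged = TRUE,
             peakZ = 10, valid = TRUE, flags = character(0))
  list(sta = sta, fit = fit)
}

test_that("extraction reads exactly the center pixel's lag series", {
  series <- makeTemporalKernel(67, 1L)
  x <- volumeWithSeries(series)
  prof <- extractProfile(x$sta, x$fit)
  expect_identical(prof@values, series)
  expect_equal(lagTimesMs(prof), (1:18) * 1000 / 60, tolerance = 1e-9)
  expect_identical(polarity(prof), 1L)
})

test_that("a center outside the grid or an all-zero series is handled", {
  x <- volumeWithSeries(rep(0, 18))
  prof <- extractProfile(x$sta, x$fit)
  expect_true("degenerate" %in% prof@flags)
  xbad <- x
  xbad$fit@center <- c(50, 50)
  expect_error(extractProfile(xbad$sta, xbad$fit), "outside")
})

test_that("non-converged fits fall back to the peak pixel", {
  series <- makeTemporalKernel(50, -1L)
  x <- volumeWithSeries(series, center = c(3, 7))
  x$fit@peakPixel <- c(3L, 7L)
  x$fit@converged <- FALSE
  x$fit@center <- c(NA_real_, NA_real_)
  prof <- extractProfile(x$sta, x$fit)
  expect_identical(prof@values, series)
  expect_identical(polarity(prof), -1L)
})

test_that("spline refinement recovers an off-grid parabolic peak", {
  dt <- 1000 / 60
  lags <- (1:18) * dt
  # parabola peaking at 55 ms, between the 16.67 ms grid points, and
  # positive over the whole window so the peak is the global extremum
  series <- 1 - ((lags - 55) / 300)^2
  x <- volumeWithSeries(series)
  prof <- splineRefine(extractProfile(x$sta, x$fit))
  expect_equal(timeToPeak(prof), 55, tolerance = 0.5)
})

test_that("a peak lying exactly on a sample is preserved by the spline", {
  dt <- 1000 / 60
  lags <- (1:18) * dt
  series <- exp(-((lags - 4 * dt) / 40)^2)   # peak at sample 4 = 66.67 ms
  x <- volumeWithSeries(series)
  prof <- splineRefine(extractProfile(x$sta, x$fit))
  expect_equal(timeToPeak(prof), 4 * dt, tolerance = 1e-9)
})

test_that("zero crossings are reported on the spike-ward side only", {
  dt <- 1000 / 60
  lags <- (1:18) * dt
  # positive peak at ~100 ms with a negative lobe nearer the spike:
  # crossing must lie between them
  series <- sin((lags - 30) / 140 * pi)
  series[lags < 30] <- -0.2
  x <- volumeWithSeries(series)
  prof <- splineRefine(extractProfile(x$sta, x$fit))
  expect_identical(polarity(prof), 1L)
  expect_false(is.na(timeToZeroCross(prof)))
  expect_lt(timeToZeroCross(prof), timeToPeak(prof))

  # monotone profile: no crossing
  mono <- volumeWithSeries(seq(0.1, 1, length.out = 18))
  prof2 <- splineRefine(extractProfile(mono$sta, mono$fit))
  expect_true(is.na(timeToZeroCross(prof2)))

  # the generator's biphasic kernel has its rebound on the far side of
  # the peak, so no spike-ward crossing exists either
  kern <- volumeWithSeries(makeTemporalKernel(67, 1L))
  prof3 <- splineRefine(extractProfile(kern$sta, kern$fit))
  expect_true(is.na(timeToZeroCross(prof3)))
})

test_that("short profiles fall back to frame resolution with a flag", {
  x <- volumeWithSeries(c(0.1, 0.9, 0.3))
  prof <- extractProfile(x$sta, x$fit)
  expect_warning(prof <- splineRefine(prof), "frame-resolution")
  expect_true("frame_resolution" %in% prof@flags)
  expect_equal(timeToPeak(prof), 2 * 1000 / 60, tolerance = 1e-9)
})

test_that("an LN cell's profile recovers polarity and roughly its latency", {
  stim <- makeCheckerboard(9, frames = 12000)
  for (pol in c(1L, -1L)) {
    cell <- makeCell(polarity = pol, latency = 67.36, base = 25, gain = 18)
    tr <- simulateLNCell(cell, stim, seed = 41 + pol)
    sta <- computeSTA(stim, tr)
    prof <- splineRefine(extractProfile(sta, fitRF(sta)))
    expect_identical(polarity(prof), pol)
    expect_lt(abs(timeToPeak(prof) - 67.36), 10)
  }
})
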