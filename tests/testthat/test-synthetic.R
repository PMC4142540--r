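test_that("checkerboard values are binary, unbiased and seed-reproducible", {
  a <- makeCheckerboard(1, frames = 2, gridRows = 2, gridCols = 2)
  b <- makeCheckerboard(1, frames = 2, gridRows = 2, gridCols = 2)
  expect_identical(stimArray(a), stimArray(b))
  expect_true(all(stimArray(a) %in% c(-1L, 1L)))
  expect_false(identical(
    stimArray(makeCheckerboard(2, frames = 2, gridRows = 2, gridCols = 2)),
    stimArray(a)))

  # per-checker mean over 1e5 draws within 3 binomial standard errors
  big <- makeCheckerboard(7, frames = 1e5, gridRows = 1, gridCols = 1)
  expect_lt(abs(mean(stimArray(big))), 3 / sqrt(1e5))

  expect_equal(frameIntervalMs(a), 1000 / 60, tolerance = 1e-12)
  expect_equal(round(frameIntervalMs(a), 2), 16.67)
  expect_error(makeCheckerboard(1, frames = 0), "positive")
  expect_error(makeCheckerboard(1, frames = 2, gridRows = -1), "positive")
})

test_that("temporal kernel peaks exactly at the requested latency", {
  for (lat in c(40, 48.6, 67.36, 94.9, 110)) {
    tau <- seq(1, 300, by = 0.01)
    k <- makeTemporalKernel(lat, 1L, tauMs = tau, normalize = FALSE)
    expect_equal(tau[which.max(k)], lat, tolerance = 0.02)
    koff <- makeTemporalKernel(lat, -1L, tauMs = tau, normalize = FALSE)
    expect_equal(tau[which.min(koff)], lat, tolerance = 0.02)
    # single dominant extremum whose sign equals the polarity
    expect_gt(max(k), 0)
    expect_lt(max(-k) / max(k), 0.5)
  }
  expect_error(makeTemporalKernel(-5), "positive")
})

test_that("gain 0 gives a homogeneous Poisson-like train at the base rate", {
  stim <- makeCheckerboard(3, frames = 6000)  # 100 s at 60 fps
  cell <- makeCell(base = 8, gain = 0)
  tr <- simulateLNCell(cell, stim, seed = 11)
  lambda <- 8 * 100
  expect_lt(abs(nSpikes(tr) - lambda), 3 * sqrt(lambda))
  # same seed reproduces the identical train
  expect_identical(spikeTimes(simulateLNCell(cell, stim, seed = 11)),
                   spikeTimes(tr))
})

test_that("stimulus-independent spike counts pass a chi-square uniformity
           check in at least 19 of 20 seeds", {
  stim <- makeCheckerboard(4, frames = 3000)
  cell <- makeCell(base = 10, gain = 0)
  fails <- 0L
  for (s in 1:20) {
    tr <- simulateLNCell(cell, stim, seed = 100 + s)
    counts <- table(cut(spikeTimes(tr), breaks = seq(0, 50, by = 5)))
    p <- suppressWarnings(chisq.test(counts)$p.value)
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("ON drive makes the spike-conditioned stimulus at the center
           and peak lag positive", {
  stim <- makeCheckerboard(5, frames = 6000)
  cell <- makeCell(polarity = 1L, center = c(10, 10), latency = 67,
                   base = 8, gain = 8)
  tr <- simulateLNCell(cell, stim, seed = 12)
  # brute-force conditional average, independent of computeSTA
  fps <- frameRateHz(stim)
  f <- floor(spikeTimes(tr) * fps) + 1L
  lag <- round(67 / frameIntervalMs(stim))
  f <- f[f > lag]
  condMean <- mean(stimArray(stim)[f - lag, 10, 10])
  expect_gt(condMean, 0)
})

test_that("spike times always fall inside the recording and map back to
           their frame", {
  stim <- makeCheckerboard(6, frames = 1200)
  for (s in 1:5) {
    tr <- simulateLNCell(makeCell(gain = 6), stim, seed = s)
    ts <- spikeTimes(tr)
    expect_true(all(ts > 0 & ts < recordingDuration(tr)))
    expect_true(all(diff(ts) > 0))
  }
})

test_that("population generation respects counts, labels and seed", {
  pop <- makePopulation(2, 8, seed = 1, stimFrames = 600)
  expect_length(pop$cells, 10)
  pols <- vapply(pop$cells, polarity, integer(1))
  expect_identical(sum(pols == -1L), 8L)
  expect_identical(sum(pols == 1L), 2L)
  pop2 <- makePopulation(2, 8, seed = 1, stimFrames = 600)
  expect_identical(lapply(pop$trains, spikeTimes),
                   lapply(pop2$trains, spikeTimes))
  expect_error(makePopulation(-1, 5), "non-negative")
  expect_error(makePopulation(0, 0), ">= 1")
})

test_that("drawn latencies converge to the configured condition means", {
  # many cells on a tiny stimulus: only the parameter draws matter here
  pop <- makePopulation(60, 240, seed = 2, stimFrames = 60)
  lat <- vapply(pop$cells, function(c) c@peakLatencyMs, numeric(1))
  pol <- vapply(pop$cells, polarity, integer(1))
  d <- latencyDefaults("control")
  expect_lt(abs(mean(lat[pol > 0]) - d$on$meanMs),
            3 * d$on$sdMs / sqrt(sum(pol > 0)))
  expect_lt(abs(mean(lat[pol < 0]) - d$off$meanMs),
            3 * d$off$sdMs / sqrt(sum(pol < 0)))

  blk <- makePopulation(30, 30, condition = "blocker", seed = 3,
                        stimFrames = 60)
  latB <- vapply(blk$cells, function(c) c@peakLatencyMs, numeric(1))
  polB <- vapply(blk$cells, polarity, integer(1))
  db <- latencyDefaults("blocker")
  expect_lt(abs(mean(latB[polB > 0]) - db$on$meanMs),
            3 * db$on$sdMs / sqrt(30))
})

test_that("synthetic ERG hits its calibrated ground truth", {
  # noiseless trace: measured b equals ground truth
  tr <- simulateERG(1.82, "control", "degu_scotopic", seed = 1)
  expect_equal(tr@groundTruth$b_amp_uv, 105.1, tolerance = 1e-3)
  m <- measureWaves(tr)
  expect_equal(m@bAmpUv, tr@groundTruth$b_amp_uv, tolerance = 0.01 * 105.1)

  # all calibration anchors are reproduced by construction
  for (profile in c("degu_scotopic", "rat_scotopic", "degu_photopic",
                    "rat_photopic")) {
    pr <- retimea:::ergProfileTable()[[profile]]
    for (i in seq_along(pr$logI)) {
      tri <- simulateERG(pr$logI[i], "control", profile, seed = 1)
      expect_equal(tri@groundTruth$b_amp_uv, pr$bUv[i], tolerance = 1e-6)
    }
  }

  # blocker factor is a plain multiplicative scaling of the b-wave
  trb <- simulateERG(1.82, "blocker", "rat_scotopic", seed = 1,
                     blockerFactor = 0.478)
  expect_equal(trb@groundTruth$b_amp_uv, 569.7 * 0.478, tolerance = 1e-6)

  expect_error(simulateERG(1.82, "control", "gerbil_scotopic"),
               "unknown species profile")
  expect_error(simulateERG(9, "control", "degu_scotopic"), "range")
})

test_that("ERG noise is reproducible and scaled to the requested SD", {
  a <- simulateERG(1.82, "control", "degu_scotopic", seed = 4,
                   noiseSdUv = 5)
  b <- simulateERG(1.82, "control", "degu_scotopic", seed = 4,
                   noiseSdUv = 5)
  expect_identical(a@voltageUv, b@voltageUv)
  clean <- simulateERG(1.82, "control", "degu_scotopic", seed = 4)
  expect_equal(sd(a@voltageUv - clean@voltageUv), 5, tolerance = 1e-8)
})
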