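test_that("noiseless synthetic traces are measured within 1 percent", {
  tr <- simulateERG(1.82, "control", "degu_scotopic", seed = 1)
  m <- measureWaves(tr)
  expect_equal(m@bAmpUv, 105.1, tolerance = 0.01 * 105.1)
  expect_lt(m@aAmpUv, 0)
  expect_gt(m@bTimeMs, m@aTimeMs)
  expect_length(m@flags, 0)
})

test_that("amplitudes are exactly invariant to a constant offset", {
  tr <- simulateERG(1.82, "control", "degu_scotopic", seed = 2,
                    noiseSdUv = 5)
  shifted <- tr
  shifted@voltageUv <- tr@voltageUv + 123.4
  m0 <- measureWaves(tr)
  m1 <- measureWaves(shifted)
  expect_equal(m1@bAmpUv, m0@bAmpUv, tolerance = 1e-9)
  expect_equal(m1@aAmpUv, m0@aAmpUv, tolerance = 1e-9)
  expect_equal(m1@baselineUv, m0@baselineUv + 123.4, tolerance = 1e-9)
})

test_that("a flat trace yields missing waves, not a crash", {
  t <- seq(0, 500, by = 1)
  flat <- new("ERGTrace", timeMs = t, voltageUv = rep(3.5, length(t)),
              onsetMs = 100, intensityLog = 1, condition = "control",
              species = "", groundTruth = list())
  m <- measureWaves(flat)
  expect_true(all(c("a_missing", "b_missing") %in% m@flags))
  expect_true(is.na(m@aAmpUv) && is.na(m@bAmpUv))
})

test_that("the polynomial-refined extremum is exact for polynomial traces", {
  # cubic whose interior maximum lies at t = 160.4 ms, off the 1 ms
  # sample grid, with value 100 exactly (by construction: the derivative
  # -0.01 u - 3e-6 u^2, u = t - 160.4, has its only nearby root at u = 0)
  t <- seq(0, 500, by = 1)
  u <- t - 160.4
  poly <- 100 - 0.005 * u^2 - 1e-6 * u^3
  poly[t < 135] <- 0   # flat baseline; the fit window [135, 185] is pure cubic
  trace <- new("ERGTrace", timeMs = t, voltageUv = poly, onsetMs = 100,
               intensityLog = 1, condition = "control", species = "",
               groundTruth = list())
  m <- measureWaves(trace)
  expect_equal(m@bTimeMs, 60.4, tolerance = 1e-6)
  expect_equal(m@bAmpUv + m@baselineUv, 100, tolerance = 1e-6)
})

test_that("with 5 uV noise the mean b-wave error stays below 3 uV and
           beats the raw argmax", {
  errPoly <- errRaw <- numeric(30)
  for (s in 1:30) {
    tr <- simulateERG(1.76, "control", "degu_scotopic", seed = 500 + s,
                      noiseSdUv = 5)
    truth <- tr@groundTruth$b_amp_uv
    m <- measureWaves(tr)
    errPoly[s] <- abs(m@bAmpUv - truth)
    # raw-sample estimate: post-onset maximum minus baseline
    bas <- mean(tr@voltageUv[tr@timeMs >= 0 & tr@timeMs < 100])
    raw <- max(tr@voltageUv[tr@timeMs >= 100]) - bas
    errRaw[s] <- abs(raw - truth)
  }
  expect_lt(mean(errPoly), 3)
  expect_lt(mean(errPoly), mean(errRaw))
})

test_that("relative change reproduces table arithmetic", {
  expect_equal(relativeChange(272.4, 569.7), -52.2)
  expect_equal(relativeChange(97.7, 47.2), 107.0)
  expect_equal(relativeChange(5, 5), 0.0)
  expect_warning(rc <- relativeChange(1, 0), "zero")
  expect_true(is.na(rc))
})

test_that("paired t-test matches the closed form and stats::t.test", {
  x <- c(105.1, 98.2, 110.4, 99.9, 104.2, 101.3)
  y <- c(57.8, 60.1, 55.4, 58.8, 61.2, 54.9)
  res <- pairedTTest(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # brute-force formula
  d <- y - x
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)

  same <- pairedTTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen <- pairedTTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(is.infinite(degen$t) && degen$t > 0)
  expect_equal(degen$p, 0)
  expect_true("zero_variance" %in% degen$flags)

  expect_error(pairedTTest(1, 2), "at least 2")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("intensity-response tables summarise and order correctly", {
  meas <- list()
  for (li in c(-0.88, 0.52, 1.82)) {
    for (s in 1:4) {
      tr <- simulateERG(li, "control", "degu_scotopic",
                        seed = 10 * s + round(li * 100), noiseSdUv = 2)
      meas[[length(meas) + 1L]] <- measureWaves(tr)
    }
  }
  ir <- buildIntensityResponse(meas)
  expect_identical(ir$intensityLog, c(-0.88, 0.52, 1.82))
  expect_true(all(diff(ir$meanBUv) > 0))   # generator is monotone
  expect_true(attr(ir, "monotone")[["control"]])
  expect_true(all(ir$n == 4))
  expect_true(all(is.finite(ir$semBUv)))

  # single replicate: sem is missing
  one <- buildIntensityResponse(data.frame(
    intensityLog = 1, condition = "control", bAmpUv = 50))
  expect_true(is.na(one$semBUv))

  # published summary means re-ingested reproduce the curve points
  tab <- buildIntensityResponse(data.frame(
    intensityLog = c(-0.88, 0.52, 1.82), condition = "control",
    bAmpUv = c(9.8, 38.4, 105.1)))
  expect_equal(tab$meanBUv, c(9.8, 38.4, 105.1))
})

test_that("blocker scaling propagates through measurement and
           relative change", {
  ctl <- measureWaves(simulateERG(1.82, "control", "rat_scotopic",
                                  seed = 1))
  blk <- measureWaves(simulateERG(1.82, "blocker", "rat_scotopic",
                                  seed = 1))
  expect_equal(relativeChange(blk@bAmpUv, ctl@bAmpUv), -52.2,
               tolerance = 0.2)
})
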