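test_that("Welch t from summary statistics matches the closed form", {
  res <- welchTTest(1, 1, 10, 0, 1, 10)
  expect_equal(res$t, sqrt(10) / sqrt(2), tolerance = 1e-12)
  expect_equal(res$t, 2.236, tolerance = 1e-3)
  expect_equal(res$df, 18)

  eq <- welchTTest(5, 2, 10, 5, 3, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  degen <- welchTTest(1, 0, 5, 0, 0, 5)
  expect_true("degenerate" %in% degen$flags)
  expect_true(is.infinite(degen$t))
})

test_that("summary-stat and raw-sample Welch paths agree exactly with
           each other and with stats::t.test", {
  x <- withr::with_seed(1, rnorm(14, 67.4, 12))
  y <- withr::with_seed(2, rnorm(23, 94.9, 19))
  a <- welchTTestRaw(x, y)
  b <- welchTTest(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_identical(a, b)
  ref <- t.test(x, y)
  expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(a$p, ref$p.value, tolerance = 1e-12)
})

test_that("latency increments reproduce published-table arithmetic", {
  on <- latencyIncrement(64.81, 94.9)
  expect_equal(on$deltaMs, 30.1)
  expect_equal(on$deltaPercent, 46.4)
  off <- latencyIncrement(48.34, 61.5)
  expect_equal(off$deltaMs, 13.2)
  expect_equal(off$deltaPercent, 27.2)
  expect_equal(latencyIncrement(50, 50), list(deltaMs = 0, deltaPercent = 0))
  expect_warning(bad <- latencyIncrement(0, 10), "non-positive")
  expect_true(is.na(bad$deltaMs))
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(roundHalfUp(0.25, 1), 0.3)
  expect_equal(roundHalfUp(-0.25, 1), -0.3)
  expect_equal(roundHalfUp(2.349, 1), 2.3)
  expect_equal(roundHalfUp(107.05, 1), 107.1)
})

test_that("firing rates are counted per window and summarised per group", {
  tr <- makeTrain(seq(0.1, 1.9, by = 0.2), duration = 2)  # 10 spikes / 2 s
  out <- firingRateSummary(list(tr))
  expect_equal(out$meanRateHz, 5.0)
  expect_true(is.na(out$sdRateHz))

  empty <- new("SpikeTrain", cellId = "e", times = numeric(0), duration = 2)
  expect_equal(firingRateSummary(list(empty))$meanRateHz, 0)

  two <- firingRateSummary(list(tr, empty, tr),
                           groups = c("on", "off", "on"))
  expect_identical(two$group, c("off", "on"))
  expect_equal(two$meanRateHz, c(0, 5))
  expect_equal(two$n, c(1L, 2L))

  expect_error(firingRateSummary(list(tr), window = c(0, 5)), "within")
})

test_that("a blocker-like halving of the rate is recovered from simulated
           populations", {
  stim <- makeCheckerboard(11, frames = 2400)  # 40 s
  rateC <- rateB <- numeric(25)
  for (i in 1:25) {
    cc <- makeCell(id = "c", base = 8.2, gain = 6)
    cb <- makeCell(id = "b", base = 4.4, gain = 3.2, condition = "blocker")
    rateC[i] <- nSpikes(simulateLNCell(cc, stim, seed = 600 + i)) / 40
    rateB[i] <- nSpikes(simulateLNCell(cb, stim, seed = 700 + i)) / 40
  }
  expect_lt(abs(mean(rateB) / mean(rateC) - 4.4 / 8.2), 0.1)
})

test_that("significance stars follow the usual thresholds", {
  expect_identical(significanceStars(c(0.2, 0.04, 0.009, 0.0005, NA)),
                   c("", "*", "**", "***", ""))
})

test_that("reports are complete and byte-identical across reruns", {
  summaries <- list(
    counts = populationCounts(
      data.frame(cellType = rep(c("ON", "OFF"), c(240, 955)))),
    config = list(seed = 1, alpha = 0.01)
  )
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  p1 <- renderReport(summaries, d1)
  p2 <- renderReport(summaries, d2)
  expect_true(all(file.exists(p1)))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "counts.tsv")),
                   readLines(file.path(d2, "counts.tsv")))
  js <- jsonlite::read_json(file.path(d1, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(js$counts$percent, c(20.1, 79.9))
  expect_equal(js$config$seed, 1)

  # empty-table input still yields a well-formed report
  p3 <- renderReport(list(counts = data.frame(cellType = character(0),
                                              n = integer(0))),
                     file.path(tempdir(), "rep3"))
  expect_true(all(file.exists(p3)))
})
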