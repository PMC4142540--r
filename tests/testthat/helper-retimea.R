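## Shared fixture builders. Everything is generated in code; sizes are
## kept small enough for a fast default run.

makeCell <- function(id = "c1", polarity = 1L, center = c(10, 10),
                     sigma = 1, latency = 67.36, base = 8.2,
                     gain = 0.75 * base, condition = "control") {
  new("GroundTruthCell", cellId = id, polarity = as.integer(polarity),
      center = center, sigma = sigma, peakLatencyMs = latency,
      baseRateHz = base, gain = gain, condition = condition)
}

makeTrain <- function(times, duration = max(times) + 1, id = "u1") {
  new("SpikeTrain", cellId = id, times = times, duration = duration)
}

## Spike train independent of the stimulus (homogeneous Bernoulli-frame
## process), for null receptive-field checks.
poissonTrain <- function(stim, rateHz, seed, id = "null") {
  dt <- frameIntervalMs(stim) / 1000
  withr::with_seed(seed, {
    sp <- which(stats::rbinom(nFrames(stim), 1L, rateHz * dt) == 1L)
    makeTrain((sp - 0.5) * dt, duration = nFrames(stim) * dt, id = id)
  })
}

## Frame-resolution temporal profile built directly from the kernel
## shape (bypasses spiking), for classification tests.
kernelProfile <- function(latency, polarity = 1L, noiseSd = 0,
                          id = "p1", seed = NULL, nLags = 18,
                          dtMs = 1000 / 60) {
  vals <- makeTemporalKernel(latency, polarity,
                             tauMs = seq_len(nLags) * dtMs)
  if (noiseSd > 0) {
    stopifnot(!is.null(seed))
    vals <- vals + withr::with_seed(seed, stats::rnorm(nLags, 0, noiseSd))
  }
  new("TemporalProfile", cellId = id,
      lagTimesMs = seq_len(nLags) * dtMs, values = vals,
      splineTimesMs = numeric(0), splineValues = numeric(0),
      timeToPeakMs = NA_real_, timeToZeroCrossMs = NA_real_,
      polarity = as.integer(polarity), flags = character(0))
}
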