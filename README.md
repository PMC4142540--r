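# retimea

Receptive-field estimation and ON/OFF classification for retinal
multi-electrode recordings, plus ERG a-/b-wave quantification.

## What this package is for

Retinal physiologists characterise ganglion-cell (GC) output by
stimulating an isolated retina with binary checkerboard white noise on
a multi-electrode array and reverse-correlating spikes with the
stimulus, and characterise the retina's massed light response in vivo
with the electroretinogram (ERG). `retimea` implements that analysis
chain as a tested, reusable pipeline:

* **Spike-triggered average (STA).** For a spike train and a
  checkerboard movie at 60 fps, the STA volume holds, per pre-spike lag
  `k = 1..18` (a 300 ms window), the mean stimulus frame shown `k`
  frames before each spike. Under white noise the STA estimates the
  cell's linear spatiotemporal receptive field (RF).
* **RF localisation and validity.** Maximal-deviation pixel, an
  axis-aligned 2D Gaussian fit for the fractional center, and a
  validity rule scoring the peak z against the noise floor of the two
  longest-lag frames with a volume-size-aware (Bonferroni) threshold.
* **Temporal profiles and classification.** The RF-center pixel's lag
  series, refined by cubic-spline interpolation on a 1 ms grid, yields
  time-to-peak and time-to-zero-cross latencies and the ON/OFF type
  (sign of the extremum); PCA + k-means groups profiles into
  functional clusters.
* **ERG quantification.** Baseline-referenced a-wave (trough) and
  b-wave (peak) amplitudes by local fifth-order polynomial fitting,
  intensity–response curves, paired and Welch t-tests, relative
  changes and latency increments.
* **Synthetic data with ground truth.** Linear–nonlinear–Poisson model
  cells (`rate = max(0, r0 + g * filtered stimulus)`, per-frame
  Bernoulli spiking) and parametric ERG waveforms whose
  intensity–response follows a Naka–Rushton curve calibrated exactly
  through published control means for degu and rat under scotopic and
  photopic adaptation. Every stage is testable end to end without any
  recorded data.

## A worked example

```r
library(retimea)

stim <- makeCheckerboard(seed = 1, frames = 12000)   # 200 s at 60 fps
cell <- new("GroundTruthCell", cellId = "gc1", polarity = -1L,
            center = c(9, 12), sigma = 1, peakLatencyMs = 48.6,
            baseRateHz = 6.2, gain = 4.65, condition = "control")
spikes <- simulateLNCell(cell, stim, seed = 2)
spikes
#> SpikeTrain 'gc1': 1312 spikes over 200.0 s (6.56 spikes/s)

sta <- computeSTA(stim, spikes)
sta
#> STAVolume 'gc1': 18 lags x 19x19 checkers (300 ms window), 1310 spikes used (2 excluded)

fit <- fitRF(sta)
fit
#> RFFit 'gc1': peak -0.266 at lag 3, pixel (9, 12)
#>   gaussian center (9.05, 11.94), sigmas (0.90, 0.98)
#>   peak z = 9.66, valid = TRUE

profile <- splineRefine(extractProfile(sta, fit))
profile
#> TemporalProfile 'gc1': OFF, time-to-peak 46.7 ms, zero-cross 17.3 ms
```

The OFF cell planted at checker (9, 12) with a 48.6 ms peak latency is
recovered as a valid RF at (9.05, 11.94) — within a tenth of a checker
— with a negative (OFF) STA extremum 3 frames (50 ms) before the
spike, spline-refined to 46.7 ms. The z score of 9.66 is the peak
deviation in units of the volume's long-lag noise SD.

The ERG branch works the same way:

```r
erg <- simulateERG(1.82, "control", "degu_scotopic", seed = 3,
                   noiseSdUv = 5)
measureWaves(erg)
#> ERGMeasurement (log I = 1.82, control): a = -34.3 uV @ 18.4 ms, b = 101.2 uV @ 76.9 ms
```

The generator's ground-truth b amplitude at this intensity is 105.1 uV
(the calibrated control mean for dark-adapted degu); with 5 uV of
band-limited noise the fifth-order polynomial refinement recovers
101.2 uV.

Summary statistics mirror published table arithmetic:

```r
latencyIncrement(64.81, 94.9)
#> $deltaMs
#> [1] 30.1
#> $deltaPercent
#> [1] 46.4

welchTTest(94.9, 19.3, 23, 64.81, 8.41, 180)$p
#> [1] 1.599696e-07
```

A one-call pipeline over all stages (simulate → STA → classify →
stats → ERG) is available as `runPipeline(pipelineConfig(seed = 1),
"outdir")`, or from a shell via
`Rscript inst/scripts/run-pipeline.R --seed 1 --outdir outdir`.

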