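## Central S4 containers. All classes are plain value objects with
## validity checks; heavy computation lives in the stage functions.

#' StimulusMovie: a binary checkerboard stimulus
#'
#' Frame-indexed spatial contrast array shown during a multi-electrode
#' recording. Values are binary contrast (-1 = dark, +1 = bright) per
#' checker per frame; the checker edge length in micrometers and the frame
#' rate are carried as metadata. A movie is regenerable bit-exactly from
#' its seed and dimensions (see [makeCheckerboard()]), so on disk it is
#' stored as a small JSON descriptor.
#'
#' @slot values integer array `frames x rows x cols` with entries in
#'   \{-1, +1\}.
#' @slot frameRateHz frames per second (default 60).
#' @slot checkerSizeUm checker edge length in micrometers (default 100).
#' @slot seed integer seed the movie was generated from (NA if unknown).
#'
#' @name StimulusMovie-class
#' @aliases StimulusMovie
#' @exportClass StimulusMovie
setClass("StimulusMovie",
  representation(
    values = "array",
    frameRateHz = "numeric",
    checkerSizeUm = "numeric",
    seed = "integer"
  )
)

setValidity("StimulusMovie", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("'values' must be a 3D array")
  if (any(dim(v) < 1L)) return("all stimulus dimensions must be >= 1")
  if (!all(v == 1L | v == -1L)) return("stimulus values must be -1 or +1")
  if (object@frameRateHz <= 0) return("'frameRateHz' must be positive")
  if (object@checkerSizeUm <= 0) return("'checkerSizeUm' must be positive")
  TRUE
})

#' SpikeTrain: sorted spike times for one unit
#'
#' Spike times (seconds from stimulus onset) of a single sorted unit;
#' the conditioning events for the spike-triggered average. Spike sorting
#' itself is out of scope: trains are consumed as two-column delimited
#' text (see [readSpikeTrains()]).
#'
#' @slot cellId unit identifier.
#' @slot times strictly increasing spike times in seconds.
#' @slot duration recording duration in seconds.
#'
#' @name SpikeTrain-class
#' @aliases SpikeTrain
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    cellId = "character",
    times = "numeric",
    duration = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  t <- object@times
  if (length(object@duration) != 1L || object@duration <= 0) {
    return("'duration' must be a single positive number")
  }
  if (length(t)) {
    if (any(!is.finite(t))) return("spike times must be finite")
    if (any(t < 0) || any(t > object@duration)) {
      return("spike times must lie within [0, duration]")
    }
    if (any(diff(t) <= 0)) return("spike times must be strictly increasing")
  }
  TRUE
})

#' GroundTruthCell: generative parameters of a model ganglion cell
#'
#' Parameters of one linear-nonlinear-Poisson model cell used by the
#' synthetic-data module: a separable receptive field (axis-symmetric
#' spatial Gaussian times a biphasic temporal kernel whose dominant lobe
#' peaks `peakLatencyMs` before the spike and whose sign equals
#' `polarity`), followed by a rectified-linear rate nonlinearity.
#'
#' @slot cellId cell identifier.
#' @slot polarity +1 (ON) or -1 (OFF); sign of the kernel's dominant lobe.
#' @slot center receptive-field center `(row, col)` in checker units
#'   (fractional allowed).
#' @slot sigma spatial Gaussian SD in checkers.
#' @slot peakLatencyMs latency of the kernel's dominant extremum, in ms
#'   before the spike.
#' @slot baseRateHz baseline firing rate of the nonlinearity (spikes/s).
#' @slot gain drive-to-rate gain (spikes/s per unit filtered contrast).
#' @slot condition `"control"` or `"blocker"` (pharmacological condition
#'   the parameters emulate).
#'
#' @name GroundTruthCell-class
#' @aliases GroundTruthCell
#' @exportClass GroundTruthCell
setClass("GroundTruthCell",
  representation(
    cellId = "character",
    polarity = "integer",
    center = "numeric",
    sigma = "numeric",
    peakLatencyMs = "numeric",
    baseRateHz = "numeric",
    gain = "numeric",
    condition = "character"
  )
)

setValidity("GroundTruthCell", function(object) {
  if (!object@polarity %in% c(-1L, 1L)) return("'polarity' must be +1 or -1")
  if (length(object@center) != 2L) return("'center' must be (row, col)")
  if (object@sigma <= 0) return("'sigma' must be positive")
  if (object@peakLatencyMs <= 0) return("'peakLatencyMs' must be positive")
  if (object@baseRateHz < 0) return("'baseRateHz' must be non-negative")
  if (!object@condition %in% c("control", "blocker")) {
    return("'condition' must be 'control' or 'blocker'")
  }
  TRUE
})

#' STAVolume: a spike-triggered average spatiotemporal volume
#'
#' The spike-conditioned mean stimulus, one spatial frame per pre-spike
#' lag: lag k holds the average of the stimulus frames shown k frames
#' before each usable spike, minus the stimulus mean. At the default
#' 60 fps and a 300 ms window the volume has 18 lag frames.
#'
#' @slot cellId cell identifier.
#' @slot values numeric array `nLags x rows x cols` (mean-subtracted).
#' @slot frameRateHz stimulus frame rate, frames/s.
#' @slot nSpikesUsed number of spikes entering the average.
#' @slot nSpikesExcluded spikes discarded because fewer than `nLags`
#'   stimulus frames preceded them (or they fell outside the stimulus).
#'
#' @name STAVolume-class
#' @aliases STAVolume
#' @exportClass STAVolume
setClass("STAVolume",
  representation(
    cellId = "character",
    values = "array",
    frameRateHz = "numeric",
    nSpikesUsed = "integer",
    nSpikesExcluded = "integer"
  )
)

setValidity("STAVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("'values' must be a 3D array")
  if (any(!is.finite(object@values))) return("STA values must be finite")
  if (object@nSpikesUsed < 0L) return("'nSpikesUsed' must be >= 0")
  if (object@frameRateHz <= 0) return("'frameRateHz' must be positive")
  TRUE
})

#' RFFit: receptive-field localisation and validity for one cell
#'
#' Result of locating the maximal-deviation pixel of an [STAVolume],
#' fitting an axis-aligned 2D Gaussian around it, and scoring the peak
#' against the volume's noise floor (see [fitRF()], [validateRF()]).
#'
#' @slot cellId cell identifier.
#' @slot peakLag lag index (1 = one frame before the spike) of the
#'   maximal absolute deviation.
#' @slot peakPixel integer `(row, col)` of the maximal deviation.
#' @slot peakValue signed STA value at the peak (contrast units).
#' @slot center fitted Gaussian center `(row, col)`, fractional checkers.
#' @slot sigmas fitted Gaussian SDs `(sigma_row, sigma_col)` in checkers.
#' @slot amplitude fitted Gaussian amplitude.
#' @slot offset fitted constant offset.
#' @slot rss residual sum of squares of the Gaussian fit.
#' @slot converged did the nonlinear fit converge.
#' @slot peakZ peak value in units of the long-lag noise SD.
#' @slot valid receptive field accepted as real (see [validateRF()]).
#' @slot flags character vector of quality flags (e.g. `"degenerate"`).
#'
#' @name RFFit-class
#' @aliases RFFit
#' @exportClass RFFit
setClass("RFFit",
  representation(
    cellId = "character",
    peakLag = "integer",
    peakPixel = "integer",
    peakValue = "numeric",
    center = "numeric",
    sigmas = "numeric",
    amplitude = "numeric",
    offset = "numeric",
    rss = "numeric",
    converged = "logical",
    peakZ = "numeric",
    valid = "logical",
    flags = "character"
  )
)

#' TemporalProfile: receptive-field time course of one cell
#'
#' STA value at the receptive-field center pixel as a function of
#' pre-spike lag, optionally refined by cubic-spline interpolation on a
#' 1 ms grid. Latencies are reported as positive milliseconds before the
#' spike (time zero = spike occurrence). The zero crossing is sought on
#' the spike-ward side of the peak and recorded as `NA` when the profile
#' does not change sign there.
#'
#' @slot cellId cell identifier.
#' @slot lagTimesMs pre-spike lag per sample, ms (frame interval times
#'   lag index).
#' @slot values STA value at the center pixel per lag.
#' @slot splineTimesMs spline evaluation grid, ms (empty until
#'   [splineRefine()] is run).
#' @slot splineValues interpolated profile on `splineTimesMs`.
#' @slot timeToPeakMs latency of the maximal absolute deviation, ms
#'   before the spike.
#' @slot timeToZeroCrossMs latency at which the profile first crosses
#'   zero moving from the peak toward the spike (`NA` if absent).
#' @slot polarity +1 if the peak deviation is positive (ON), -1 if
#'   negative (OFF).
#' @slot flags quality flags (`"degenerate"`, `"frame_resolution"`).
#'
#' @name TemporalProfile-class
#' @aliases TemporalProfile
#' @exportClass TemporalProfile
setClass("TemporalProfile",
  representation(
    cellId = "character",
    lagTimesMs = "numeric",
    values = "numeric",
    splineTimesMs = "numeric",
    splineValues = "numeric",
    timeToPeakMs = "numeric",
    timeToZeroCrossMs = "numeric",
    polarity = "integer",
    flags = "character"
  )
)

setValidity("TemporalProfile", function(object) {
  if (length(object@lagTimesMs) != length(object@values)) {
    return("'lagTimesMs' and 'values' must have equal length")
  }
  if (length(object@splineTimesMs) != length(object@splineValues)) {
    return("spline grid and values must have equal length")
  }
  TRUE
})

#' ERGTrace: one electroretinogram voltage trace
#'
#' Uniformly sampled corneal field potential around a light flash. For
#' synthetic traces the generator's noiseless component amplitudes are
#' carried in `groundTruth`.
#'
#' @slot timeMs uniform time grid in ms.
#' @slot voltageUv voltage in microvolts.
#' @slot onsetMs stimulus (flash) onset on the time grid, ms.
#' @slot intensityLog flash intensity, log photons/um^2 (opaque label).
#' @slot condition `"control"` or `"blocker"`.
#' @slot species species/adaptation profile label (e.g.
#'   `"degu_scotopic"`); empty for real data.
#' @slot groundTruth list with `a_amp_uv`, `b_amp_uv`, `a_time_ms`,
#'   `b_time_ms` for synthetic traces; empty list otherwise.
#'
#' @name ERGTrace-class
#' @aliases ERGTrace
#' @exportClass ERGTrace
setClass("ERGTrace",
  representation(
    timeMs = "numeric",
    voltageUv = "numeric",
    onsetMs = "numeric",
    intensityLog = "numeric",
    condition = "character",
    species = "character",
    groundTruth = "list"
  )
)

setValidity("ERGTrace", function(object) {
  t <- object@timeMs
  if (length(t) != length(object@voltageUv)) {
    return("'timeMs' and 'voltageUv' must have equal length")
  }
  if (length(t) > 2L) {
    dt <- diff(t)
    if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
      return("'timeMs' must be a uniform grid")
    }
    if (dt[1] <= 0) return("'timeMs' must be increasing")
  }
  if (object@onsetMs < t[1] || object@onsetMs > t[length(t)]) {
    return("'onsetMs' must lie within the time grid")
  }
  TRUE
})

#' ERGMeasurement: extracted a-/b-wave amplitudes of one trace
#'
#' Baseline-referenced trough (a-wave, negative) and peak (b-wave,
#' positive) amplitudes of an [ERGTrace], with the refined extremum times
#' measured from stimulus onset. Missing waves are `NA` and flagged.
#'
#' @slot intensityLog flash intensity label of the parent trace.
#' @slot condition condition label of the parent trace.
#' @slot aAmpUv a-wave amplitude, uV (negative; `NA` if missing).
#' @slot bAmpUv b-wave amplitude, uV (positive; `NA` if missing).
#' @slot aTimeMs a-wave trough time from onset, ms.
#' @slot bTimeMs b-wave peak time from onset, ms.
#' @slot baselineUv mean pre-onset baseline voltage, uV.
#' @slot flags quality flags (`"a_missing"`, `"b_missing"`,
#'   `"window_clipped"`).
#'
#' @name ERGMeasurement-class
#' @aliases ERGMeasurement
#' @exportClass ERGMeasurement
setClass("ERGMeasurement",
  representation(
    intensityLog = "numeric",
    condition = "character",
    aAmpUv = "numeric",
    bAmpUv = "numeric",
    aTimeMs = "numeric",
    bTimeMs = "numeric",
    baselineUv = "numeric",
    flags = "character"
  )
)

setValidity("ERGMeasurement", function(object) {
  if (is.finite(object@aTimeMs) && is.finite(object@bTimeMs) &&
      object@bTimeMs <= object@aTimeMs) {
    return("'bTimeMs' must exceed 'aTimeMs' when both waves are detected")
  }
  TRUE
})
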