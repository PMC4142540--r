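## Generics and accessor methods. Slots are never accessed with `@` from
## user code; these accessors are the supported surface.

#' @rdname accessors
#' @param x a retimea object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("frameRateHz", function(x) standardGeneric("frameRateHz"))

#' @rdname accessors
#' @export
setGeneric("frameIntervalMs", function(x) standardGeneric("frameIntervalMs"))

#' @rdname accessors
#' @export
setGeneric("stimArray", function(x) standardGeneric("stimArray"))

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("nLags", function(x) standardGeneric("nLags"))

#' @rdname accessors
#' @export
setGeneric("lagTimesMs", function(x) standardGeneric("lagTimesMs"))

#' @rdname accessors
#' @export
setGeneric("staArray", function(x) standardGeneric("staArray"))

#' @rdname accessors
#' @export
setGeneric("nSpikesUsed", function(x) standardGeneric("nSpikesUsed"))

#' @rdname accessors
#' @export
setGeneric("rfCenter", function(x) standardGeneric("rfCenter"))

#' @rdname accessors
#' @export
setGeneric("isValidRF", function(x) standardGeneric("isValidRF"))

#' @rdname accessors
#' @export
setGeneric("peakZ", function(x) standardGeneric("peakZ"))

#' @rdname accessors
#' @export
setGeneric("timeToPeak", function(x) standardGeneric("timeToPeak"))

#' @rdname accessors
#' @export
setGeneric("timeToZeroCross", function(x) standardGeneric("timeToZeroCross"))

#' @rdname accessors
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' Accessors for retimea classes
#'
#' Read-only accessors for the slots of [StimulusMovie], [SpikeTrain],
#' [STAVolume], [RFFit] and [TemporalProfile] objects.
#'
#' @return the corresponding slot value (`gridDims` and `rfCenter` return
#'   length-2 numeric vectors `(row, col)`).
#' @name accessors
#' @aliases nFrames,StimulusMovie-method
NULL

setMethod("nFrames", "StimulusMovie", function(x) dim(x@values)[1L])
setMethod("gridDims", "StimulusMovie", function(x) dim(x@values)[2:3])
setMethod("frameRateHz", "StimulusMovie", function(x) x@frameRateHz)
setMethod("frameIntervalMs", "StimulusMovie", function(x) 1000 / x@frameRateHz)
setMethod("stimArray", "StimulusMovie", function(x) x@values)

setMethod("cellId", "SpikeTrain", function(x) x@cellId)
setMethod("cellId", "GroundTruthCell", function(x) x@cellId)
setMethod("cellId", "STAVolume", function(x) x@cellId)
setMethod("cellId", "RFFit", function(x) x@cellId)
setMethod("cellId", "TemporalProfile", function(x) x@cellId)

setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
setMethod("recordingDuration", "SpikeTrain", function(x) x@duration)

setMethod("nLags", "STAVolume", function(x) dim(x@values)[1L])
setMethod("gridDims", "STAVolume", function(x) dim(x@values)[2:3])
setMethod("frameRateHz", "STAVolume", function(x) x@frameRateHz)
setMethod("frameIntervalMs", "STAVolume", function(x) 1000 / x@frameRateHz)
setMethod("lagTimesMs", "STAVolume", function(x) {
  seq_len(nLags(x)) * frameIntervalMs(x)
})
setMethod("staArray", "STAVolume", function(x) x@values)
setMethod("nSpikesUsed", "STAVolume", function(x) x@nSpikesUsed)

setMethod("rfCenter", "RFFit", function(x) x@center)
setMethod("rfCenter", "GroundTruthCell", function(x) x@center)
setMethod("isValidRF", "RFFit", function(x) x@valid)
setMethod("peakZ", "RFFit", function(x) x@peakZ)

setMethod("lagTimesMs", "TemporalProfile", function(x) x@lagTimesMs)
setMethod("timeToPeak", "TemporalProfile", function(x) x@timeToPeakMs)
setMethod("timeToZeroCross", "TemporalProfile", function(x) x@timeToZeroCrossMs)
setMethod("polarity", "TemporalProfile", function(x) x@polarity)
setMethod("polarity", "GroundTruthCell", function(x) x@polarity)

setMethod("show", "StimulusMovie", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "StimulusMovie: %d frames of %dx%d checkers (%.0f um) at %g fps (%.2f ms/frame)\n",
    d[1], d[2], d[3], object@checkerSizeUm, object@frameRateHz,
    1000 / object@frameRateHz))
  if (!is.na(object@seed)) cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (%.2f spikes/s)\n",
              object@cellId, length(object@times), object@duration,
              length(object@times) / object@duration))
})

setMethod("show", "GroundTruthCell", function(object) {
  cat(sprintf(
    "GroundTruthCell '%s': %s, center (%.2f, %.2f), sigma %.2f, peak %.1f ms, %s\n",
    object@cellId, if (object@polarity > 0) "ON" else "OFF",
    object@center[1], object@center[2], object@sigma,
    object@peakLatencyMs, object@condition))
})

setMethod("show", "STAVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "STAVolume '%s': %d lags x %dx%d checkers (%.0f ms window), %d spikes used (%d excluded)\n",
    object@cellId, d[1], d[2], d[3], d[1] * 1000 / object@frameRateHz,
    object@nSpikesUsed, object@nSpikesExcluded))
})

setMethod("show", "RFFit", function(object) {
  cat(sprintf("RFFit '%s': peak %.3f at lag %d, pixel (%d, %d)\n",
              object@cellId, object@peakValue, object@peakLag,
              object@peakPixel[1], object@peakPixel[2]))
  cat(sprintf("  gaussian center (%.2f, %.2f), sigmas (%.2f, %.2f)%s\n",
              object@center[1], object@center[2],
              object@sigmas[1], object@sigmas[2],
              if (object@converged) "" else " [not converged]"))
  cat(sprintf("  peak z = %.2f, valid = %s\n", object@peakZ, object@valid))
})

setMethod("show", "TemporalProfile", function(object) {
  cat(sprintf(
    "TemporalProfile '%s': %s, time-to-peak %.1f ms, zero-cross %s\n",
    object@cellId, if (object@polarity > 0) "ON" else "OFF",
    object@timeToPeakMs,
    if (is.na(object@timeToZeroCrossMs)) "absent"
    else sprintf("%.1f ms", object@timeToZeroCrossMs)))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "ERGTrace", function(object) {
  cat(sprintf(
    "ERGTrace: %d samples, %.1f-%.1f ms, onset %.1f ms, log I = %.2f, %s%s\n",
    length(object@timeMs), object@timeMs[1], tail(object@timeMs, 1),
    object@onsetMs, object@intensityLog, object@condition,
    if (nzchar(object@species)) paste0(" (", object@species, ")") else ""))
})

setMethod("show", "ERGMeasurement", function(object) {
  cat(sprintf(
    "ERGMeasurement (log I = %.2f, %s): a = %s uV @ %s ms, b = %s uV @ %s ms\n",
    object@intensityLog, object@condition,
    fmtNum(object@aAmpUv), fmtNum(object@aTimeMs),
    fmtNum(object@bAmpUv), fmtNum(object@bTimeMs)))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

fmtNum <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", x)
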