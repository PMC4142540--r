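## Readers and writers for the package's plain-text interchange formats:
## spike tables (TSV: cell_id, time_s), stimulus descriptors (JSON),
## ERG traces (TSV: time_ms, voltage_uv + JSON sidecar). All round-trips
## are lossless to the stated precision; malformed rows are reported
## with their line numbers.

#' Write spike trains to a two-column delimited table
#'
#' @param trains list of [SpikeTrain] objects (or a single one).
#' @param path output file; tab-separated with header
#'   `cell_id\ttime_s`. Times are written with microsecond precision.
#' @param duration recording duration recorded in a header comment line.
#' @return invisibly, `path`.
#' @export
writeSpikeTrains <- function(trains, path, duration = NULL) {
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  stopifnot(all(vapply(trains, is, logical(1), "SpikeTrain")))
  if (is.null(duration)) {
    duration <- max(vapply(trains, recordingDuration, numeric(1)))
  }
  df <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(cell_id = rep(cellId(tr), nSpikes(tr)),
               time_s = sprintf("%.6f", spikeTimes(tr)),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.6f", duration), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from a delimited table
#'
#' Expects the format written by [writeSpikeTrains()]: an optional
#' `# duration_s=` comment, a `cell_id`/`time_s` header, one spike per
#' row. Non-numeric or negative times and non-monotone times within a
#' cell are reported as errors with the offending line number.
#'
#' @param path input file.
#' @param duration recording duration in seconds; when `NULL`, taken
#'   from the header comment (or the last spike time if absent).
#' @return named list of [SpikeTrain] objects.
#' @export
readSpikeTrains <- function(path, duration = NULL) {
  lines <- readLines(path)
  hdrDur <- grep("^# *duration_s=", lines, value = TRUE)
  if (is.null(duration) && length(hdrDur)) {
    duration <- as.numeric(sub("^# *duration_s=", "", hdrDur[1]))
  }
  body <- grep("^#", lines, invert = TRUE)
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  hdrLine <- body[1]
  cols <- strsplit(lines[hdrLine], "\t", fixed = TRUE)[[1]]
  need <- c("cell_id", "time_s")
  if (!all(need %in% cols)) {
    stop(sprintf("schema mismatch in %s: missing column '%s'", path,
                 setdiff(need, cols)[1]), call. = FALSE)
  }
  rows <- body[-1]
  if (!length(rows)) stop("no spikes in ", path, call. = FALSE)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s", rows[bad[1]], path),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  colnames(m) <- cols
  timeChr <- m[, "time_s"]
  times <- suppressWarnings(as.numeric(timeChr))
  if (anyNA(times)) {
    stop(sprintf("non-numeric time_s at line %d of %s",
                 rows[which(is.na(times))[1]], path), call. = FALSE)
  }
  if (any(times < 0)) {
    stop(sprintf("negative time_s at line %d of %s",
                 rows[which(times < 0)[1]], path), call. = FALSE)
  }
  if (is.null(duration)) duration <- max(times)
  ids <- m[, "cell_id"]
  out <- lapply(unique(ids), function(id) {
    sel <- which(ids == id)
    tt <- times[sel]
    nonMono <- which(diff(tt) <= 0)
    if (length(nonMono)) {
      stop(sprintf("non-monotone spike times for cell '%s' at line %d of %s",
                   id, rows[sel[nonMono[1] + 1L]], path), call. = FALSE)
    }
    new("SpikeTrain", cellId = id, times = tt, duration = duration)
  })
  names(out) <- unique(ids)
  out
}

#' Write / read a stimulus descriptor
#'
#' A [StimulusMovie] is fully determined by its seed and dimensions, so
#' it is stored as a small JSON descriptor; reading regenerates the
#' identical movie via [makeCheckerboard()].
#'
#' @param stim a [StimulusMovie] generated by [makeCheckerboard()] (its
#'   seed must be known).
#' @param path JSON file path.
#' @return `writeStimulusDescriptor`: invisibly, `path`;
#'   `readStimulusDescriptor`: the regenerated [StimulusMovie].
#' @export
writeStimulusDescriptor <- function(stim, path) {
  stopifnot(is(stim, "StimulusMovie"))
  if (is.na(stim@seed)) {
    stop("stimulus has no seed: cannot serialise as a descriptor",
         call. = FALSE)
  }
  d <- dim(stim@values)
  jsonlite::write_json(list(
    seed = stim@seed, frames = d[1], grid_rows = d[2], grid_cols = d[3],
    frame_rate_hz = stim@frameRateHz, checker_size_um = stim@checkerSizeUm
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStimulusDescriptor
#' @export
readStimulusDescriptor <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("seed", "frames", "grid_rows", "grid_cols", "frame_rate_hz")
  miss <- setdiff(need, names(js))
  if (length(miss)) {
    stop(sprintf("stimulus descriptor %s: missing field '%s'", path,
                 miss[1]), call. = FALSE)
  }
  makeCheckerboard(js$seed, js$frames, js$grid_rows, js$grid_cols,
                   js$frame_rate_hz,
                   if (is.null(js$checker_size_um)) 100 else
                     js$checker_size_um)
}

#' Write / read an ERG trace
#'
#' The voltage series is stored as tab-separated `time_ms`/`voltage_uv`
#' text; onset, intensity, condition, species and any ground truth go to
#' a JSON sidecar (`<path>.json`).
#'
#' @param trace an [ERGTrace].
#' @param path TSV file path.
#' @return `writeERGTrace`: invisibly, `path`; `readERGTrace`: the
#'   [ERGTrace].
#' @export
writeERGTrace <- function(trace, path) {
  stopifnot(is(trace, "ERGTrace"))
  df <- data.frame(time_ms = sprintf("%.6f", trace@timeMs),
                   voltage_uv = sprintf("%.6f", trace@voltageUv))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    onset_ms = trace@onsetMs, intensity_log = trace@intensityLog,
    condition = trace@condition, species = trace@species,
    ground_truth = trace@groundTruth
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeERGTrace
#' @export
readERGTrace <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_ms", "voltage_uv")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("schema mismatch in %s: missing column '%s'", path,
                 miss[1]), call. = FALSE)
  }
  meta <- list(onset_ms = 0, intensity_log = NA_real_,
               condition = "control", species = "", ground_truth = list())
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(js)] <- js
  }
  new("ERGTrace", timeMs = as.numeric(df$time_ms),
      voltageUv = as.numeric(df$voltage_uv),
      onsetMs = as.numeric(meta$onset_ms),
      intensityLog = as.numeric(meta$intensity_log),
      condition = meta$condition, species = meta$species,
      groundTruth = as.list(meta$ground_truth))
}

#' Write a table of receptive-field fits
#'
#' One row per cell: id, peak lag and pixel, Gaussian center and sigmas,
#' z score and validity.
#'
#' @param fits list of [RFFit] objects.
#' @param path output TSV path (omit to get the data.frame only).
#' @return the assembled data.frame, invisibly when written.
#' @export
rfFitTable <- function(fits, path = NULL) {
  stopifnot(all(vapply(fits, is, logical(1), "RFFit")))
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f@cellId, peak_lag = f@peakLag,
               peak_row = f@peakPixel[1], peak_col = f@peakPixel[2],
               peak_value = f@peakValue,
               center_row = f@center[1], center_col = f@center[2],
               sigma_row = f@sigmas[1], sigma_col = f@sigmas[2],
               peak_z = f@peakZ, valid = f@valid,
               stringsAsFactors = FALSE)
  }))
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
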