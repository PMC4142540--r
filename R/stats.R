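#' Welch's t-test from summary statistics
#'
#' Two-sided Welch (unequal-variance) t-test computed from group means,
#' SDs and sizes: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom. Useful for comparing latency
#' distributions reported only as mean +/- SD per condition.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (n1 >= 2,
#'   sd1 >= 0).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `p` and `flags` (`"degenerate"` when
#'   both variances are zero).
#' @export
#' @examples
#' welchTTest(94.9, 19.3, 23, 64.81, 8.41, 180)
welchTTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  flags <- character(0)
  if (v1 + v2 == 0) {
    flags <- "degenerate"
    if (mean1 == mean2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      t <- sign(mean1 - mean2) * Inf; df <- n1 + n2 - 2; p <- 0
    }
  } else {
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df = df)
  }
  list(t = t, df = df, p = p, flags = flags)
}

#' Welch's t-test from raw samples
#'
#' Computes the group summaries and delegates to [welchTTest()], so the
#' raw-sample and summary-statistic paths agree exactly.
#'
#' @param x,y numeric sample vectors (each of length >= 2).
#' @return as [welchTTest()].
#' @export
welchTTestRaw <- function(x, y) {
  welchTTest(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Latency increment between conditions
#'
#' Treated-minus-control change in mean time-to-peak, in ms and as a
#' percentage of the control mean, both rounded half-away-from-zero to
#' one decimal (reproducing table-style reporting such as a 30.1 ms /
#' 46.4 percent ON-latency increase).
#'
#' @param controlMean,treatedMean mean time-to-peak per condition, ms
#'   (`controlMean > 0`).
#' @return list with `deltaMs` and `deltaPercent`; both `NA` with a
#'   warning for a non-positive control mean.
#' @export
#' @examples
#' latencyIncrement(64.81, 94.9)  # 30.1 ms, 46.4 %
latencyIncrement <- function(controlMean, treatedMean) {
  if (controlMean <= 0) {
    warning("non-positive control mean: increment undefined")
    return(list(deltaMs = NA_real_, deltaPercent = NA_real_))
  }
  delta <- treatedMean - controlMean
  list(deltaMs = roundHalfUp(delta, 1),
       deltaPercent = roundHalfUp(100 * delta / controlMean, 1))
}

#' Firing-rate summary per group
#'
#' Mean +/- SD of the firing rate (spike count in a time window divided
#' by the window length) across spike trains, grouped e.g. by cell type
#' or condition. Empty trains contribute a rate of 0.
#'
#' @param trains list of [SpikeTrain] objects.
#' @param window numeric `(start, end)` in seconds; defaults to the full
#'   recording of each train.
#' @param groups optional vector of group labels (one per train);
#'   a single group when missing.
#' @return data.frame with columns `group`, `meanRateHz`, `sdRateHz`,
#'   `n`.
#' @export
firingRateSummary <- function(trains, window = NULL, groups = NULL) {
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, is, logical(1), "SpikeTrain")))
  rates <- vapply(trains, function(tr) {
    w <- if (is.null(window)) c(0, recordingDuration(tr)) else window
    if (w[2] <= w[1]) stop("'window' must have positive length",
                           call. = FALSE)
    if (w[1] < 0 || w[2] > recordingDuration(tr)) {
      stop("'window' must lie within the recording", call. = FALSE)
    }
    ts <- spikeTimes(tr)
    sum(ts >= w[1] & ts <= w[2]) / (w[2] - w[1])
  }, numeric(1))
  if (is.null(groups)) groups <- rep("all", length(trains))
  out <- do.call(rbind, lapply(split(rates, groups), function(r) {
    data.frame(meanRateHz = mean(r),
               sdRateHz = if (length(r) > 1L) sd(r) else NA_real_,
               n = length(r))
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""`
#' otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star strings.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Render delimited and JSON reports of the population summaries
#'
#' Writes the supplied summary tables as tab-delimited text plus a
#' single JSON report bundling every table with the configuration used
#' (seeds, thresholds), so a report documents its own provenance.
#' Output is byte-identical across reruns on identical input.
#'
#' @param summaries named list of data.frames (each written to
#'   `<name>.tsv`) plus optionally `config`, a list recorded only in the
#'   JSON report.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
renderReport <- function(summaries, dir) {
  stopifnot(is.list(summaries))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  isTab <- vapply(summaries, is.data.frame, logical(1))
  paths <- character(0)
  for (nm in names(summaries)[isTab]) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(summaries[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(summaries, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(paths, jp))
}
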