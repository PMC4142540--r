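#' Measure ERG a- and b-wave amplitudes
#'
#' Quantifies one flash response: the baseline is the mean voltage over
#' the `baselineMs` window before stimulus onset; the a-wave is the
#' earliest post-onset local minimum falling below baseline (by more
#' than 3 baseline SDs, a noise guard that is inactive on noiseless
#' traces); the b-wave is the subsequent maximum. Each raw extremum is
#' refined by least-squares fitting a fifth-order polynomial over a
#' +/-`fitHalfWindowMs` window around it and taking the fitted
#' extremum (located exactly from the roots of the fitted derivative).
#' Amplitudes are fitted extremum minus baseline, so they are invariant
#' to constant offsets. A missing wave is reported as `NA` with a flag;
#' fit windows clipped at a trace edge are fitted on the available
#' samples and flagged.
#'
#' @param trace an [ERGTrace] spanning the baseline window and at least
#'   250 ms after onset.
#' @param baselineMs pre-onset baseline window length, ms (default 100).
#' @param fitHalfWindowMs half-width of the polynomial fit window, ms
#'   (default 25).
#' @return an [ERGMeasurement].
#' @export
#' @examples
#' tr <- simulateERG(1.82, "control", "degu_scotopic", seed = 1)
#' measureWaves(tr)
measureWaves <- function(trace, baselineMs = 100, fitHalfWindowMs = 25) {
  stopifnot(is(trace, "ERGTrace"))
  t <- trace@timeMs
  v <- trace@voltageUv
  on <- trace@onsetMs
  if (on - t[1] < baselineMs) {
    stop("trace does not span the pre-onset baseline window", call. = FALSE)
  }
  if (t[length(t)] - on < 250) {
    stop("trace must extend at least 250 ms past stimulus onset",
         call. = FALSE)
  }
  basIdx <- which(t >= on - baselineMs & t < on)
  baseline <- mean(v[basIdx])
  noiseSd <- sd(v[basIdx])
  if (!is.finite(noiseSd)) noiseSd <- 0
  flags <- character(0)

  post <- which(t >= on)
  tp <- t[post]; vp <- v[post]
  n <- length(vp)

  # earliest post-onset local minimum below baseline (noise-guarded)
  thrA <- baseline - 3 * noiseSd
  isMin <- c(FALSE, vp[2:(n - 1)] < vp[1:(n - 2)] &
                    vp[2:(n - 1)] <= vp[3:n], FALSE)
  aCand <- which(isMin & vp < thrA)
  aIdx <- if (length(aCand)) post[aCand[1]] else NA_integer_

  # subsequent maximum (global post-onset maximum when no a-wave)
  bFrom <- if (is.na(aIdx)) post[1] else aIdx + 1L
  bReg <- seq.int(bFrom, post[n])
  bIdxRaw <- bReg[which.max(v[bReg])]
  bIdx <- if (v[bIdxRaw] > baseline + 3 * noiseSd) bIdxRaw else NA_integer_

  refine <- function(idx, type) {
    res <- refineExtremum(t, v, idx, fitHalfWindowMs, type)
    if (res$clipped) flags <<- unique(c(flags, "window_clipped"))
    res
  }
  if (!is.na(aIdx)) {
    aref <- refine(aIdx, "min")
    aAmp <- aref$value - baseline
    aTime <- aref$time - on
  } else {
    flags <- c(flags, "a_missing")
    aAmp <- NA_real_; aTime <- NA_real_
  }
  if (!is.na(bIdx)) {
    bref <- refine(bIdx, "max")
    bAmp <- bref$value - baseline
    bTime <- bref$time - on
  } else {
    flags <- c(flags, "b_missing")
    bAmp <- NA_real_; bTime <- NA_real_
  }
  new("ERGMeasurement", intensityLog = trace@intensityLog,
      condition = trace@condition, aAmpUv = aAmp, bAmpUv = bAmp,
      aTimeMs = aTime, bTimeMs = bTime, baselineUv = baseline,
      flags = flags)
}

## Fit a 5th-order polynomial around sample `idx` and return its
## extremum of the requested type, located from the real roots of the
## fitted derivative inside the window (falling back to the best
## window sample if no interior critical point of the right type
## exists).
refineExtremum <- function(t, v, idx, halfWindowMs, type = c("max", "min")) {
  type <- match.arg(type)
  win <- which(t >= t[idx] - halfWindowMs & t <= t[idx] + halfWindowMs)
  clipped <- t[idx] - halfWindowMs < t[1] ||
             t[idx] + halfWindowMs > t[length(t)]
  tw <- t[win]; vw <- v[win]
  deg <- min(5L, length(win) - 1L)
  if (deg < 1L) {
    return(list(time = t[idx], value = v[idx], clipped = clipped))
  }
  tc <- tw - t[idx]                     # center for conditioning
  fit <- lm(vw ~ poly(tc, deg, raw = TRUE))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0
  dcoef <- beta[-1] * seq_len(deg)      # derivative coefficients
  roots <- polyroot(dcoef)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  real <- real[real >= min(tc) & real <= max(tc)]
  evalPoly <- function(x) {
    drop(outer(x, 0:deg, "^") %*% beta)
  }
  cand <- c(real, min(tc), max(tc))
  vals <- evalPoly(cand)
  i <- if (type == "max") which.max(vals) else which.min(vals)
  list(time = cand[i] + t[idx], value = vals[i], clipped = clipped)
}

#' Relative change between condition means
#'
#' `100 * (treated - control) / control`, rounded half-away-from-zero to
#' one decimal (so published values like a -52.2 percent b-wave
#' reduction are reproduced exactly from the underlying means).
#'
#' @param meanTreated,meanControl condition means (same units).
#' @return percent change (one decimal); `NA` with a warning when the
#'   control mean is zero.
#' @export
#' @examples
#' relativeChange(272.4, 569.7)  # -52.2
relativeChange <- function(meanTreated, meanControl) {
  if (any(meanControl == 0)) {
    warning("control mean is zero: relative change undefined")
    return(NA_real_)
  }
  roundHalfUp(100 * (meanTreated - meanControl) / meanControl, 1)
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test computed in closed form from the pairwise
#' differences. Degenerate inputs follow the documented conventions:
#' identical vectors give `t = 0, p = 1`; constant non-zero differences
#' (zero variance) give an infinite t with `p = 0` and a
#' `"zero_variance"` flag.
#'
#' @param control,treated paired numeric vectors of equal length
#'   (n >= 2).
#' @return list with `t`, `df`, `p`, `meanDiff` and `flags`.
#' @export
#' @examples
#' pairedTTest(c(105.1, 110, 98), c(57.8, 60, 55))
pairedTTest <- function(control, treated) {
  if (length(control) != length(treated)) {
    stop("'control' and 'treated' must have equal length", call. = FALSE)
  }
  n <- length(control)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- treated - control
  md <- mean(d)
  s <- sd(d)
  flags <- character(0)
  if (s == 0) {
    if (md == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(md) * Inf; p <- 0
      flags <- "zero_variance"
    }
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p = p, meanDiff = md, flags = flags)
}

#' Build an intensity-response table
#'
#' Per-intensity, per-condition mean b-wave amplitude with s.e.m.
#' (reported `NA` for single replicates) and n, sorted by increasing
#' intensity. Monotonicity of the means in intensity is reported per
#' condition as attribute `monotone`, not enforced.
#'
#' @param measurements list of [ERGMeasurement] objects, or a data.frame
#'   with columns `intensityLog`, `condition`, `bAmpUv`.
#' @return data.frame with columns `condition`, `intensityLog`,
#'   `meanBUv`, `semBUv`, `n`.
#' @export
buildIntensityResponse <- function(measurements) {
  df <- if (is.data.frame(measurements)) {
    measurements
  } else {
    stopifnot(length(measurements) >= 1L,
              all(vapply(measurements, is, logical(1), "ERGMeasurement")))
    data.frame(
      intensityLog = vapply(measurements, function(m) m@intensityLog,
                            numeric(1)),
      condition = vapply(measurements, function(m) m@condition,
                         character(1)),
      bAmpUv = vapply(measurements, function(m) m@bAmpUv, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(df) >= 1L)
  df <- df[is.finite(df$bAmpUv), , drop = FALSE]
  grp <- interaction(df$condition, df$intensityLog, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, grp), function(g) {
    data.frame(
      condition = g$condition[1],
      intensityLog = g$intensityLog[1],
      meanBUv = mean(g$bAmpUv),
      semBUv = if (nrow(g) > 1L) sd(g$bAmpUv) / sqrt(nrow(g)) else NA_real_,
      n = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$condition, out$intensityLog), , drop = FALSE]
  rownames(out) <- NULL
  mono <- vapply(split(out, out$condition), function(g) {
    all(diff(g$meanBUv[order(g$intensityLog)]) > 0)
  }, logical(1))
  attr(out, "monotone") <- mono
  out
}
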