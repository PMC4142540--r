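#' Classify temporal profiles by PCA + k-means
#'
#' Projects spline-refined temporal profiles onto the leading principal
#' components (enough to explain at least `varianceCutoff` of the
#' variance, capped at `maxPcs`) and partitions them with k-means
#' (`nstart` restarts under a fixed seed, best inertia kept). Functional
#' clusters are descriptive subtypes; the ON/OFF type is assigned
#' independently of the clustering from each profile's polarity (sign of
#' the global extremum), so the two labelling schemes cannot disagree by
#' construction.
#'
#' @param profiles list of [TemporalProfile] objects sharing one lag
#'   grid (spline-refined profiles use their spline values).
#' @param k number of clusters (default 5). When fewer profiles than `k`
#'   are supplied, `k` is reduced with a warning.
#' @param varianceCutoff minimum cumulative explained variance of the
#'   retained components (default 0.9).
#' @param maxPcs cap on retained components (default 5).
#' @param nstart k-means restarts (default 20).
#' @param seed RNG seed for the k-means restarts (default 1).
#' @return data.frame with one row per cell: `cellId`, `cluster`,
#'   `cellType` (`"ON"`/`"OFF"`), `timeToPeakMs`, `timeToZeroCrossMs`
#'   and the retained PC coordinates (`pc1`, `pc2`, ...). The number of
#'   retained components is attached as attribute `nPcs`.
#' @export
classifyProfiles <- function(profiles, k = 5, varianceCutoff = 0.9,
                             maxPcs = 5, nstart = 20, seed = 1) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "TemporalProfile")))
  n <- length(profiles)
  if (n < k) {
    warning(sprintf("only %d profiles: reducing k from %d to %d", n, k, n))
    k <- n
  }
  rows <- lapply(profiles, function(p) {
    if (length(p@splineValues)) p@splineValues else p@values
  })
  len <- vapply(rows, length, integer(1))
  if (length(unique(len)) != 1L) {
    stop("profiles must share a common (spline) time grid", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  # standardise each time point across cells; drop constant columns
  sds <- apply(m, 2, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all profiles are constant", call. = FALSE)
  pca <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  nPcs <- min(which(cumsum(ev) >= varianceCutoff), maxPcs, ncol(pca$x))
  nPcs <- max(nPcs, 1L)
  coords <- pca$x[, seq_len(nPcs), drop = FALSE]
  clusters <- if (k >= n) {
    seq_len(n)  # trivial partition: kmeans needs k < n
  } else {
    withSeed(seed, kmeans(coords, centers = k, nstart = nstart))$cluster
  }
  out <- data.frame(
    cellId = vapply(profiles, cellId, character(1)),
    cluster = as.integer(clusters),
    cellType = ifelse(vapply(profiles, polarity, integer(1)) > 0,
                      "ON", "OFF"),
    timeToPeakMs = vapply(profiles, timeToPeak, numeric(1)),
    timeToZeroCrossMs = vapply(profiles, timeToZeroCross, numeric(1)),
    stringsAsFactors = FALSE
  )
  colnames(coords) <- paste0("pc", seq_len(nPcs))
  out <- cbind(out, as.data.frame(coords, row.names = NULL))
  attr(out, "nPcs") <- nPcs
  out
}

#' Tabulate ON/OFF counts and percentages
#'
#' Counts cells per type (and per condition when present) and reports
#' percentages of the condition total rounded half-away-from-zero to one
#' decimal, the convention of published distribution tables (e.g. ON 240
#' of 1195 is reported as 20.1).
#'
#' @param results data.frame with a `cellType` column and optionally a
#'   `condition` column (e.g. the output of [classifyProfiles()]).
#' @return data.frame with columns `condition` (if supplied),
#'   `cellType`, `n`, `percent`.
#' @export
#' @examples
#' populationCounts(data.frame(cellType = rep(c("ON", "OFF"), c(240, 955))))
populationCounts <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            "cellType" %in% names(results))
  hasCond <- "condition" %in% names(results)
  split <- if (hasCond) split(results, results$condition) else list(results)
  out <- do.call(rbind, lapply(seq_along(split), function(i) {
    g <- split[[i]]
    tab <- table(factor(g$cellType, levels = c("ON", "OFF")))
    tab <- tab[tab > 0 | names(tab) %in% g$cellType]
    df <- data.frame(
      cellType = names(tab),
      n = as.integer(tab),
      percent = roundHalfUp(100 * as.integer(tab) / nrow(g), 1),
      stringsAsFactors = FALSE
    )
    if (hasCond) df <- cbind(condition = names(split)[i], df)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Best-permutation agreement between two labelings
#'
#' Accuracy of a clustering against ground-truth group labels, maximised
#' over all assignments of cluster labels to groups (exhaustive over the
#' k! permutations; k <= 8).
#'
#' @param truth vector of ground-truth group labels.
#' @param clusters vector of cluster labels of equal length.
#' @return proportion of items correctly assigned under the best
#'   label permutation.
#' @export
#' @examples
#' bestPermutationAccuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
bestPermutationAccuracy <- function(truth, clusters) {
  stopifnot(length(truth) == length(clusters))
  tl <- unique(truth)
  cl <- unique(clusters)
  if (length(cl) > 8L) stop("too many clusters for exhaustive matching",
                            call. = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  # map each cluster label to a truth label; extra/missing labels allowed
  ktab <- table(factor(clusters, levels = cl), factor(truth, levels = tl))
  best <- 0
  if (length(cl) <= length(tl)) {
    for (p in perms(seq_along(tl))) {
      sel <- p[seq_along(cl)]
      best <- max(best, sum(ktab[cbind(seq_along(cl), sel)]))
    }
  } else {
    for (p in perms(seq_along(cl))) {
      sel <- p[seq_along(tl)]
      best <- max(best, sum(ktab[cbind(sel, seq_along(tl))]))
    }
  }
  best / length(truth)
}
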