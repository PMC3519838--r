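# Overlapped and Enhanced k-means (Fahim-style point shortcuts).
#
# Both variants keep two per-point caches, Clusterid and Pointdis: the
# cluster each point was last assigned to and the distance recorded for it.
# Per iteration each point is first compared only against the updated
# centroid of its own cluster (one distance evaluation); if that distance
# does not exceed the cached one the point stays put, otherwise it is
# reassigned against all k centroids. The variants differ only in the
# cache-refresh policy for kept points.

# Row-wise distance between data[i, ] and cen[i, ] for all i.
pairDistance <- function(data, cen, kind) {
  if (kind %in% c("sq_euclidean", "euclidean")) {
    d2 <- rowSums((data - cen)^2)
    if (kind == "euclidean") sqrt(d2) else d2
  } else {
    a <- data - rowMeans(data)
    b <- cen - rowMeans(cen)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    r <- ifelse(den == 0, 0, rowSums(a * b) / den)
    if (any(den == 0)) {
      warning("zero-variance vector in pearson_dissimilarity; treating r as 0")
    }
    1 - r
  }
}

runFahim <- function(data, params, refreshKept, algorithm, audit = FALSE) {
  stopifnotMatrix(data)
  if (nrow(data) < params@k) stop("need n >= k")
  n <- nrow(data); k <- params@k; kind <- params@distance
  cen <- list(means = initCentroids(data, params), sizes = integer(k))
  trace <- emptyTrace()
  evals <- 0
  converged <- FALSE
  auditLog <- if (audit) list() else NULL

  # Iteration 1: full assignment, caches filled for every point.
  a <- assignPoints(data, cen$means, NULL, NULL, kind)
  labels <- a$labels
  pointdis <- pairDistance(data, cen$means[labels, , drop = FALSE], kind)
  evals <- evals + a$distEvals
  trace[1L, ] <- list(1L, clusterMSE(data, cen$means, labels), a$moved, 0L,
                      evals)
  cen <- updateCentroids(data, labels, k, cen$means)

  for (i in seq.int(2L, length.out = params@maxIter - 1L)) {
    dNew <- pairDistance(data, cen$means[labels, , drop = FALSE], kind)
    keep <- dNew <= pointdis
    if (audit) {
      auditLog[[length(auditLog) + 1L]] <- list(
        iteration = i, kept = which(keep), dNew = dNew, cached = pointdis,
        labels = labels, means = cen$means)
    }
    moved <- 0L
    evals <- evals + n                       # one probe per point
    if (refreshKept) pointdis[keep] <- dNew[keep]
    if (!all(keep)) {
      idx <- which(!keep)
      D <- distanceMatrix(data[idx, , drop = FALSE], cen$means, kind)
      newLab <- max.col(-D, ties.method = "first")
      evals <- evals + length(idx) * (k - 1L)  # own-centroid probe reused
      moved <- sum(newLab != labels[idx])
      labels[idx] <- newLab
      pointdis[idx] <- D[cbind(seq_along(idx), newLab)]
    }
    trace[i, ] <- list(i, clusterMSE(data, cen$means, labels),
                       as.integer(moved), 0L, evals)
    cen <- updateCentroids(data, labels, k, cen$means)
    if (moved == 0L) { converged <- TRUE; break }
  }
  run <- makeRun("KmeansRun", algorithm, data, labels, cen, trace, params,
                 converged)
  if (audit) attr(run, "audit") <- auditLog
  run
}

#' Enhanced k-means (point-stability shortcut, cache refreshed)
#'
#' Per iteration each point is probed once against its own cluster's
#' updated centroid; if that distance is no larger than the cached
#' point-to-centroid distance, the point keeps its membership and the
#' cache is refreshed to the new distance. Otherwise the point is
#' reassigned against all k centroids. The per-iteration trace exposes the
#' resulting distance-evaluation counts so the shortcut's cost can be
#' compared with Traditional k-means.
#'
#' @param data n x d numeric matrix.
#' @param params a \code{\link{KmeansParams}}.
#' @param audit if TRUE, attach a per-iteration log of kept-point shortcut
#'   decisions (attribute \code{"audit"}) for verification.
#' @return a \code{\linkS4class{KmeansRun}}.
#' @export
runEnhanced <- function(data, params, audit = FALSE) {
  runFahim(data, params, refreshKept = TRUE, algorithm = "enhanced",
           audit = audit)
}

#' Overlapped k-means (point-stability shortcut, cache anchored)
#'
#' Identical loop to \code{\link{runEnhanced}} except that the cached
#' distance of a kept point is NOT refreshed: comparisons stay anchored to
#' the distance recorded at the point's last full reassignment. The
#' distinction between the two variants is under-documented in the
#' original design; this cache-refresh policy is the package's documented
#' reading, with all other machinery shared.
#'
#' @inheritParams runEnhanced
#' @return a \code{\linkS4class{KmeansRun}}.
#' @export
runOverlapped <- function(data, params, audit = FALSE) {
  runFahim(data, params, refreshKept = FALSE, algorithm = "overlapped",
           audit = audit)
}
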