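#' Pearson correlation between two vectors
#'
#' Sample Pearson product-moment correlation. A vector with zero variance
#' has no defined correlation; following the package's degenerate-input
#' policy the function then returns 0 with a warning (clustered expression
#' centroids are flat only in pathological cases, and 0 keeps downstream
#' eigenvalue computations finite).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \code{[-1, 1]}.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 4))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  if (length(x) < 2L) stop("need at least 2 coordinates")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero-variance vector in pearsonR; returning 0")
    return(0)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
  min(1, max(-1, r))
}

#' Distance between two points
#'
#' @param x,y numeric vectors of equal length.
#' @param kind \code{"sq_euclidean"} (default), \code{"euclidean"}, or
#'   \code{"pearson_dissimilarity"} (\code{1 - r(x, y)}).
#' @return a non-negative scalar.
#' @examples
#' pointDistance(c(0, 0), c(3, 4))                  # 25
#' pointDistance(c(0, 0), c(3, 4), "euclidean")     # 5
#' @export
pointDistance <- function(x, y, kind = c("sq_euclidean", "euclidean",
                                         "pearson_dissimilarity")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("dimension mismatch")
  switch(kind,
    sq_euclidean = sum((x - y)^2),
    euclidean = sqrt(sum((x - y)^2)),
    pearson_dissimilarity = 1 - pearsonR(x, y)
  )
}

# n x k matrix of distances from each data row to each centroid row.
# One vectorised evaluation per (point, centroid) pair; callers account
# for nrow(data) * nrow(centroids) distance evaluations per call.
distanceMatrix <- function(data, centroids, kind) {
  if (kind %in% c("sq_euclidean", "euclidean")) {
    d2 <- outer(rowSums(data^2), rep(1, nrow(centroids))) +
      outer(rep(1, nrow(data)), rowSums(centroids^2)) -
      2 * tcrossprod(data, centroids)
    d2[d2 < 0] <- 0
    if (kind == "euclidean") sqrt(d2) else d2
  } else {
    r <- suppressWarnings(stats::cor(t(data), t(centroids)))
    if (anyNA(r)) {
      warning("zero-variance vector in pearson_dissimilarity; treating r as 0")
      r[is.na(r)] <- 0
    }
    1 - r
  }
}

#' Mean squared error of a clustering
#'
#' Mean squared Euclidean distance of each point to its assigned centroid.
#' Always squared-Euclidean-based, whatever distance kind drove the
#' assignment, so objective curves are comparable across distance kinds.
#'
#' @param data n x d numeric matrix.
#' @param centroids k x d matrix of centroids.
#' @param labels integer assignment in \code{1..k}.
#' @return non-negative scalar.
#' @export
clusterMSE <- function(data, centroids, labels) {
  if (length(labels) != nrow(data)) stop("labels/data mismatch")
  mean(rowSums((data - centroids[labels, , drop = FALSE])^2))
}

#' Initial centroids
#'
#' Forgy sampling (\code{init = "forgy_sample"}): k distinct rows drawn
#' without replacement using \code{params@seed} — deterministic given the
#' seed and never touching the caller's RNG. \code{"first_k"}: rows
#' \code{1..k}. Cross-algorithm comparisons must share seed and init so
#' all variants start from the same centroids.
#'
#' @param data n x d numeric matrix.
#' @param params a \code{\link{KmeansParams}}.
#' @return k x d matrix.
#' @export
initCentroids <- function(data, params) {
  stopifnotMatrix(data)
  k <- params@k
  if (nrow(data) < k) stop("need n >= k")
  rows <- switch(params@init,
    first_k = seq_len(k),
    forgy_sample = withSeed(params@seed, sample.int(nrow(data), k))
  )
  m <- data[rows, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Assign points to nearest centroids
#'
#' Every point whose previous cluster is not frozen is assigned to the
#' nearest of ALL k centroids (ties to the lowest cluster index, making
#' runs bit-reproducible); a point whose previous cluster is frozen keeps
#' its label and costs no distance evaluations.
#'
#' @param data n x d matrix.
#' @param centroids k x d matrix.
#' @param frozen logical k-vector of per-cluster stability flags (default
#'   none frozen).
#' @param prevLabels previous assignment (NULL on the first pass).
#' @param kind distance kind (see \code{\link{pointDistance}}).
#' @return list with \code{labels} (integer n-vector), \code{moved}
#'   (points that changed cluster; \code{n} on the first pass) and
#'   \code{distEvals} (point-centroid distance computations performed).
#' @export
assignPoints <- function(data, centroids, frozen = NULL, prevLabels = NULL,
                         kind = "sq_euclidean") {
  n <- nrow(data); k <- nrow(centroids)
  if (is.null(frozen)) frozen <- rep(FALSE, k)
  if (length(frozen) != k) stop("frozen must have length k")
  if (!is.null(prevLabels) && length(prevLabels) != n) {
    stop("prevLabels/data mismatch")
  }
  active <- if (is.null(prevLabels)) rep(TRUE, n) else !frozen[prevLabels]
  labels <- if (is.null(prevLabels)) integer(n) else as.integer(prevLabels)
  if (any(active)) {
    D <- distanceMatrix(data[active, , drop = FALSE], centroids, kind)
    labels[active] <- max.col(-D, ties.method = "first")
  }
  moved <- if (is.null(prevLabels)) n else sum(labels != prevLabels)
  list(labels = labels, moved = as.integer(moved),
       distEvals = sum(active) * k)
}

#' Update centroids
#'
#' Each cluster's centroid becomes the mean of its member rows. A cluster
#' with no members keeps its previous mean and reports size 0 (it is not
#' re-seeded); empty clusters are expected when k exceeds the data
#' dimension.
#'
#' @param data n x d matrix.
#' @param labels assignment in \code{1..k}.
#' @param k cluster count.
#' @param previous k x d matrix of previous centroids.
#' @return list with \code{means} (k x d) and \code{sizes} (integer k).
#' @export
updateCentroids <- function(data, labels, k, previous) {
  sizes <- tabulate(labels, nbins = k)
  means <- previous
  present <- which(sizes > 0L)
  sums <- rowsum(data, group = labels, reorder = TRUE)
  means[present, ] <- sums / sizes[present]
  list(means = means, sizes = as.integer(sizes))
}

# Shared plumbing to package a finished run.
makeRun <- function(class, algorithm, data, labels, cen, trace, params,
                    converged, ...) {
  new(class, algorithm = algorithm,
      labels = stats::setNames(as.integer(labels), matrixIds(data)),
      centroids = cen$means, sizes = cen$sizes,
      trace = trace, params = params, converged = converged, ...)
}

emptyTrace <- function() {
  data.frame(iteration = integer(), mse = numeric(), moved = integer(),
             stable_clusters = integer(), dist_evals = numeric())
}

#' Traditional (Lloyd) k-means
#'
#' Plain Lloyd iterations: assign each point to the nearest centroid, then
#' recompute centroids as cluster means; stop when no point moves or after
#' \code{maxIter} iterations. The trace records the objective after each
#' assignment step, so with squared-Euclidean assignment the MSE sequence
#' is non-increasing. Deterministic given \code{params@seed}.
#'
#' @param data n x d numeric matrix (rownames become point ids).
#' @param params a \code{\link{KmeansParams}}.
#' @return a \code{\linkS4class{KmeansRun}}.
#' @examples
#' sim <- generateMixture(n = 300, d = 8, kTrue = 3, seed = 5)
#' fit <- runTraditional(sim$data, KmeansParams(k = 3, seed = 5))
#' fit
#' @export
runTraditional <- function(data, params) {
  stopifnotMatrix(data)
  if (nrow(data) < params@k) stop("need n >= k")
  k <- params@k
  cen <- list(means = initCentroids(data, params),
              sizes = integer(k))
  labels <- NULL
  trace <- emptyTrace()
  evals <- 0
  converged <- FALSE
  for (i in seq_len(params@maxIter)) {
    a <- assignPoints(data, cen$means, NULL, labels, params@distance)
    evals <- evals + a$distEvals
    mse <- clusterMSE(data, cen$means, a$labels)
    trace[i, ] <- list(i, mse, a$moved, 0L, evals)
    labels <- a$labels
    cen <- updateCentroids(data, labels, k, cen$means)
    if (a$moved == 0L) { converged <- TRUE; break }
  }
  makeRun("KmeansRun", "traditional", data, labels, cen, trace, params,
          converged)
}
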