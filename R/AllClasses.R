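#' @import methods
NULL

#' Tuning parameters for the k-means family
#'
#' Holds every tunable shared by \code{\link{runTraditional}},
#' \code{\link{runEnhanced}}, \code{\link{runOverlapped}} and
#' \code{\link{runMMKmeans}}. Construct with \code{\link{KmeansParams}}.
#'
#' @slot k cluster count.
#' @slot seed RNG seed used by Forgy initialization.
#' @slot maxIter iteration cap.
#' @slot distance assignment distance: \code{"sq_euclidean"},
#'   \code{"euclidean"} or \code{"pearson_dissimilarity"}.
#' @slot init \code{"forgy_sample"} (k distinct rows drawn with \code{seed})
#'   or \code{"first_k"}.
#' @slot L0,H1 lower/upper ends of the stability band applied to relative
#'   eigenvalue changes of the metric matrix (defaults 0.5\% and 1.5\%).
#' @slot epsilon convergence-band half-width used to detect the switch-on
#'   iteration (MMI); default 0.007.
#' @slot epsilonMode \code{"relative"} (band is \code{epsilon * MSE_1}) or
#'   \code{"absolute"}.
#' @slot stabilityMode \code{"threshold"} (stable when the relative
#'   eigenvalue change is at most \code{H1}) or \code{"strict_interval"}
#'   (change must lie in \code{[L0, H1]}).
#' @slot mmiOverride optional fixed MMI; \code{Inf} disables the stability
#'   mechanism entirely; \code{NA} (default) means estimate MMI from data.
#' @exportClass KmeansParams
setClass("KmeansParams",
  representation(
    k = "integer",
    seed = "integer",
    maxIter = "integer",
    distance = "character",
    init = "character",
    L0 = "numeric",
    H1 = "numeric",
    epsilon = "numeric",
    epsilonMode = "character",
    stabilityMode = "character",
    mmiOverride = "numeric"
  )
)

setValidity("KmeansParams", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L) {
    msg <- c(msg, "k must be a single integer >= 1")
  }
  if (length(object@maxIter) != 1L || object@maxIter < 1L) {
    msg <- c(msg, "maxIter must be >= 1")
  }
  if (!object@distance %in% c("sq_euclidean", "euclidean",
                              "pearson_dissimilarity")) {
    msg <- c(msg, "unknown distance kind")
  }
  if (!object@init %in% c("forgy_sample", "first_k")) {
    msg <- c(msg, "unknown init method")
  }
  if (!(object@L0 >= 0 && object@L0 < object@H1)) {
    msg <- c(msg, "need 0 <= L0 < H1")
  }
  if (!(object@epsilon > 0)) msg <- c(msg, "epsilon must be > 0")
  if (!object@epsilonMode %in% c("relative", "absolute")) {
    msg <- c(msg, "epsilonMode must be 'relative' or 'absolute'")
  }
  if (!object@stabilityMode %in% c("threshold", "strict_interval")) {
    msg <- c(msg, "stabilityMode must be 'threshold' or 'strict_interval'")
  }
  if (length(object@mmiOverride) != 1L ||
      (!is.na(object@mmiOverride) && object@mmiOverride < 1)) {
    msg <- c(msg, "mmiOverride must be NA, Inf or an integer >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @param k cluster count (required).
#' @param seed integer RNG seed for initialization.
#' @param maxIter maximum number of Lloyd iterations (default 300).
#' @param distance,init,L0,H1,epsilon,epsilonMode,stabilityMode,mmiOverride
#'   see the slot documentation.
#' @return a validated \code{KmeansParams} object.
#' @examples
#' KmeansParams(k = 10, seed = 1)
#' @rdname KmeansParams-class
#' @export
KmeansParams <- function(k, seed = 1L, maxIter = 300L,
                         distance = c("sq_euclidean", "euclidean",
                                      "pearson_dissimilarity"),
                         init = c("forgy_sample", "first_k"),
                         L0 = 0.005, H1 = 0.015, epsilon = 0.007,
                         epsilonMode = c("relative", "absolute"),
                         stabilityMode = c("threshold", "strict_interval"),
                         mmiOverride = NA_real_) {
  new("KmeansParams",
      k = as.integer(k), seed = as.integer(seed),
      maxIter = as.integer(maxIter),
      distance = match.arg(distance), init = match.arg(init),
      L0 = L0, H1 = H1, epsilon = epsilon,
      epsilonMode = match.arg(epsilonMode),
      stabilityMode = match.arg(stabilityMode),
      mmiOverride = as.numeric(mmiOverride))
}

#' Result of one k-means run
#'
#' Returned by \code{\link{runTraditional}}, \code{\link{runEnhanced}} and
#' \code{\link{runOverlapped}}. Use the accessors
#' \code{\link{clusterLabels}}, \code{\link{centroids}},
#' \code{\link{clusterSizes}} and \code{\link{runTrace}} rather than slots.
#'
#' @slot algorithm one of "traditional", "enhanced", "overlapped", "mmk".
#' @slot labels integer cluster index in \code{1..k} per point, named by
#'   row id.
#' @slot centroids k x d matrix of cluster mean vectors.
#' @slot sizes per-cluster point counts (an empty cluster keeps its previous
#'   mean and reports size 0).
#' @slot trace one row per iteration: \code{iteration}, \code{mse} (mean
#'   squared Euclidean distance to the assigned centroid, measured after the
#'   assignment step), \code{moved} (points that changed cluster),
#'   \code{stable_clusters} (frozen-cluster count; 0 for non-MM variants),
#'   \code{dist_evals} (cumulative point-centroid distance evaluations).
#' @slot params the \code{KmeansParams} used.
#' @slot converged TRUE when the run stopped because no point moved.
#' @exportClass KmeansRun
setClass("KmeansRun",
  representation(
    algorithm = "character",
    labels = "integer",
    centroids = "matrix",
    sizes = "integer",
    trace = "data.frame",
    params = "KmeansParams",
    converged = "logical"
  )
)

setValidity("KmeansRun", function(object) {
  msg <- character()
  k <- object@params@k
  if (length(object@sizes) != k) msg <- c(msg, "sizes must have length k")
  if (nrow(object@centroids) != k) msg <- c(msg, "centroids must have k rows")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > k)) {
    msg <- c(msg, "labels out of 1..k")
  }
  if (sum(object@sizes) != length(object@labels)) {
    msg <- c(msg, "sizes must sum to the number of points")
  }
  need <- c("iteration", "mse", "moved", "stable_clusters", "dist_evals")
  if (!all(need %in% names(object@trace))) {
    msg <- c(msg, "trace is missing required columns")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an MMk-means run
#'
#' Extends \code{\linkS4class{KmeansRun}} with the stability-mechanism
#' state: the estimated multiplier, the detected switch-on iteration (MMI)
#' and the per-iteration metric-matrix records.
#'
#' @slot mmi the iteration from which the metric-matrix mechanism was
#'   active, or \code{NA} if it never switched on.
#' @slot multiplier list with \code{m}, \code{sse1}, \code{frobSq},
#'   \code{sigmaSq} (top-k squared singular values) and \code{mseLEst};
#'   empty when \code{mmiOverride} was used.
#' @slot mmRecords list of per-iteration metric-matrix records (see
#'   \code{\link{computeMMStep}}).
#' @exportClass MMKmeansRun
setClass("MMKmeansRun",
  contains = "KmeansRun",
  representation(
    mmi = "integer",
    multiplier = "list",
    mmRecords = "list"
  )
)

setMethod("show", "KmeansRun", function(object) {
  tr <- object@trace
  cat(sprintf("%s k-means run: n=%d, d=%d, k=%d\n",
              object@algorithm, length(object@labels),
              ncol(object@centroids), object@params@k))
  cat(sprintf("  iterations: %d (%s), final MSE: %.6g\n",
              nrow(tr), if (object@converged) "converged" else "max_iter",
              tr$mse[nrow(tr)]))
  cat(sprintf("  distance evaluations: %.0f; empty clusters: %d\n",
              tr$dist_evals[nrow(tr)], sum(object@sizes == 0L)))
  invisible(object)
})

setMethod("show", "MMKmeansRun", function(object) {
  callNextMethod()
  if (is.na(object@mmi)) {
    cat("  MMI: not detected (ran as Traditional k-means)\n")
  } else {
    cat(sprintf("  MMI: %d; stable clusters at termination: %d\n",
                object@mmi,
                object@trace$stable_clusters[nrow(object@trace)]))
  }
  if (length(object@multiplier)) {
    cat(sprintf("  multiplier m: %.4f, estimated optimal MSE: %.6g\n",
                object@multiplier$m, object@multiplier$mseLEst))
  }
  invisible(object)
})
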