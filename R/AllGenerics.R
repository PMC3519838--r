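#' Accessors for k-means run objects
#'
#' @param object a \code{\linkS4class{KmeansRun}} or
#'   \code{\linkS4class{MMKmeansRun}}.
#' @return \code{clusterLabels}: named integer vector of cluster
#'   assignments in \code{1..k}; \code{centroids}: k x d matrix of cluster
#'   means; \code{clusterSizes}: integer vector of per-cluster counts;
#'   \code{runTrace}: per-iteration data.frame (iteration, mse, moved,
#'   stable_clusters, dist_evals); \code{mmIteration}: the detected MMI or
#'   \code{NA}; \code{multiplierEstimate}: list describing the spectral
#'   estimate of the optimal objective; \code{metricMatrixRecords}: list of
#'   per-iteration metric-matrix records.
#' @name kmeans-accessors
#' @aliases clusterLabels centroids clusterSizes runTrace mmIteration
#'   multiplierEstimate metricMatrixRecords
#' @examples
#' sim <- generateMixture(n = 60, d = 4, kTrue = 3, seed = 1)
#' fit <- runTraditional(sim$data, KmeansParams(k = 3, seed = 1))
#' table(clusterLabels(fit), sim$labels)
#' runTrace(fit)
NULL

#' @rdname kmeans-accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname kmeans-accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname kmeans-accessors
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname kmeans-accessors
#' @export
setGeneric("runTrace", function(object) standardGeneric("runTrace"))

#' @rdname kmeans-accessors
#' @export
setGeneric("mmIteration", function(object) standardGeneric("mmIteration"))

#' @rdname kmeans-accessors
#' @export
setGeneric("multiplierEstimate",
           function(object) standardGeneric("multiplierEstimate"))

#' @rdname kmeans-accessors
#' @export
setGeneric("metricMatrixRecords",
           function(object) standardGeneric("metricMatrixRecords"))

#' @rdname kmeans-accessors
setMethod("clusterLabels", "KmeansRun", function(object) object@labels)

#' @rdname kmeans-accessors
setMethod("centroids", "KmeansRun", function(object) object@centroids)

#' @rdname kmeans-accessors
setMethod("clusterSizes", "KmeansRun", function(object) object@sizes)

#' @rdname kmeans-accessors
setMethod("runTrace", "KmeansRun", function(object) object@trace)

#' @rdname kmeans-accessors
setMethod("mmIteration", "MMKmeansRun", function(object) object@mmi)

#' @rdname kmeans-accessors
setMethod("multiplierEstimate", "MMKmeansRun",
          function(object) object@multiplier)

#' @rdname kmeans-accessors
setMethod("metricMatrixRecords", "MMKmeansRun",
          function(object) object@mmRecords)
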