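# The metric-matrix stability mechanism: a spectral estimate of the
# optimal k-means objective decides when ("MMI") to start monitoring
# cluster stability; from then on, eigenvalues of the k x k Pearson
# correlation matrix between successive centroid sets decide which whole
# clusters are frozen.

#' Spectral multiplier estimate of the optimal objective
#'
#' Uses the PCA/k-means relation: the optimal sum of squared errors is
#' bounded below by \code{||X||_F^2 - sum_{j<=k} sigma_j^2}, with
#' \code{sigma_j} the j-th largest singular value of the data matrix. The
#' dimensionless multiplier \code{m = bound / SSE_1} then predicts the
#' optimal objective from the first-iteration one:
#' \code{MSE_l ~ m * MSE_1}.
#'
#' @param data n x d numeric matrix.
#' @param k cluster count (singular values beyond \code{min(n, d)} are
#'   treated as 0, so the bound can reach 0 and \code{m = 0}).
#' @param sse1 first-iteration sum of squared errors (> 0).
#' @return list with \code{m} (in \code{[0, 1]}), \code{sse1},
#'   \code{frobSq} (squared Frobenius norm), \code{sigmaSq} (top-k squared
#'   singular values) and \code{mseLEst} (\code{m * sse1 / n}).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' a <- assignPoints(x, x[1:2, ])
#' sse1 <- clusterMSE(x, x[1:2, ], a$labels) * nrow(x)
#' computeMultiplier(x, 2, sse1)$m
#' @export
computeMultiplier <- function(data, k, sse1) {
  stopifnotMatrix(data)
  if (k < 1L || nrow(data) < k) stop("need n >= k >= 1")
  if (!(sse1 > 0)) stop("sse1 must be > 0 (degenerate data)")
  sv <- svd(data, nu = 0, nv = 0)$d
  sigmaSq <- numeric(k)
  top <- seq_len(min(k, length(sv)))
  sigmaSq[top] <- sv[top]^2
  frobSq <- sum(data^2)
  bound <- max(0, frobSq - sum(sigmaSq))
  m <- min(1, bound / sse1)
  list(m = m, sse1 = sse1, frobSq = frobSq, sigmaSq = sigmaSq,
       mseLEst = m * sse1 / nrow(data))
}

effectiveEpsilon <- function(params, mse1) {
  if (params@epsilonMode == "relative") params@epsilon * mse1
  else params@epsilon
}

# Upper bound on MMI: MMI <= MSE_1 * k / MSE_l.
mmiUpperBound <- function(mse1, k, mseLEst) {
  ceiling(mse1 * k / max(mseLEst, 1e-12))
}

#' Detect the metric-matrix switch-on iteration (MMI)
#'
#' Scans an objective trace for the first iteration whose MSE lies within
#' an epsilon-band of the estimated optimal MSE:
#' \code{|MSE_i - mseLEst| <= eps_eff}, where \code{eps_eff} is
#' \code{epsilon * MSE_1} in relative mode (default) or \code{epsilon} in
#' absolute mode (a Cauchy-style closeness criterion on the convergent MSE
#' sequence). The result is clamped to the theoretical upper bound
#' \code{ceiling(MSE_1 * k / mseLEst)}.
#'
#' @param trace data.frame with an \code{mse} column (or an
#'   \code{\linkS4class{KmeansRun}} trace).
#' @param estimate result of \code{\link{computeMultiplier}}.
#' @param params a \code{\link{KmeansParams}} (uses \code{epsilon},
#'   \code{epsilonMode}, \code{k}).
#' @return list with \code{mmi} (integer, \code{NA} if the band is never
#'   entered within the trace), \code{epsilon} (effective band width) and
#'   \code{mode}.
#' @export
detectMMI <- function(trace, estimate, params) {
  mse <- trace$mse
  if (!length(mse)) stop("trace has no iterations")
  epsEff <- effectiveEpsilon(params, mse[1L])
  hit <- which(abs(mse - estimate$mseLEst) <= epsEff)
  mmi <- if (length(hit)) {
    min(hit[1L], mmiUpperBound(mse[1L], params@k, estimate$mseLEst))
  } else NA_integer_
  list(mmi = as.integer(mmi), epsilon = epsEff, mode = params@epsilonMode)
}

#' Metric matrix between two centroid sets
#'
#' Entry (i, j) is the Pearson correlation between centroid i of the
#' previous iteration and centroid j of the current one. Zero-variance
#' centroids yield 0 entries with a warning.
#'
#' @param prev,curr k x d matrices of centroids (same k, d >= 2).
#' @return k x k matrix with entries in \code{[-1, 1]}.
#' @export
buildMetricMatrix <- function(prev, curr) {
  if (nrow(prev) != nrow(curr)) stop("centroid-set size mismatch")
  if (ncol(prev) < 2L || ncol(curr) != ncol(prev)) {
    stop("centroids must share a dimension >= 2")
  }
  mm <- suppressWarnings(stats::cor(t(prev), t(curr)))
  if (anyNA(mm)) {
    warning("zero-variance centroid in metric matrix; treating r as 0")
    mm[is.na(mm)] <- 0
  }
  mm
}

#' Eigenvalues of a metric matrix
#'
#' Returns the eigenvalues of the symmetrized matrix
#' \code{(mm + t(mm)) / 2}, sorted descending. The metric matrix pairs
#' different vectors in its (i, j) and (j, i) entries and so is not exactly
#' symmetric away from convergence; symmetrizing guarantees real, sortable
#' eigenvalues and is exact whenever the matrix is symmetric (the converged
#' regime in which the stability mechanism operates).
#'
#' @param mm square numeric matrix.
#' @return numeric vector of length \code{nrow(mm)}, descending.
#' @export
mmEigenvalues <- function(mm) {
  if (!is.matrix(mm) || nrow(mm) != ncol(mm)) stop("mm must be square")
  eigen((mm + t(mm)) / 2, symmetric = TRUE, only.values = TRUE)$values
}

#' One step of the cluster-stability monitor
#'
#' Builds the metric matrix between the previous and current centroid
#' sets, extracts its sorted eigenvalues, and compares them with the
#' previous step's eigenvalues: cluster j (in descending eigenvalue order)
#' is flagged stable when its relative eigenvalue change
#' \code{|e_j - pe_j| / max(|pe_j|, 1e-12)} falls within the stability
#' band — at most \code{H1} in \code{"threshold"} mode (default; a fully
#' converged cluster with change 0 counts as stable), or inside
#' \code{[L0, H1]} in \code{"strict_interval"} mode. The bootstrap call
#' (\code{prevRecord = NULL}) records eigenvalues but flags nothing.
#'
#' @param prevRecord the record from the previous step, or NULL.
#' @param prev,curr centroid matrices for \code{\link{buildMetricMatrix}}.
#' @param params a \code{\link{KmeansParams}} (uses \code{L0}, \code{H1},
#'   \code{stabilityMode}).
#' @return list with \code{mm}, \code{eigenvalues}, \code{prevEigenvalues},
#'   \code{diff}, \code{diffRel} and logical \code{stable}.
#' @export
computeMMStep <- function(prevRecord, prev, curr, params) {
  mm <- buildMetricMatrix(prev, curr)
  e <- mmEigenvalues(mm)
  k <- length(e)
  if (is.null(prevRecord)) {
    return(list(mm = mm, eigenvalues = e, prevEigenvalues = NULL,
                diff = rep(NA_real_, k), diffRel = rep(NA_real_, k),
                stable = rep(FALSE, k)))
  }
  pe <- prevRecord$eigenvalues
  if (length(pe) != k) stop("cluster count differs from previous record")
  dif <- abs(e - pe)
  difRel <- dif / pmax(abs(pe), 1e-12)
  stable <- if (params@stabilityMode == "threshold") {
    difRel <= params@H1
  } else {
    difRel >= params@L0 & difRel <= params@H1
  }
  list(mm = mm, eigenvalues = e, prevEigenvalues = pe,
       diff = dif, diffRel = difRel, stable = stable)
}

#' MMk-means: Lloyd iterations with whole-cluster freezing
#'
#' Runs like Traditional k-means, with three additions. (1) After the
#' first assignment it estimates the optimal objective from the data
#' matrix's top-k squared singular values (\code{\link{computeMultiplier}}).
#' (2) It watches the objective online and switches the stability monitor
#' on at the first iteration whose MSE enters the epsilon-band around that
#' estimate (the MMI; \code{\link{detectMMI}} semantics). (3) From then on
#' each iteration ends with \code{\link{computeMMStep}}; clusters whose
#' metric-matrix eigenvalue change sits within the stability band are
#' frozen, and their members skip reassignment (zero distance evaluations)
#' in the next iteration, while unfrozen points still compare against all
#' k centroids. Frozen clusters still receive centroid updates, may gain
#' points, and may unfreeze again if their eigenvalue shifts.
#'
#' Stops when no point moves, all clusters are stable, or \code{maxIter}
#' is reached. With \code{mmiOverride = Inf} (or beyond the iteration
#' count) the mechanism never fires and the run is bit-identical to
#' \code{\link{runTraditional}} under the same seed. A warning is emitted
#' when the input contains negative values: the eigenvalue stability
#' condition is not well behaved on negative expression values, though the
#' algorithm still runs.
#'
#' @param data n x d numeric matrix, d >= 2.
#' @param params a \code{\link{KmeansParams}}.
#' @return an \code{\linkS4class{MMKmeansRun}}.
#' @examples
#' sim <- generateMixture(n = 500, d = 10, kTrue = 4, seed = 3)
#' fit <- runMMKmeans(sim$data, KmeansParams(k = 4, seed = 3))
#' mmIteration(fit)
#' @export
runMMKmeans <- function(data, params) {
  stopifnotMatrix(data)
  if (nrow(data) < params@k) stop("need n >= k")
  if (ncol(data) < 2L) stop("the metric-matrix mechanism needs d >= 2")
  if (any(data < 0)) {
    warning("input contains negative values; the eigenvalue stability ",
            "condition is not designed for negative expression values")
  }
  n <- nrow(data); k <- params@k
  overridden <- !is.na(params@mmiOverride)
  cen <- list(means = initCentroids(data, params), sizes = integer(k))
  labels <- NULL
  frozen <- rep(FALSE, k)
  trace <- emptyTrace()
  evals <- 0
  converged <- FALSE
  mmi <- if (overridden) params@mmiOverride else NA_real_
  estimate <- list()
  mmRecords <- list()
  prevRecord <- NULL
  mse1 <- NA_real_
  epsEff <- NA_real_
  upper <- Inf

  for (i in seq_len(params@maxIter)) {
    a <- assignPoints(data, cen$means, frozen, labels, params@distance)
    evals <- evals + a$distEvals
    mse <- clusterMSE(data, cen$means, a$labels)
    if (i == 1L) {
      mse1 <- mse
      # a zero first-pass objective means the clustering is already exact;
      # there is nothing left for the stability mechanism to save
      if (!overridden && mse1 > 0) {
        estimate <- computeMultiplier(data, k, mse1 * n)
        epsEff <- effectiveEpsilon(params, mse1)
        upper <- mmiUpperBound(mse1, k, estimate$mseLEst)
      }
    }
    if (length(estimate) && is.na(mmi) &&
        abs(mse - estimate$mseLEst) <= epsEff) {
      mmi <- min(i, upper)
    }
    labels <- a$labels
    prevMeans <- cen$means
    cen <- updateCentroids(data, labels, k, cen$means)
    if (!is.na(mmi) && i >= mmi) {
      prevRecord <- computeMMStep(prevRecord, prevMeans, cen$means, params)
      mmRecords[[length(mmRecords) + 1L]] <- prevRecord
      frozen <- prevRecord$stable
    }
    trace[i, ] <- list(i, mse, a$moved, sum(frozen), evals)
    if (a$moved == 0L || all(frozen)) {
      converged <- TRUE
      break
    }
  }
  makeRun("MMKmeansRun", "mmk", data, labels, cen, trace, params, converged,
          mmi = as.integer(if (is.finite(mmi)) mmi else NA_integer_),
          multiplier = estimate, mmRecords = mmRecords)
}
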