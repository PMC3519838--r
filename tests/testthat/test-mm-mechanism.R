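test_that("the spectral multiplier matches a Gram-matrix eigenvalue oracle", {
  # 6 x 3 integer matrix, k = 2: bound from eigen(X'X) instead of svd(X)
  x <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 1, 0, 3, 2, 1,
                5, 4, 3, 2, 1, 0), 6, 3)
  rownames(x) <- paste0("r", 1:6)
  est <- computeMultiplier(x, k = 2, sse1 = 100)
  ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  oracleBound <- sum(ev) - sum(ev[1:2])
  expect_equal(est$frobSq - sum(est$sigmaSq), oracleBound, tolerance = 1e-9)
  expect_equal(est$m, oracleBound / 100, tolerance = 1e-9)
  expect_equal(est$mseLEst, est$m * 100 / 6)

  # property: m in [0, 1] and mseLEst <= MSE_1 when sse1 comes from a
  # genuine first Lloyd pass
  for (s in 1:5) {
    set.seed(s)
    y <- matrix(rnorm(8 * 5), 8, 5)
    p <- KmeansParams(k = 3, seed = s)
    a <- assignPoints(y, initCentroids(y, p))
    sse1 <- clusterMSE(y, initCentroids(y, p), a$labels) * 8
    e <- computeMultiplier(y, 3, sse1)
    expect_gte(e$m, 0); expect_lte(e$m, 1)
    expect_lte(e$mseLEst, sse1 / 8)
    evy <- eigen(crossprod(y), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(e$frobSq - sum(e$sigmaSq),
                 max(0, sum(evy) - sum(evy[1:3])), tolerance = 1e-9)
  }
})

test_that("rank-deficient and degenerate multiplier cases behave as defined", {
  # exactly k distinct rows, repeated: rank <= k, so the bound collapses to 0
  x <- rbind(c(1, 0, 2), c(0, 3, 1))[rep(1:2, 5), ]
  expect_equal(computeMultiplier(x, k = 2, sse1 = 7)$m, 0)
  # k = 1: bound is ||X||_F^2 minus the top squared singular value
  y <- matrix(c(3, 0, 0, 4), 2, 2)
  e1 <- computeMultiplier(y, 1, sse1 = 50)
  sv <- svd(y)$d
  expect_equal(e1$frobSq - sum(e1$sigmaSq), sum(y^2) - sv[1]^2,
               tolerance = 1e-12)
  # k beyond the rank: missing singular values count as zero
  ek <- computeMultiplier(rbind(y, y, y), 6, sse1 = 10)
  expect_equal(ek$m, 0)
  expect_error(computeMultiplier(y, 1, sse1 = 0), "sse1")
})

test_that("MMI detection scans the epsilon band and applies the upper bound", {
  p <- KmeansParams(k = 3, epsilon = 0.007)
  # perfect estimate: the band holds at iteration 1
  tr <- data.frame(mse = c(10, 6, 5))
  est <- list(mseLEst = 10)
  expect_identical(detectMMI(tr, est, p)$mmi, 1L)

  # a trace that never enters a tight absolute band stays unset
  pAbs <- KmeansParams(k = 3, epsilon = 1e-4, epsilonMode = "absolute")
  expect_identical(detectMMI(data.frame(mse = c(10, 6, 5)),
                             list(mseLEst = 0), pAbs)$mmi, NA_integer_)

  # relative vs absolute band widths
  d1 <- detectMMI(data.frame(mse = c(10, 6.05)), list(mseLEst = 6), p)
  expect_identical(d1$mmi, 2L)
  expect_equal(d1$epsilon, 0.07)

  # the MMI upper bound MSE_1 * k / MSE_l clamps late detections:
  # band entry at iteration 10, but ceiling(2 * 2 / 0.5) = 8 caps it
  trLate <- data.frame(mse = c(2, rep(1.9, 8), 0.5))
  dLate <- detectMMI(trLate, list(mseLEst = 0.5),
                     KmeansParams(k = 2, epsilon = 0.001))
  expect_identical(dLate$mmi, 8L)
})

test_that("the metric matrix is the pairwise centroid correlation table", {
  set.seed(3)
  prev <- matrix(rnorm(12), 3, 4)
  curr <- matrix(rnorm(12), 3, 4)
  mm <- buildMetricMatrix(prev, curr)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(mm[i, j], pearsonR(prev[i, ], curr[j, ]), tolerance = 1e-12)
  }
  expect_true(all(mm >= -1 & mm <= 1))

  # prev vs itself has a unit diagonal; affine transforms leave r unchanged
  expect_equal(diag(buildMetricMatrix(prev, prev)), rep(1, 3))
  expect_equal(buildMetricMatrix(prev, 2 * prev + 3),
               buildMetricMatrix(prev, prev), tolerance = 1e-12)

  expect_error(buildMetricMatrix(prev, curr[1:2, ]), "mismatch")
  expect_warning(buildMetricMatrix(rbind(c(1, 1, 1), c(1, 2, 3)),
                                   rbind(c(1, 2, 4), c(2, 2, 5))),
                 "zero-variance")
})

test_that("metric-matrix eigenvalues match a characteristic-polynomial oracle", {
  expect_equal(mmEigenvalues(diag(4)), rep(1, 4))
  r <- 0.3
  expect_equal(mmEigenvalues(matrix(c(1, r, r, 1), 2, 2)),
               c(1 + r, 1 - r))
  set.seed(9)
  a <- matrix(rnorm(16), 4, 4)
  s <- (a + t(a)) / 2
  roots <- Re(polyroot(rev(pracma::charpoly(s))))
  expect_equal(mmEigenvalues(s), sort(roots, decreasing = TRUE),
               tolerance = 1e-9)
  expect_error(mmEigenvalues(matrix(1, 2, 3)), "square")
})

test_that("stability flags follow the Ding-He band in both modes", {
  set.seed(4)
  cen <- matrix(rnorm(20), 4, 5)
  p <- KmeansParams(k = 4)
  boot <- computeMMStep(NULL, cen, cen, p)
  expect_false(any(boot$stable))                       # bootstrap freezes nothing
  expect_equal(boot$eigenvalues, sort(boot$eigenvalues, decreasing = TRUE))

  # converged regime: identical consecutive centroid sets, diff exactly 0
  stepA <- computeMMStep(boot, cen, cen, p)
  expect_equal(stepA$diff, rep(0, 4))
  expect_true(all(stepA$stable))                       # threshold mode
  pStrict <- KmeansParams(k = 4, stabilityMode = "strict_interval")
  stepB <- computeMMStep(boot, cen, cen, pStrict)
  expect_false(any(stepB$stable))                      # 0 < L0 excludes it

  expect_error(computeMMStep(list(eigenvalues = rep(1, 3)), cen, cen, p),
               "differs")
})

test_that("disabling the mechanism reduces MMk-means to Lloyd bit-for-bit", {
  sim <- generateMixture(n = 600, d = 8, kTrue = 5, separation = 5,
                         noiseSd = 1, seed = 14)
  p0 <- KmeansParams(k = 5, seed = 14)
  pInf <- KmeansParams(k = 5, seed = 14, mmiOverride = Inf)
  ft <- runTraditional(sim$data, p0)
  fm <- suppressWarnings(runMMKmeans(sim$data, pInf))
  expect_identical(clusterLabels(fm), clusterLabels(ft))
  expect_identical(centroids(fm), centroids(ft))
  expect_identical(runTrace(fm), runTrace(ft))
  expect_identical(mmIteration(fm), NA_integer_)
})

test_that("MMk-means handles k = n and input validation", {
  set.seed(15)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("p", 1:6)
  fit <- suppressWarnings(runMMKmeans(x, KmeansParams(k = 6, seed = 1)))
  tr <- runTrace(fit)
  expect_equal(tr$mse[nrow(tr)], 0)
  expect_identical(nrow(tr), 2L)
  expect_identical(sort(unname(clusterLabels(fit))), 1:6)

  expect_error(runMMKmeans(matrix(1:4, 4, 1),
                           KmeansParams(k = 2, seed = 1)), "d >= 2")
  expect_warning(runMMKmeans(matrix(c(-1, 2, 3, 4, 5, 6), 3, 2),
                             KmeansParams(k = 2, seed = 1)),
                 "negative")
})

test_that("online MMI detection matches an offline rescan of the same trace", {
  fx <- orthNoiseFixture(seed = 11)
  p <- KmeansParams(k = 4, seed = 2)
  run <- suppressWarnings(runMMKmeans(fx$data, p))
  expect_false(is.na(mmIteration(run)))
  offline <- detectMMI(runTrace(run), multiplierEstimate(run), p)
  expect_identical(offline$mmi, mmIteration(run))
  # on this fixture the spectral estimate is tight
  tr <- runTrace(run)
  expect_lt(abs(multiplierEstimate(run)$mseLEst - tr$mse[nrow(tr)]),
            0.01 * tr$mse[1])
})

test_that("freezing reduces per-iteration distance evaluations below n*k", {
  sim <- generateMixture(n = 2000, d = 20, kTrue = 8, separation = 8,
                         noiseSd = 1, seed = 4)
  p <- KmeansParams(k = 8, seed = 4, mmiOverride = 2)
  run <- suppressWarnings(runMMKmeans(sim$data, p))
  tr <- runTrace(run)
  n <- nrow(sim$data); k <- 8
  recs <- metricMatrixRecords(run)
  # flags recorded at iteration i apply to the assignment at i+1
  firstMM <- nrow(tr) - length(recs) + 1L
  for (j in seq_along(recs)[-length(recs)]) {
    i <- firstMM + j          # iteration using recs[[j]]'s flags
    if (i > nrow(tr)) break
    if (any(recs[[j]]$stable)) {
      expect_lt(tr$dist_evals[i] - tr$dist_evals[i - 1], n * k)
    }
  }
  # the mechanism saved evaluations relative to a full pass per iteration
  expect_lt(tr$dist_evals[nrow(tr)], n * k * nrow(tr))
})

test_that("clusters frozen at termination are essentially final (membership audit)", {
  movedFrac <- vapply(1:5, function(s) {
    sim <- generateMixture(n = 2000, d = 20, kTrue = 8, separation = 8,
                           noiseSd = 1, seed = s)
    run <- suppressWarnings(runMMKmeans(
      sim$data, KmeansParams(k = 8, seed = s, mmiOverride = 3)))
    recs <- metricMatrixRecords(run)
    frozen <- recs[[length(recs)]]$stable
    if (!any(frozen)) return(0)
    full <- assignPoints(sim$data, centroids(run), NULL, clusterLabels(run))
    inFrozen <- frozen[clusterLabels(run)]
    sum(full$labels[inFrozen] != clusterLabels(run)[inFrozen]) /
      max(sum(inFrozen), 1)
  }, numeric(1))
  expect_true(all(movedFrac < 0.01))
})

test_that("a run can terminate with every cluster stable", {
  fx <- orthNoiseFixture(seed = 11)
  run <- suppressWarnings(runMMKmeans(fx$data, KmeansParams(k = 4, seed = 2)))
  tr <- runTrace(run)
  # this fixture converges with all clusters flagged stable
  expect_identical(tr$stable_clusters[nrow(tr)], 4L)
  expect_true(run@converged)
  expect_equal(ariHA(clusterLabels(run), fx$labels), 1)
})
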