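# Shared fixtures and independent oracles for the test suite.

# Cluster means on scaled basis vectors in the first k coordinates with
# Gaussian noise confined to the remaining d-k coordinates. Because the
# noise is orthogonal to the span of the means, the spectral bound
# ||X||_F^2 - sum_{j<=k} sigma_j^2 essentially equals the optimal k-means
# objective, so the stability mechanism's switch-on criterion can fire
# without an override.
orthNoiseFixture <- function(n = 1000, d = 12, k = 4, sep = 10,
                             noiseSd = 0.5, seed = 11) {
  set.seed(seed)
  means <- diag(sep, k, d)
  lab <- rep(seq_len(k), length.out = n)
  lab <- sort(lab)
  x <- means[lab, , drop = FALSE]
  x[, (k + 1):d] <- x[, (k + 1):d] +
    matrix(rnorm(n * (d - k), sd = noiseSd), n)
  rownames(x) <- paste0("g", seq_len(n))
  list(data = x, labels = stats::setNames(as.integer(lab), rownames(x)))
}

# Brute-force adjusted Rand index by enumeration of all point pairs
# (agree/agree vs agree/disagree counts), independent of the contingency
# formula used by ariHA().
ariPairCounting <- function(p, q) {
  n <- length(p)
  stopifnot(length(q) == n, n >= 2)
  ut <- upper.tri(matrix(0, n, n))
  sameP <- outer(p, p, "==")[ut]
  sameQ <- outer(q, q, "==")[ut]
  a <- sum(sameP & sameQ)
  pairsP <- sum(sameP)
  pairsQ <- sum(sameQ)
  M <- choose(n, 2)
  expected <- pairsP * pairsQ / M
  (a - expected) / ((pairsP + pairsQ) / 2 - expected)
}

# Write a small expression matrix in the tab-delimited layout used for
# time-course microarray files (header line, ID column, one numeric
# column per timepoint).
writeBozdechStyle <- function(data, path, header = TRUE) {
  lines <- character()
  if (header) {
    lines <- paste(c("GeneID", paste0("TP", seq_len(ncol(data)))),
                   collapse = "\t")
  }
  body <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(rownames(data)[i], format(data[i, ], digits = 10)),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
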