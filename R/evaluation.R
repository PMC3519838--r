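#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same points,
#' computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}
#'   {\frac{1}{2}[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}] - E},
#'   \quad E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{n}{2}.}
#' Symmetric in its arguments and invariant to label permutation. If both
#' vectors are named the second is re-aligned to the first by id, so
#' partitions survive file round-trips in any row order.
#'
#' Degenerate partitions (both trivial: the formula's denominator is 0,
#' e.g. both single-cluster or both all-singletons) return 1 when the two
#' partitions are identical as set partitions and 0 otherwise, with a
#' message.
#'
#' @param p,q integer label vectors over the same points (named by id, or
#'   unnamed and in the same order).
#' @return a scalar \code{<= 1}.
#' @examples
#' ariHA(c(a = 1L, b = 1L, c = 2L, d = 2L), c(a = 1L, b = 2L, c = 1L, d = 2L))
#' @export
ariHA <- function(p, q) {
  if (length(p) != length(q)) stop("partitions must cover the same points")
  if (length(p) < 2L) stop("need at least 2 points")
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)) || anyDuplicated(names(p))) {
      stop("partitions have mismatched ids")
    }
    q <- q[names(p)]
  }
  tab <- table(p, q)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) {
    # both partitions trivial: identical iff the table is a permutation
    identicalPartition <-
      all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
    message("degenerate partitions in ariHA; returning ",
            if (identicalPartition) 1 else 0, " by convention")
    return(if (identicalPartition) 1 else 0)
  }
  (sumij - expected) / denom
}

#' Pairwise ARI report against a reference clustering
#'
#' Compares each algorithm's partition with a reference partition
#' (conventionally the Traditional k-means structure) via
#' \code{\link{ariHA}}, and additionally reports the
#' Enhanced-vs-Overlapped cell when both are present, mirroring the usual
#' cluster-quality table layout.
#'
#' @param runs named list of partitions (named integer label vectors, or
#'   \code{\linkS4class{KmeansRun}} objects).
#' @param reference name of the entry in \code{runs} to compare against.
#' @return data.frame with columns \code{comparison} and \code{ari}.
#' @export
comparePartitionsReport <- function(runs, reference = "traditional") {
  if (!reference %in% names(runs)) {
    stop("reference '", reference, "' not found among runs")
  }
  labs <- lapply(runs, function(r) {
    if (is(r, "KmeansRun")) clusterLabels(r) else r
  })
  ref <- labs[[reference]]
  others <- setdiff(names(labs), reference)
  comparison <- paste0(reference, " vs ", reference)
  ari <- 1.0
  if (length(others)) {
    comparison <- c(comparison, paste0(others, " vs ", reference))
    ari <- c(ari, vapply(others, function(nm) ariHA(labs[[nm]], ref),
                         numeric(1)))
  }
  rows <- data.frame(comparison = comparison, ari = unname(ari),
                     row.names = NULL)
  if (all(c("enhanced", "overlapped") %in% names(labs))) {
    rows <- rbind(rows, data.frame(
      comparison = "enhanced vs overlapped",
      ari = ariHA(labs$enhanced, labs$overlapped)))
  }
  rows
}
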