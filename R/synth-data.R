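# Synthetic benchmark generators. Both are fully deterministic given their
# seed and never touch the caller's RNG stream.

# Deterministic component-mean placement: scaled canonical basis vectors
# when k <= d (all pairs of means exactly `separation` apart), otherwise
# the first k points of an integer lattice over the first dimensions with
# adjacent lattice neighbours `separation` apart.
componentMeans <- function(kTrue, d, separation) {
  if (kTrue <= d) {
    m <- diag(1, kTrue, d) * separation / sqrt(2)
  } else {
    g <- ceiling(kTrue^(1 / d))
    idx <- seq_len(kTrue) - 1L
    m <- matrix(0, kTrue, d)
    for (j in seq_len(d)) {
      m[, j] <- idx %% g
      idx <- idx %/% g
    }
    m <- m * separation
  }
  m
}

#' Generate a seeded spherical Gaussian mixture
#'
#' Draws \code{n} points from \code{kTrue} spherical Gaussian components
#' whose means sit at deterministic lattice/basis positions scaled so
#' adjacent means are \code{separation} apart. Component sizes follow
#' \code{weights} by largest remainder, so the same spec always yields the
#' same class sizes; only the Gaussian noise consumes random numbers.
#' Identical seeds give bit-identical output.
#'
#' Defaults emulate the well-separated large-matrix benchmarks used for
#' k-means timing studies (for example 10000 x 50 with 10 components).
#'
#' @param n number of points.
#' @param d dimension.
#' @param kTrue number of mixture components.
#' @param separation distance between adjacent component means, in units of
#'   feature space (default \code{8 * noiseSd}: well separated).
#' @param noiseSd within-component standard deviation per coordinate.
#' @param seed RNG seed.
#' @param weights component proportions, summing to 1 (default uniform).
#' @return list with \code{data} (n x d matrix, rownames \code{g1..gn}) and
#'   \code{labels} (named integer vector of true component indices).
#' @examples
#' sim <- generateMixture(n = 200, d = 5, kTrue = 4, seed = 7)
#' dim(sim$data)
#' table(sim$labels)
#' @export
generateMixture <- function(n, d, kTrue, separation = 8 * noiseSd,
                            noiseSd = 1, seed = 1L,
                            weights = rep(1 / kTrue, kTrue)) {
  if (n < kTrue || kTrue < 1L || d < 1L) {
    stop("need n >= kTrue >= 1 and d >= 1")
  }
  if (!(noiseSd > 0)) stop("noiseSd must be > 0")
  if (length(weights) != kTrue || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be kTrue non-negative proportions summing to 1")
  }
  sizes <- floor(n * weights)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(n * weights - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  means <- componentMeans(kTrue, d, separation)
  labels <- rep.int(seq_len(kTrue), sizes)
  x <- withSeed(seed, {
    matrix(stats::rnorm(n * d, sd = noiseSd), n, d)
  })
  x <- x + means[labels, , drop = FALSE]
  rownames(x) <- paste0("g", seq_len(n))
  list(data = x, labels = stats::setNames(as.integer(labels), rownames(x)))
}

#' Generate periodic expression-like profiles
#'
#' Microarray-style fixture: each row is a sinusoid over \code{d} equally
#' spaced timepoints (one full period), with \code{kTrue} distinct phase
#' classes, optional per-row phase jitter, and additive Gaussian noise.
#' Emulates periodic time-course expression programs (e.g. the
#' intraerythrocytic developmental cycle) without any claim to microarray
#' noise physics.
#'
#' @param n rows (genes).
#' @param d timepoints (>= 4).
#' @param kTrue number of phase classes, evenly spaced on \code{[0, 2*pi)}.
#' @param phaseJitter SD of per-row phase perturbation (radians).
#' @param noiseSd SD of additive Gaussian noise.
#' @param seed RNG seed.
#' @param amplitude sinusoid amplitude (default 1).
#' @return list with \code{data} and \code{labels} as in
#'   \code{\link{generateMixture}}.
#' @examples
#' sim <- generatePeriodicProfiles(n = 100, d = 12, kTrue = 4, seed = 2)
#' @export
generatePeriodicProfiles <- function(n, d, kTrue, phaseJitter = 0.1,
                                     noiseSd = 0.2, seed = 1L,
                                     amplitude = 1) {
  if (d < 4L) stop("need d >= 4")
  if (n < kTrue || kTrue < 1L) stop("need n >= kTrue >= 1")
  if (phaseJitter < 0 || noiseSd < 0) stop("jitter and noise must be >= 0")
  tgrid <- 2 * pi * (seq_len(d) - 1L) / d
  phases <- 2 * pi * (seq_len(kTrue) - 1L) / kTrue
  sizes <- floor(n / kTrue) + (seq_len(kTrue) <= n %% kTrue)
  labels <- rep.int(seq_len(kTrue), sizes)
  x <- withSeed(seed, {
    rowPhase <- phases[labels] +
      if (phaseJitter > 0) stats::rnorm(n, sd = phaseJitter) else 0
    base <- amplitude * sin(outer(rowPhase, tgrid, "+"))
    if (noiseSd > 0) base + matrix(stats::rnorm(n * d, sd = noiseSd), n, d)
    else base
  })
  rownames(x) <- paste0("g", seq_len(n))
  list(data = x, labels = stats::setNames(as.integer(labels), rownames(x)))
}
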