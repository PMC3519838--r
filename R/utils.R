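# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Every stochastic operation in the package routes through this, so
# no function leaves global RNG state behind.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnotMatrix <- function(x, what = "data") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " must contain only finite values")
  }
  invisible(x)
}

# Row ids for a matrix, synthesising "r<i>" when rownames are absent.
matrixIds <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(x)))
  ids
}
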