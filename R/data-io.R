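#' Read a tab-delimited expression matrix
#'
#' Reads matrices in the layout used for time-course microarray data: one
#' row per gene, a leading identifier column, then one numeric column per
#' timepoint. A first line whose second field is non-numeric is treated as
#' a header and skipped. Parsing is locale-independent (decimal point
#' \code{"."}).
#'
#' The dimension \code{d} is fixed by the first parseable data row. Rows
#' with missing/non-numeric cells or a deviant column count are handled per
#' \code{naPolicy}: \code{"drop_row"} removes them (counts are reported via
#' \code{message}), \code{"impute_row_mean"} replaces missing numeric cells
#' with the mean of the row's remaining values but still rejects rows whose
#' column count differs from \code{d}.
#'
#' @param path file to read.
#' @param delimiter field separator (default tab).
#' @param idColumn if TRUE (default) the first field is a row identifier;
#'   if FALSE identifiers \code{r1..rn} are synthesised.
#' @param naPolicy \code{"drop_row"} (default) or \code{"impute_row_mean"}.
#' @return numeric matrix with unique rownames (ids), rows in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("g1\t1.0\t2.0", "g2\t3.0\t4.0"), tf)
#' readExpressionMatrix(tf)
#' @export
readExpressionMatrix <- function(path, delimiter = "\t", idColumn = TRUE,
                                 naPolicy = c("drop_row",
                                              "impute_row_mean")) {
  naPolicy <- match.arg(naPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no parseable rows in ", path)

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  asNum <- function(v) suppressWarnings(as.numeric(v))

  # Header heuristic: first line whose second field is non-numeric.
  first <- fields[[1L]]
  probe <- if (idColumn) first[-1L] else first
  if (length(probe) >= 1L && is.na(asNum(probe[[1L]]))) {
    fields <- fields[-1L]
    if (!length(fields)) stop("no parseable rows in ", path)
  }

  firstRow <- fields[[1L]]
  d <- length(firstRow) - as.integer(idColumn)
  if (d < 1L) stop("first data row has no numeric fields")

  n0 <- length(fields)
  ids <- character(n0)
  vals <- vector("list", n0)
  keep <- logical(n0)
  dropped <- 0L
  imputed <- 0L
  for (i in seq_len(n0)) {
    f <- fields[[i]]
    ids[i] <- if (idColumn) f[[1L]] else paste0("r", i)
    v <- asNum(if (idColumn) f[-1L] else f)
    if (length(v) != d) {
      if (naPolicy == "drop_row") { dropped <- dropped + 1L; next }
      stop("row ", i, " has ", length(v), " numeric fields, expected ", d)
    }
    if (anyNA(v)) {
      if (naPolicy == "drop_row") { dropped <- dropped + 1L; next }
      if (all(is.na(v))) { stop("row ", i, " has no numeric values to impute from") }
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      imputed <- imputed + 1L
    }
    vals[[i]] <- v
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("zero parseable rows in ", path)
  if (dropped > 0L) message("dropped ", dropped, " row(s) with missing or ragged cells")
  if (imputed > 0L) message("imputed missing cells in ", imputed, " row(s) with the row mean")

  out <- do.call(rbind, vals[keep])
  rownames(out) <- make.unique(ids[keep])
  out
}

#' Write / read a partition file
#'
#' A partition is a named integer vector of cluster labels (names are row
#' ids). On disk it is a two-column TSV \code{id<TAB>cluster} with a
#' header; \code{readPartition(writePartition(...))} is the identity.
#'
#' @param labels named integer vector of cluster labels.
#' @param path file to write/read.
#' @return \code{writePartition}: the path, invisibly. \code{readPartition}:
#'   a named integer vector.
#' @examples
#' p <- c(g1 = 1L, g2 = 1L, g3 = 2L)
#' tf <- tempfile()
#' writePartition(p, tf)
#' identical(readPartition(tf), p)
#' @export
writePartition <- function(labels, path) {
  if (!is.numeric(labels)) stop("labels must be an integer vector")
  ids <- names(labels)
  if (is.null(ids) && length(labels)) {
    stop("labels must be named by row id")
  }
  df <- data.frame(id = as.character(ids), cluster = as.integer(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"),
                          col.names = c("id", "cluster"))
  if (nrow(df) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  lab <- suppressWarnings(as.numeric(df$cluster))
  if (anyNA(lab) || any(lab != round(lab))) {
    stop("malformed partition file: non-integer cluster labels in ", path)
  }
  stats::setNames(as.integer(lab), df$id)
}

#' Write a run trace
#'
#' Serialises the per-iteration trace of a run as a TSV with columns
#' \code{iteration}, \code{mse}, \code{moved}, \code{stable_clusters},
#' \code{dist_evals}. MSE is written with 12 significant digits so a
#' round-trip preserves it to that precision.
#'
#' @param trace the data.frame returned by \code{\link{runTrace}}.
#' @param path file to write.
#' @return the path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  need <- c("iteration", "mse", "moved", "stable_clusters", "dist_evals")
  if (!is.data.frame(trace) || !all(need %in% names(trace))) {
    stop("trace must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(trace) == 0L) stop("trace is empty")
  out <- trace[, need]
  out$mse <- formatC(out$mse, digits = 12, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
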