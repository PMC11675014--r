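#' Time-by-feature data matrix
#'
#' The basic input container for the Mapper pipeline: an \code{N x M} real
#' matrix whose rows are time frames sampled every \code{tr} seconds and
#' whose columns are features (parcels, voxels, or coordinates), with
#' optional per-row state labels.
#'
#' @param values numeric matrix, rows = time points, columns = features.
#' @param tr sampling interval in seconds per row.
#' @param feature_names optional character vector of length \code{ncol(values)}.
#' @param labels optional per-row categorical state (character or factor,
#'   length \code{nrow(values)}).
#'
#' @return An object of class \code{mapper_data}: the matrix with
#'   \code{tr} and \code{labels} attributes.
#' @export
#' @examples
#' dm <- data_matrix(matrix(rnorm(40), 10, 4), tr = 0.72)
#' n_points(dm)
data_matrix <- function(values, tr = 1, feature_names = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("data matrix needs at least 2 rows (time points)")
  if (ncol(values) < 1L) stop("data matrix needs at least 1 column (feature)")
  if (!all(is.finite(values))) stop("data matrix entries must all be finite")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("'tr' must be a positive scalar (seconds)")
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(values))
    colnames(values) <- feature_names
  } else if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("'labels' must have one entry per row (", nrow(values), ")")
    labels <- as.character(labels)
  }
  structure(values, tr = tr, labels = labels, class = c("mapper_data", "matrix", "array"))
}

#' @export
print.mapper_data <- function(x, ...) {
  cat(sprintf("<mapper_data> %d time points x %d features, TR = %g s%s\n",
              nrow(x), ncol(x), attr(x, "tr"),
              if (is.null(attr(x, "labels"))) "" else ", labeled"))
  invisible(x)
}

#' @rdname data_matrix
#' @param x a \code{mapper_data} object.
#' @export
n_points <- function(x) nrow(x)

#' @rdname data_matrix
#' @export
tr_seconds <- function(x) attr(x, "tr")

#' @rdname data_matrix
#' @export
state_labels <- function(x) attr(x, "labels")

#' Read / write a data matrix as delimited text
#'
#' TSV or CSV (chosen by file extension, or forced via \code{sep}); one row
#' per time point, one column per feature, with a header of feature names.
#'
#' @param path file path; \code{.csv} is read comma-separated, anything else
#'   tab-separated.
#' @param tr sampling interval in seconds.
#' @param labels_path optional path to a two-column (time, state) TSV with the
#'   per-row labels.
#' @param sep field separator override.
#' @return \code{read_data_matrix} returns a \code{mapper_data} object.
#' @export
read_data_matrix <- function(path, tr = 1, labels_path = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, header = TRUE, sep = "\t", check.names = FALSE)
    labels <- as.character(lab[[2L]])
  }
  data_matrix(as.matrix(df), tr = tr, labels = labels)
}

#' @rdname read_data_matrix
#' @param data a \code{mapper_data} object to write.
#' @export
write_data_matrix <- function(data, path, sep = "\t") {
  utils::write.table(unclass(data), path, sep = sep, row.names = FALSE, quote = FALSE)
  lab <- state_labels(data)
  if (!is.null(lab)) {
    lp <- sub("(\\.[a-zA-Z]+)?$", "_labels.tsv", path)
    utils::write.table(
      data.frame(time = (seq_len(nrow(data)) - 1) * tr_seconds(data), state = lab),
      lp, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Z-score each feature column
#'
#' Standard per-feature normalization used as optional preprocessing before
#' the pipeline; zero-variance features are left centered at zero.
#'
#' @param data a \code{mapper_data} object.
#' @return a \code{mapper_data} with each column centered and scaled.
#' @export
zscore_features <- function(data) {
  v <- unclass(data)
  mu <- colMeans(v)
  sd_ <- apply(v, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  out <- sweep(sweep(v, 2L, mu), 2L, sd_, "/")
  data_matrix(out, tr = tr_seconds(data), labels = state_labels(data))
}
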