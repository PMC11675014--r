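#' Shape graph assembly
#'
#' The final Mapper step: one node per cluster, and an undirected edge
#' between two nodes exactly when their member sets share at least one time
#' point. Self-loops are never created. Derived objects are the temporal
#' connectivity matrix (TCM) and the normalized degree series used for
#' transition extraction.
#'
#' @param clusters a \code{cluster_set} from [cluster_bins()].
#' @param n_points number of rows in the source matrix (defaults to the
#'   value recorded in the cluster set).
#' @return A \code{shape_graph}: list with \code{members} (list of integer
#'   vectors), \code{provenance} (bin of origin per node), \code{edges}
#'   (2-column node-id matrix), \code{n_points}.
#' @export
build_shape_graph <- function(clusters, n_points = attr(clusters, "n_points")) {
  members <- lapply(clusters, `[[`, "points")
  keep <- lengths(members) > 0L
  members <- members[keep]
  provenance <- vapply(clusters, `[[`, integer(1), "bin")[keep]
  k <- length(members)
  if (k == 0L) {
    return(structure(list(members = list(), provenance = integer(0),
                          edges = matrix(integer(0), 0, 2), n_points = n_points),
                     class = "shape_graph"))
  }
  # sparse node x point incidence; edge iff shared member
  B <- Matrix::sparseMatrix(i = rep.int(seq_len(k), lengths(members)),
                            j = unlist(members), x = 1, dims = c(k, n_points))
  shared <- Matrix::tcrossprod(B)
  sh <- Matrix::which(shared > 0, arr.ind = TRUE)
  idx <- sh[sh[, 1] < sh[, 2], , drop = FALSE]
  structure(list(members = members, provenance = provenance,
                 edges = unname(idx), n_points = n_points),
            class = "shape_graph")
}

#' @export
print.shape_graph <- function(x, ...) {
  cat(sprintf("<shape_graph> %d nodes, %d edges over %d time points (%d covered)\n",
              length(x$members), nrow(x$edges), x$n_points,
              length(unique(unlist(x$members)))))
  invisible(x)
}

#' @rdname build_shape_graph
#' @param graph a \code{shape_graph}.
#' @export
shape_igraph <- function(graph) {
  g <- igraph::make_empty_graph(length(graph$members), directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  igraph::V(g)$size <- lengths(graph$members)
  g
}

#' Temporal connectivity matrix
#'
#' Binary \code{N x N} matrix with \code{TCM[i, j] = 1} exactly when some
#' node containing time point \code{i} and some node containing \code{j} are
#' the same node or joined by an edge. Diagonal entries are 1 for covered
#' points; rows of uncovered points are all zero.
#'
#' @param graph a \code{shape_graph}.
#' @return a 0/1 matrix with attribute \code{rule} describing the
#'   construction.
#' @export
compute_tcm <- function(graph) {
  k <- length(graph$members)
  n <- graph$n_points
  if (k == 0L) {
    out <- matrix(0L, n, n)
  } else {
    members <- graph$members
    B <- Matrix::sparseMatrix(i = rep.int(seq_len(k), lengths(members)),
                              j = unlist(members), x = 1, dims = c(k, n))
    e <- graph$edges
    A <- Matrix::sparseMatrix(i = c(seq_len(k), e[, 1], e[, 2]),
                              j = c(seq_len(k), e[, 2], e[, 1]),
                              x = 1, dims = c(k, k))
    out <- as.matrix(Matrix::crossprod(B, A %*% B) > 0) + 0L
  }
  attr(out, "rule") <- "same node or adjacent nodes (binary)"
  out
}

#' Normalized degree of the temporal connectivity matrix
#'
#' Per-time-point mean of the TCM row excluding the diagonal, min-max
#' rescaled to [0, 1] across time points. Abrupt changes in this series mark
#' transitions between recurring brain states. A constant series (e.g. from
#' an all-ones TCM) maps to all zeros with a warning.
#'
#' @param tcm a matrix from [compute_tcm()].
#' @return numeric vector in [0, 1], with the unscaled row means in
#'   attribute \code{raw}.
#' @export
normalized_degree <- function(tcm) {
  n <- nrow(tcm)
  if (n < 2L) stop("normalized degree needs at least 2 time points")
  raw <- (rowSums(tcm) - diag(tcm)) / (n - 1)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("constant normalized-degree series (fully connected or empty TCM)")
    out <- rep(0, n)
  } else {
    out <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  attr(out, "raw") <- raw
  out
}

#' Export a shape graph
#'
#' \code{write_shape_graph} writes GraphML (via \pkg{igraph}) and a JSON
#' document (nodes with member lists, edges); \code{membership_table}
#' returns/writes the time-point to node-id mapping.
#'
#' @param graph a \code{shape_graph}.
#' @param path_graphml,path_json output paths (either may be NULL to skip).
#' @export
write_shape_graph <- function(graph, path_graphml = NULL, path_json = NULL) {
  if (!is.null(path_graphml)) {
    g <- shape_igraph(graph)
    igraph::V(g)$members <- vapply(graph$members, paste, "", collapse = ",")
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  if (!is.null(path_json)) {
    doc <- list(
      n_points = graph$n_points,
      nodes = lapply(seq_along(graph$members), function(i)
        list(id = i, bin = graph$provenance[[i]], members = graph$members[[i]])),
      edges = if (nrow(graph$edges)) apply(graph$edges, 1L, as.list) else list())
    jsonlite::write_json(doc, path_json, auto_unbox = TRUE)
  }
  invisible(graph)
}

#' @rdname write_shape_graph
#' @param path optional CSV path; when given the table is also written.
#' @return \code{membership_table} returns a data frame (time_point,
#'   node_ids) where node_ids is a comma-joined id list.
#' @export
membership_table <- function(graph, path = NULL) {
  ids <- vector("list", graph$n_points)
  for (i in seq_along(graph$members))
    for (p in graph$members[[i]]) ids[[p]] <- c(ids[[p]], i)
  df <- data.frame(
    time_point = seq_len(graph$n_points),
    node_ids = vapply(ids, function(v) paste(v, collapse = ","), ""))
  if (!is.null(path))
    utils::write.csv(df, path, row.names = FALSE)
  df
}
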