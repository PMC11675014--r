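#' Pairwise dissimilarities between time frames
#'
#' Computes the full \code{N x N} matrix of dissimilarities between rows of
#' the input under one of five direct metrics: three magnitude measures
#' (\code{euclidean}, \code{cityblock}, \code{chebychev}) and two angle
#' measures (\code{cosine}, \code{correlation}). Correlation distance is
#' defined as 1 - Pearson correlation; in this form it does not satisfy the
#' triangle inequality (the square root of it would), but it is kept in this
#' widespread form deliberately.
#'
#' @param data a \code{mapper_data} object (or plain matrix).
#' @param metric one of \code{"euclidean"}, \code{"cityblock"},
#'   \code{"chebychev"}, \code{"cosine"}, \code{"correlation"}.
#' @return A \code{mapper_dist} object: list with \code{values} (symmetric
#'   \code{N x N} matrix, zero diagonal), \code{metric_name}, and for geodesic
#'   matrices \code{base_metric} and \code{k}.
#' @seealso [build_prknng()], [geodesic_distances()]
#' @export
#' @examples
#' d <- pairwise_distance(data_matrix(rbind(c(0, 0), c(3, 4)), tr = 1), "euclidean")
#' d$values[1, 2]  # 5
pairwise_distance <- function(data,
                              metric = c("euclidean", "cityblock", "chebychev",
                                         "cosine", "correlation")) {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(data))
  storage.mode(x) <- "double"
  n <- nrow(x)
  v <- switch(metric,
    euclidean = as.matrix(stats::dist(x, method = "euclidean")),
    cityblock = as.matrix(stats::dist(x, method = "manhattan")),
    chebychev = as.matrix(stats::dist(x, method = "maximum")),
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0))
        stop("cosine distance undefined for zero row(s): ",
             paste(which(nrm == 0), collapse = ", "))
      1 - tcrossprod(x / nrm)
    },
    correlation = {
      sds <- apply(x, 1L, stats::sd)
      if (any(sds == 0))
        stop("correlation distance undefined for zero-variance row(s): ",
             paste(which(sds == 0), collapse = ", "))
      1 - stats::cor(t(x))
    })
  # numerical cleanup: exact symmetry, zero diagonal, clamp fp negatives
  v <- (v + t(v)) / 2
  v[v < 0 & v > -1e-12] <- 0
  diag(v) <- 0
  dimnames(v) <- NULL
  new_mapper_dist(v, metric_name = metric)
}

new_mapper_dist <- function(values, metric_name, base_metric = NULL, k = NULL) {
  structure(list(values = values, metric_name = metric_name,
                 base_metric = base_metric, k = k),
            class = "mapper_dist")
}

#' @export
print.mapper_dist <- function(x, ...) {
  cat(sprintf("<mapper_dist> %d x %d, metric = %s%s\n",
              nrow(x$values), ncol(x$values), x$metric_name,
              if (is.null(x$k)) "" else sprintf(" (base %s, k = %d)", x$base_metric, x$k)))
  invisible(x)
}

#' Penalized reciprocal k-nearest-neighbor graph
#'
#' Builds the reciprocal k-NN graph: an undirected edge (i, j) exists only if
#' j is among the k nearest neighbors of i AND i is among the k nearest of j,
#' which damps the influence of outliers. If the reciprocal graph is
#' disconnected, components are merged greedily: the minimum-distance
#' inter-component pair is repeatedly added as a "bridge" edge with an
#' exponentially penalized weight until one component remains. Bridge edges
#' are flagged so the pure reciprocal graph can be recovered.
#'
#' The default penalty is \code{w = d * exp(d / dbar)} where \code{d} is the
#' raw inter-component distance and \code{dbar} the mean weight of the
#' existing reciprocal edges: the penalty is exponential in the gap size and
#' scale-free through the normalization. An alternative rule can be supplied
#' through \code{penalty}.
#'
#' Nearest-neighbor ties in distance are broken by lower row index, so the
#' construction is deterministic.
#'
#' @param dist a \code{mapper_dist} from a direct metric.
#' @param k neighbor count, \code{1 <= k < N}.
#' @param penalty function \code{(d, dbar) -> weight} for bridge edges.
#' @return A \code{mapper_knn} object: list with \code{n_points},
#'   \code{edges} (2-column index matrix), \code{weights}, \code{bridge}
#'   (logical flags), \code{k}, \code{base_metric}.
#' @export
build_prknng <- function(dist, k, penalty = function(d, dbar) d * exp(d / dbar)) {
  stopifnot(inherits(dist, "mapper_dist"))
  d <- dist$values
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 points to build a neighbor graph")
  if (k < 1L || k >= n) stop("'k' must satisfy 1 <= k <= N - 1 (N = ", n, ")")
  k <- as.integer(k)

  # k nearest neighbors per row, excluding self, ties broken by lower index
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    nn[i, ord] <- TRUE
  }
  mutual <- nn & t(nn)
  idx <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
  edges <- unname(idx)
  weights <- d[idx]
  bridge <- rep(FALSE, nrow(edges))

  comp <- graph_components(n, edges)
  dbar <- if (length(weights)) mean(weights) else mean(d[upper.tri(d)])
  if (dbar <= 0) dbar <- 1  # all-duplicate degenerate input
  while (max(comp) > 1L) {
    inter <- d
    same <- outer(comp, comp, "==")
    inter[same | lower.tri(inter, diag = TRUE)] <- Inf
    ij <- which(inter == min(inter), arr.ind = TRUE)[1L, , drop = TRUE]
    raw <- d[ij[1L], ij[2L]]
    edges <- rbind(edges, c(ij[1L], ij[2L]))
    weights <- c(weights, penalty(raw, dbar))
    bridge <- c(bridge, TRUE)
    comp <- graph_components(n, edges)
  }

  structure(list(n_points = n, edges = edges, weights = weights,
                 bridge = bridge, k = k, base_metric = dist$metric_name),
            class = "mapper_knn")
}

# connected-component labels for an n-node undirected edge list
graph_components <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' @export
print.mapper_knn <- function(x, ...) {
  cat(sprintf("<mapper_knn> %d points, k = %d (%s), %d reciprocal edges + %d bridges\n",
              x$n_points, x$k, x$base_metric,
              sum(!x$bridge), sum(x$bridge)))
  invisible(x)
}

#' Convert a neighbor graph to igraph
#'
#' @param graph a \code{mapper_knn} object.
#' @return an \pkg{igraph} undirected weighted graph with a logical
#'   \code{bridge} edge attribute.
#' @export
knn_igraph <- function(graph) {
  g <- igraph::make_empty_graph(graph$n_points, directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, t(graph$edges))
    igraph::E(g)$weight <- graph$weights
    igraph::E(g)$bridge <- graph$bridge
  }
  g
}

#' Geodesic (shortest-path) distances on a neighbor graph
#'
#' All-pairs shortest-path lengths on the penalized reciprocal k-NN graph.
#' Weighted mode (the default) sums edge weights; hops mode counts edges.
#' The result is a path metric: symmetric, zero diagonal, triangle
#' inequality holds.
#'
#' @param graph a connected \code{mapper_knn}.
#' @param mode \code{"weighted"} (default) or \code{"hops"}.
#' @return a \code{mapper_dist} with \code{metric_name = "geodesic"}.
#' @export
geodesic_distances <- function(graph, mode = c("weighted", "hops")) {
  mode <- match.arg(mode)
  g <- knn_igraph(graph)
  if (igraph::components(g)$no != 1L)
    stop("internal error: neighbor graph is disconnected after bridge repair")
  w <- if (mode == "weighted") igraph::E(g)$weight else NA
  v <- igraph::distances(g, weights = w)
  dimnames(v) <- NULL
  new_mapper_dist(v, metric_name = "geodesic",
                  base_metric = graph$base_metric, k = graph$k)
}

#' One-call geodesic metric
#'
#' Convenience wrapper chaining [pairwise_distance()], [build_prknng()] and
#' [geodesic_distances()].
#'
#' @inheritParams pairwise_distance
#' @inheritParams build_prknng
#' @inheritParams geodesic_distances
#' @return a geodesic \code{mapper_dist}; the neighbor graph is attached as
#'   attribute \code{"graph"}.
#' @export
geodesic_metric <- function(data, base_metric = "euclidean", k = 12,
                            mode = "weighted") {
  base <- pairwise_distance(data, base_metric)
  g <- build_prknng(base, k)
  out <- geodesic_distances(g, mode)
  attr(out, "graph") <- g
  out
}

#' Persist a distance matrix as TSV
#'
#' Writes the matrix with a one-line \code{#} header recording the metric
#' name (and base metric / k for geodesic matrices).
#'
#' @param dist a \code{mapper_dist}.
#' @param path output file.
#' @export
write_dist_tsv <- function(dist, path) {
  hdr <- sprintf("# metric=%s%s", dist$metric_name,
                 if (is.null(dist$k)) "" else sprintf(" base=%s k=%d", dist$base_metric, dist$k))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(dist$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
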