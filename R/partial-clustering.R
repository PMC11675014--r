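#' Partial clustering of bin members
#'
#' Each bin's members are clustered in the ORIGINAL high-dimensional space
#' (the lens never reaches this step): the distance submatrix indexed by the
#' bin members drives either single-linkage with the classic histogram-gap
#' cutoff, or density-based clustering (DBSCAN semantics). Clusters become
#' the nodes of the shape graph.
#'
#' @name partial_clustering
NULL

#' Single-linkage clustering with histogram-gap cutoff
#'
#' Builds the single-linkage dendrogram of the members under the original
#' distances, histograms the merge heights into \code{hist_bins} equal-width
#' bins over \code{[0, max height]}, and cuts at the left edge of the first
#' empty histogram bin that follows a nonempty one — a gap in the height
#' distribution separates within-cluster merges from between-cluster merges,
#' whereas empty bins below every observed height carry no information. If
#' no such gap exists the members stay in one cluster. This is the classic
#' Mapper rule for deciding how many clusters a bin supports.
#'
#' @param members integer vector of time-point indices (may be empty).
#' @param dist the full original-space \code{mapper_dist}.
#' @param hist_bins number of histogram bins (>= 2).
#' @return list of integer vectors (clusters), partitioning \code{members}.
#' @export
#' @examples
#' d <- pairwise_distance(data_matrix(cbind(c(0, .1, 10, 10.1)), tr = 1), "euclidean")
#' cluster_bin_linkage(1:4, d, hist_bins = 10)  # two clusters
cluster_bin_linkage <- function(members, dist, hist_bins = 10) {
  stopifnot(inherits(dist, "mapper_dist"), hist_bins >= 2)
  members <- as.integer(members)
  if (length(members) == 0L) return(list())
  if (length(members) == 1L) return(list(members))
  sub <- dist$values[members, members, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  hmax <- max(h)
  if (hmax <= 0) return(list(members))  # all members identical
  breaks <- seq(0, hmax, length.out = hist_bins + 1L)
  # bin b covers [breaks[b], breaks[b+1]) except the last, which is closed
  bin_of <- pmin(findInterval(h, breaks), hist_bins)
  counts <- tabulate(bin_of, nbins = hist_bins)
  # the gap must separate observed merge heights: cut at the first empty bin
  # that follows a nonempty one (an empty bin below every height is no gap)
  first_filled <- which(counts > 0L)[1L]
  empty <- which(counts == 0L & seq_along(counts) > first_filled)
  if (length(empty) == 0L) return(list(members))
  cutoff <- breaks[empty[1L]]
  cl <- stats::cutree(hc, h = cutoff)
  unname(lapply(split(members, cl), sort))
}

#' Density-based clustering of a bin (DBSCAN semantics)
#'
#' Standard density-based clustering on the member submatrix of original
#' distances: a core point has at least \code{min_pts} points (itself
#' included) within \code{eps}; clusters are the connected components of
#' density reachability; non-reachable points are noise and excluded from
#' every cluster (they feed the coverage criterion downstream rather than
#' being silently reassigned). Border points reachable from several clusters
#' join the first cluster discovered in index order, so the result is
#' deterministic and independent of input ordering.
#'
#' @param members integer vector of time-point indices.
#' @param dist the full original-space \code{mapper_dist}.
#' @param eps neighborhood radius (> 0).
#' @param min_pts minimum neighborhood size for a core point (default 3).
#' @return list of integer vectors (clusters); union is a subset of
#'   \code{members}.
#' @export
cluster_bin_density <- function(members, dist, eps, min_pts = 3) {
  stopifnot(inherits(dist, "mapper_dist"), eps > 0, min_pts >= 1)
  members <- sort(as.integer(members))
  m <- length(members)
  if (m == 0L) return(list())
  sub <- dist$values[members, members, drop = FALSE]
  neigh <- lapply(seq_len(m), function(i) which(sub[i, ] <= eps))
  core <- lengths(neigh) >= min_pts
  assigned <- integer(m)  # 0 = unvisited/noise
  cid <- 0L
  for (i in seq_len(m)) {
    if (!core[i] || assigned[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    assigned[i] <- cid
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (q in neigh[[p]]) {
        if (assigned[q] == 0L) {
          assigned[q] <- cid
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  if (cid == 0L) return(list())
  lapply(seq_len(cid), function(k) members[assigned == k])
}

#' Cluster every bin of a cover
#'
#' Applies [cluster_bin_linkage()] or [cluster_bin_density()] to each bin of
#' a cover, returning the cluster set that [build_shape_graph()] consumes.
#'
#' @param cover a \code{bin_cover}.
#' @param dist the full original-space \code{mapper_dist} (a direct metric;
#'   lens coordinates are deliberately not accepted here).
#' @param method \code{"linkage"} or \code{"dbscan"}.
#' @param hist_bins histogram bins for linkage mode.
#' @param eps,min_pts parameters for dbscan mode.
#' @return a \code{cluster_set}: list of clusters, each a list with
#'   \code{points} (global indices), \code{bin}, \code{method}.
#' @export
cluster_bins <- function(cover, dist, method = c("linkage", "dbscan"),
                         hist_bins = 10, eps = NULL, min_pts = 3) {
  method <- match.arg(method)
  stopifnot(inherits(cover, "bin_cover"))
  if (method == "dbscan" && is.null(eps)) stop("dbscan clustering requires 'eps'")
  out <- list()
  for (b in seq_along(cover$bins)) {
    cls <- if (method == "linkage")
      cluster_bin_linkage(cover$bins[[b]], dist, hist_bins)
    else
      cluster_bin_density(cover$bins[[b]], dist, eps, min_pts)
    for (cl in cls)
      out[[length(out) + 1L]] <- list(points = cl, bin = b, method = method)
  }
  structure(out, class = "cluster_set",
            n_points = nrow(dist$values), kind = cover$kind)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d points\n",
              length(x), attr(x, "n_points")))
  invisible(x)
}
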