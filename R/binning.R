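#' Overlapping bin covers of the lens
#'
#' A \code{bin_cover} is an ordered list of (possibly empty) time-point index
#' sets covering the lens, parameterized by resolution \code{R} and gain
#' \code{g}. Extrinsic covers are Cartesian products of overlapping
#' intervals (\code{R^d} rectangular bins); intrinsic covers are \code{R}
#' geodesic balls around farthest-point-sampled landmarks. Empty bins are
#' kept so that bin indexing is a pure function of (R, g); they produce no
#' graph nodes.
#'
#' @name bin_cover
NULL

new_bin_cover <- function(bins, descriptors, resolution, gain, kind) {
  structure(list(bins = bins, descriptors = descriptors,
                 resolution = resolution, gain = gain, kind = kind),
            class = "bin_cover")
}

#' @export
print.bin_cover <- function(x, ...) {
  cat(sprintf("<bin_cover> %s, %d bins (%d nonempty), resolution = %d, gain = %g%%\n",
              x$kind, length(x$bins), sum(lengths(x$bins) > 0),
              x$resolution, x$gain))
  invisible(x)
}

#' Extrinsic rectangular binning
#'
#' Divides each lens dimension into \code{R} overlapping intervals whose
#' centers tile \code{[min, max]} evenly at spacing \code{s = range / R} and
#' whose width is \code{w = s / (1 - g/100)}, so the overlap between
#' adjacent intervals is exactly \code{g}\% of the interval width. Bins are
#' the Cartesian products of per-dimension intervals (\code{R^d} bins); by
#' construction every lens point belongs to at least one bin. A
#' zero-range dimension degenerates to a single full-width interval (with a
#' warning); the remaining intervals of that dimension stay empty so the bin
#' count is still \code{R^d}.
#'
#' @param lens an extrinsic \code{mapper_lens}.
#' @param resolution \code{R >= 1}, segments per dimension.
#' @param gain overlap percentage \code{0 < g < 100}.
#' @return a \code{bin_cover}; descriptors hold per-bin rectangle bounds.
#' @export
#' @examples
#' lens <- new_lens_for_examples()
#' length(extrinsic_bins(lens, resolution = 4, gain = 33)$bins)  # 16
extrinsic_bins <- function(lens, resolution, gain) {
  stopifnot(inherits(lens, "mapper_lens"), lens$kind == "extrinsic")
  R <- as.integer(resolution)
  if (R < 1L) stop("'resolution' must be >= 1")
  if (gain <= 0 || gain >= 100) stop("'gain' must lie strictly between 0 and 100")
  co <- lens$coords
  d <- ncol(co)

  # per-dimension interval bounds: R x 2 matrices
  intervals <- lapply(seq_len(d), function(j) {
    lo <- min(co[, j]); hi <- max(co[, j])
    if (hi == lo) {
      warning("lens dimension ", j, " has zero range; using one full-width interval")
      b <- matrix(NA_real_, R, 2)
      b[1L, ] <- c(-Inf, Inf)
      return(b)
    }
    s <- (hi - lo) / R
    w <- s / (1 - gain / 100)
    centers <- lo + (seq_len(R) - 0.5) * s
    cbind(centers - w / 2, centers + w / 2)
  })

  # membership per dimension per interval (closed intervals)
  memb <- lapply(seq_len(d), function(j) {
    b <- intervals[[j]]
    lapply(seq_len(R), function(i) {
      if (is.na(b[i, 1L])) return(integer(0))
      which(co[, j] >= b[i, 1L] & co[, j] <= b[i, 2L])
    })
  })

  grid <- as.matrix(expand.grid(rep(list(seq_len(R)), d)))  # varies dim 1 fastest
  bins <- vector("list", nrow(grid))
  descriptors <- vector("list", nrow(grid))
  for (b in seq_len(nrow(grid))) {
    ids <- memb[[1L]][[grid[b, 1L]]]
    if (d > 1L) for (j in 2L:d) ids <- intersect(ids, memb[[j]][[grid[b, j]]])
    bins[[b]] <- sort(ids)
    descriptors[[b]] <- do.call(rbind, lapply(seq_len(d), function(j)
      intervals[[j]][grid[b, j], ]))
  }
  new_bin_cover(bins, descriptors, R, gain, "extrinsic")
}

#' Intrinsic landmark binning
#'
#' Selects \code{R} landmarks on the k-NN-graph lens by farthest-point
#' sampling on geodesic distances (each new landmark maximizes its minimum
#' geodesic distance to the landmarks already chosen; ties break to the
#' lowest index). With \code{2 * eps} the minimum pairwise landmark
#' distance, the bin of landmark \code{x} contains every point within
#' geodesic distance \code{4 * eps * g / 100} of \code{x}. Coverage is not
#' guaranteed for small gain: uncovered points are counted in the
#' \code{uncovered} attribute and lower the coverage criterion downstream.
#'
#' @param lens an intrinsic \code{mapper_lens}.
#' @param resolution number of landmarks, \code{2 <= R <= N}.
#' @param gain percentage \code{0 < g <= 100}.
#' @param start index of the first landmark (default 1).
#' @return a \code{bin_cover}; descriptors hold (landmark, radius, eps).
#' @export
intrinsic_bins <- function(lens, resolution, gain, start = 1L) {
  stopifnot(inherits(lens, "mapper_lens"), lens$kind == "intrinsic")
  R <- as.integer(resolution)
  geo <- lens$geo$values
  n <- nrow(geo)
  if (R < 2L) stop("'resolution' (landmark count) must be >= 2")
  if (R > n) stop("'resolution' = ", R, " exceeds the number of points N = ", n)
  if (gain <= 0 || gain > 100) stop("'gain' must lie in (0, 100]")

  landmarks <- integer(R)
  landmarks[1L] <- as.integer(start)
  if (R > 1L) {
    mind <- geo[, landmarks[1L]]
    for (i in 2L:R) {
      nxt <- order(-mind, seq_len(n))[1L]  # max distance, ties -> lowest index
      landmarks[i] <- nxt
      mind <- pmin(mind, geo[, nxt])
    }
  }
  two_eps <- min(geo[landmarks, landmarks][upper.tri(diag(R))])
  eps <- two_eps / 2
  radius <- 4 * eps * gain / 100

  bins <- lapply(landmarks, function(l) which(geo[, l] <= radius))
  descriptors <- lapply(landmarks, function(l)
    list(landmark = l, radius = radius, eps = eps))
  cover <- new_bin_cover(bins, descriptors, R, gain, "intrinsic")
  attr(cover, "uncovered") <- setdiff(seq_len(n), unique(unlist(bins)))
  cover
}

#' Points left uncovered by a cover
#'
#' @param cover a \code{bin_cover}.
#' @param n_points total number of points.
#' @return integer vector of uncovered point indices.
#' @export
uncovered_points <- function(cover, n_points) {
  setdiff(seq_len(n_points), unique(unlist(cover$bins)))
}

# tiny fixture used in roxygen examples
#' @keywords internal
#' @export
new_lens_for_examples <- function() {
  set.seed(1)
  new_lens("extrinsic", coords = matrix(stats::runif(60), 30, 2),
           algorithm = "CMDS", params = list(d = 2))
}
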