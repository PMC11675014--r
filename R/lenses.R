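#' Lens (filter-function output) objects
#'
#' The lens is the reduced representation the cover is built on: either an
#' extrinsic low-dimensional embedding (\code{coords}, an \code{N x d}
#' matrix) or the intrinsic penalized k-NN graph together with its geodesic
#' distance matrix. Exactly one of the two is populated.
#'
#' @name lens
NULL

new_lens <- function(kind, coords = NULL, graph = NULL, geo = NULL,
                     algorithm = NULL, params = list()) {
  structure(list(kind = kind, coords = coords, graph = graph, geo = geo,
                 algorithm = algorithm, params = params),
            class = "mapper_lens")
}

#' @export
print.mapper_lens <- function(x, ...) {
  if (x$kind == "extrinsic")
    cat(sprintf("<mapper_lens> extrinsic %s, %d points x %d dims\n",
                x$algorithm, nrow(x$coords), ncol(x$coords)))
  else
    cat(sprintf("<mapper_lens> intrinsic k-NN graph, %d points\n",
                x$graph$n_points))
  invisible(x)
}

#' Classical multidimensional scaling lens
#'
#' Native Torgerson MDS on a pairwise distance matrix: the squared-distance
#' matrix is double-centered (\code{-1/2 J D^2 J}), and the top-\code{d}
#' eigenvectors scaled by the square root of their eigenvalues give the
#' embedding. Negative eigenvalues among the top \code{d} (possible for
#' non-Euclidean dissimilarities) produce zero-filled axes and a warning.
#'
#' @param dist a \code{mapper_dist} (symmetric, zero diagonal).
#' @param d embedding dimension (default 2, the usual practice).
#' @return an extrinsic \code{mapper_lens}.
#' @export
#' @examples
#' pts <- matrix(rnorm(40), 20, 2)
#' lens <- embed_cmds(pairwise_distance(data_matrix(pts, 1), "euclidean"), d = 2)
#' dim(lens$coords)  # 20 x 2
embed_cmds <- function(dist, d = 2) {
  stopifnot(inherits(dist, "mapper_dist"))
  n <- nrow(dist$values)
  if (d < 1L) stop("'d' must be >= 1")
  if (d >= n) stop("embedding dimension d = ", d, " must be < N = ", n)
  D2 <- dist$values^2
  # double centering without forming J explicitly
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values[seq_len(d)]
  vec <- e$vectors[, seq_len(d), drop = FALSE]
  if (any(lam <= 0)) {
    warning(sum(lam <= 0), " of the top ", d,
            " CMDS eigenvalues are non-positive; those axes are zero-filled")
    lam[lam < 0] <- 0
  }
  coords <- vec %*% diag(sqrt(lam), nrow = d)
  new_lens("extrinsic", coords = coords, algorithm = "CMDS",
           params = list(d = d))
}

# --- Table-style registry of embedding algorithms --------------------------

.lens_registry <- new.env(parent = emptyenv())

register_builtin_backends <- function() {
  reg <- function(name, input, fn = NULL, stochastic = FALSE)
    assign(name, list(input = input, fn = fn, stochastic = stochastic),
           envir = .lens_registry)
  reg("CMDS", "distances", function(x, d, params) embed_cmds(x, d)$coords)
  reg("PCA", "distances", function(x, d, params)
    stats::prcomp(x$values, rank. = d)$x[, seq_len(d), drop = FALSE])
  reg("LDA", "distances", function(x, d, params) {
    if (is.null(params$labels)) stop("LDA backend requires params$labels")
    fit <- MASS::lda(x$values, grouping = params$labels)
    pred <- stats::predict(fit)$x
    pred[, seq_len(min(d, ncol(pred))), drop = FALSE]
  })
  reg("FactorAnalysis", "distances", function(x, d, params)
    stats::factanal(x$values, factors = d, scores = "regression")$scores)
  reg("Sammon", "distances", function(x, d, params) {
    v <- x$values
    v[v == 0 & upper.tri(v)] <- .Machine$double.eps  # sammon rejects off-diag zeros
    v <- (v + t(v)) / 2; diag(v) <- 0
    MASS::sammon(stats::as.dist(v), k = d, trace = FALSE)$points
  })
  reg("Isomap", "data", function(x, d, params) {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("the Isomap backend needs the 'vegan' package")
    k <- if (is.null(params$k)) 10L else params$k
    fit <- vegan::isomap(stats::dist(x), ndim = d, k = k)
    fit$points[, seq_len(d), drop = FALSE]
  })
  reg("DiffusionMaps", "distances")
  reg("UMAP", "data", stochastic = TRUE)
  reg("LLE", "data")
  reg("HessianLLE", "data")
  reg("Laplacian", "data")
  reg("LTSA", "data")
  reg("tSNE", "distances", stochastic = TRUE)
}

#' Embedding-algorithm registry
#'
#' The delegation contract for extrinsic filter functions: each algorithm
#' name maps to exactly one backend and one declared input form, either
#' \code{"distances"} (the backend consumes a pairwise \code{mapper_dist})
#' or \code{"data"} (it consumes the original matrix). Names without an
#' attached backend are part of the contract but error at call time until a
#' backend is registered with [register_lens_backend()].
#'
#' @return \code{lens_registry()} returns a data frame with columns
#'   \code{algorithm}, \code{input}, \code{available}, \code{stochastic}.
#' @export
lens_registry <- function() {
  nms <- sort(ls(.lens_registry))
  do.call(rbind, lapply(nms, function(nm) {
    e <- get(nm, envir = .lens_registry)
    data.frame(algorithm = nm, input = e$input,
               available = !is.null(e$fn), stochastic = e$stochastic)
  }))
}

#' @rdname lens_registry
#' @param algorithm registry name.
#' @param input \code{"distances"} or \code{"data"}.
#' @param fn backend function \code{(x, d, params) -> N x d coordinate matrix}.
#' @param stochastic whether the backend requires a seed.
#' @export
register_lens_backend <- function(algorithm, input = c("distances", "data"),
                                  fn, stochastic = FALSE) {
  input <- match.arg(input)
  assign(algorithm, list(input = input, fn = fn, stochastic = stochastic),
         envir = .lens_registry)
  invisible(algorithm)
}

#' Delegated extrinsic lens
#'
#' Runs a registered embedding backend on its declared input form and wraps
#' the result as a lens. Stochastic backends require a seed; a fixed seed and
#' fixed input give identical coordinates.
#'
#' @param x a \code{mapper_dist} (for \code{input = "distances"} algorithms)
#'   or a data matrix (for \code{input = "data"} algorithms).
#' @param algorithm a name from [lens_registry()].
#' @param d embedding dimension.
#' @param params named list passed to the backend and recorded in the lens
#'   (e.g. \code{perplexity} for tSNE).
#' @param seed integer seed, mandatory for stochastic backends.
#' @return an extrinsic \code{mapper_lens}.
#' @export
embed_delegate <- function(x, algorithm, d = 2, params = list(), seed = NULL) {
  if (!exists(algorithm, envir = .lens_registry))
    stop("unknown embedding algorithm '", algorithm, "'; registry: ",
         paste(sort(ls(.lens_registry)), collapse = ", "))
  entry <- get(algorithm, envir = .lens_registry)
  if (entry$input == "distances" && !inherits(x, "mapper_dist"))
    stop("algorithm '", algorithm, "' is applied on pairwise distances; ",
         "pass a mapper_dist")
  if (entry$input == "data" && inherits(x, "mapper_dist"))
    stop("algorithm '", algorithm, "' is applied on the original data; ",
         "pass the data matrix")
  if (is.null(entry$fn))
    stop("no backend registered for '", algorithm,
         "'; attach one with register_lens_backend()")
  if (entry$stochastic && is.null(seed))
    stop("algorithm '", algorithm, "' is stochastic; a seed is required")
  if (!is.null(seed)) set.seed(seed)
  xin <- if (entry$input == "data") unclass(as.matrix(x)) else x
  coords <- entry$fn(xin, d, params)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) >= 1L)
  new_lens("extrinsic", coords = unname(coords[, seq_len(min(d, ncol(coords))), drop = FALSE]),
           algorithm = algorithm, params = c(params, list(d = d, seed = seed)))
}

#' Intrinsic k-NN-graph lens
#'
#' The filter that skips dimensionality reduction: the lens is the penalized
#' reciprocal k-NN graph itself, with geodesic distances standing in for
#' coordinates. Binning then happens by landmarks on the graph.
#'
#' @param graph a connected \code{mapper_knn}.
#' @return an intrinsic \code{mapper_lens} with the graph and its geodesic
#'   \code{mapper_dist}.
#' @export
intrinsic_lens <- function(graph) {
  stopifnot(inherits(graph, "mapper_knn"))
  new_lens("intrinsic", graph = graph, geo = geodesic_distances(graph),
           algorithm = "knn-graph")
}

#' @rdname lens
#' @param lens an extrinsic \code{mapper_lens}.
#' @param path output TSV path.
#' @export
write_lens_tsv <- function(lens, path) {
  stopifnot(lens$kind == "extrinsic")
  utils::write.table(lens$coords, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
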