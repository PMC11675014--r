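# Independent oracles used across the suite. Each is a direct, brute-force
# computation kept deliberately separate from the package's implementation.

# all-pairs shortest paths by Floyd-Warshall dynamic programming
fw_shortest_paths <- function(n, edges, weights) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    D[i, j] <- D[j, i] <- min(D[i, j], weights[e])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# rigid-motion + reflection alignment residual (no scaling)
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  max(abs(Yc %*% s$v %*% t(s$u) - Xc))
}

# quadratic all-pairs intersection oracle for shape-graph edges
edge_oracle <- function(members) {
  k <- length(members)
  out <- matrix(integer(0), 0, 2)
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (length(intersect(members[[i]], members[[j]])) > 0)
      out <- rbind(out, c(i, j))
  out
}

# double-loop oracle for the temporal connectivity matrix
tcm_oracle <- function(members, edges, n_points) {
  k <- length(members)
  adj <- matrix(FALSE, k, k)
  diag(adj) <- TRUE
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  out <- matrix(0L, n_points, n_points)
  for (u in seq_len(k)) for (v in seq_len(k))
    if (adj[u, v]) out[members[[u]], members[[v]]] <- 1L
  out
}

# exhaustive changepoint search for K = 1 or 2 (piecewise-constant mean SSE)
exhaustive_changepoints <- function(x, K) {
  n <- length(x)
  sse <- function(seg) sum((seg - mean(seg))^2)
  cost_of <- function(starts) {
    bounds <- c(1, starts, n + 1)
    sum(vapply(seq_len(length(bounds) - 1), function(i)
      sse(x[bounds[i]:(bounds[i + 1] - 1)]), numeric(1)))
  }
  cands <- utils::combn(2:n, K)
  costs <- apply(cands, 2, cost_of)
  cands[, which.min(costs)]
}

# exhaustive simple-path oracle for the circleness criterion on small graphs
circleness_oracle <- function(members, edges, n_nodes, labels) {
  states <- c("stable-low", "transition-up", "stable-high", "transition-down")
  node_state <- vapply(members, function(m) {
    tab <- table(factor(labels[m], levels = states))
    names(tab)[which.max(tab)]
  }, "")
  adj <- matrix(FALSE, n_nodes, n_nodes)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  arc <- function(trans, drop) {
    keep <- node_state != drop
    found <- FALSE
    lows <- which(node_state == "stable-low" & keep)
    highs <- which(node_state == "stable-high" & keep)
    dfs <- function(path) {
      last <- path[length(path)]
      if (node_state[last] == "stable-high" && length(path) >= 3) {
        interior <- path[-c(1, length(path))]
        if (all(node_state[interior] == trans)) { found <<- TRUE; return() }
      }
      for (nxt in which(adj[last, ] & keep)) {
        if (nxt %in% path) next
        # interiors must be the transition state; endpoint may be stable-high
        if (node_state[nxt] %in% c(trans, "stable-high")) dfs(c(path, nxt))
      }
    }
    for (l in lows) { dfs(l); if (found) break }
    found
  }
  arc("transition-up", "transition-down") &&
    arc("transition-down", "transition-up")
}

# assemble a shape_graph object directly (for evaluation-only tests where
# edges need not arise from shared members)
make_shape_graph <- function(members, edges, n_points) {
  structure(list(members = members,
                 provenance = rep(1L, length(members)),
                 edges = matrix(as.integer(edges), ncol = 2),
                 n_points = n_points),
            class = "shape_graph")
}

# a path-graph neighbor object with given consecutive edge weights
chain_knn <- function(weights) {
  n <- length(weights) + 1L
  structure(list(n_points = n,
                 edges = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                 weights = weights, bridge = rep(FALSE, n - 1L),
                 k = 1L, base_metric = "euclidean"),
            class = "mapper_knn")
}

# random shape graph built from random overlapping member sets
random_shape_graph <- function(n_points, n_nodes, seed) {
  set.seed(seed)
  members <- lapply(seq_len(n_nodes), function(i)
    sort(sample(n_points, sample(1:4, 1))))
  g <- build_shape_graph(
    structure(lapply(seq_along(members), function(i)
      list(points = members[[i]], bin = i, method = "test")),
      class = "cluster_set", n_points = n_points, kind = "extrinsic"),
    n_points = n_points)
  g
}

# the example grid configuration used in the batch-runner docs
example_grid_config <- function() {
  list(dist = list(type = "geodesic_euclidean", k = c(12, 16)),
       embed = list(type = "CMDS", dims = 2),
       bin = list(type = "extrinsic", resolution = c(10, 20),
                  gain = c(50, 60, 70, 80), sides = 4),
       cluster = list(type = "linkage", bins = 10),
       analyses = list(list(type = "plot_graph"),
                       list(type = "compute_stats", hrf_threshold = 11)))
}
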