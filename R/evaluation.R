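#' Shape-graph validation (coverage, autocorrelation, complexity)
#'
#' A shape graph is worth interpreting only if it (a) employs most of the
#' input data, (b) captures more than trivial autocorrelation dynamics, and
#' (c) has nontrivial structure. The three criteria are:
#' \itemize{
#'   \item coverage \code{beta}: percent of time points inside the largest
#'     connected component (must exceed \code{beta_min});
#'   \item \code{alpha}: percent of nodes whose member time span,
#'     \code{(max index - min index) * tr} seconds, exceeds the
#'     autocorrelation threshold \code{tau} (must reach \code{alpha_min});
#'     \code{tau} defaults to 11 s, the typical hemodynamic response peak;
#'   \item entropy \code{S}: Shannon entropy (base 2) of the unit-width
#'     integer histogram of pairwise shortest-path hop distances between all
#'     node pairs of the largest connected component (must reach
#'     \code{s_min}); low entropy flags degenerate clique-like graphs.
#' }
#'
#' The alpha predicate operationalizes "describes data points over the
#' autocorrelation threshold" as the node's temporal span; the predicate can
#' be swapped via \code{span_fn}.
#'
#' @param graph a \code{shape_graph} with at least one node.
#' @param tr sampling interval in seconds.
#' @param tau autocorrelation threshold in seconds (default 11).
#' @param alpha_min,beta_min,s_min validity thresholds (defaults 15, 70, 2).
#' @param span_fn function(members, tr) -> seconds; default temporal span.
#' @return a \code{validation_report}: list with \code{alpha}, \code{beta},
#'   \code{entropy}, \code{valid} and the thresholds used. Valid iff
#'   \code{alpha >= alpha_min & beta > beta_min & entropy >= s_min}.
#' @export
validate_shape_graph <- function(graph, tr, tau = 11,
                                 alpha_min = 15, beta_min = 70, s_min = 2,
                                 span_fn = NULL) {
  stopifnot(inherits(graph, "shape_graph"))
  if (length(graph$members) == 0L) stop("cannot validate a graph with zero nodes")
  if (is.null(span_fn))
    span_fn <- function(members, tr) (max(members) - min(members)) * tr

  g <- shape_igraph(graph)
  comp <- igraph::components(g)
  comp_points <- vapply(seq_len(comp$no), function(cc)
    length(unique(unlist(graph$members[comp$membership == cc]))), integer(1))
  big <- which.max(comp_points)
  beta <- 100 * comp_points[big] / graph$n_points

  spans <- vapply(graph$members, span_fn, numeric(1), tr = tr)
  alpha <- 100 * sum(spans > tau) / length(spans)

  in_big <- which(comp$membership == big)
  entropy <- if (length(in_big) < 2L) 0 else {
    hops <- igraph::distances(igraph::induced_subgraph(g, in_big), weights = NA)
    hops <- hops[upper.tri(hops)]
    counts <- table(hops)
    p <- as.numeric(counts) / sum(counts)
    -sum(p * log2(p))
  }

  structure(list(alpha = alpha, beta = beta, entropy = entropy,
                 tau = tau, tr = tr,
                 alpha_min = alpha_min, beta_min = beta_min, s_min = s_min,
                 valid = alpha >= alpha_min && beta > beta_min && entropy >= s_min),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation> alpha = %.1f%% (>= %g), beta = %.1f%% (> %g), S = %.3f bits (>= %g) -> %s\n",
              x$alpha, x$alpha_min, x$beta, x$beta_min, x$entropy, x$s_min,
              if (x$valid) "VALID" else "invalid"))
  invisible(x)
}

.circle_states <- c("stable-low", "transition-up", "stable-high", "transition-down")

# majority state per node; ties resolve to the earliest state in the fixed order
node_states <- function(graph, labels) {
  vapply(graph$members, function(m) {
    tab <- table(factor(labels[m], levels = .circle_states))
    names(tab)[which.max(tab)]
  }, "")
}

#' Circleness goodness-of-fit criterion
#'
#' Tests whether the shape graph represents the circular state trajectory of
#' the simulated paradigm: after labeling each node by the majority state of
#' its members, the graph restricted away from transition-down nodes must
#' contain a path from a stable-low node to a stable-high node whose
#' interior nodes are all transition-up (at least one of them), and
#' symmetrically for the transition-down arc with transition-up nodes
#' removed. Both arcs present = the loop is captured.
#'
#' A direct stable-low/stable-high edge does not by itself fail the
#' criterion; set \code{strict = TRUE} to additionally reject graphs with
#' such a shortcut edge.
#'
#' @param graph a \code{shape_graph}.
#' @param labels per-time-point states from \code{"stable-low"},
#'   \code{"transition-up"}, \code{"stable-high"}, \code{"transition-down"}.
#' @param strict also fail on a direct stable-low/stable-high edge.
#' @return logical scalar.
#' @export
circleness <- function(graph, labels, strict = FALSE) {
  stopifnot(inherits(graph, "shape_graph"))
  if (length(labels) != graph$n_points)
    stop("'labels' must have length n_points = ", graph$n_points)
  if (!all(labels %in% .circle_states))
    stop("labels must be drawn from: ", paste(.circle_states, collapse = ", "))
  if (length(graph$members) == 0L) return(FALSE)
  st <- node_states(graph, labels)

  arc_ok <- function(trans_state, drop_state) {
    keep <- which(st != drop_state)
    if (length(keep) == 0L) return(FALSE)
    g <- shape_igraph(graph)
    sub <- igraph::induced_subgraph(g, keep)
    sst <- st[keep]
    trans <- which(sst == trans_state)
    if (length(trans) == 0L) return(FALSE)
    # a valid arc exists iff some connected component of the transition-only
    # subgraph touches both a stable-low and a stable-high node
    tg <- igraph::induced_subgraph(sub, trans)
    tc <- igraph::components(tg)$membership
    adj <- igraph::as_adjacency_matrix(sub, sparse = FALSE) > 0
    low <- which(sst == "stable-low"); high <- which(sst == "stable-high")
    for (cc in seq_len(max(tc))) {
      tn <- trans[tc == cc]
      touch_low <- length(low) && any(adj[tn, low, drop = FALSE])
      touch_high <- length(high) && any(adj[tn, high, drop = FALSE])
      if (touch_low && touch_high) return(TRUE)
    }
    FALSE
  }

  up_ok <- arc_ok("transition-up", "transition-down")
  down_ok <- arc_ok("transition-down", "transition-up")
  res <- up_ok && down_ok
  if (res && strict) {
    low <- which(st == "stable-low"); high <- which(st == "stable-high")
    if (length(low) && length(high) && nrow(graph$edges)) {
      e <- graph$edges
      direct <- any((e[, 1] %in% low & e[, 2] %in% high) |
                    (e[, 1] %in% high & e[, 2] %in% low))
      if (direct) res <- FALSE
    }
  }
  res
}

#' Exact changepoint detection (piecewise-constant mean)
#'
#' Finds the \code{n_change} changepoints of the piecewise-constant-mean
#' model minimizing total within-segment squared error, by exact dynamic
#' programming over all segmentations (no heuristics, so small cases can be
#' checked against exhaustive search).
#'
#' @param x numeric series (the normalized degree).
#' @param n_change number of changepoints (>= 1).
#' @param tr seconds per sample; returned times are
#'   \code{(first index of the new segment - 1) * tr}.
#' @return numeric vector of \code{n_change} changepoint times (seconds),
#'   with the 1-based segment-start indices in attribute \code{index}.
#' @export
#' @examples
#' detect_transitions(rep(c(0, 1), each = 50), n_change = 1)  # 50 * tr
detect_transitions <- function(x, n_change, tr = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n_change < 1L) stop("'n_change' must be >= 1")
  if (n < n_change + 1L) stop("series too short for ", n_change, " changepoints")
  if (stats::sd(x) == 0) stop("constant series: no detectable changepoint")
  K <- as.integer(n_change)

  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  # cost[i, j]: best cost of x[1..j] split into i segments
  cost <- matrix(Inf, K + 1L, n)
  back <- matrix(0L, K + 1L, n)
  cost[1L, ] <- (s2[-1L] - s1[-1L]^2 / seq_len(n))
  for (i in 2L:(K + 1L)) {
    for (j in i:n) {
      t <- (i - 1L):(j - 1L)  # last segment is x[(t+1)..j]
      seg <- (s2[j + 1L] - s2[t + 1L]) - (s1[j + 1L] - s1[t + 1L])^2 / (j - t)
      v <- cost[i - 1L, t] + seg
      arg <- which.min(v)
      cost[i, j] <- v[arg]; back[i, j] <- t[arg]
    }
  }
  # recover segment starts
  starts <- integer(K)
  j <- n
  for (i in (K + 1L):2L) {
    t <- back[i, j]
    starts[i - 1L] <- t + 1L
    j <- t
  }
  structure((starts - 1L) * tr, index = starts)
}

#' Average delay between extracted and expected transitions
#'
#' Mean, over the EXPECTED transition times, of the absolute difference to
#' the nearest extracted time, in seconds. Averaging over the expected list
#' means a missed transition inflates the delay instead of disappearing. An
#' empty extracted list returns \code{Inf}.
#'
#' @param extracted numeric vector of extracted transition times (seconds).
#' @param expected numeric vector of expected transition times (nonempty).
#' @return nonnegative scalar (seconds), possibly \code{Inf}.
#' @export
#' @examples
#' average_delay(c(100, 300), c(100, 200, 300))  # (0 + 100 + 0) / 3
average_delay <- function(extracted, expected) {
  if (length(expected) == 0L) stop("'expected' must be nonempty")
  if (length(extracted) == 0L) return(Inf)
  mean(vapply(expected, function(e) min(abs(extracted - e)), numeric(1)))
}

#' Transition-extraction goodness of fit
#'
#' Chains [compute_tcm()], [normalized_degree()], [detect_transitions()] and
#' [average_delay()]: extracts \code{length(expected)} transitions from the
#' shape graph's normalized degree and scores them against the expected
#' (instruction-boundary) times. The graph passes if the average delay is at
#' most \code{delta} seconds.
#'
#' @param graph a \code{shape_graph}.
#' @param tr seconds per sample.
#' @param expected expected transition times (seconds).
#' @param delta pass threshold in seconds (default 12).
#' @return a \code{gof_result}: list with \code{transitions},
#'   \code{average_delay}, \code{delta}, \code{pass}.
#' @export
transition_gof <- function(graph, tr, expected, delta = 12) {
  deg <- normalized_degree(compute_tcm(graph))
  extracted <- tryCatch(
    as.numeric(detect_transitions(deg, n_change = length(expected), tr = tr)),
    error = function(e) numeric(0))
  ad <- average_delay(extracted, expected)
  structure(list(transitions = extracted, average_delay = ad,
                 delta = delta, pass = is.finite(ad) && ad <= delta),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof> %d transitions, average delay = %.2f s (delta = %g) -> %s\n",
              length(x$transitions), x$average_delay, x$delta,
              if (x$pass) "PASS" else "fail"))
  invisible(x)
}
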