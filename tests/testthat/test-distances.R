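test_that("direct metrics match their closed forms on hand cases", {
  dm <- data_matrix(rbind(c(0, 0), c(3, 4)), tr = 1)
  expect_equal(pairwise_distance(dm, "euclidean")$values[1, 2], 5)
  expect_equal(pairwise_distance(dm, "cityblock")$values[1, 2], 7)
  expect_equal(pairwise_distance(dm, "chebychev")$values[1, 2], 4)

  ortho <- data_matrix(rbind(c(1, 0), c(0, 1)), tr = 1)
  expect_equal(pairwise_distance(ortho, "cosine")$values[1, 2], 1)

  anti <- data_matrix(rbind(c(1, 2, 3), c(3, 2, 1)), tr = 1)
  expect_equal(pairwise_distance(anti, "correlation")$values[1, 2], 2)

  for (m in c("euclidean", "cityblock", "chebychev", "cosine", "correlation")) {
    d <- pairwise_distance(data_matrix(matrix(rnorm(30), 10, 3), 1), m)
    expect_equal(diag(d$values), rep(0, 10))
  }
})

test_that("degenerate rows are rejected by name for angle metrics", {
  z <- data_matrix(rbind(c(1, 2), c(0, 0), c(3, 4)), tr = 1)
  expect_error(pairwise_distance(z, "cosine"), "row.*2")
  flat <- data_matrix(rbind(c(1, 2), c(5, 5)), tr = 1)
  expect_error(pairwise_distance(flat, "correlation"), "row.*2")
})

test_that("distance matrices are symmetric, nonnegative, zero-diagonal", {
  set.seed(42)
  for (m in c("euclidean", "cityblock", "chebychev", "cosine", "correlation")) {
    d <- pairwise_distance(data_matrix(matrix(rnorm(60), 15, 4), 1), m)$values
    expect_identical(d, t(d))
    expect_true(all(d >= 0))
    expect_equal(diag(d), rep(0, 15))
  }
})

triangle_violations <- function(d) {
  n <- nrow(d); bad <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (d[i, j] > d[i, k] + d[k, j] + 1e-9) bad <- bad + 1L
  bad
}

test_that("triangle inequality holds for magnitude metrics and geodesic, not correlation", {
  set.seed(7)
  x <- data_matrix(matrix(rnorm(40), 20, 2), 1)
  for (m in c("euclidean", "cityblock", "chebychev"))
    expect_identical(triangle_violations(pairwise_distance(x, m)$values), 0L)
  geo <- geodesic_metric(x, "euclidean", k = 4)
  expect_identical(triangle_violations(geo$values), 0L)

  # a kept counterexample for 1 - Pearson correlation:
  # d13 = 1.662 > d12 + d23 = 0.365 + 1.074
  y <- data_matrix(rbind(c(-3, 0, 5, 3), c(-5, 2, 0, 4), c(4, 1, -4, 4)), 1)
  dc <- pairwise_distance(y, "correlation")$values
  expect_gt(dc[1, 3], dc[1, 2] + dc[2, 3] + 0.05)
})

test_that("reciprocal k-NN graph matches hand enumeration and repairs connectivity", {
  # 1-D points {0, 1, 3}, k = 1: only (1,2) reciprocal; point 3 bridged
  d <- pairwise_distance(data_matrix(cbind(c(0, 1, 3)), 1), "euclidean")
  g <- build_prknng(d, k = 1)
  recip <- g$edges[!g$bridge, , drop = FALSE]
  expect_equal(recip, cbind(1L, 2L), ignore_attr = TRUE)
  expect_identical(sum(g$bridge), 1L)
  expect_equal(igraph::components(knn_igraph(g))$no, 1L)
  # bridge connects the isolated point to its nearest neighbor with a
  # penalized weight strictly above the raw gap distance (gap = 2)
  expect_setequal(g$edges[g$bridge, ], c(2L, 3L))
  expect_gt(g$weights[g$bridge], 2)

  # k = N - 1 gives the complete graph, no bridges
  d5 <- pairwise_distance(data_matrix(matrix(rnorm(10), 5, 2), 1), "euclidean")
  g5 <- build_prknng(d5, k = 4)
  expect_identical(nrow(g5$edges), 10L)
  expect_false(any(g5$bridge))

  # two tight clusters across a large gap: exactly one bridge
  pts <- c(seq(0, 0.4, by = 0.1), seq(100, 100.4, by = 0.1))
  dg <- pairwise_distance(data_matrix(cbind(pts), 1), "euclidean")
  gg <- build_prknng(dg, k = 2)
  expect_identical(sum(gg$bridge), 1L)
  gap <- min(abs(outer(pts[1:5], pts[6:10], "-")))
  expect_gt(gg$weights[gg$bridge], gap)
})

test_that("k >= N and tiny inputs are rejected", {
  d <- pairwise_distance(data_matrix(matrix(rnorm(6), 3, 2), 1), "euclidean")
  expect_error(build_prknng(d, k = 3), "k")
})

test_that("geodesic distances agree with the shortest-path oracle", {
  ch <- chain_knn(c(1, 2))
  gd <- geodesic_distances(ch, "weighted")
  expect_equal(gd$values[1, 3], 3)
  expect_equal(geodesic_distances(ch, "hops")$values[1, 3], 2)
  expect_equal(diag(gd$values), rep(0, 3))

  set.seed(11)
  for (rep in 1:20) {
    x <- data_matrix(matrix(rnorm(20), 10, 2), 1)
    g <- build_prknng(pairwise_distance(x, "euclidean"), k = sample(2:5, 1))
    got <- geodesic_distances(g)$values
    want <- fw_shortest_paths(10, g$edges, g$weights)
    expect_equal(got, want)
  }
})

test_that("graph invariants: connectivity, bridge removal, k-monotonicity", {
  set.seed(3)
  for (rep in 1:10) {
    x <- data_matrix(matrix(rnorm(36), 18, 2), 1)
    d <- pairwise_distance(x, "euclidean")
    g2 <- build_prknng(d, 2)
    expect_equal(igraph::components(knn_igraph(g2))$no, 1L)
    # removing flagged bridges restores the pure reciprocal graph
    recip <- g2$edges[!g2$bridge, , drop = FALSE]
    dm <- d$values
    n <- nrow(dm)
    nn <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      ord <- order(dm[i, ], seq_len(n)); ord <- ord[ord != i][1:2]
      nn[i, ord] <- TRUE
    }
    want <- which(nn & t(nn) & upper.tri(nn), arr.ind = TRUE)
    expect_equal(recip[order(recip[, 1], recip[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
    # reciprocal edge set is non-decreasing in k
    e2 <- apply(g2$edges[!g2$bridge, , drop = FALSE], 1, paste, collapse = "-")
    g4 <- build_prknng(d, 4)
    e4 <- apply(g4$edges[!g4$bridge, , drop = FALSE], 1, paste, collapse = "-")
    expect_true(all(e2 %in% e4))
  }
})

test_that("distance matrices persist to TSV with a metric header", {
  d <- pairwise_distance(data_matrix(matrix(1:6, 3, 2), 1), "cityblock")
  tf <- tempfile(fileext = ".tsv")
  write_dist_tsv(d, tf)
  expect_match(readLines(tf, n = 1), "metric=cityblock")
  body <- as.matrix(utils::read.table(tf, skip = 1))
  expect_equal(unname(body), d$values)
})
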