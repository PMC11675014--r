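test_that("the coupling schedule and labels agree", {
  sch <- g_schedule(g_low = 1, g_high = 3, stable_s = 10, trans_s = 20,
                    cycles = 3, tr = 0.5)
  expect_equal(sch$total_s, 3 * 60)
  expect_length(sch$segment_types, 12L)
  expect_length(sch$G, length(sch$labels))
  # G constant on stable segments, strictly monotone on transitions
  for (lab in c("stable-low", "stable-high"))
    expect_equal(stats::sd(sch$G[sch$labels == lab]), 0)
  up <- sch$G[sch$labels == "transition-up"]
  runs <- split(up, cumsum(c(TRUE, diff(which(sch$labels == "transition-up")) > 1)))
  for (r in runs) expect_true(all(diff(r) > 0))
  expect_error(g_schedule(tr = 0), "tr")
})

test_that("the block paradigm arithmetic is exact", {
  p <- paradigm_schedule(n_blocks = 4, block_s = 100, instr_s = 10, tr = 2)
  expect_equal(p$total_s, 4 * 100 + 3 * 10)
  expect_length(p$boundaries, 3L)
  expect_true(all(p$labels %in% c("Rest", "Memory", "Video", "Math",
                                  "instructions")))
})

test_that("the network simulator is deterministic and settles without noise", {
  sch <- g_schedule(g_low = 2, g_high = 2, stable_s = 30, trans_s = 30,
                    cycles = 1, tr = 1)
  cfg <- wc_config(n_nodes = 8, noise_sd = 0, seed = 3, dt = 0.05)
  b1 <- simulate_wc_bold(cfg, sch)
  expect_identical(dim(unclass(b1)), c(length(sch$G), 8L))
  expect_identical(state_labels(b1), sch$labels)
  b2 <- simulate_wc_bold(cfg, sch)
  expect_identical(unclass(b1), unclass(b2))
  # constant G, no noise: the sampled response converges to a fixed point
  tail_diff <- max(abs(unclass(b1)[length(sch$G), ] -
                       unclass(b1)[length(sch$G) - 1L, ]))
  expect_lt(tail_diff, 1e-6)
  cfgn <- wc_config(n_nodes = 8, noise_sd = 0.02, seed = 3, dt = 0.05)
  expect_identical(unclass(simulate_wc_bold(cfgn, sch)),
                   unclass(simulate_wc_bold(cfgn, sch)))
})

test_that("the circular generator closes its loop and separates its arcs", {
  sch <- g_schedule(stable_s = 20, trans_s = 40, tr = 0.72)
  clean <- synth_circular_bold(n_features = 10, schedule = sch, noise_sd = 0)
  v <- unclass(clean)
  step <- max(sqrt(rowSums(diff(v)^2)))
  expect_lt(sqrt(sum((v[1, ] - v[nrow(v), ])^2)), step + 1e-9)

  # midpoints of the two arcs are arc_separation apart
  mid_up <- v[which(sch$labels == "transition-up")[28], ]
  mid_dn <- v[which(sch$labels == "transition-down")[28], ]
  expect_gte(sqrt(sum((mid_up - mid_dn)^2)), 1 - 0.05)
  expect_identical(state_labels(clean), sch$labels)
  # pure function of (parameters, seed)
  a <- synth_circular_bold(schedule = sch, seed = 9)
  b <- synth_circular_bold(schedule = sch, seed = 9)
  expect_identical(unclass(a), unclass(b))
})

test_that("the trefoil knot follows its parameterization", {
  tk <- trefoil_knot(120)
  expect_identical(dim(unclass(tk)), c(120L, 3L))
  t <- attr(tk, "angle")
  expect_equal(unclass(tk)[, 1], sin(t) + 2 * sin(2 * t), ignore_attr = TRUE)
  expect_equal(unclass(tk)[, 3], -sin(3 * t), ignore_attr = TRUE)
})

test_that("noise injection hits the target SNR", {
  set.seed(71)
  sig <- data_matrix(cbind(sin(seq_len(10000) / 50), cos(seq_len(10000) / 80)),
                     tr = 1)
  for (snr in c(10, 1, 0.5)) {
    noisy <- add_noise(sig, target_snr = snr, seed = 5)
    ratio <- apply(unclass(noisy) - unclass(sig), 2, stats::sd) /
      apply(unclass(sig), 2, stats::sd)
    expect_equal(ratio, rep(1 / snr, 2), tolerance = 0.05, ignore_attr = TRUE)
  }
  # SNR 0.5: noise sd is twice the signal sd, within 1% at this length
  noisy <- add_noise(sig, 0.5, seed = 6)
  ratio <- stats::sd((unclass(noisy) - unclass(sig))[, 1]) /
    stats::sd(unclass(sig)[, 1])
  expect_equal(ratio, 2, tolerance = 0.01)

  expect_identical(add_noise(sig, Inf), sig)
  flat <- data_matrix(cbind(rep(1, 100), stats::rnorm(100)), 1)
  expect_warning(add_noise(flat, 1), "zero variance")
})

test_that("smoothed downsampling keeps the arithmetic of the paradigm", {
  sch <- g_schedule()
  dat <- synth_circular_bold(n_features = 4, schedule = sch, noise_sd = 0)
  ds <- smooth_downsample(dat, factor = 3)
  expect_identical(nrow(ds), 556L)
  expect_equal(tr_seconds(ds), 2.16)

  same <- smooth_downsample(dat, factor = 1)
  expect_identical(nrow(same), nrow(dat))
  expect_false(identical(unclass(same), unclass(dat)))  # smoothed

  const <- data_matrix(matrix(5, 50, 2), 1)
  expect_equal(unclass(smooth_downsample(const, 1))[, 1], rep(5, 50),
               ignore_attr = TRUE)
  expect_error(smooth_downsample(const, 50), "factor")
})

test_that("block shuffling permutes blocks, preserving within-block order", {
  set.seed(72)
  dat <- data_matrix(matrix(stats::rnorm(100 * 3), 100, 3), 1,
                     labels = sample(letters[1:4], 100, TRUE))
  sh <- shuffle_blocks(dat, block = 7, seed = 11)
  perm <- attr(sh, "permutation")
  # multiset equality of rows
  expect_equal(unclass(sh), unclass(dat)[perm, ], ignore_attr = TRUE)
  expect_setequal(perm, 1:100)
  # within any block, consecutive input rows remain consecutive
  for (b in split(seq_len(100), (seq_len(100) - 1L) %/% 7L)) {
    pos <- match(b, perm)
    expect_equal(diff(pos), rep(1L, length(b) - 1L))
  }
  # same seed, same shape: identical permutation across matrices
  dat2 <- data_matrix(matrix(stats::runif(100 * 2), 100, 2), 1)
  sh2 <- shuffle_blocks(dat2, block = 7, seed = 11)
  expect_identical(attr(sh2, "permutation"), perm)
  expect_identical(state_labels(sh), state_labels(dat)[perm])
})
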