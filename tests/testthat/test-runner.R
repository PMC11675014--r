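test_that("grid expansion is a deterministic Cartesian product", {
  cfgs <- expand_grid_config(example_grid_config())
  expect_length(cfgs, 16L)
  # deterministic order: k varies slowest among the swept fields
  expect_equal(vapply(cfgs, function(c) c$dist$k, numeric(1)),
               rep(c(12, 16), each = 8))
  expect_equal(vapply(cfgs, function(c) c$bin$gain, numeric(1)),
               rep(c(50, 60, 70, 80), 4))
  expect_identical(cfgs, expand_grid_config(example_grid_config()))

  scalar <- list(dist = list(type = "euclidean"),
                 bin = list(type = "extrinsic", resolution = 5, gain = 50),
                 cluster = list(type = "linkage", bins = 10))
  expect_length(expand_grid_config(scalar), 1L)
})

test_that("unknown config fields and bad polygons are rejected by name", {
  bad <- example_grid_config()
  bad$frobnicate <- 1
  expect_error(expand_grid_config(bad), "frobnicate")
  bad2 <- example_grid_config()
  bad2$bin$shape <- "hex"
  expect_error(expand_grid_config(bad2), "shape")
  tri <- example_grid_config()
  tri$bin$sides <- 3
  expect_error(expand_grid_config(tri), "4-sided")
})

test_that("config hashes are stable and key-order insensitive", {
  c1 <- list(dist = list(type = "euclidean", k = 12),
             bin = list(resolution = 10, gain = 50))
  c2 <- list(bin = list(gain = 50, resolution = 10),
             dist = list(k = 12, type = "euclidean"))
  expect_identical(config_hash(c1), config_hash(c2))
  expect_identical(nchar(config_hash(c1)), 12L)
  c3 <- c1; c3$dist$k <- 16
  expect_false(config_hash(c1) == config_hash(c3))
})

test_that("mapper_run enforces stage compatibility", {
  dat <- synth_circular_bold(schedule = g_schedule(stable_s = 10, trans_s = 20))
  expect_error(
    mapper_run(dat, list(dist = list(type = "euclidean"),
                         bin = list(type = "intrinsic", resolution = 5, gain = 50),
                         cluster = list(type = "linkage"))),
    "geodesic")
  expect_error(
    mapper_run(dat, list(dist = list(type = "euclidean", k = c(2, 3)),
                         bin = list(type = "extrinsic", resolution = 5, gain = 50),
                         cluster = list(type = "linkage"))),
    "expand")
})

write_cohort_fixture <- function(root, n_inputs = 2) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  sch <- g_schedule(stable_s = 15, trans_s = 30, cycles = 2, tr = 0.72)
  ids <- paste0("sub", seq_len(n_inputs))
  for (i in seq_len(n_inputs))
    write_data_matrix(synth_circular_bold(n_features = 6, schedule = sch,
                                          seed = i),
                      file.path(root, paste0(ids[i], ".tsv")))
  cohort <- data.frame(id = ids, path = paste0(ids, ".tsv"))
  utils::write.csv(cohort, file.path(root, "cohort.csv"), row.names = FALSE)
  list(cohort = file.path(root, "cohort.csv"), sch = sch)
}

small_grid <- function() {
  list(dist = list(type = "geodesic_euclidean", k = 6),
       embed = list(type = "CMDS", dims = 2),
       bin = list(type = "extrinsic", resolution = c(8, 12), gain = 60),
       cluster = list(type = "linkage", bins = 10))
}

test_that("cohort runs produce the documented layout and aggregate cleanly", {
  root <- file.path(tempdir(), "cohortrun")
  fx <- write_cohort_fixture(root)
  out <- file.path(root, "out")
  man <- run_cohort(fx$cohort, small_grid(), data_root = root, out_dir = out,
                    poolsize = 1, seed = 1, tr = 0.72)
  expect_length(man$tasks, 4L)  # 2 inputs x 2 configs
  expect_true(all(vapply(man$tasks, `[[`, "", "status") == "ok"))
  dirs <- list.dirs(out, recursive = TRUE)
  stats_files <- list.files(out, "stats.csv", recursive = TRUE)
  expect_length(stats_files, 4L)
  for (f in file.path(out, stats_files[1])) {
    expect_true(file.exists(file.path(dirname(f), "graph.json")))
    expect_true(file.exists(file.path(dirname(f), "graph.graphml")))
    expect_true(file.exists(file.path(dirname(f), "membership.csv")))
  }
  agg <- aggregate_stats(out)
  expect_identical(nrow(agg), 4L)
  expect_true(all(c("id", "resolution", "gain", "alpha", "beta", "valid")
                  %in% names(agg)))
  # pass counts equal a manual recount from the per-graph stats
  pm <- pass_count_matrix(agg, "valid")
  expect_identical(sum(pm), sum(as.logical(agg$valid)))
  expect_warning(aggregate_stats(file.path(root, "nowhere")), "no stats")
})

test_that("cohort results are poolsize-invariant and failures are recorded", {
  root <- file.path(tempdir(), "cohortrun2")
  fx <- write_cohort_fixture(root, n_inputs = 1)
  out1 <- file.path(root, "o1"); out2 <- file.path(root, "o2")
  run_cohort(fx$cohort, small_grid(), root, out1, poolsize = 1, seed = 4,
             tr = 0.72)
  run_cohort(fx$cohort, small_grid(), root, out2, poolsize = 2, seed = 4,
             tr = 0.72)
  f1 <- sort(list.files(out1, "stats.csv", recursive = TRUE))
  expect_identical(f1, sort(list.files(out2, "stats.csv", recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  # a missing input is recorded as failed; other results still present
  cohort <- utils::read.csv(fx$cohort)
  cohort <- rbind(cohort, data.frame(id = "ghost", path = "missing.tsv"))
  out3 <- file.path(root, "o3")
  man <- suppressWarnings(
    run_cohort(cohort, small_grid(), root, out3, seed = 4, tr = 0.72))
  status <- vapply(man$tasks, `[[`, "", "status")
  ids <- vapply(man$tasks, `[[`, "", "id")
  expect_true(all(status[ids == "ghost"] == "failed"))
  expect_true(all(status[ids != "ghost"] == "ok"))
})
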