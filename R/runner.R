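#' Single-configuration Mapper run
#'
#' Executes the five-stage pipeline on one matrix under one flat
#' configuration: distance (optionally geodesic on the penalized reciprocal
#' k-NN graph), lens, binning, partial clustering, graph creation; then
#' validation and, when the data carries labels / expected transition
#' times, the goodness-of-fit measures.
#'
#' The configuration is a nested list in the grid-config dialect (see
#' [read_grid_config()]) with all scalar values, e.g.
#' \code{list(dist = list(type = "geodesic_euclidean", k = 12),
#' embed = list(type = "CMDS", dims = 2),
#' bin = list(type = "extrinsic", resolution = 20, gain = 70),
#' cluster = list(type = "linkage", bins = 10))}.
#'
#' @param data a \code{mapper_data}.
#' @param config flat configuration list.
#' @param expected optional expected transition times (seconds) for the
#'   delay GOF; defaults to the \code{boundaries} attribute of \code{data}
#'   when present.
#' @param seed integer seed forwarded to stochastic lens backends.
#' @return a \code{mapper_result}: list with \code{graph}, \code{lens},
#'   \code{cover}, \code{validation}, \code{stats} (one-row data frame),
#'   \code{config}.
#' @export
mapper_run <- function(data, config, expected = NULL, seed = NULL) {
  stopifnot(inherits(data, "mapper_data"))
  config <- validate_config(config, scalar = TRUE)
  if ("zscore" %in% (config$preprocess %||% character(0)))
    data <- zscore_features(data)

  # --- distances ---
  dtype <- config$dist$type
  geo <- grepl("^geodesic_", dtype)
  base_metric <- sub("^geodesic_", "", dtype)
  base <- pairwise_distance(data, base_metric)
  knn <- NULL
  dist_for_lens <- base
  if (geo) {
    knn <- build_prknng(base, config$dist$k)
    dist_for_lens <- geodesic_distances(knn)
  }

  # --- lens + binning ---
  if (identical(config$bin$type, "intrinsic")) {
    if (is.null(knn))
      stop("intrinsic binning requires a geodesic distance type (the k-NN lens)")
    lens <- intrinsic_lens(knn)
    cover <- intrinsic_bins(lens, config$bin$resolution, config$bin$gain)
  } else {
    alg <- config$embed$type %||% "CMDS"
    d <- config$embed$dims %||% 2
    lens <- if (identical(alg, "CMDS")) embed_cmds(dist_for_lens, d = d)
      else {
        entry_input <- lens_registry()
        input <- entry_input$input[entry_input$algorithm == alg]
        if (length(input) == 0L)
          stop("unknown embedding algorithm '", alg, "' in config")
        embed_delegate(if (input == "data") data else dist_for_lens,
                       alg, d = d, params = config$embed$params %||% list(),
                       seed = seed)
      }
    cover <- extrinsic_bins(lens, config$bin$resolution, config$bin$gain)
  }

  # --- partial clustering on ORIGINAL-space distances ---
  clusters <- cluster_bins(cover, base,
                           method = config$cluster$type,
                           hist_bins = config$cluster$bins %||% 10,
                           eps = config$cluster$eps,
                           min_pts = config$cluster$min_pts %||% 3)
  graph <- build_shape_graph(clusters, n_points = nrow(data))

  # --- evaluation ---
  tau <- config$analyses_tau %||% 11
  report <- if (length(graph$members))
    validate_shape_graph(graph, tr = tr_seconds(data), tau = tau) else NULL
  labels <- state_labels(data)
  circ <- if (!is.null(labels) && all(labels %in% .circle_states) &&
              length(graph$members))
    circleness(graph, labels) else NA
  if (is.null(expected)) expected <- attr(data, "boundaries")
  gof <- if (!is.null(expected) && length(graph$members))
    transition_gof(graph, tr_seconds(data), expected) else NULL

  stats <- data.frame(
    distance = dtype, k = if (geo) config$dist$k else NA_integer_,
    embed = if (identical(config$bin$type, "intrinsic")) "knn-graph"
            else (config$embed$type %||% "CMDS"),
    bin_kind = config$bin$type %||% "extrinsic",
    resolution = config$bin$resolution, gain = config$bin$gain,
    clusterer = config$cluster$type,
    n_nodes = length(graph$members), n_edges = nrow(graph$edges),
    alpha = report$alpha %||% NA_real_, beta = report$beta %||% NA_real_,
    entropy = report$entropy %||% NA_real_,
    valid = isTRUE(report$valid), circleness = circ,
    n_transitions = if (is.null(gof)) NA_integer_ else length(gof$transitions),
    average_delay = if (is.null(gof)) NA_real_ else gof$average_delay,
    pass_12s = if (is.null(gof)) NA else is.finite(gof$average_delay) && gof$average_delay <= 12,
    pass_20s = if (is.null(gof)) NA else is.finite(gof$average_delay) && gof$average_delay <= 20)

  structure(list(graph = graph, lens = lens, cover = cover,
                 validation = report, gof = gof, stats = stats,
                 config = config),
            class = "mapper_result")
}

#' @export
print.mapper_result <- function(x, ...) {
  cat("<mapper_result>\n")
  print(x$graph)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_schema <- list(
  dist = c("type", "k"),
  embed = c("type", "dims", "params"),
  bin = c("type", "resolution", "gain", "sides"),
  cluster = c("type", "bins", "eps", "min_pts"),
  analyses = NULL, preprocess = NULL, analyses_tau = NULL)

validate_config <- function(config, scalar = FALSE) {
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), c("dist", "embed", "bin", "cluster"))) {
    bad <- setdiff(names(config[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("unknown config field(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(config$dist$type)) stop("config requires dist$type")
  if (is.null(config$bin)) stop("config requires a bin section")
  sides <- config$bin$sides
  if (!is.null(sides) && any(sides != 4))
    stop("only 4-sided (rectangular) bins are supported; got sides = ",
         paste(unique(sides), collapse = ", "))
  if (is.null(config$cluster$type)) config$cluster$type <- "linkage"
  if (is.null(config$bin$type)) config$bin$type <- "extrinsic"
  if (scalar) {
    len_ok <- function(x) is.null(x) || !is.atomic(x) || length(x) <= 1L
    flat <- c(config$dist, config$bin, config$cluster, config$embed["dims"])
    if (!all(vapply(flat, len_ok, logical(1))))
      stop("configuration still contains list-valued fields; expand it first")
  }
  config
}

#' Read a grid configuration (JSON dialect)
#'
#' Parses the JSON parameter-grid dialect: sections \code{dist}
#' \{type, k\}, \code{embed} \{type, dims\}, \code{bin} \{type, resolution,
#' gain, sides\}, \code{cluster} \{type, bins | eps\}, plus optional
#' \code{preprocess} (e.g. "zscore") and \code{analyses}. Any field holding
#' an array of values is swept over by [expand_grid_config()]. Unknown
#' fields are rejected by name.
#'
#' @param path JSON file path (or a list already in the dialect).
#' @return a validated \code{grid_config} list.
#' @export
read_grid_config <- function(path) {
  config <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  config <- validate_config(config)
  structure(config, class = "grid_config")
}

#' Expand a grid configuration into single configurations
#'
#' Cartesian product over all list-valued fields (e.g. two k values, two
#' resolutions and four gains give 16 configurations), in deterministic
#' lexicographic order of (field, value index).
#'
#' @param config a \code{grid_config} (or plain list in the dialect).
#' @return list of flat configuration lists, each runnable by [mapper_run()].
#' @export
expand_grid_config <- function(config) {
  config <- validate_config(config)
  # sweepable (section, field) slots, in fixed order
  slots <- list(c("dist", "type"), c("dist", "k"),
                c("embed", "type"), c("embed", "dims"),
                c("bin", "type"), c("bin", "resolution"), c("bin", "gain"),
                c("cluster", "type"), c("cluster", "bins"), c("cluster", "eps"))
  values <- lapply(slots, function(s) {
    v <- config[[s[1]]][[s[2]]]
    if (is.null(v)) list(NULL) else as.list(v)
  })
  counts <- lengths(values)
  grid <- expand.grid(lapply(rev(counts), seq_len))  # last slot varies fastest
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    cfg <- config
    for (si in seq_along(slots)) {
      s <- slots[[si]]
      cfg[[s[1]]][[s[2]]] <- values[[si]][[grid[r, si]]]
    }
    class(cfg) <- NULL
    cfg
  })
}

#' Stable hash of a single configuration
#'
#' Canonicalizes the configuration (recursively name-sorted, unboxed JSON)
#' and returns the first 12 hex digits of its MD5, used as the per-config
#' output directory name.
#'
#' @param config flat configuration list.
#' @return 12-character string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  js <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  substr(unname(tools::md5sum(tf)), 1L, 12L)
}

#' Batch execution over a cohort
#'
#' Runs every expanded configuration on every cohort input. The cohort CSV
#' has columns \code{id} and \code{path} (paths resolved under
#' \code{data_root}); extra columns are carried into the manifest. Each
#' (input, config) pair writes
#' \code{out_dir/<id>/<config_hash>/\{graph.json, graph.graphml,
#' membership.csv, stats.csv\}}. Per-task seeds are derived from the master
#' seed and the task's (id, hash) so results are independent of
#' \code{poolsize}; reruns are idempotent. Unreadable inputs are recorded
#' as failures in the manifest and the run continues.
#'
#' @param cohort_csv path to the cohort CSV (or a data frame).
#' @param config a \code{grid_config} (or path to its JSON).
#' @param data_root directory against which cohort paths resolve.
#' @param out_dir output directory (created).
#' @param poolsize number of worker processes (default 1).
#' @param seed master seed.
#' @param tr sampling interval passed to [read_data_matrix()].
#' @return the run manifest (invisibly written as \code{manifest.json}).
#' @export
run_cohort <- function(cohort_csv, config, data_root = ".", out_dir,
                       poolsize = 1, seed = 1, tr = 1) {
  cohort <- if (is.character(cohort_csv))
    utils::read.csv(cohort_csv, stringsAsFactors = FALSE) else cohort_csv
  if (!all(c("id", "path") %in% names(cohort)))
    stop("cohort table must have 'id' and 'path' columns")
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique")
  if (is.character(config)) config <- read_grid_config(config)
  configs <- expand_grid_config(config)  # aborts before execution if invalid
  hashes <- vapply(configs, config_hash, "")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tasks <- expand.grid(input = seq_len(nrow(cohort)),
                       config = seq_along(configs))
  run_one <- function(ti) {
    ci <- tasks$input[ti]; ki <- tasks$config[ti]
    id <- cohort$id[ci]; hash <- hashes[ki]
    dest <- file.path(out_dir, id, hash)
    task_seed <- (seed + ti * 10007L) %% .Machine$integer.max
    res <- tryCatch({
      data <- read_data_matrix(file.path(data_root, cohort$path[ci]), tr = tr)
      r <- mapper_run(data, configs[[ki]], seed = task_seed)
      dir.create(dest, recursive = TRUE, showWarnings = FALSE)
      write_shape_graph(r$graph, file.path(dest, "graph.graphml"),
                        file.path(dest, "graph.json"))
      membership_table(r$graph, file.path(dest, "membership.csv"))
      utils::write.csv(cbind(id = id, config = hash, r$stats),
                       file.path(dest, "stats.csv"), row.names = FALSE)
      list(id = id, config = hash, status = "ok", seed = task_seed)
    }, error = function(e)
      list(id = id, config = hash, status = "failed",
           message = conditionMessage(e), seed = task_seed))
    res
  }
  results <- if (poolsize > 1L)
    parallel::mclapply(seq_len(nrow(tasks)), run_one, mc.cores = poolsize)
  else lapply(seq_len(nrow(tasks)), run_one)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tsmapper")),
    master_seed = seed,
    configs = stats::setNames(configs, hashes),
    tasks = results)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Aggregate per-graph statistics over a run directory
#'
#' Collects every \code{stats.csv} under \code{out_dir} into one long-format
#' table (input, configuration parameters, validation metrics, GOF), from
#' which resolution-by-gain pass-count matrices can be tabulated.
#'
#' @param out_dir a completed [run_cohort()] output directory.
#' @return a data frame; zero rows (with a warning) for an empty directory.
#' @export
aggregate_stats <- function(out_dir) {
  files <- list.files(out_dir, pattern = "^stats\\.csv$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    warning("no stats.csv files under ", out_dir)
    return(data.frame())
  }
  do.call(rbind, lapply(files, utils::read.csv, stringsAsFactors = FALSE))
}

#' Pass-count matrix over a resolution-by-gain sweep
#'
#' @param stats an [aggregate_stats()] table (or any data frame with
#'   \code{resolution}, \code{gain} and a logical \code{pass} column name).
#' @param pass_col which column defines a pass (default \code{"valid"}).
#' @return an integer matrix, rows = resolutions, columns = gains.
#' @export
pass_count_matrix <- function(stats, pass_col = "valid") {
  stopifnot(all(c("resolution", "gain", pass_col) %in% names(stats)))
  tab <- tapply(as.logical(stats[[pass_col]]),
                list(stats$resolution, stats$gain), sum, default = 0L)
  tab
}
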