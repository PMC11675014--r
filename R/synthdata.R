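#' Coupling-parameter schedule and state labels
#'
#' Builds the piecewise schedule of the global coupling parameter G that
#' drives the simulated paradigm: per cycle, a stable-low plateau
#' (\code{stable_s} seconds at \code{g_low}), a linear ramp up
#' (\code{trans_s} seconds), a stable-high plateau, and a linear ramp down,
#' repeated \code{cycles} times. Samples are taken at t = 0, tr, 2 tr, ...
#' strictly below the total duration. With the defaults (100 s plateaus,
#' 200 s ramps, 2 cycles, TR 0.72 s) the schedule spans 1,200 s and yields
#' 1,667 samples in 8 labeled segments, two of each of the four state types.
#'
#' @param g_low,g_high coupling extremes (defaults 1.1 and 5.0).
#' @param stable_s plateau duration, seconds (default 100).
#' @param trans_s ramp duration, seconds (default 200).
#' @param cycles number of repetitions (default 2).
#' @param tr sampling interval, seconds (default 0.72).
#' @return a \code{g_schedule}: list with \code{G} (per-sample values),
#'   \code{labels} (per-sample state), \code{times}, \code{tr},
#'   \code{total_s}, and \code{boundaries} (segment start times after the
#'   first, i.e. the expected transition times in seconds).
#' @export
#' @examples
#' sch <- g_schedule()
#' sch$total_s           # 1200
#' length(sch$G)         # 1667
g_schedule <- function(g_low = 1.1, g_high = 5.0, stable_s = 100,
                       trans_s = 200, cycles = 2, tr = 0.72) {
  if (tr <= 0) stop("'tr' must be positive")
  stopifnot(stable_s > 0, trans_s > 0, cycles >= 1)
  seg_types <- rep(c("stable-low", "transition-up", "stable-high", "transition-down"),
                   cycles)
  seg_dur <- rep(c(stable_s, trans_s, stable_s, trans_s), cycles)
  seg_end <- cumsum(seg_dur)
  seg_start <- c(0, seg_end[-length(seg_end)])
  total <- seg_end[length(seg_end)]

  times <- seq(0, total - 1e-9, by = tr)
  seg_of <- findInterval(times, seg_start)
  labels <- seg_types[seg_of]
  G <- numeric(length(times))
  for (s in seq_along(seg_types)) {
    in_s <- seg_of == s
    u <- (times[in_s] - seg_start[s]) / seg_dur[s]
    G[in_s] <- switch(seg_types[s],
      "stable-low" = rep(g_low, sum(in_s)),
      "stable-high" = rep(g_high, sum(in_s)),
      "transition-up" = g_low + u * (g_high - g_low),
      "transition-down" = g_high - u * (g_high - g_low))
  }
  structure(list(G = G, labels = labels, times = times, tr = tr,
                 total_s = total, boundaries = seg_start[-1L],
                 segment_types = seg_types),
            class = "g_schedule")
}

#' Block-paradigm labels (task blocks with instruction periods)
#'
#' Label builder for a multitask block design: \code{n_blocks} task blocks
#' of \code{block_s} seconds each, separated by \code{instr_s}-second
#' instruction periods between consecutive blocks. With the defaults
#' (8 blocks of 180 s, 12 s instructions) the paradigm totals 1,524 s,
#' i.e. 25 min 24 s.
#'
#' @param n_blocks number of task blocks (default 8).
#' @param block_s task block duration, seconds (default 180).
#' @param instr_s instruction duration between consecutive blocks (default 12).
#' @param tasks optional character vector of task names recycled over blocks.
#' @param tr sampling interval, seconds (default 1.5).
#' @return list with \code{labels} (per-sample task or "instructions"),
#'   \code{times}, \code{total_s}, and \code{boundaries} (instruction
#'   midpoint times, the expected transition times in seconds).
#' @export
paradigm_schedule <- function(n_blocks = 8, block_s = 180, instr_s = 12,
                              tasks = c("Rest", "Memory", "Video", "Math"),
                              tr = 1.5) {
  stopifnot(n_blocks >= 1, block_s > 0, instr_s >= 0, tr > 0)
  seg_names <- character(0); seg_dur <- numeric(0)
  task_seq <- rep_len(tasks, n_blocks)
  for (b in seq_len(n_blocks)) {
    if (b > 1L) { seg_names <- c(seg_names, "instructions"); seg_dur <- c(seg_dur, instr_s) }
    seg_names <- c(seg_names, task_seq[b]); seg_dur <- c(seg_dur, block_s)
  }
  seg_end <- cumsum(seg_dur)
  seg_start <- c(0, seg_end[-length(seg_end)])
  total <- seg_end[length(seg_end)]
  times <- seq(0, total - 1e-9, by = tr)
  labels <- seg_names[findInterval(times, seg_start)]
  instr <- which(seg_names == "instructions")
  list(labels = labels, times = times, total_s = total, tr = tr,
       boundaries = seg_start[instr] + instr_s / 2)
}

#' Seeded random modular connectome
#'
#' Symmetric nonnegative coupling matrix with zero diagonal and block-modular
#' structure: dense strong weights within modules, sparse weak ones between.
#' A stand-in for empirical structural connectivity used by the simulator.
#'
#' @param n_nodes number of regions (default 66).
#' @param n_modules number of modules (default 4).
#' @param p_between probability of a between-module connection (default 0.1).
#' @param seed integer seed.
#' @return \code{n_nodes x n_nodes} matrix, rows normalized to unit sum.
#' @export
modular_connectome <- function(n_nodes = 66, n_modules = 4, p_between = 0.1,
                               seed = 1) {
  set.seed(seed)
  mod <- rep_len(seq_len(n_modules), n_nodes)
  C <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    w <- if (mod[i] == mod[j]) stats::runif(1, 0.5, 1)
         else if (stats::runif(1) < p_between) stats::runif(1, 0, 0.2)
         else 0
    C[i, j] <- C[j, i] <- w
  }
  rs <- rowSums(C); rs[rs == 0] <- 1
  C / rs
}

#' Simulator configuration
#'
#' Parameter record for the two-population network simulator. Each region
#' holds an excitatory (E) and an inhibitory (I) population coupled by four
#' local weights (\code{w_ee}: E self-excitation, \code{w_ei}: E driving I,
#' \code{w_ie}: I inhibiting E, \code{w_ii}: I self-inhibition); long-range
#' coupling enters each E population as \code{G(t) * sum_j C[i, j] * E_j}.
#' Defaults are the package's own choices of a well-behaved operating point;
#' the hemodynamic stage defaults to convolution with a canonical
#' double-gamma response (a balloon-type transform can be plugged in via
#' \code{hemodynamics}).
#'
#' @param n_nodes number of regions (default 66).
#' @param C coupling matrix; defaults to [modular_connectome()].
#' @param w_ee,w_ei,w_ie,w_ii local weights.
#' @param tau_e,tau_i population time constants, seconds.
#' @param slope,threshold sigmoid transfer-function parameters.
#' @param i_e,i_i constant background drives.
#' @param dt integration step, seconds.
#' @param noise_sd diffusion coefficient of the additive state noise.
#' @param seed integer seed for the noise stream.
#' @param hemodynamics \code{"hrf"} (double-gamma convolution) or a function
#'   \code{(E_matrix, dt) -> matrix} implementing another transform.
#' @return a \code{wc_config} list.
#' @export
wc_config <- function(n_nodes = 66, C = NULL,
                      w_ee = 2.8, w_ei = 2.0, w_ie = 2.5, w_ii = 0.5,
                      tau_e = 0.5, tau_i = 1.0,
                      slope = 4, threshold = 1.0,
                      i_e = 0.3, i_i = 0.1,
                      dt = 0.05, noise_sd = 0.01, seed = 1,
                      hemodynamics = "hrf") {
  if (is.null(C)) C <- modular_connectome(n_nodes, seed = seed)
  stopifnot(nrow(C) == n_nodes, ncol(C) == n_nodes, all(C >= 0),
            all(diag(C) == 0), tau_e > 0, tau_i > 0, dt > 0)
  structure(list(n_nodes = n_nodes, C = C, w_ee = w_ee, w_ei = w_ei,
                 w_ie = w_ie, w_ii = w_ii, tau_e = tau_e, tau_i = tau_i,
                 slope = slope, threshold = threshold, i_e = i_e, i_i = i_i,
                 dt = dt, noise_sd = noise_sd, seed = seed,
                 hemodynamics = hemodynamics),
            class = "wc_config")
}

# canonical double-gamma hemodynamic response, sampled at dt
double_gamma_hrf <- function(dt, duration = 32) {
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Two-population network simulation of the coupled paradigm
#'
#' Integrates, per region, excitatory/inhibitory rate dynamics
#' \deqn{\tau_E dE/dt = -E + f(w_{EE} E - w_{IE} I + G(t) \sum_j C_{ij} E_j + I_E)}
#' \deqn{\tau_I dI/dt = -I + f(w_{EI} E - w_{II} I + I_I)}
#' with a logistic transfer function f, Euler-Maruyama integration with
#' seeded additive noise on E, and the schedule's G(t) as the time-varying
#' global coupling. The excitatory activity is passed through the
#' hemodynamic transform and sampled at the schedule's TR; rows carry the
#' schedule's state labels.
#'
#' @param cfg a [wc_config()].
#' @param schedule a [g_schedule()].
#' @return a \code{mapper_data} matrix, (schedule length) x n_nodes.
#' @export
simulate_wc_bold <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "wc_config"), inherits(schedule, "g_schedule"))
  dt <- cfg$dt
  n <- cfg$n_nodes
  total <- schedule$total_s
  nsteps <- ceiling(total / dt)
  step_t <- (seq_len(nsteps) - 1L) * dt
  # G at integration resolution: piecewise linear through the sampled schedule
  Gt <- stats::approx(schedule$times, schedule$G, xout = step_t, rule = 2)$y

  f <- function(x) 1 / (1 + exp(-cfg$slope * (x - cfg$threshold)))
  set.seed(cfg$seed)
  E <- rep(0.1, n); I <- rep(0.1, n)
  Em <- matrix(NA_real_, nsteps, n)
  sqdt <- sqrt(dt)
  for (s in seq_len(nsteps)) {
    net <- Gt[s] * as.numeric(cfg$C %*% E)
    dE <- (-E + f(cfg$w_ee * E - cfg$w_ie * I + net + cfg$i_e)) / cfg$tau_e
    dI <- (-I + f(cfg$w_ei * E - cfg$w_ii * I + cfg$i_i)) / cfg$tau_i
    E <- E + dt * dE + if (cfg$noise_sd > 0) cfg$noise_sd * sqdt * stats::rnorm(n) else 0
    I <- I + dt * dI
    E <- pmin(pmax(E, 0), 1); I <- pmin(pmax(I, 0), 1)
    if (!all(is.finite(E)) || !all(is.finite(I)))
      stop("non-finite state at integration step ", s)
    Em[s, ] <- E
  }
  bold <- if (is.function(cfg$hemodynamics)) {
    cfg$hemodynamics(Em, dt)
  } else {
    h <- double_gamma_hrf(dt)
    apply(Em, 2L, function(x)
      stats::convolve(x, rev(h), type = "open")[seq_along(x)])
  }
  sample_idx <- pmin(floor(schedule$times / dt) + 1L, nsteps)
  data_matrix(bold[sample_idx, , drop = FALSE], tr = schedule$tr,
              labels = schedule$labels)
}

#' Phenomenological circular-trajectory generator
#'
#' Generates a multi-feature time series with the same label structure as
#' the simulated paradigm and a known circular topology: the two stable
#' states sit at two fixed feature-space patterns, and the up and down
#' transitions interpolate between them along two DISTINCT arcs, offset in
#' opposite directions along a third orthogonal pattern by
#' \code{arc_separation / 2} each, so the noiseless trajectory is a closed
#' loop (not a back-and-forth line). Seeded Gaussian noise is added on top.
#'
#' @param n_features number of features (>= 3, default 12).
#' @param schedule a [g_schedule()] supplying labels and timing.
#' Transitions between the attractors are time-warped with a sigmoidal
#' profile (\code{jump_steepness}): the trajectory lingers near the
#' attractor it is leaving, crosses the middle of the arc quickly, and
#' settles into the destination — the characteristic jump of a driven
#' bistable system. \code{jump_steepness = 0} gives constant-speed
#' interpolation.
#'
#' @param arc_separation distance between the up-arc and down-arc midpoints
#'   (default 1).
#' @param noise_sd standard deviation of the added i.i.d. noise (default 0.1).
#' @param jump_steepness sigmoidal warp of transition timing (default 8).
#' @param seed integer seed.
#' @return a labeled \code{mapper_data}, (schedule length) x n_features.
#' @export
synth_circular_bold <- function(n_features = 12, schedule = g_schedule(),
                                arc_separation = 1, noise_sd = 0.1,
                                jump_steepness = 8, seed = 1) {
  stopifnot(n_features >= 3, arc_separation > 0, jump_steepness >= 0)
  warp <- if (jump_steepness == 0) identity else function(u)
    (tanh(jump_steepness * (u - 0.5)) / tanh(jump_steepness / 2) + 1) / 2
  n <- length(schedule$times)
  # three orthonormal patterns: low->high axis, and the arc-offset direction
  basis <- qr.Q(qr(cbind(rep(1, n_features),
                         rep(c(1, -1), length.out = n_features),
                         rep(c(1, 1, -1), length.out = n_features))))
  a_low <- -basis[, 1]; a_high <- basis[, 1]  # separation 2 along axis 1
  v_arc <- basis[, 3]

  seg_types <- schedule$segment_types
  seg_start <- c(0, schedule$boundaries)
  seg_end <- c(schedule$boundaries, schedule$total_s)
  seg_of <- findInterval(schedule$times, seg_start)
  X <- matrix(NA_real_, n, n_features)
  for (s in seq_along(seg_types)) {
    in_s <- which(seg_of == s)
    u <- (schedule$times[in_s] - seg_start[s]) / (seg_end[s] - seg_start[s])
    if (seg_types[s] %in% c("transition-up", "transition-down")) u <- warp(u)
    P <- switch(seg_types[s],
      "stable-low" = matrix(a_low, length(in_s), n_features, byrow = TRUE),
      "stable-high" = matrix(a_high, length(in_s), n_features, byrow = TRUE),
      "transition-up" = outer(1 - u, a_low) + outer(u, a_high) +
        outer(sin(pi * u) * arc_separation / 2, v_arc),
      "transition-down" = outer(1 - u, a_high) + outer(u, a_low) -
        outer(sin(pi * u) * arc_separation / 2, v_arc))
    X[in_s, ] <- P
  }
  if (noise_sd > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  }
  data_matrix(X, tr = schedule$tr, labels = schedule$labels)
}

#' Trefoil-knot point cloud
#'
#' The standard (2,3)-torus-knot parameterization
#' \code{(sin t + 2 sin 2t, cos t - 2 cos 2t, -sin 3t)} sampled at \code{n}
#' evenly spaced values of t in [0, 2 pi), plus optional seeded Gaussian
#' noise. Its true shape is a closed loop, which a correct Mapper
#' configuration should recover as a graph with cycle rank >= 1.
#'
#' @param n number of samples (>= 10, default 500).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed.
#' @return a \code{mapper_data} with 3 features and the angle parameter per
#'   row in attribute \code{angle}.
#' @export
trefoil_knot <- function(n = 500, noise_sd = 0, seed = 1) {
  stopifnot(n >= 10)
  t <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  X <- cbind(sin(t) + 2 * sin(2 * t),
             cos(t) - 2 * cos(2 * t),
             -sin(3 * t))
  if (noise_sd > 0) {
    set.seed(seed)
    X <- X + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  }
  out <- data_matrix(X, tr = 1, feature_names = c("x", "y", "z"))
  attr(out, "angle") <- t
  out
}

#' Inject noise at a target signal-to-noise ratio
#'
#' Per feature, a noise vector (equal-variance mix of the requested
#' components: linear+quadratic drift, seeded AR(1), and white noise) is
#' scaled so its standard deviation equals (signal standard deviation) /
#' \code{target_snr}, then added. "Amplitude" is read as the per-feature
#' standard deviation, so at SNR 0.5 the injected noise has twice the
#' signal's standard deviation. Zero-variance features are skipped with a
#' warning; \code{target_snr = Inf} returns the data unchanged.
#'
#' @param data a \code{mapper_data}.
#' @param target_snr positive SNR (may be \code{Inf}).
#' @param seed integer seed.
#' @param components subset of \code{c("drift", "ar", "white")}.
#' @param ar_phi AR(1) coefficient for the autoregressive component.
#' @return a \code{mapper_data} of the same shape.
#' @export
add_noise <- function(data, target_snr, seed = 1,
                      components = c("drift", "ar", "white"), ar_phi = 0.5) {
  stopifnot(inherits(data, "mapper_data"), target_snr > 0)
  components <- match.arg(components, several.ok = TRUE)
  if (is.infinite(target_snr)) return(data)
  v <- unclass(data)
  n <- nrow(v)
  set.seed(seed)
  tt <- seq_len(n) / n
  for (j in seq_len(ncol(v))) {
    sd_sig <- stats::sd(v[, j])
    if (sd_sig == 0) {
      warning("feature ", j, " has zero variance; noise injection skipped")
      next
    }
    parts <- list()
    if ("drift" %in% components) {
      dr <- stats::runif(1, -1, 1) * tt + stats::runif(1, -1, 1) * tt^2
      parts <- c(parts, list(dr))
    }
    if ("ar" %in% components)
      parts <- c(parts, list(as.numeric(stats::filter(stats::rnorm(n), ar_phi,
                                                      method = "recursive"))))
    if ("white" %in% components)
      parts <- c(parts, list(stats::rnorm(n)))
    # equal-variance mix, then scale the mix to sd_sig / target_snr
    parts <- lapply(parts, function(p) {
      s <- stats::sd(p); if (s == 0) p else p / s
    })
    noise <- Reduce(`+`, parts)
    noise <- noise / stats::sd(noise) * sd_sig / target_snr
    v[, j] <- v[, j] + noise
  }
  data_matrix(v, tr = tr_seconds(data), labels = state_labels(data))
}

#' Boxcar smoothing followed by downsampling
#'
#' Applies a same-length moving average of \code{width} samples (windows
#' truncated at the edges), then keeps every \code{factor}-th row starting
#' from the first. The sampling interval is multiplied by \code{factor};
#' smoothing first preserves the temporal structure that plain decimation
#' destroys.
#'
#' @param data a \code{mapper_data}.
#' @param factor keep every \code{factor}-th sample (>= 1).
#' @param width boxcar width in samples (default 4).
#' @return a \code{mapper_data} with \code{ceiling(N / factor)} rows.
#' @export
smooth_downsample <- function(data, factor, width = 4) {
  stopifnot(inherits(data, "mapper_data"), factor >= 1, width >= 1)
  v <- unclass(data)
  n <- nrow(v)
  if (factor >= n) stop("'factor' must be smaller than the number of rows")
  factor <- as.integer(factor); width <- as.integer(width)
  lo <- pmax(seq_len(n) - (width - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(n) + width %/% 2L, n)
  cs <- rbind(0, apply(v, 2L, cumsum))
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  keep <- seq(1L, n, by = factor)
  lab <- state_labels(data)
  data_matrix(sm[keep, , drop = FALSE], tr = tr_seconds(data) * factor,
              labels = if (is.null(lab)) NULL else lab[keep])
}

#' Block-shuffled null
#'
#' Cuts the rows into consecutive blocks of \code{block} frames (the last
#' block may be short) and permutes the block order with a seeded uniform
#' permutation, preserving within-block order. The permutation depends only
#' on (number of blocks, seed), so matrices of equal length shuffled with
#' the same seed receive the identical block permutation. This preserves
#' short-range autocorrelation but dismantles the global temporal structure,
#' giving the null against which transition extraction is benchmarked.
#'
#' @param data a \code{mapper_data}.
#' @param block block length in frames (default 7).
#' @param seed integer seed.
#' @return a \code{mapper_data} with the same rows in shuffled block order;
#'   the row permutation is in attribute \code{permutation}.
#' @export
shuffle_blocks <- function(data, block = 7, seed = 1) {
  stopifnot(inherits(data, "mapper_data"), block >= 1)
  n <- nrow(data)
  block <- as.integer(block)
  nb <- ceiling(n / block)
  set.seed(seed)
  perm <- sample(nb)
  blocks <- split(seq_len(n), (seq_len(n) - 1L) %/% block + 1L)
  order_rows <- unlist(blocks[perm], use.names = FALSE)
  lab <- state_labels(data)
  out <- data_matrix(unclass(data)[order_rows, , drop = FALSE],
                     tr = tr_seconds(data),
                     labels = if (is.null(lab)) NULL else lab[order_rows])
  attr(out, "permutation") <- order_rows
  out
}
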