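# Population simulation engine for the Reichardt model.
#
# An engine precomputes everything that does not change between trials of an
# experiment: detector placement, the (filters x space) weight matrix, class
# gains, and per-detector thresholds. Per-trial work then reduces to one
# matrix product with the stimulus frames plus the temporal recursions.

# Build the simulation engine for a config on its own retina grid.
rd_engine <- function(cfg) {
  stopifnot(inherits(cfg, "rd_config"))
  n_space <- round(cfg$retina_extent_deg / cfg$dx_deg)
  x_deg <- (seq_len(n_space) - 0.5) * cfg$dx_deg
  classes <- lapply(cfg$classes, function(cl) {
    if (is.null(cl$gain)) {
      cl <- rd_normalize_gain(cl, cfg$temporal, cfg$dx_deg, cfg$sim_dt_s,
                              amplitude_cdm2 = cfg$norm_amplitude_cdm2)
    }
    cl
  })
  rng <- local_rng(cfg$placement_seed)
  pos <- list()
  class_id <- integer(0)
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    margin <- 3 * cl$sigma_deg + cl$separation_deg / 2 + cfg$dx_deg
    if (2 * margin >= cfg$retina_extent_deg) {
      stop("placement error: retina too small for the class filters")
    }
    p <- rng$runif(cl$count, margin, cfg$retina_extent_deg - margin)
    pos[[i]] <- p
    class_id <- c(class_id, rep(i, cl$count))
  }
  positions <- unlist(pos)
  n_det <- length(positions)
  W <- matrix(0, 2 * n_det, n_space)
  for (d in seq_len(n_det)) {
    cl <- classes[[class_id[d]]]
    half <- cl$separation_deg / 2
    W[2 * d - 1, ] <- subunit_weights(x_deg, positions[d] - half,
                                      cl$sigma_deg, cfg$dx_deg)
    W[2 * d, ] <- subunit_weights(x_deg, positions[d] + half,
                                  cl$sigma_deg, cfg$dx_deg)
  }
  n_time <- round(cfg$trial_duration_s / cfg$sim_dt_s)
  t_sim <- (seq_len(n_time) - 1L) * cfg$sim_dt_s
  frame_of_t <- floor(t_sim * cfg$frame_rate_hz + 1e-9) + 1L
  list(
    cfg = cfg, classes = classes, positions = positions, class_id = class_id,
    n_detectors = n_det, n_space = n_space, x_deg = x_deg, W = W,
    w_sums = rowSums(W),
    left_idx = seq(1L, 2L * n_det, by = 2L),
    right_idx = seq(2L, 2L * n_det, by = 2L),
    gains = vapply(classes, function(cl) cl$gain, numeric(1))[class_id],
    thresholds = vapply(classes, function(cl) cl$vote_threshold,
                        numeric(1))[class_id],
    n_time = n_time, frame_of_t = frame_of_t,
    window_samples = max(1L, round(cfg$integrator_window_s / cfg$sim_dt_s))
  )
}

# Detector response matrix (time x detectors) from luminance frames
# (space x frames) already on the engine grid. mean_lum is subtracted from
# the subunit signals under contrast input coding.
rd_detector_responses <- function(engine, lum_frames, mean_lum = NULL) {
  cfg <- engine$cfg
  S <- engine$W %*% lum_frames                 # 2 n_det x n_frames
  if (cfg$input_coding == "contrast") {
    S <- S - engine$w_sums * (mean_lum %||% mean(lum_frames))
  }
  X <- t(S[, engine$frame_of_t, drop = FALSE]) # time x 2 n_det
  R <- rd_correlate(X[, engine$left_idx, drop = FALSE],
                    X[, engine$right_idx, drop = FALSE],
                    cfg$temporal, cfg$sim_dt_s)
  R * rep(engine$gains, each = nrow(R))
}

# votes (time x detectors) -> optomotor signal r(t) given a noise stream
rd_optomotor_signal <- function(engine, votes, rng) {
  cfg <- engine$cfg
  vote_sum <- rowSums(votes)
  noise <- rng$rnorm(length(vote_sum), sd = cfg$noise$xi * engine$n_detectors)
  z <- vote_sum + noise
  switch(cfg$nonlinearity,
         sign = sign(z),
         satlin = pmax(-1, pmin(1, z / engine$n_detectors)))
}

#' Population response of the Reichardt model to a stimulus
#'
#' Places the configured detector classes on the stimulus extent (uniformly
#' at random under `cfg$placement_seed`, avoiding margins where filters would
#' clip), computes every detector's response, the ternary votes, and the
#' noisy optomotor signal r(t).
#'
#' @param stim A `spacetime_stimulus` whose extent matches
#'   `cfg$retina_extent_deg` and sampling matches `cfg$dx_deg` (e.g. from
#'   [generate_stimulus()] on the matching geometry, or built directly).
#' @param cfg An [rd_config()].
#' @param noise_seed Seed for the mantis noise stream.
#' @param engine Optional precomputed engine (from repeated calls).
#' @return List with `t_s`, `r` (optomotor signal in [-1, 1]), `votes`
#'   (time x detectors), `vote_sum`, and the `engine` used.
#' @export
rd_population_response <- function(stim, cfg = rd_config(), noise_seed = 1L,
                                   engine = NULL) {
  stopifnot(inherits(stim, "spacetime_stimulus"))
  if (is.null(engine)) {
    cfg$retina_extent_deg <- stim$extent_deg
    cfg$dx_deg <- stim$dx_deg
    engine <- rd_engine(cfg)
  }
  if (engine$n_space != nrow(stim$luminance)) {
    stop("stimulus grid does not match the engine retina grid")
  }
  # resample stimulus columns onto the simulation clock (sample-and-hold)
  n_frames_avail <- ncol(stim$luminance)
  t_sim <- (seq_len(engine$n_time) - 1L) * cfg$sim_dt_s
  col_of_t <- pmin(floor(t_sim / stim$dt_s + 1e-9) + 1L, n_frames_avail)
  used <- sort(unique(col_of_t))
  lum <- stim$luminance[, used, drop = FALSE]
  map <- match(col_of_t, used)
  S <- engine$W %*% lum
  if (cfg$input_coding == "contrast") {
    S <- S - engine$w_sums * stimulus_mean_luminance(stim)
  }
  X <- t(S[, map, drop = FALSE])
  R <- rd_correlate(X[, engine$left_idx, drop = FALSE],
                    X[, engine$right_idx, drop = FALSE],
                    cfg$temporal, cfg$sim_dt_s)
  R <- R * rep(engine$gains, each = nrow(R))
  votes <- detector_vote(R, engine$thresholds, cfg$integrator_window_s,
                         cfg$sim_dt_s)
  rng <- local_rng(noise_seed)
  r <- rd_optomotor_signal(engine, votes, rng)
  list(t_s = t_sim, r = r, votes = votes, vote_sum = rowSums(votes),
       engine = engine)
}

# Ternary observer decision from the optomotor signal.
rd_decide <- function(r, cfg, rng) {
  z <- mean(r) + rng$rnorm(1, sd = cfg$noise$eta)
  if (z > cfg$observer_deadzone) "right"
  else if (z < -cfg$observer_deadzone) "left"
  else "other"
}

#' Simulate a single behavioural trial of the Reichardt model
#'
#' Generates a fresh stepped chequerboard on the model retina, runs the
#' population, integrates r(t) over the trial, adds observer noise and
#' returns the ternary judgement.
#'
#' @param spec A [chequerboard_spec()] (its `duration_s` is overridden by
#'   `cfg$trial_duration_s`).
#' @param cfg An [rd_config()].
#' @param seed Trial seed controlling both the mantis and observer noise.
#' @param engine Optional precomputed engine.
#' @return `"left"`, `"right"` or `"other"`.
#' @export
rd_simulate_trial <- function(spec, cfg = rd_config(), seed = 1L,
                              engine = NULL) {
  if (is.null(engine)) engine <- rd_engine(cfg)
  lum_frames <- trial_frames(engine, spec)
  mean_lum <- (spec$luminance_dark_cdm2 + spec$luminance_light_cdm2) / 2
  R <- rd_detector_responses(engine, lum_frames, mean_lum)
  votes <- detector_vote(R, engine$thresholds, cfg$integrator_window_s,
                         cfg$sim_dt_s)
  rng <- local_rng(derive_seed(seed, 5L))
  r <- rd_optomotor_signal(engine, votes, rng)
  rd_decide(r, engine$cfg, rng)
}

# stimulus frames (space x distinct monitor frames) for one trial, plus the
# engine's frame_of_t already maps sim time -> frame columns
trial_frames <- function(engine, spec) {
  cfg <- engine$cfg
  base <- chequer_pattern(spec, engine$n_space, cfg$dx_deg)
  pos <- frame_positions(spec, cfg$frame_rate_hz, cfg$trial_duration_s)
  shift <- round(pos / cfg$dx_deg) %% engine$n_space
  idx0 <- seq_len(engine$n_space) - 1L
  vapply(shift, function(s) base[((idx0 - s) %% engine$n_space) + 1L],
         numeric(engine$n_space))
}

#' Simulate a behavioural experiment with the Reichardt model
#'
#' Runs `n_trials` simulated trials per (element size, step size) condition
#' with balanced left/right directions, a fresh random pattern per trial,
#' and per-trial noise substreams, mirroring the behavioural protocol.
#' Detector placement is fixed across the whole experiment
#' (`cfg$placement_seed`).
#'
#' @param elements_deg Element sizes (deg).
#' @param steps_deg Step sizes: a vector shared by all elements or a list of
#'   one vector per element size.
#' @param n_trials Trials per condition (split between directions).
#' @param cfg An [rd_config()].
#' @param seed Master seed for patterns and noise.
#' @param subject_id Label for the output records.
#' @param progress Print per-condition progress.
#' @return Trial-record data frame (see [read_trials()]).
#' @export
rd_simulate_experiment <- function(elements_deg, steps_deg, n_trials,
                                   cfg = rd_config(), seed = 1L,
                                   subject_id = "model2", progress = FALSE) {
  stopifnot(n_trials >= 1)
  if (!is.list(steps_deg)) steps_deg <- rep(list(steps_deg), length(elements_deg))
  stopifnot(length(steps_deg) == length(elements_deg))
  engine <- rd_engine(cfg)
  rows <- list()
  cond <- 0L
  for (i in seq_along(elements_deg)) {
    el <- elements_deg[i]
    for (st in steps_deg[[i]]) {
      cond <- cond + 1L
      if (progress) {
        message(sprintf("condition %d: element %.3g deg, step %.3g deg",
                        cond, el, st))
      }
      dirs <- rep_len(c(1L, -1L), n_trials)
      resp <- character(n_trials)
      for (k in seq_len(n_trials)) {
        sp <- chequerboard_spec(
          element_size_deg = el, step_size_deg = st,
          speed_deg_s = cfg$speed_deg_s, direction = dirs[k],
          duration_s = cfg$trial_duration_s,
          seed = derive_seed(seed, cond, k, 1L)
        )
        resp[k] <- rd_simulate_trial(sp, cfg, seed = derive_seed(seed, cond, k, 2L),
                                     engine = engine)
      }
      rows[[cond]] <- data.frame(
        subject_id = subject_id, element_size_deg = el, step_size_deg = st,
        direction = dirs, response = resp, stringsAsFactors = FALSE
      )
    }
  }
  mark_detected(do.call(rbind, rows))
}
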