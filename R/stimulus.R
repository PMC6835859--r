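#' Specification of a stepped random-chequerboard stimulus
#'
#' Describes one moving-chequerboard condition: a 1D random binary pattern of
#' square elements that is displaced horizontally by a fixed step \eqn{\Delta x}
#' every \eqn{\Delta t = \Delta x / v}, so the mean speed \eqn{v} is constant
#' across conditions. Luminance defaults are the black/white chequer levels of
#' the CRT display (0.161 and 54.1 cd/m^2).
#'
#' @param element_size_deg Width of one chequer element (deg, > 0).
#' @param step_size_deg Displacement per step \eqn{\Delta x} (deg, > 0).
#' @param speed_deg_s Constant apparent speed \eqn{v} (deg/s). The default
#'   44.4 deg/s is the screen-averaged optic flow of a 12.5 cm/s physical
#'   speed at 7 cm viewing distance.
#' @param direction +1 for rightward motion, -1 for leftward.
#' @param duration_s Presentation duration (s).
#' @param luminance_dark_cdm2,luminance_light_cdm2 Chequer luminances (cd/m^2).
#' @param seed Integer RNG seed for the random pattern; `NULL` draws one from
#'   the session RNG.
#' @return An object of class `chequerboard_spec`.
#' @export
chequerboard_spec <- function(element_size_deg, step_size_deg,
                              speed_deg_s = 44.4, direction = 1L,
                              duration_s = 1,
                              luminance_dark_cdm2 = 0.161,
                              luminance_light_cdm2 = 54.1,
                              seed = NULL) {
  stopifnot(
    element_size_deg > 0, step_size_deg > 0, speed_deg_s > 0, duration_s > 0,
    direction %in% c(-1, 1)
  )
  if (!(luminance_dark_cdm2 < luminance_light_cdm2)) {
    stop("`luminance_dark_cdm2` must be smaller than `luminance_light_cdm2`")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  structure(
    list(
      element_size_deg = element_size_deg,
      step_size_deg = step_size_deg,
      speed_deg_s = speed_deg_s,
      direction = as.integer(direction),
      duration_s = duration_s,
      luminance_dark_cdm2 = luminance_dark_cdm2,
      luminance_light_cdm2 = luminance_light_cdm2,
      seed = as.integer(seed),
      dt_step_s = step_size_deg / speed_deg_s
    ),
    class = "chequerboard_spec"
  )
}

#' @export
print.chequerboard_spec <- function(x, ...) {
  cat(sprintf(
    "<chequerboard_spec> element %.3g deg, step %.3g deg (dt = %.1f ms), v = %.3g deg/s, dir %+d, %.2g s, seed %d\n",
    x$element_size_deg, x$step_size_deg, 1000 * x$dt_step_s,
    x$speed_deg_s, x$direction, x$duration_s, x$seed
  ))
  invisible(x)
}

# Random binary pattern sampled onto the spatial grid. Element i covers
# [i*w, (i+1)*w); the pattern tiles the retina periodically (the last element
# may be clipped by the wrap).
chequer_pattern <- function(spec, n_space, dx_deg) {
  extent_deg <- n_space * dx_deg
  n_elements <- ceiling(extent_deg / spec$element_size_deg)
  rng <- local_rng(spec$seed)
  light <- rng$runif(n_elements) < 0.5
  lum <- ifelse(light, spec$luminance_light_cdm2, spec$luminance_dark_cdm2)
  x <- (seq_len(n_space) - 0.5) * dx_deg
  idx <- pmin(floor(x / spec$element_size_deg) + 1L, n_elements)
  lum[idx]
}

# Pattern displacement schedule sampled at monitor frames. The underlying
# sample-and-hold position is step*floor(t/dt_step); it is re-quantised to the
# monitor frame grid because the display can only change at frame boundaries.
# Returns, for each frame 0..(n_frames-1), the signed cumulative displacement
# in degrees.
frame_positions <- function(spec, frame_rate_hz, duration_s = spec$duration_s) {
  n_frames <- max(1L, ceiling(duration_s * frame_rate_hz - 1e-9))
  t_frame <- (seq_len(n_frames) - 1L) / frame_rate_hz
  n_steps <- floor(t_frame / spec$dt_step_s + 1e-9)
  spec$direction * spec$step_size_deg * n_steps
}

#' Generate a stepped chequerboard space-time stimulus
#'
#' Samples the 1D random chequerboard pattern of `spec` onto an angular grid
#' spanning the screen's horizontal extent and displaces it in steps of
#' \eqn{\Delta x} every \eqn{\Delta t = \Delta x/v}, with displacement instants
#' quantised to monitor frame boundaries. The pattern wraps periodically at
#' the retina edge. Generation is deterministic given `spec$seed`.
#'
#' @param spec A [chequerboard_spec()].
#' @param geom A [screen_geometry()].
#' @param dx_deg Spatial sampling (deg/sample). Must resolve the elements
#'   (at most `element_size_deg / 4`).
#' @param dt_s Temporal sampling (s/sample); defaults to one monitor frame.
#'   Must not exceed one frame.
#' @return An object of class `spacetime_stimulus`: a list with `luminance`
#'   (space x time matrix, cd/m^2), `dx_deg`, `dt_s`, `extent_deg`, `x_deg`,
#'   `t_s` and the originating `spec`.
#' @export
generate_stimulus <- function(spec, geom = screen_geometry(),
                              dx_deg = 0.05, dt_s = NULL) {
  stopifnot(inherits(spec, "chequerboard_spec"), inherits(geom, "screen_geometry"))
  if (is.null(dt_s)) dt_s <- 1 / geom$frame_rate_hz
  if (dx_deg > spec$element_size_deg / 4 + 1e-12) {
    stop("resolution error: `dx_deg` must be <= element_size_deg / 4")
  }
  if (dt_s > 1 / geom$frame_rate_hz + 1e-12) {
    stop("resolution error: `dt_s` must not exceed one monitor frame")
  }
  if (spec$step_size_deg < dx_deg - 1e-12) {
    stop("resolution error: step size is smaller than one spatial sample")
  }
  if (spec$duration_s < spec$dt_step_s) {
    warning("duration shorter than one displacement interval; pattern held static")
  }
  n_space <- round(geom$angular_extent_deg / dx_deg)
  base <- chequer_pattern(spec, n_space, dx_deg)
  pos_frames <- frame_positions(spec, geom$frame_rate_hz)
  n_time <- max(1L, round(spec$duration_s / dt_s))
  t_s <- (seq_len(n_time) - 1L) * dt_s
  frame_of_t <- pmin(floor(t_s * geom$frame_rate_hz + 1e-9) + 1L, length(pos_frames))
  shift <- round(pos_frames[frame_of_t] / dx_deg) %% n_space
  idx0 <- seq_len(n_space) - 1L
  lum <- vapply(
    shift,
    function(s) base[((idx0 - s) %% n_space) + 1L],
    numeric(n_space)
  )
  structure(
    list(
      luminance = lum,
      dx_deg = dx_deg,
      dt_s = dt_s,
      extent_deg = n_space * dx_deg,
      x_deg = (seq_len(n_space) - 0.5) * dx_deg,
      t_s = t_s,
      spec = spec
    ),
    class = "spacetime_stimulus"
  )
}

#' Build a space-time stimulus from a luminance matrix
#'
#' Low-level constructor for arbitrary stimuli (gratings, uniform fields)
#' sharing the container used by [generate_stimulus()].
#'
#' @param luminance Space x time matrix of luminances (cd/m^2, non-negative).
#' @param dx_deg,dt_s Sampling resolutions.
#' @return A `spacetime_stimulus`.
#' @export
spacetime_stimulus <- function(luminance, dx_deg, dt_s) {
  luminance <- as.matrix(luminance)
  if (any(!is.finite(luminance))) stop("input error: non-finite luminance")
  if (any(luminance < 0)) stop("input error: negative luminance")
  stopifnot(dx_deg > 0, dt_s > 0)
  n_space <- nrow(luminance)
  structure(
    list(
      luminance = luminance,
      dx_deg = dx_deg,
      dt_s = dt_s,
      extent_deg = n_space * dx_deg,
      x_deg = (seq_len(n_space) - 0.5) * dx_deg,
      t_s = (seq_len(ncol(luminance)) - 1L) * dt_s,
      spec = NULL
    ),
    class = "spacetime_stimulus"
  )
}

#' Drifting sinusoidal grating stimulus
#'
#' @param spatial_freq_cpd Spatial frequency (cycles/deg).
#' @param temporal_freq_hz Temporal frequency (Hz); positive drifts rightward.
#' @param extent_deg Spatial extent (deg).
#' @param duration_s Duration (s).
#' @param dx_deg,dt_s Sampling resolutions.
#' @param mean_cdm2,amplitude_cdm2 Mean luminance and modulation amplitude.
#' @return A `spacetime_stimulus`.
#' @export
grating_stimulus <- function(spatial_freq_cpd, temporal_freq_hz,
                             extent_deg = 40, duration_s = 2,
                             dx_deg = 0.05, dt_s = 0.001,
                             mean_cdm2 = 27.1, amplitude_cdm2 = 26.9) {
  stopifnot(spatial_freq_cpd > 0, amplitude_cdm2 <= mean_cdm2)
  n_space <- max(2L, round(extent_deg / dx_deg))
  n_time <- max(2L, round(duration_s / dt_s))
  x <- (seq_len(n_space) - 0.5) * dx_deg
  t <- (seq_len(n_time) - 1L) * dt_s
  ph <- outer(2 * pi * spatial_freq_cpd * x, 2 * pi * temporal_freq_hz * t, `-`)
  spacetime_stimulus(mean_cdm2 + amplitude_cdm2 * cos(ph), dx_deg, dt_s)
}

# Design mean luminance of a stimulus: midpoint of the chequer levels when
# the generating spec is known, otherwise the empirical mean.
stimulus_mean_luminance <- function(stim) {
  if (!is.null(stim$spec)) {
    (stim$spec$luminance_dark_cdm2 + stim$spec$luminance_light_cdm2) / 2
  } else {
    mean(stim$luminance)
  }
}

#' @export
print.spacetime_stimulus <- function(x, ...) {
  cat(sprintf(
    "<spacetime_stimulus> %d space x %d time samples (%.3g deg at %.3g deg/sample, %.3g s at %.3g ms/sample)\n",
    nrow(x$luminance), ncol(x$luminance), x$extent_deg, x$dx_deg,
    ncol(x$luminance) * x$dt_s, 1000 * x$dt_s
  ))
  invisible(x)
}
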