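# Model 2: population of Hassenstein-Reichardt correlators.
#
# Each detector has two Gaussian-weighted spatial subunits separated by
# separation_deg on a 1D retina. Each subunit's raw signal is filtered into
# a delayed copy (unit-gain low pass, time constant tau_lp) and a transient
# copy (high pass: the input minus its unit-gain low-passed version at
# tau_hp, which kills DC). The detector output is the opponent difference
# of the cross products, LP(left) * HP(right) - LP(right) * HP(left),
# scaled so the mean steady-state response to the optimal drifting grating
# is 1. Keeping the low pass on the raw signal matters for apparent motion:
# its DC retention carries the pre-step pattern across arbitrarily long
# inter-step intervals, so displacement steps can be correlated across the
# two subunits even when dt_step far exceeds the filter time constants. Detector outputs are averaged over a trailing 300 ms window and
# passed through two-sided hard thresholds to give ternary votes; summed
# votes plus Gaussian "mantis" noise drive a sign nonlinearity producing the
# optomotor signal r(t) in [-1, 1]; the trial-mean of r(t) plus Gaussian
# "observer" noise is thresholded into a ternary judgement.

#' Temporal filter time constants of the Reichardt detector
#'
#' @param tau_lp_s Low-pass (delay arm) time constant, default 13 ms.
#' @param tau_hp_s High-pass time constant, default 40 ms.
#' @return An object of class `rd_temporal_filters`.
#' @export
rd_temporal_filters <- function(tau_lp_s = 0.013, tau_hp_s = 0.040) {
  stopifnot(tau_lp_s > 0, tau_hp_s > 0)
  structure(list(tau_lp_s = tau_lp_s, tau_hp_s = tau_hp_s),
            class = "rd_temporal_filters")
}

#' One spatial-tuning class of Reichardt detectors
#'
#' @param sigma_deg Gaussian SD of the subunit spatial filters (deg).
#' @param separation_deg Subunit separation \eqn{\Delta x} (deg); the
#'   modelled interommatidial angle.
#' @param vote_threshold Two-sided threshold on the 300 ms-averaged detector
#'   output, in units of the normalised maximum response.
#' @param count Number of detectors in the class.
#' @param gain Output gain; `NULL` until set by [rd_normalize_gain()].
#' @return An object of class `rd_class`. Derived optics:
#'   acceptance angle `2.35 * sigma_deg`, interommatidial angle
#'   `separation_deg`.
#' @export
rd_class <- function(sigma_deg, separation_deg, vote_threshold = 0.022,
                     count = 25, gain = NULL) {
  stopifnot(sigma_deg > 0, separation_deg > 0, vote_threshold >= 0, count >= 1)
  structure(
    list(sigma_deg = sigma_deg, separation_deg = separation_deg,
         vote_threshold = vote_threshold, count = as.integer(count),
         gain = gain,
         acceptance_deg = acceptance_angle(sigma_deg),
         interommatidial_deg = interommatidial_angle(separation_deg)),
    class = "rd_class"
  )
}

#' @export
print.rd_class <- function(x, ...) {
  cat(sprintf(
    "<rd_class> sigma %.3g deg, separation %.3g deg (rho %.2f, phi %.2f), T %.3g, n = %d, gain %s\n",
    x$sigma_deg, x$separation_deg, x$acceptance_deg, x$interommatidial_deg,
    x$vote_threshold, x$count,
    if (is.null(x$gain)) "unset" else sprintf("%.3g", x$gain)
  ))
  invisible(x)
}

#' Noise levels of the population model
#'
#' Both are expressed as fractions of the corresponding maximum signal:
#' `xi` scales the mantis noise added to the summed votes (SD =
#' `xi * total detector count`), `eta` the observer noise added to the
#' trial-integrated response (SD = `eta * 1`).
#'
#' @param xi Mantis noise level (default: fitted value 0.0112).
#' @param eta Observer noise level (default: fitted value 0.0588).
#' @return An object of class `rd_noise`.
#' @export
rd_noise <- function(xi = 0.0112, eta = 0.0588) {
  stopifnot(xi >= 0, eta >= 0)
  structure(list(xi = xi, eta = eta), class = "rd_noise")
}

#' Full configuration of the Reichardt population model
#'
#' Defaults are the fitted two-class parameter set: near-foveal class 1
#' (sigma 1.07 deg, separation 1.0 deg) and peripheral class 2 (sigma
#' 3.42 deg, separation 2.5 deg), vote thresholds 0.022, 25 detectors per
#' class, noise xi = 0.0112 / eta = 0.0588, tau_lp = 13 ms, tau_hp = 40 ms,
#' 1 s trials on a 142 deg retina.
#'
#' @param classes List of [rd_class()] objects (normally two).
#' @param temporal [rd_temporal_filters()].
#' @param noise [rd_noise()].
#' @param integrator_window_s Trailing-average window for votes (s).
#' @param trial_duration_s Simulated trial length (s).
#' @param retina_extent_deg Extent of the simulated 1D retina (deg).
#' @param frame_rate_hz Monitor frame rate driving stimulus updates (Hz).
#' @param dx_deg Spatial sampling of the retina (deg/sample).
#' @param sim_dt_s Simulation time step (s).
#' @param speed_deg_s Constant stimulus speed (deg/s).
#' @param placement_seed Seed for random detector placement (fixed per
#'   experiment, not per trial).
#' @param observer_deadzone Half-width of the observer's "other" zone on the
#'   noisy trial-integrated response in [-1, 1]. The default 0.2 is the most
#'   liberal criterion at which false-direction judgements on undetectable
#'   stimuli become negligible (matching the rarity of opposite-direction
#'   codings in the behavioural protocol).
#' @param nonlinearity Vote-sum nonlinearity producing r(t): `"satlin"`
#'   (summed votes divided by the detector count, saturating at +/-1;
#'   default) or `"sign"` (hard ternary sign).
#' @param input_coding `"contrast"` (default): subunit inputs are luminance
#'   minus the pattern mean, as after photoreceptor adaptation; or
#'   `"luminance"`: raw luminance (the delay arm then carries a DC
#'   pedestal).
#' @param norm_amplitude_cdm2 Modulation amplitude of the calibration
#'   grating used for gain normalisation. The default is the full
#'   dark-to-light luminance range of the chequerboard (53.94 cd/m^2), i.e.
#'   a unit-amplitude grating on the normalised luminance scale.
#' @return An object of class `rd_config`.
#' @export
rd_config <- function(classes = list(rd_class(1.07, 1.0, 0.022),
                                     rd_class(3.42, 2.5, 0.022)),
                      temporal = rd_temporal_filters(),
                      noise = rd_noise(),
                      integrator_window_s = 0.3,
                      trial_duration_s = 1,
                      retina_extent_deg = 142,
                      frame_rate_hz = 85,
                      dx_deg = 0.05,
                      sim_dt_s = 0.001,
                      speed_deg_s = 44.4,
                      placement_seed = 1001L,
                      observer_deadzone = 0.2,
                      nonlinearity = c("satlin", "sign"),
                      input_coding = c("contrast", "luminance"),
                      norm_amplitude_cdm2 = 54.1 - 0.161) {
  stopifnot(length(classes) >= 1, integrator_window_s > 0, trial_duration_s > 0,
            retina_extent_deg > 0, dx_deg > 0, sim_dt_s > 0,
            observer_deadzone >= 0, observer_deadzone < 1,
            norm_amplitude_cdm2 > 0)
  nonlinearity <- match.arg(nonlinearity)
  input_coding <- match.arg(input_coding)
  structure(
    list(classes = classes, temporal = temporal, noise = noise,
         integrator_window_s = integrator_window_s,
         trial_duration_s = trial_duration_s,
         retina_extent_deg = retina_extent_deg,
         frame_rate_hz = frame_rate_hz,
         dx_deg = dx_deg, sim_dt_s = sim_dt_s, speed_deg_s = speed_deg_s,
         placement_seed = as.integer(placement_seed),
         observer_deadzone = observer_deadzone,
         nonlinearity = nonlinearity,
         input_coding = input_coding,
         norm_amplitude_cdm2 = norm_amplitude_cdm2),
    class = "rd_config"
  )
}

#' @export
print.rd_config <- function(x, ...) {
  cat(sprintf(
    "<rd_config> %d classes, %d detectors, retina %.0f deg, %.0f ms trials, xi %.3g / eta %.3g\n",
    length(x$classes), sum(vapply(x$classes, `[[`, integer(1), "count")),
    x$retina_extent_deg, 1000 * x$trial_duration_s, x$noise$xi, x$noise$eta
  ))
  for (cl in x$classes) print(cl)
  invisible(x)
}

# ---- temporal filtering (exact first-order discrete recursions) ----------

# Unit-DC-gain low pass, column-wise over a time x channels matrix (exact
# discrete recursion y_t = a y_{t-1} + (1-a) x_t, a = exp(-dt/tau)).
# States start at steady state for the first sample (y_0 = x_1), i.e. the
# stimulus is treated as having been static before onset, which avoids a
# spurious appearance-from-black transient at trial start.
lp_filter <- function(x, tau_s, dt_s) {
  a <- exp(-dt_s / tau_s)
  x <- as.matrix(x)
  y <- stats::filter((1 - a) * x, a, method = "recursive",
                     init = matrix(x[1, ], nrow = 1))
  matrix(as.numeric(y), nrow = nrow(x))
}

# High pass: input minus its low-passed copy (zero DC gain, h_1 = 0).
hp_filter <- function(x, tau_s, dt_s) {
  as.matrix(x) - lp_filter(x, tau_s, dt_s)
}

# Correlator stage: x_left/x_right are raw subunit signal matrices (time x
# detectors, matched columns). Each is split into a low-passed delayed copy
# and a high-passed transient copy; the output is the opponent difference of
# the cross products (rightward positive).
rd_correlate <- function(x_left, x_right, temporal, dt_s) {
  d_left <- lp_filter(x_left, temporal$tau_lp_s, dt_s)
  d_right <- lp_filter(x_right, temporal$tau_lp_s, dt_s)
  h_left <- hp_filter(x_left, temporal$tau_hp_s, dt_s)
  h_right <- hp_filter(x_right, temporal$tau_hp_s, dt_s)
  d_left * h_right - d_right * h_left
}

# Gaussian subunit weight profile on a spatial grid, truncated at +/- 3 sigma
# and scaled by dx so the weighted sum approximates the integral.
subunit_weights <- function(x_deg, centre_deg, sigma_deg, dx_deg) {
  w <- exp(-(x_deg - centre_deg)^2 / (2 * sigma_deg^2))
  w[abs(x_deg - centre_deg) > 3 * sigma_deg] <- 0
  w * dx_deg
}

#' Response time series of a single Reichardt detector
#'
#' Runs one detector of class `cls` centred at `x0_deg` over a space-time
#' stimulus. Subunit centres sit at `x0_deg +/- separation_deg / 2`; their
#' Gaussian filters (truncated at 3 sigma) must lie within the stimulus
#' extent. The stimulus is internally resampled (sample-and-hold) to the
#' simulation step when its own temporal sampling is coarser.
#'
#' @param stim A `spacetime_stimulus`.
#' @param cls An [rd_class()]; its `gain` is applied if set (else 1).
#' @param x0_deg Detector position (deg).
#' @param temporal [rd_temporal_filters()].
#' @param sim_dt_s Simulation step (s).
#' @param input_coding `"contrast"` (default) subtracts the stimulus mean
#'   luminance from the input; `"luminance"` uses it raw.
#' @param mean_luminance_cdm2 Mean luminance reference for contrast coding;
#'   by default the design mean of the stimulus spec, falling back to the
#'   empirical mean.
#' @return List with `t_s` and `response`.
#' @export
rd_output <- function(stim, cls, x0_deg, temporal = rd_temporal_filters(),
                      sim_dt_s = 0.001,
                      input_coding = c("contrast", "luminance"),
                      mean_luminance_cdm2 = NULL) {
  stopifnot(inherits(stim, "spacetime_stimulus"), inherits(cls, "rd_class"))
  input_coding <- match.arg(input_coding)
  half <- cls$separation_deg / 2
  reach <- 3 * cls$sigma_deg
  if (x0_deg - half - reach < 0 || x0_deg + half + reach > stim$extent_deg) {
    stop("placement error: subunit filters extend beyond the stimulus extent")
  }
  w_l <- subunit_weights(stim$x_deg, x0_deg - half, cls$sigma_deg, stim$dx_deg)
  w_r <- subunit_weights(stim$x_deg, x0_deg + half, cls$sigma_deg, stim$dx_deg)
  s <- rbind(drop(crossprod(w_l, stim$luminance)),
             drop(crossprod(w_r, stim$luminance)))
  if (input_coding == "contrast") {
    ml <- mean_luminance_cdm2 %||% stimulus_mean_luminance(stim)
    s <- s - c(sum(w_l), sum(w_r)) * ml
  }
  dt <- stim$dt_s
  if (dt > sim_dt_s * (1 + 1e-9)) {
    r <- round(dt / sim_dt_s)
    s <- s[, rep(seq_len(ncol(s)), each = r), drop = FALSE]
    dt <- dt / r
  }
  X <- t(s)  # time x 2
  R <- rd_correlate(X[, 1, drop = FALSE], X[, 2, drop = FALSE], temporal, dt)
  g <- cls$gain %||% 1
  list(t_s = (seq_len(nrow(R)) - 1L) * dt, response = g * drop(R))
}

#' Mean steady-state detector response to a drifting grating
#'
#' Simulates a sinusoidal grating drifting rightward at
#' (`spatial_freq_cpd`, `temporal_freq_hz`) and returns the detector's mean
#' response after transients, averaged over an integer number of temporal
#' periods. The default modulation amplitude is the full dark-to-light
#' luminance range of the chequerboard stimuli (a unit-amplitude grating on
#' the normalised luminance scale), the calibration signal used for gain
#' normalisation.
#'
#' @param cls An [rd_class()] (gain applied if set).
#' @param temporal [rd_temporal_filters()].
#' @param spatial_freq_cpd,temporal_freq_hz Grating frequencies.
#' @param dx_deg,sim_dt_s Sampling resolutions.
#' @param amplitude_cdm2 Modulation amplitude (cd/m^2).
#' @return Mean steady-state response (scalar).
#' @export
rd_grating_response <- function(cls, temporal, spatial_freq_cpd,
                                temporal_freq_hz, dx_deg = 0.05,
                                sim_dt_s = 0.001,
                                amplitude_cdm2 = 54.1 - 0.161) {
  extent <- 2 * (3 * cls$sigma_deg) + cls$separation_deg + 2 * dx_deg
  settle_s <- 0.5
  n_per <- max(1, floor(1 * abs(temporal_freq_hz)))
  avg_s <- n_per / abs(temporal_freq_hz)
  stim <- grating_stimulus(
    spatial_freq_cpd, temporal_freq_hz,
    extent_deg = extent, duration_s = settle_s + avg_s + 2 * sim_dt_s,
    dx_deg = dx_deg, dt_s = sim_dt_s,
    mean_cdm2 = amplitude_cdm2, amplitude_cdm2 = amplitude_cdm2
  )
  out <- rd_output(stim, cls, stim$extent_deg / 2, temporal, sim_dt_s,
                   mean_luminance_cdm2 = amplitude_cdm2)
  keep <- out$t_s >= settle_s & out$t_s < settle_s + avg_s
  mean(out$response[keep])
}

#' Normalise a detector class to unit optimal-grating response
#'
#' Searches grating frequency space (coarse log-spaced grid, then simplex
#' refinement) for the (spatial, temporal) frequency maximising the mean
#' unnormalised response, and sets the class gain to the reciprocal of that
#' maximum, so the optimal drifting grating evokes a mean steady-state
#' response of 1. Idempotent: re-normalising a normalised class leaves the
#' gain unchanged.
#'
#' @param cls An [rd_class()].
#' @param temporal [rd_temporal_filters()].
#' @param dx_deg,sim_dt_s Sampling resolutions.
#' @param fs_grid_cpd,ft_grid_hz Coarse search grids.
#' @param amplitude_cdm2 Calibration grating amplitude (see
#'   [rd_grating_response()]).
#' @return The class with `gain` set and attributes `opt_fs_cpd`,
#'   `opt_ft_hz`, `max_response` attached.
#' @export
rd_normalize_gain <- function(cls, temporal = rd_temporal_filters(),
                              dx_deg = 0.05, sim_dt_s = 0.001,
                              fs_grid_cpd = exp(seq(log(0.005), log(0.6),
                                                    length.out = 13)),
                              ft_grid_hz = exp(seq(log(0.5), log(30),
                                                   length.out = 9)),
                              amplitude_cdm2 = 54.1 - 0.161) {
  raw <- cls
  raw$gain <- NULL
  resp <- function(fs, ft) {
    rd_grating_response(raw, temporal, fs, ft, dx_deg, sim_dt_s,
                        amplitude_cdm2 = amplitude_cdm2)
  }
  grid <- expand.grid(fs = fs_grid_cpd, ft = ft_grid_hz)
  vals <- mapply(resp, grid$fs, grid$ft)
  best <- which.max(vals)
  opt <- stats::optim(
    log(c(grid$fs[best], grid$ft[best])),
    function(p) -resp(exp(p[1]), exp(p[2])),
    method = "Nelder-Mead",
    control = list(maxit = 120, reltol = 1e-6)
  )
  peak <- -opt$value
  if (!is.finite(peak) || peak <= 0) {
    stop("normalization error: optimal grating response is not positive")
  }
  out <- cls
  out$gain <- 1 / peak
  attr(out, "opt_fs_cpd") <- exp(opt$par[1])
  attr(out, "opt_ft_hz") <- exp(opt$par[2])
  attr(out, "max_response") <- peak
  out
}

#' Ternary votes from a detector response series
#'
#' Applies a trailing boxcar average of `window_s` (expanding during the
#' first window) and a two-sided hard threshold: +1 above `vote_threshold`,
#' -1 below its negative, else 0.
#'
#' @param response Numeric response series (or time x detectors matrix).
#' @param vote_threshold Threshold (scalar or per-detector vector).
#' @param window_s Averaging window (s).
#' @param dt_s Sampling step of the series (s).
#' @return Integer series (or matrix) of votes in \{-1, 0, +1\}.
#' @export
detector_vote <- function(response, vote_threshold, window_s = 0.3,
                          dt_s = 0.001) {
  x <- as.matrix(response)
  w <- max(1L, round(window_s / dt_s))
  if (nrow(x) <= w) {
    warning("response series shorter than the averaging window; using expanding mean")
  }
  m <- boxcar_mean(x, w)
  thr <- rep_len(vote_threshold, ncol(x))
  v <- (m > rep(thr, each = nrow(x))) - (m < -rep(thr, each = nrow(x)))
  if (is.null(dim(response))) drop(v) else v
}

# Trailing boxcar mean with expanding start-up window, column-wise.
boxcar_mean <- function(x, w) {
  x <- as.matrix(x)
  n <- nrow(x)
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  lagged <- rbind(matrix(0, min(w, n), ncol(x)),
                  cs[seq_len(max(0, n - w)), , drop = FALSE])
  (cs - lagged) / pmin(seq_len(n), w)
}
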