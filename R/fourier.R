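# Model 1: spatiotemporal Fourier unaliased-energy model.
#
# Stepping a smoothly moving pattern is a sample-and-hold operation with
# interval dt = dx_step / v. It aliases temporal frequencies above 1/(2 dt),
# casting pattern energy into the opposite-motion quadrants of the
# spatiotemporal Fourier plane. Aliased components are assumed to contribute
# no net motion energy, so the model scores a stimulus by its signed
# (opponent) energy restricted to the unaliased spatial-frequency window
# around DC, and predicts Dmax as the step size at which this energy falls
# to a threshold T.

#' Spatiotemporal power spectrum of a stimulus
#'
#' Removes the mean luminance, applies the 2D discrete Fourier transform and
#' returns DC-centred power with physical frequency axes. Power is scaled so
#' that its total equals the mean-removed signal energy (Parseval). The
#' temporal-frequency axis follows the motion convention: components drifting
#' rightward (positive direction) carry power in quadrants 1 and 3
#' (\eqn{f_s f_t > 0}).
#'
#' @param stim A `spacetime_stimulus`.
#' @return An object of class `spacetime_spectrum`: list with `power`
#'   (space-frequency x time-frequency matrix), `f_s_cpd`, `f_t_hz`.
#' @export
power_spectrum <- function(stim) {
  stopifnot(inherits(stim, "spacetime_stimulus"))
  L <- stim$luminance
  if (any(!is.finite(L))) stop("input error: non-finite luminance")
  if (nrow(L) < 2 || ncol(L) < 2) {
    stop("input error: need >= 2 samples along each axis")
  }
  n <- nrow(L)
  m <- ncol(L)
  P <- Mod(stats::fft(L - mean(L)))^2 / (n * m)
  fs_raw <- dft_freqs(n, stim$dx_deg)
  ft_raw <- dft_freqs(m, stim$dt_s)
  # motion convention: f_t = -raw temporal frequency, axes sorted ascending
  os <- order(fs_raw)
  ot <- order(-ft_raw)
  structure(
    list(
      power = P[os, ot, drop = FALSE],
      f_s_cpd = fs_raw[os],
      f_t_hz = -ft_raw[ot]
    ),
    class = "spacetime_spectrum"
  )
}

# DFT bin frequencies in cycles per unit (bin k-1 of n, sampling interval d)
dft_freqs <- function(n, d) {
  k <- seq_len(n) - 1L
  (k - n * (k >= ceiling(n / 2))) / (n * d)
}

#' @export
print.spacetime_spectrum <- function(x, ...) {
  cat(sprintf(
    "<spacetime_spectrum> %d x %d bins, f_s up to %.2f cpd, f_t up to %.1f Hz\n",
    length(x$f_s_cpd), length(x$f_t_hz),
    max(abs(x$f_s_cpd)), max(abs(x$f_t_hz))
  ))
  invisible(x)
}

#' Configuration of the Fourier energy model
#'
#' @param threshold_T Energy threshold at which Dmax is read off an energy
#'   curve (model units; fitted via [fit_energy_threshold()] or placed at
#'   `threshold_fraction` of the curve maxima).
#' @param window_halfwidth_rule Spatial-frequency half-width of the unaliased
#'   window as a function of step size: `"1/dx"` (window
#'   \eqn{[-1/\Delta x, 1/\Delta x]}, the default) or `"1/(2dx)"`.
#' @param n_patterns Number of independent random patterns averaged per
#'   condition.
#' @param measure Quantity summed inside the window for energy curves:
#'   `"windowed_total"` (default) sums all off-axis power inside the window,
#'   treating aliased components as contributing energy whose net direction
#'   cancels (the model's first-order approximation); `"opponent"` sums
#'   signed power over the opponent quadrants (the direct directional
#'   measure, which decays much faster because in-window aliased components
#'   cancel coherently).
#' @param threshold_fraction When `threshold_T` is `NULL`: place the
#'   threshold at this fraction of the curves' common maximum, in the regime
#'   where the curves are parallel shifts of one another.
#' @return An object of class `model1_config`.
#' @export
model1_config <- function(threshold_T = NULL,
                          window_halfwidth_rule = c("1/dx", "1/(2dx)"),
                          n_patterns = 20,
                          measure = c("windowed_total", "opponent"),
                          threshold_fraction = 0.2) {
  window_halfwidth_rule <- match.arg(window_halfwidth_rule)
  measure <- match.arg(measure)
  if (!is.null(threshold_T) && threshold_T <= 0) {
    stop("`threshold_T` must be > 0")
  }
  stopifnot(n_patterns >= 1, threshold_fraction > 0, threshold_fraction < 1)
  structure(
    list(threshold_T = threshold_T,
         window_halfwidth_rule = window_halfwidth_rule,
         n_patterns = as.integer(n_patterns),
         measure = measure,
         threshold_fraction = threshold_fraction),
    class = "model1_config"
  )
}

window_halfwidth <- function(step_deg, rule) {
  switch(rule, "1/dx" = 1 / step_deg, "1/(2dx)" = 1 / (2 * step_deg))
}

#' Opponent motion energy within the unaliased window
#'
#' Sums signed spectral power over the opponent-quadrant mask (+1 in
#' quadrants 1 and 3, -1 in quadrants 2 and 4, 0 on the \eqn{f_s = 0} and
#' \eqn{f_t = 0} axes), restricted to spatial frequencies
#' \eqn{|f_s|} within the aliasing window set by the step size. Positive for
#' net rightward motion, negative for leftward.
#'
#' @param spect A `spacetime_spectrum`.
#' @param step_deg Step size \eqn{\Delta x} (deg, > 0) defining the window.
#' @param cfg A [model1_config()].
#' @return Signed energy (model units).
#' @export
opponent_energy <- function(spect, step_deg, cfg = model1_config()) {
  stopifnot(inherits(spect, "spacetime_spectrum"), step_deg > 0)
  hw <- window_halfwidth(step_deg, cfg$window_halfwidth_rule)
  f_s <- spect$f_s_cpd
  df <- f_s[2] - f_s[1]
  if (hw < df) {
    warning("aliasing window narrower than one spatial-frequency bin")
  }
  in_win <- abs(f_s) <= hw
  sgn <- outer(sign(f_s), sign(spect$f_t_hz))
  sum(spect$power[in_win, , drop = FALSE] * sgn[in_win, , drop = FALSE])
}

#' Total motion energy within the unaliased window
#'
#' Sums all spectral power inside the aliasing window, excluding the
#' \eqn{f_s = 0} and \eqn{f_t = 0} axes (which carry no motion information).
#' This is the model's first-order "unaliased energy" approximation: aliased
#' components inside the window retain their energy while their net
#' direction is taken as zero, so the curve measures how much pattern energy
#' survives the sample-and-hold operation rather than its signed direction.
#'
#' @inheritParams opponent_energy
#' @return Non-negative energy (model units).
#' @export
windowed_motion_energy <- function(spect, step_deg, cfg = model1_config()) {
  stopifnot(inherits(spect, "spacetime_spectrum"), step_deg > 0)
  hw <- window_halfwidth(step_deg, cfg$window_halfwidth_rule)
  f_s <- spect$f_s_cpd
  df <- f_s[2] - f_s[1]
  if (hw < df) {
    warning("aliasing window narrower than one spatial-frequency bin")
  }
  in_win <- abs(f_s) <= hw & f_s != 0
  keep_t <- spect$f_t_hz != 0
  sum(spect$power[in_win, keep_t, drop = FALSE])
}

#' Mean motion energy versus step size
#'
#' Builds the Model-1 energy curve for one element size: for each step size
#' in the grid, generates `cfg$n_patterns` independent stepped chequerboards
#' (rightward motion), computes the windowed motion energy (or, when
#' `cfg$measure = "opponent"`, the signed opponent energy) inside the
#' aliasing window, and averages over patterns.
#'
#' @param element_deg Element size (deg).
#' @param step_grid Step sizes (deg), sorted ascending.
#' @param cfg A [model1_config()].
#' @param geom A [screen_geometry()].
#' @param seed Seed; pattern seeds are derived per (step, replicate).
#' @param speed_deg_s,duration_s Stimulus motion parameters.
#' @param dx_deg Spatial sampling; defaults to `min(0.05, element/8)` capped
#'   below by 0.0125 deg.
#' @return An object of class `energy_curve`: data frame-like list with
#'   `step_sizes_deg`, `energy`, `element_size_deg`.
#' @export
energy_vs_step <- function(element_deg, step_grid, cfg = model1_config(),
                           geom = screen_geometry(), seed = 1L,
                           speed_deg_s = 44.4, duration_s = 1,
                           dx_deg = NULL) {
  stopifnot(!is.unsorted(step_grid), all(step_grid > 0))
  if (is.null(dx_deg)) dx_deg <- max(min(0.05, element_deg / 8), 0.0125)
  energy <- vapply(seq_along(step_grid), function(i) {
    e <- vapply(seq_len(cfg$n_patterns), function(r) {
      sp <- chequerboard_spec(
        element_size_deg = element_deg, step_size_deg = step_grid[i],
        speed_deg_s = speed_deg_s, direction = 1L, duration_s = duration_s,
        seed = derive_seed(seed, i, r)
      )
      stim <- generate_stimulus(sp, geom, dx_deg = dx_deg)
      spect <- power_spectrum(stim)
      if (cfg$measure == "opponent") {
        opponent_energy(spect, step_grid[i], cfg)
      } else {
        windowed_motion_energy(spect, step_grid[i], cfg)
      }
    }, numeric(1))
    mean(e)
  }, numeric(1))
  structure(
    list(step_sizes_deg = step_grid, energy = energy,
         element_size_deg = element_deg),
    class = "energy_curve"
  )
}

#' @export
print.energy_curve <- function(x, ...) {
  cat(sprintf(
    "<energy_curve> element %.3g deg, %d steps in [%.3g, %.3g] deg, energy [%.3g, %.3g]\n",
    x$element_size_deg, length(x$step_sizes_deg),
    min(x$step_sizes_deg), max(x$step_sizes_deg),
    min(x$energy), max(x$energy)
  ))
  invisible(x)
}

#' Dmax predicted by the Fourier energy model
#'
#' Reads Dmax off an energy curve as the step size at which the mean opponent
#' energy first crosses the threshold downwards, using log-linear
#' interpolation (linear in log step vs log energy) between the bracketing
#' grid points.
#'
#' @param curve An [energy_vs_step()] result.
#' @param threshold_T Energy threshold; must lie within the curve's range.
#' @return Dmax in degrees.
#' @export
dmax_from_energy <- function(curve, threshold_T) {
  stopifnot(inherits(curve, "energy_curve"))
  e <- curve$energy
  s <- curve$step_sizes_deg
  if (threshold_T > max(e) || threshold_T < min(e)) {
    stop(sprintf(
      "threshold out of range: T = %.4g outside curve energies [%.4g, %.4g]",
      threshold_T, min(e), max(e)
    ))
  }
  if (threshold_T >= e[1]) return(s[1])
  i <- which(e[-length(e)] >= threshold_T & e[-1] < threshold_T)[1]
  if (is.na(i)) {
    # no downward crossing found (non-monotone curve touching T from below)
    i <- max(which(e >= threshold_T))
    if (i == length(e)) return(s[i])
  }
  e_lo <- max(e[i], 1e-12)
  e_hi <- max(e[i + 1], 1e-12)
  frac <- (log(e_lo) - log(threshold_T)) / (log(e_lo) - log(e_hi))
  exp(log(s[i]) + frac * (log(s[i + 1]) - log(s[i])))
}

#' Model-1 Dmax predictions across element sizes
#'
#' @param curves List of [energy_vs_step()] results (one per element size).
#' @param threshold_T Energy threshold.
#' @return Data frame with `element_size_deg` and `dmax_deg`.
#' @export
dmax_curve_model1 <- function(curves, threshold_T) {
  out <- data.frame(
    element_size_deg = vapply(curves, `[[`, numeric(1), "element_size_deg"),
    dmax_deg = vapply(curves, dmax_from_energy, numeric(1),
                      threshold_T = threshold_T)
  )
  out[order(out$element_size_deg), , drop = FALSE]
}

#' Fit the Model-1 energy threshold to observed Dmax values
#'
#' Finds the threshold T minimising the sum of squared differences between
#' the Dmax values read off the energy curves and the observed Dmax per
#' element size (derivative-free simplex search on log T, with optional
#' random multi-start).
#'
#' @param observed Data frame with `element_size_deg` and `dmax_deg`
#'   (>= 2 rows).
#' @param curves List of [energy_vs_step()] results covering the observed
#'   element sizes.
#' @param n_starts Number of random restarts.
#' @param seed Seed for restart initialisation.
#' @return A [model1_config()] with `threshold_T` set, plus attributes
#'   `sse` (objective at the optimum) and `starts` (per-start results).
#' @export
fit_energy_threshold <- function(observed, curves, n_starts = 1, seed = 1L) {
  stopifnot(nrow(observed) >= 2, length(curves) >= 1)
  el_curves <- vapply(curves, `[[`, numeric(1), "element_size_deg")
  idx <- match(observed$element_size_deg, el_curves)
  if (any(is.na(idx))) {
    stop("every observed element size needs a matching energy curve")
  }
  lo <- max(vapply(curves[idx], function(cv) min(cv$energy), numeric(1)))
  hi <- min(vapply(curves[idx], function(cv) max(cv$energy), numeric(1)))
  if (!(hi > lo) || hi <= 0) {
    stop("infeasible threshold: energy curves share no common energy range")
  }
  lo <- max(lo, 1e-12)
  objective <- function(logT) {
    T_ <- exp(logT)
    if (T_ < lo || T_ > hi) return(1e12)
    pred <- vapply(curves[idx], dmax_from_energy, numeric(1), threshold_T = T_)
    sum((pred - observed$dmax_deg)^2)
  }
  rng <- local_rng(derive_seed(seed, 31L))
  starts <- log(sqrt(lo * hi))
  if (n_starts > 1) {
    starts <- c(starts, rng$runif(n_starts - 1, log(lo), log(hi)))
  }
  results <- lapply(starts, function(s0) {
    stats::optim(s0, objective, method = "Nelder-Mead",
                 control = list(maxit = 500, warn.1d.NelderMead = FALSE))
  })
  best <- results[[which.min(vapply(results, `[[`, numeric(1), "value"))]]
  cfg <- model1_config(threshold_T = exp(best$par),
                       n_patterns = length(curves[[1]]$energy))
  attr(cfg, "sse") <- best$value
  attr(cfg, "starts") <- data.frame(
    start_logT = starts,
    threshold_T = vapply(results, function(r) exp(r$par), numeric(1)),
    sse = vapply(results, `[[`, numeric(1), "value")
  )
  cfg
}
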