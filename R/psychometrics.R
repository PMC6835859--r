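#' Cumulative-Gaussian detection probability
#'
#' Probability that motion is detected at step size \eqn{\Delta x}, modelled as
#' a decreasing cumulative Gaussian
#' \deqn{P(\Delta x; D_{max}, \sigma) = \frac{1}{2}\left[1 -
#'   \mathrm{erf}\!\left(\frac{\Delta x - D_{max}}{\sqrt{2}\,\sigma}\right)\right],}
#' i.e. \eqn{P = \Phi((D_{max} - \Delta x)/\sigma)}. By construction
#' \eqn{P(D_{max}) = 1/2}: Dmax is the step size at which detection drops to
#' 50%.
#'
#' @param step_deg Step size(s) \eqn{\Delta x} in degrees.
#' @param dmax_deg The 50% point (deg).
#' @param width_deg Transition width \eqn{\sigma} (deg, > 0).
#' @return Detection probabilities in (0, 1).
#' @export
detection_probability <- function(step_deg, dmax_deg, width_deg) {
  if (!all(is.finite(width_deg)) || any(width_deg <= 0)) {
    stop("parameter error: `width_deg` must be > 0")
  }
  stats::pnorm((dmax_deg - step_deg) / width_deg)
}

#' Fit the psychometric function by binomial maximum likelihood
#'
#' Estimates \eqn{(D_{max}, \sigma)} from per-step detection counts by
#' maximising the binomial log-likelihood
#' \eqn{\sum_i [\log C(m_i, n_i) + n_i \log P_i + (m_i - n_i)\log(1 - P_i)]},
#' where \eqn{P_i} is [detection_probability()] at step \eqn{i}. Predicted
#' probabilities are clamped away from 0 and 1 for numerical stability.
#' Optional percentile-bootstrap confidence intervals resample the detection
#' counts binomially under the fitted curve.
#'
#' @param step_deg Step sizes (deg), at least two distinct values.
#' @param n_detected,n_total Detected and total trial counts per step.
#' @param init Optional initial `c(dmax, sigma)`.
#' @param n_boot Number of bootstrap resamples for 95% CIs (0 to skip).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `psychometric_fit`: a list with `dmax_deg`,
#'   `width_deg`, `loglik`, `n_obs`, `ci` (when bootstrapped) and the input
#'   summary table.
#' @export
fit_psychometric <- function(step_deg, n_detected, n_total, init = NULL,
                             n_boot = 0, seed = 1L) {
  stopifnot(length(step_deg) == length(n_detected),
            length(step_deg) == length(n_total))
  keep <- n_total > 0
  step_deg <- step_deg[keep]
  n_detected <- n_detected[keep]
  n_total <- n_total[keep]
  if (length(unique(step_deg)) < 2) {
    stop("need detection counts at >= 2 distinct step sizes")
  }
  if (any(n_detected < 0) || any(n_detected > n_total)) {
    stop("detection counts must satisfy 0 <= n_detected <= n_total")
  }
  if (sum(n_detected) == 0 || sum(n_detected) == sum(n_total)) {
    stop(paste(
      "non-identifiable data: all trials detected or none were;",
      "the 50% point is outside the sampled step range --",
      "extend the step-size grid to bracket the transition"
    ))
  }

  nll <- function(par) {
    p <- detection_probability(step_deg, par[1], exp(par[2]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(n_detected, n_total, p, log = TRUE))
  }
  if (is.null(init)) {
    # crude start: weighted mean step at p ~ 0.5, spread from the step range
    prop <- n_detected / n_total
    w <- 1 - abs(prop - 0.5) * 2
    d0 <- if (sum(w) > 0) sum(step_deg * w) / sum(w) else mean(step_deg)
    s0 <- max(diff(range(step_deg)) / 4, 1e-3)
    init <- c(d0, s0)
  }
  opt <- stats::optim(c(init[1], log(init[2])), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  fit <- list(
    dmax_deg = opt$par[1],
    width_deg = exp(opt$par[2]),
    loglik = -opt$value + sum(lchoose(n_total, n_detected)),
    n_obs = sum(n_total),
    convergence = opt$convergence,
    data = data.frame(step_size_deg = step_deg, n_detected = n_detected,
                      n_total = n_total)
  )
  if (n_boot > 0) {
    rng <- local_rng(derive_seed(seed, 977L))
    p_hat <- detection_probability(step_deg, fit$dmax_deg, fit$width_deg)
    boots <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      nb <- rng$rbinom(length(step_deg), n_total, p_hat)
      bf <- tryCatch(
        fit_psychometric(step_deg, nb, n_total,
                         init = c(fit$dmax_deg, fit$width_deg)),
        error = function(e) NULL
      )
      if (!is.null(bf)) boots[b, ] <- c(bf$dmax_deg, bf$width_deg)
    }
    fit$ci <- list(
      dmax_deg = stats::quantile(boots[, 1], c(0.025, 0.975), na.rm = TRUE),
      width_deg = stats::quantile(boots[, 2], c(0.025, 0.975), na.rm = TRUE)
    )
  }
  structure(fit, class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> Dmax = %.3f deg, sigma = %.3f deg (logLik %.2f, n = %d)\n",
    x$dmax_deg, x$width_deg, x$loglik, x$n_obs
  ))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI Dmax [%.3f, %.3f], sigma [%.3f, %.3f]\n",
                x$ci$dmax_deg[1], x$ci$dmax_deg[2],
                x$ci$width_deg[1], x$ci$width_deg[2]))
  }
  invisible(x)
}

#' Fit psychometric functions per element size from trial records
#'
#' Convenience wrapper: summarises a trial-record data frame into per-step
#' detection counts for each element size and fits [fit_psychometric()] to
#' each.
#'
#' @param trials A trial-record data frame (see [read_trials()]).
#' @param n_boot,seed Passed to [fit_psychometric()].
#' @return A data frame with one row per element size: `element_size_deg`,
#'   `dmax_deg`, `width_deg`, `loglik`, `n_obs` (plus CI columns when
#'   bootstrapped).
#' @export
fit_psychometric_by_element <- function(trials, n_boot = 0, seed = 1L) {
  summ <- condition_summary(trials)
  out <- lapply(split(summ, summ$element_size_deg), function(d) {
    f <- fit_psychometric(d$step_size_deg, d$n_detected, d$n_total,
                          n_boot = n_boot, seed = seed)
    row <- data.frame(
      element_size_deg = d$element_size_deg[1],
      dmax_deg = f$dmax_deg, width_deg = f$width_deg,
      loglik = f$loglik, n_obs = f$n_obs
    )
    if (!is.null(f$ci)) {
      row$dmax_lo <- f$ci$dmax_deg[[1]]
      row$dmax_hi <- f$ci$dmax_deg[[2]]
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$element_size_deg), , drop = FALSE]
}

#' Fit the Dmax power law
#'
#' Fits \eqn{D_{max} = k\,x^{e}} to per-element Dmax estimates by least
#' squares in linear Dmax units (Gaussian maximum likelihood with constant
#' variance), optionally with the exponent held fixed. The reported fit
#' quality is the standard error of the regression
#' \eqn{S = \sqrt{SS_{res}/(n - p)}} with \eqn{p} the number of free
#' parameters.
#'
#' @param element_deg Element sizes \eqn{x} (deg, > 0).
#' @param dmax_deg Dmax estimates (deg, > 0).
#' @param fixed_exponent Optional exponent to hold fixed (then only \eqn{k}
#'   is estimated).
#' @return An object of class `power_law_fit`: list with `k`, `exponent`,
#'   `S`, `fixed_exponent`, `n`, `residuals`.
#' @export
fit_power_law <- function(element_deg, dmax_deg, fixed_exponent = NULL) {
  stopifnot(length(element_deg) == length(dmax_deg))
  if (any(element_deg <= 0) || any(dmax_deg <= 0)) {
    stop("domain error: element sizes and Dmax must be > 0")
  }
  n <- length(element_deg)
  if (is.null(fixed_exponent)) {
    if (n < 2) stop("need >= 2 points to fit both k and the exponent")
    # log-log regression gives the starting point for linear-space LS
    lf <- stats::lm(log(dmax_deg) ~ log(element_deg))
    start <- c(k = exp(unname(stats::coef(lf)[1])), e = unname(stats::coef(lf)[2]))
    sse <- function(par) sum((dmax_deg - par[1] * element_deg^par[2])^2)
    opt <- stats::optim(start, sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    k <- unname(opt$par[1])
    e <- unname(opt$par[2])
    p <- 2L
  } else {
    if (n < 1) stop("need >= 1 point with a fixed exponent")
    e <- fixed_exponent
    xe <- element_deg^e
    k <- sum(dmax_deg * xe) / sum(xe^2)
    p <- 1L
  }
  res <- dmax_deg - k * element_deg^e
  S <- if (n > p) sqrt(sum(res^2) / (n - p)) else 0
  structure(
    list(k = k, exponent = e, S = S, fixed_exponent = fixed_exponent,
         n = n, residuals = res, df = n - p,
         underdetermined = n <= p),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> Dmax = %.3f * x^%.3f%s  (S = %.3f deg, n = %d%s)\n",
    x$k, x$exponent,
    if (!is.null(x$fixed_exponent)) " [exponent fixed]" else "",
    x$S, x$n,
    if (x$underdetermined) ", saturated: S undefined, reported as 0" else ""
  ))
  invisible(x)
}

#' Predict Dmax from a power-law fit
#'
#' @param object A `power_law_fit`.
#' @param element_deg Element sizes (deg).
#' @param ... Unused.
#' @return Predicted Dmax (deg).
#' @export
predict.power_law_fit <- function(object, element_deg, ...) {
  object$k * element_deg^object$exponent
}

#' Ommatidial optics conversions
#'
#' When a Reichardt-detector class is identified with a patch of ommatidia,
#' its Gaussian spatial-filter SD maps to the ommatidial acceptance angle
#' \eqn{\Delta\rho = 2.35\,\sigma} (the Gaussian full width at half maximum)
#' and the subunit separation maps to the interommatidial angle
#' \eqn{\Delta\phi = \Delta x}.
#'
#' @param sigma_deg Gaussian SD of the spatial filter (deg, > 0).
#' @return Acceptance angle in degrees.
#' @export
acceptance_angle <- function(sigma_deg) {
  if (any(sigma_deg <= 0)) stop("domain error: `sigma_deg` must be > 0")
  2.35 * sigma_deg
}

#' @rdname acceptance_angle
#' @param separation_deg Subunit separation (deg, > 0).
#' @export
interommatidial_angle <- function(separation_deg) {
  if (any(separation_deg <= 0)) stop("domain error: `separation_deg` must be > 0")
  separation_deg
}
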