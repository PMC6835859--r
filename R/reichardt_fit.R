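# Fitting the free parameters of the Reichardt population model to
# behavioural detection proportions.

rd_free_params <- c("sigma1", "sigma2", "dx1", "dx2", "T1", "T2", "xi", "eta")

rd_params_get <- function(cfg) {
  c(sigma1 = cfg$classes[[1]]$sigma_deg,
    sigma2 = if (length(cfg$classes) > 1) cfg$classes[[2]]$sigma_deg else NA,
    dx1 = cfg$classes[[1]]$separation_deg,
    dx2 = if (length(cfg$classes) > 1) cfg$classes[[2]]$separation_deg else NA,
    T1 = cfg$classes[[1]]$vote_threshold,
    T2 = if (length(cfg$classes) > 1) cfg$classes[[2]]$vote_threshold else NA,
    xi = cfg$noise$xi, eta = cfg$noise$eta)
}

rd_params_set <- function(cfg, par) {
  upd_class <- function(cl, sigma, dxp, thr) {
    spatial_changed <- !isTRUE(all.equal(c(cl$sigma_deg, cl$separation_deg),
                                         c(sigma, dxp)))
    out <- rd_class(sigma, dxp, thr, cl$count,
                    gain = if (spatial_changed) NULL else cl$gain)
    out
  }
  p <- rd_params_get(cfg)
  p[names(par)] <- par
  cfg$classes[[1]] <- upd_class(cfg$classes[[1]], p[["sigma1"]], p[["dx1"]],
                                p[["T1"]])
  if (length(cfg$classes) > 1) {
    cfg$classes[[2]] <- upd_class(cfg$classes[[2]], p[["sigma2"]], p[["dx2"]],
                                  p[["T2"]])
  }
  cfg$noise <- rd_noise(p[["xi"]], p[["eta"]])
  cfg
}

#' Squared-error objective of the Reichardt model against behavioural data
#'
#' Simulates the model on the data's condition grid (with a fixed simulation
#' seed, so the objective is deterministic in the parameters) and returns the
#' sum of squared differences between model and observed detection
#' proportions across conditions.
#'
#' @param data Trial-record data frame (observed behaviour).
#' @param cfg An [rd_config()].
#' @param n_sim_trials Simulated trials per condition.
#' @param sim_seed Seed shared across objective evaluations (common random
#'   numbers).
#' @return Scalar sum of squared proportion differences.
#' @export
rd_objective <- function(data, cfg, n_sim_trials = 50, sim_seed = 42L) {
  obs <- condition_summary(data)
  elements <- unique(obs$element_size_deg)
  steps <- lapply(elements, function(el) {
    obs$step_size_deg[obs$element_size_deg == el]
  })
  sim <- rd_simulate_experiment(elements, steps, n_sim_trials, cfg,
                                seed = sim_seed)
  simsum <- condition_summary(sim)
  key <- function(d) paste(signif(d$element_size_deg, 8),
                           signif(d$step_size_deg, 8))
  m <- match(key(obs), key(simsum))
  p_obs <- obs$n_detected / obs$n_total
  p_sim <- simsum$n_detected[m] / simsum$n_total[m]
  sum((p_obs - p_sim)^2)
}

#' Fit free parameters of the Reichardt model to behavioural data
#'
#' Derivative-free simplex search (Nelder-Mead in log-parameter space) over
#' any subset of (`sigma1`, `sigma2`, `dx1`, `dx2`, `T1`, `T2`, `xi`, `eta`),
#' minimising [rd_objective()]. Supports random multi-start; class gains are
#' renormalised whenever spatial parameters change.
#'
#' @param data Trial-record data frame covering >= 2 element sizes.
#' @param free Character vector naming the free parameters.
#' @param cfg Starting configuration (also supplies all fixed parts).
#' @param n_sim_trials Simulated trials per condition per objective
#'   evaluation.
#' @param n_starts Number of starts; starts beyond the first perturb the
#'   initial parameters randomly within +/- 50%.
#' @param maxit Simplex iterations per start.
#' @param sim_seed,seed Seeds for the simulation and for start perturbation.
#' @return List with `config` (best fit), `objective`, `par` (fitted values),
#'   `starts` (per-start data frame), `convergence`.
#' @export
rd_fit <- function(data, free = c("T1", "T2", "xi", "eta"),
                   cfg = rd_config(), n_sim_trials = 50, n_starts = 1,
                   maxit = 100, sim_seed = 42L, seed = 1L) {
  stopifnot(all(free %in% rd_free_params))
  if (length(unique(data$element_size_deg)) < 2) {
    stop("data must cover >= 2 element sizes")
  }
  init <- rd_params_get(cfg)[free]
  if (any(!is.finite(init)) || any(init <= 0)) {
    stop("free parameters must be positive and present in `cfg`")
  }
  obj <- function(logp) {
    par <- exp(logp)
    names(par) <- free
    rd_objective(data, rd_params_set(cfg, par), n_sim_trials, sim_seed)
  }
  rng <- local_rng(derive_seed(seed, 17L))
  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    p0 <- if (s == 1) init else init * exp(rng$runif(length(init), log(0.5), log(1.5)))
    results[[s]] <- stats::optim(log(p0), obj, method = "Nelder-Mead",
                                 control = list(maxit = maxit))
  }
  vals <- vapply(results, `[[`, numeric(1), "value")
  best <- results[[which.min(vals)]]
  par <- exp(best$par)
  names(par) <- free
  list(
    config = rd_params_set(cfg, par),
    objective = best$value,
    par = par,
    convergence = best$convergence,
    starts = data.frame(
      start = seq_len(n_starts), objective = vals,
      t(vapply(results, function(r) exp(r$par), numeric(length(free))))
    )
  )
}
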