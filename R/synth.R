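#' Generate synthetic behavioural trial records
#'
#' Simulates ternary optomotor trial records with the statistical structure
#' the Dmax analysis assumes. For each condition (element size, step size) the
#' ground-truth detection probability is the cumulative-Gaussian psychometric
#' function whose 50% point comes from a truth power law
#' \eqn{D_{max}(x) = k\,x^{e}}; each presentation is an independent Bernoulli
#' draw from it. Directions are balanced left/right within every condition.
#' Trials in which motion is not detected are coded `"other"`, except for a
#' small fraction `opposite_rate` coded as the opposite direction (emulating
#' rare opposite-direction observer codings).
#'
#' @param elements_deg Element sizes of the condition grid (deg).
#' @param steps_deg Step sizes: either a numeric vector shared by all element
#'   sizes, or a list of one step vector per element size.
#' @param n_trials Trials per (element, step) condition (split equally
#'   between the two directions).
#' @param truth_k,truth_exponent Power-law truth for Dmax vs element size;
#'   defaults are the fitted mantis values \eqn{5.36 x^{0.462}}.
#' @param width_rule Function mapping Dmax (deg) to the psychometric width
#'   sigma (deg); default `0.3 * dmax` keeps the transition shape
#'   scale-invariant.
#' @param opposite_rate Probability that a non-detected trial is coded as the
#'   opposite direction rather than "other".
#' @param subject_id Label stored in the `subject_id` column.
#' @param seed Master seed; per-condition substreams are derived from it so
#'   conditions are independently reproducible.
#' @return Trial-record data frame (see [read_trials()]).
#' @export
synth_behavior <- function(elements_deg, steps_deg, n_trials,
                           truth_k = 5.36, truth_exponent = 0.462,
                           width_rule = function(dmax) 0.3 * dmax,
                           opposite_rate = 0.04,
                           subject_id = "synthetic",
                           seed = 1L) {
  stopifnot(opposite_rate >= 0, opposite_rate <= 1, n_trials >= 0)
  if (!is.list(steps_deg)) {
    steps_deg <- rep(list(steps_deg), length(elements_deg))
  }
  stopifnot(length(steps_deg) == length(elements_deg))
  rows <- list()
  for (i in seq_along(elements_deg)) {
    el <- elements_deg[i]
    dmax <- truth_k * el^truth_exponent
    sigma <- width_rule(dmax)
    for (st in steps_deg[[i]]) {
      if (n_trials == 0) next
      p <- detection_probability(st, dmax, sigma)
      rng <- local_rng(derive_seed(seed, round(el * 1000), round(st * 1000)))
      n_right <- ceiling(n_trials / 2)
      dir <- rep(c(1L, -1L), c(n_right, n_trials - n_right))
      det <- rng$runif(n_trials) < p
      opp <- rng$runif(n_trials) < opposite_rate
      resp <- ifelse(
        det,
        ifelse(dir == 1L, "right", "left"),
        ifelse(opp, ifelse(dir == 1L, "left", "right"), "other")
      )
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id,
        element_size_deg = el,
        step_size_deg = st,
        direction = dir,
        response = resp,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(
      subject_id = character(0), element_size_deg = numeric(0),
      step_size_deg = numeric(0), direction = integer(0),
      response = character(0), stringsAsFactors = FALSE
    )
    out$detected <- logical(0)
    return(out)
  }
  mark_detected(do.call(rbind, rows))
}

#' Default step-size grid spanning a psychometric transition
#'
#' Log-spaced step sizes centred on an anticipated Dmax so the sampled
#' detection probabilities cover the transition from near-1 to near-0.
#'
#' @param dmax_anchor_deg Anticipated Dmax (deg), e.g. from the truth power
#'   law or a pilot fit.
#' @param n_steps Number of step sizes.
#' @param span Multiplicative half-range: steps run from
#'   `dmax_anchor_deg / span` to `dmax_anchor_deg * span`.
#' @return Numeric vector of step sizes (deg).
#' @export
transition_steps <- function(dmax_anchor_deg, n_steps = 7, span = 4) {
  stopifnot(dmax_anchor_deg > 0, n_steps >= 2, span > 1)
  exp(seq(log(dmax_anchor_deg / span), log(dmax_anchor_deg * span),
          length.out = n_steps))
}
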