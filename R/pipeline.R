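# End-to-end orchestration: stimuli -> models -> psychometric fits ->
# power laws -> comparison report and artifacts.

#' Simulate the Reichardt model and fit the Dmax power law
#'
#' The headline Model-2 analysis: simulate a behavioural experiment over a
#' grid of element sizes (balanced directions, fresh pattern per trial), fit
#' a cumulative-Gaussian psychometric function per element size, extract
#' Dmax at 50%, and fit \eqn{D_{max} = k x^e}.
#'
#' @param elements_deg Element sizes (deg); default seven log-spaced sizes
#'   spanning 0.5-9.55 deg.
#' @param n_trials Trials per (element, step) condition.
#' @param cfg An [rd_config()].
#' @param steps_deg Step grids (vector or list per element). By default each
#'   element's grid is log-spaced around the anticipated transition from the
#'   reference power law \eqn{5.36 x^{0.462}}.
#' @param n_steps Steps per element for the default grids.
#' @param seed Master seed.
#' @param progress Print per-condition progress.
#' @return List with `trials`, `fits` (per-element Dmax table) and
#'   `power_law` (a [fit_power_law()] result).
#' @export
simulate_dmax_scaling <- function(elements_deg = exp(seq(log(0.5), log(9.55),
                                                         length.out = 7)),
                                  n_trials = 50, cfg = rd_config(),
                                  steps_deg = NULL, n_steps = 7,
                                  seed = 1L, progress = FALSE) {
  if (is.null(steps_deg)) {
    steps_deg <- lapply(elements_deg, function(el) {
      transition_steps(predict_reference_dmax(el), n_steps = n_steps)
    })
  }
  trials <- rd_simulate_experiment(elements_deg, steps_deg, n_trials, cfg,
                                   seed = seed, progress = progress)
  fits <- fit_psychometric_by_element(trials)
  pl <- fit_power_law(fits$element_size_deg, fits$dmax_deg)
  list(trials = trials, fits = fits, power_law = pl)
}

# Reference Dmax anchor used to centre step grids on the psychometric
# transition (the pooled behavioural power law).
predict_reference_dmax <- function(element_deg, k = 5.36, exponent = 0.462) {
  k * element_deg^exponent
}

#' Model-1 Dmax scaling analysis
#'
#' Builds windowed motion-energy curves for a grid of element sizes, places
#' the energy threshold (either supplied, fitted to reference Dmax values,
#' or at `cfg$threshold_fraction` of the curves' common maximum - inside the
#' regime where the curves are parallel shifts of one another), reads off
#' Dmax per element and fits the power law.
#'
#' @param elements_deg Element sizes (deg).
#' @param cfg A [model1_config()]; its `threshold_T` is used when set.
#' @param reference Optional data frame (`element_size_deg`, `dmax_deg`) to
#'   fit the threshold against.
#' @param step_grid Step sizes shared by all elements; the default log grid
#'   samples both the small-step plateau and the decay of every curve.
#' @param geom,seed,... Passed to [energy_vs_step()].
#' @return List with `curves`, `threshold_T`, `dmax` (per-element table) and
#'   `power_law`.
#' @export
model1_dmax_scaling <- function(elements_deg = c(1, 2, 4, 8),
                                cfg = model1_config(),
                                reference = NULL,
                                step_grid = exp(seq(log(0.4), log(44),
                                                    length.out = 14)),
                                geom = screen_geometry(), seed = 1L, ...) {
  curves <- lapply(seq_along(elements_deg), function(i) {
    energy_vs_step(elements_deg[i], step_grid, cfg,
                   geom = geom, seed = derive_seed(seed, i), ...)
  })
  threshold_T <- cfg$threshold_T
  if (is.null(threshold_T) && !is.null(reference)) {
    fitted <- fit_energy_threshold(reference, curves, n_starts = 3, seed = seed)
    threshold_T <- fitted$threshold_T
  }
  if (is.null(threshold_T)) {
    hi <- min(vapply(curves, function(cv) max(cv$energy), numeric(1)))
    if (hi <= 0) stop("infeasible threshold: curves share no energy range")
    threshold_T <- cfg$threshold_fraction * hi
  }
  dmax <- dmax_curve_model1(curves, threshold_T)
  list(curves = curves, threshold_T = threshold_T, dmax = dmax,
       power_law = fit_power_law(dmax$element_size_deg, dmax$dmax_deg))
}

#' Configuration of a full pipeline run
#'
#' @param elements_deg Element-size grid (deg).
#' @param n_trials Trials per condition for behavioural synthesis and
#'   Model-2 simulation.
#' @param n_steps Step sizes per element.
#' @param data_csv Optional path to an observed trial CSV; when `NULL` the
#'   reference behaviour is synthesised from the truth power law.
#' @param truth_k,truth_exponent Truth power law for synthetic behaviour.
#' @param geom [screen_geometry()].
#' @param model1 [model1_config()].
#' @param model2 [rd_config()].
#' @param master_seed Master seed recorded in all outputs.
#' @param out_dir Output directory for artifacts (`NULL` for none).
#' @return An object of class `run_config`.
#' @export
run_config <- function(elements_deg = c(1, 2, 4, 8), n_trials = 50,
                       n_steps = 7, data_csv = NULL,
                       truth_k = 5.36, truth_exponent = 0.462,
                       geom = screen_geometry(),
                       model1 = model1_config(n_patterns = 10),
                       model2 = rd_config(),
                       master_seed = 1L, out_dir = NULL) {
  structure(
    list(elements_deg = elements_deg, n_trials = n_trials, n_steps = n_steps,
         data_csv = data_csv, truth_k = truth_k,
         truth_exponent = truth_exponent, geom = geom, model1 = model1,
         model2 = model2, master_seed = as.integer(master_seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full comparison pipeline
#'
#' Obtains reference behaviour (an observed trial CSV or synthetic records
#' from the truth power law), fits its psychometric functions and power law,
#' then runs both models on the same element grid: Model 1 with its energy
#' threshold fitted to the reference Dmax values, Model 2 with its
#' configured parameters. Reports per-model Dmax tables, power-law fits and
#' the standard error S of each model's Dmax predictions against the
#' reference. Deterministic given `master_seed`; artifacts (trial CSVs, fit
#' CSVs, power-law JSON, a manifest with the seed and configuration hash)
#' are written when `out_dir` is set. Input data files are never modified.
#'
#' @param cfg A [run_config()].
#' @param progress Print stage progress.
#' @return An object of class `comparison_report`.
#' @export
run_pipeline <- function(cfg = run_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    if (progress) message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  steps <- lapply(cfg$elements_deg, function(el) {
    transition_steps(predict_reference_dmax(el, cfg$truth_k,
                                            cfg$truth_exponent),
                     n_steps = cfg$n_steps)
  })
  reference <- stage("reference behaviour", {
    if (!is.null(cfg$data_csv)) {
      read_trials(cfg$data_csv)
    } else {
      synth_behavior(cfg$elements_deg, steps, cfg$n_trials,
                     truth_k = cfg$truth_k,
                     truth_exponent = cfg$truth_exponent,
                     seed = derive_seed(cfg$master_seed, 1L))
    }
  })
  ref_fits <- stage("reference psychometrics", {
    fit_psychometric_by_element(reference)
  })
  ref_pl <- fit_power_law(ref_fits$element_size_deg, ref_fits$dmax_deg)
  ref_tbl <- ref_fits[c("element_size_deg", "dmax_deg")]

  m1 <- stage("model 1", {
    model1_dmax_scaling(cfg$elements_deg, cfg$model1, reference = ref_tbl,
                        geom = cfg$geom,
                        seed = derive_seed(cfg$master_seed, 2L))
  })
  m2 <- stage("model 2", {
    simulate_dmax_scaling(cfg$elements_deg, cfg$n_trials, cfg$model2,
                          steps_deg = steps,
                          seed = derive_seed(cfg$master_seed, 3L),
                          progress = progress)
  })

  s_of <- function(pred_tbl, n_params) {
    m <- match(ref_tbl$element_size_deg, pred_tbl$element_size_deg)
    res <- pred_tbl$dmax_deg[m] - ref_tbl$dmax_deg
    sqrt(sum(res^2) / max(1, length(res) - n_params))
  }
  report <- structure(
    list(
      reference = list(trials = reference, fits = ref_fits, power_law = ref_pl),
      model1 = c(m1, list(S_vs_reference = s_of(m1$dmax, 1L))),
      model2 = c(m2, list(
        S_vs_reference = s_of(m2$fits[c("element_size_deg", "dmax_deg")], 0L)
      )),
      power_laws = data.frame(
        source = c("reference", "model1", "model2"),
        k = c(ref_pl$k, m1$power_law$k, m2$power_law$k),
        exponent = c(ref_pl$exponent, m1$power_law$exponent,
                     m2$power_law$exponent),
        S = c(ref_pl$S, m1$power_law$S, m2$power_law$S)
      ),
      master_seed = cfg$master_seed
    ),
    class = "comparison_report"
  )
  if (!is.null(cfg$out_dir)) write_report_artifacts(report, cfg)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  Model 1 S vs reference: %.3f deg (threshold T = %.4g)\n",
              x$model1$S_vs_reference, x$model1$threshold_T))
  cat(sprintf("  Model 2 S vs reference: %.3f deg\n", x$model2$S_vs_reference))
  cat("  power laws (Dmax = k * x^e):\n")
  print(x$power_laws, row.names = FALSE)
  invisible(x)
}

write_report_artifacts <- function(report, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_trials(report$reference$trials, p("reference_trials.csv"))
  write_trials(report$model2$trials, p("model2_trials.csv"))
  utils::write.csv(report$reference$fits, p("reference_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model2$fits, p("model2_fits.csv"), row.names = FALSE)
  utils::write.csv(report$model1$dmax, p("model1_dmax.csv"), row.names = FALSE)
  pl_json <- lapply(split(report$power_laws, report$power_laws$source),
                    function(d) as.list(d[setdiff(names(d), "source")]))
  jsonlite::write_json(pl_json, p("power_laws.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "apparentmotion",
    version = as.character(utils::packageVersion("apparentmotion")),
    master_seed = report$master_seed,
    elements_deg = cfg$elements_deg,
    n_trials = cfg$n_trials,
    config_hash = config_hash(cfg),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(cfg$out_dir)
}

# order-stable hash of the run configuration (no external digest dependency)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 10)),
             collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
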