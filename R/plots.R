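# Figures for pipeline reports (psychometric panels and Dmax scaling).

#' Psychometric panels per element size
#'
#' Observed detection proportions against step size with the fitted
#' cumulative-Gaussian curves, one panel per element size.
#'
#' @param trials Trial-record data frame.
#' @param fits Per-element fit table from [fit_psychometric_by_element()]
#'   (computed from `trials` when `NULL`).
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials, fits = NULL) {
  summ <- condition_summary(trials)
  if (is.null(fits)) fits <- fit_psychometric_by_element(trials)
  summ$proportion <- summ$n_detected / summ$n_total
  curves <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i) {
    d <- summ[summ$element_size_deg == fits$element_size_deg[i], ]
    st <- exp(seq(log(min(d$step_size_deg)), log(max(d$step_size_deg)),
                  length.out = 80))
    data.frame(
      element_size_deg = fits$element_size_deg[i], step_size_deg = st,
      proportion = detection_probability(st, fits$dmax_deg[i],
                                         fits$width_deg[i])
    )
  }))
  lab <- function(x) paste0(signif(as.numeric(x), 3), " deg elements")
  ggplot2::ggplot(summ, ggplot2::aes(.data$step_size_deg, .data$proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~element_size_deg, labeller = ggplot2::as_labeller(lab)) +
    ggplot2::labs(x = "step size (deg)", y = "detection probability") +
    ggplot2::theme_minimal()
}

#' Dmax versus element size on log-log axes
#'
#' Per-source Dmax estimates and their fitted power laws from a
#' comparison report.
#'
#' @param report A `comparison_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_dmax_scaling <- function(report) {
  pts <- rbind(
    data.frame(source = "reference",
               report$reference$fits[c("element_size_deg", "dmax_deg")]),
    data.frame(source = "model1", report$model1$dmax),
    data.frame(source = "model2",
               report$model2$fits[c("element_size_deg", "dmax_deg")])
  )
  rng <- range(pts$element_size_deg)
  lines <- do.call(rbind, lapply(seq_len(nrow(report$power_laws)), function(i) {
    x <- exp(seq(log(rng[1]), log(rng[2]), length.out = 50))
    data.frame(source = report$power_laws$source[i], element_size_deg = x,
               dmax_deg = report$power_laws$k[i] *
                 x^report$power_laws$exponent[i])
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$element_size_deg, .data$dmax_deg,
                                    colour = .data$source)) +
    ggplot2::geom_line(data = lines) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "element size (deg)", y = "Dmax (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render report figures to files
#'
#' Writes the psychometric panels and the Dmax scaling figure for a
#' comparison report. No-op with a warning when the report is empty.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Paths of the written files, invisibly.
#' @export
make_figures <- function(report, dir, width = 7, height = 5, dpi = 150) {
  if (is.null(report$reference) || nrow(report$reference$fits) == 0) {
    warning("empty report: no figures written")
    return(invisible(character(0)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    psychometric = file.path(dir, "psychometric_panels.png"),
    scaling = file.path(dir, "dmax_scaling.png")
  )
  ggplot2::ggsave(paths[["psychometric"]],
                  plot_psychometric(report$model2$trials, report$model2$fits),
                  width = width, height = height, dpi = dpi)
  ggplot2::ggsave(paths[["scaling"]], plot_dmax_scaling(report),
                  width = width, height = height, dpi = dpi)
  invisible(paths)
}
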