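#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline geom_hline
#'   geom_jitter facet_wrap labs theme_minimal stat_summary annotate
NULL

#' Plot a standard curve
#'
#' Included calibration points with the fitted line and its R^2.
#'
#' @param object A [build_standard_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot(object$points, aes(x = .data$x_true, y = .data$k_mean)) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "grey40") +
    geom_point(size = 2) +
    annotate("text", x = min(object$points$x_true),
             y = max(object$points$k_mean), hjust = 0, vjust = 1,
             label = sprintf("R^2 == %.4f", object$r_squared),
             parse = TRUE) +
    labs(x = "Predefined VIC-allele fraction x",
         y = "Transformed fluorescence ratio k'",
         title = sprintf("Standard curve (%s)", object$assay)) +
    theme_minimal()
}

#' Plot per-tissue allele-frequency estimates
#'
#' Per-sample estimates by tissue with the balanced 1:1 line at 0.5 — the
#' standard summary figure of a tissue ASE comparison.
#'
#' @param object An `ase_pipeline` result with unknown samples.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ase_pipeline
#' @export
autoplot.ase_pipeline <- function(object, ...) {
  if (is.null(object$estimates)) {
    abort("Pipeline has no unknown-sample estimates to plot.")
  }
  ggplot(object$estimates, aes(x = .data$tissue, y = .data$x_hat)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                 colour = "grey30") +
    geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    labs(x = NULL, y = "Estimated VIC-allele expression fraction",
         title = "Allele-specific expression by tissue") +
    theme_minimal()
}

#' Plot raw amplification curves with their fitted sigmoids
#'
#' @param data Long-format fluorescence tibble (`well`, `cycle`, `channel`,
#'   `fluorescence`).
#' @param fits Optional [fit_amplification()] output; fitted curves are
#'   overlaid where available.
#' @param wells Optional subset of wells to show.
#' @return A ggplot faceted by well.
#' @export
plot_amplification <- function(data, fits = NULL, wells = NULL) {
  data <- validate_fluorescence(data)
  if (!is.null(wells)) {
    data <- filter(data, .data$well %in% wells)
    if (!is.null(fits)) {
      fits <- filter(fits, .data$well %in% wells)
    }
  }
  p <- ggplot(data, aes(x = .data$cycle, y = .data$fluorescence,
                        colour = .data$channel)) +
    geom_point(size = 0.7, alpha = 0.7) +
    facet_wrap(~well) +
    labs(x = "Cycle", y = "Raw fluorescence", colour = "Channel") +
    theme_minimal()
  if (!is.null(fits)) {
    ok <- filter(fits, .data$converged)
    if (nrow(ok) > 0) {
      grid <- ok |>
        mutate(curve = pmap(list(.data$y0, .data$a, .data$b, .data$c),
                            function(y0, a, b, c) {
                              t <- seq(min(data$cycle), max(data$cycle),
                                       length.out = 200)
                              tibble(cycle = t,
                                     fluorescence = sigmoid4(t, y0, a, b, c))
                            })) |>
        select("well", "channel", "curve") |>
        tidyr::unnest("curve")
      p <- p + geom_line(data = grid, linewidth = 0.4)
    }
  }
  p
}
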