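# ggplot2 visualizations for the main result types.

#' @method autoplot connectome
#' @export
autoplot.connectome <- function(object, ...) {
  tab <- expand_grid(a = seq_len(object$n_regions),
                     b = seq_len(object$n_regions)) |>
    mutate(weight = as.vector(object$weights))
  ggplot(tab, aes(.data$a, .data$b, fill = .data$weight)) +
    geom_raster() +
    scale_fill_viridis_c() +
    scale_y_reverse() +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "weight",
         title = "Structural connectome") +
    theme_minimal()
}

#' @method autoplot nm_simulation
#' @export
autoplot.nm_simulation <- function(object, regions = 1:3, seconds = 4, ...) {
  keep <- rownames(object$eeg)[regions]
  tidy(object) |>
    filter(.data$region %in% keep, .data$time <= seconds) |>
    ggplot(aes(.data$time, .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~region, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "excitatory membrane potential (mV)") +
    theme_minimal()
}

#' @method autoplot hdi_fit
#' @export
autoplot.hdi_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$reference, .data$delta)) +
    geom_point(alpha = 0.7) +
    geom_abline(intercept = object$offset, slope = object$slope,
                color = "firebrick") +
    labs(
      x = "functional degree, balanced model",
      y = "degree change (perturbed - balanced)",
      title = sprintf("Hub disruption index = %.3f (p = %.2g)",
                      object$slope, object$p_value)
    ) +
    theme_minimal()
}

#' Sweep heatmaps of the whole-brain measures
#'
#' One tile per (Vd2, S) model, faceted by condition and measure -- the
#' standard view of how signal variability and symbolic connectivity depend
#' on the E-I control parameter and the coupling strength.
#'
#' @param sr A `study_result`.
#' @param measures Subset of `c("pe", "wsmi", "jpe_inv")`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sr, measures = c("pe", "wsmi", "jpe_inv")) {
  summarize_whole_brain(sr) |>
    filter(.data$measure %in% measures) |>
    ggplot(aes(factor(.data$s), factor(.data$vd2), fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c() +
    facet_grid(measure ~ condition, scales = "free") +
    labs(x = "coupling strength S", y = "inhibitory threshold Vd2 (mV)",
         fill = "value") +
    theme_minimal()
}
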