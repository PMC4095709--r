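#' Plot a fitted ensemble: density overlay and components
#'
#' Histogram of the scores with the fitted mixture density and its
#' weighted components superimposed, the standard diagnostic for mixture
#' fits. Differential components are drawn dashed.
#'
#' @param object A `mix_ensemble` or `mix_fit`.
#' @param data Data frame with `y`; taken from the ensemble object when
#'   omitted.
#' @param bins Histogram bins; default 80.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mix_ensemble
#' @export
autoplot.mix_ensemble <- function(object, bins = 80, ...) {
  plot_mixture_fit(object$best, object$data, bins = bins,
                   differential = object$labels$differential_normals)
}

#' @rdname autoplot.mix_ensemble
#' @method autoplot mix_fit
#' @export
autoplot.mix_fit <- function(object, data, bins = 80, ...) {
  plot_mixture_fit(object, data, bins = bins)
}

plot_mixture_fit <- function(fit, data, bins = 80, differential = integer()) {
  data <- as_fit_data(data)
  y <- data$y
  grid <- seq(min(y), max(y), length.out = 512)
  m <- fit$model
  dens <- component_densities(m, grid)
  wts <- component_weights(m)
  comp <- purrr::map_dfr(seq_along(wts), function(j) {
    nm <- colnames(dens)[j]
    tibble::tibble(
      y = grid, density = dens[, j] * wts[j], component = nm,
      differential = !startsWith(nm, "N") ||
        as.integer(sub("N", "", nm)) %in% differential
    )
  })
  total <- tibble::tibble(y = grid, density = as.numeric(dens %*% wts))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$y)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density, colour = .data$component,
                                    linetype = .data$differential)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linewidth = 0.9) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "difference score y", y = "density",
                  title = sprintf("%s fit (K = %d)", m$model_class, m$K)) +
    ggplot2::theme_minimal()
}

#' QQ plot of a fitted model against the data
#'
#' @inheritParams qq_table
#' @return A ggplot object.
#' @export
plot_model_qq <- function(fit, data = NULL, n_points = 200) {
  qq <- qq_table(fit, data, n_points = n_points)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$model_quantile,
                                   y = .data$data_quantile)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "model quantiles", y = "data quantiles") +
    ggplot2::theme_minimal()
}

#' Plot TPR across replicates of a simulation study
#'
#' @param results Tibble from [run_simulation_study()].
#' @return A ggplot object.
#' @export
plot_study_tpr <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$class, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "true positive rate") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
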