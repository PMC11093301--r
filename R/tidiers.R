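# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation metrics
#'
#' @param x an `"fchybrid_cv"` object
#' @param ... unused
#' @return long tibble (`fold`, `metric`, `value`)
#' @exportS3Method generics::tidy
tidy.fchybrid_cv <- function(x, ...) {
  tidyr::pivot_longer(
    x$fold_metrics[c("fold", "ACC", "SEN", "SPE", "FPR", "FNR",
                     "Precision", "F1")],
    cols = -"fold", names_to = "metric", values_to = "value")
}

#' One-row cross-validation summary
#'
#' @param x an `"fchybrid_cv"` object
#' @param ... unused
#' @return one-row tibble of mean metrics plus fold count and best fold
#' @exportS3Method generics::glance
glance.fchybrid_cv <- function(x, ...) {
  dplyr::mutate(x$mean_metrics,
                n_folds = nrow(x$fold_metrics),
                best_fold = x$best_fold)
}

#' Plot per-fold metrics
#'
#' @param object an `"fchybrid_cv"` object
#' @param metrics which metrics to show
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.fchybrid_cv <- function(object,
                                 metrics = c("ACC", "SEN", "SPE", "F1"),
                                 ...) {
  df <- dplyr::filter(tidy(object), .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = "value",
                  title = "Cross-validated classification metrics") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a region-importance ranking
#'
#' @param object a [rank_regions()] result
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.region_ranking <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$rank)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(utils::head(df, attr(object, "top_k")),
                  ggplot2::aes(x = .data$importance, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "sum |conv weight|", y = NULL,
                  title = sprintf("Top regions (%s branch)",
                                  attr(object, "branch"))) +
    ggplot2::theme_minimal()
}

#' Plot a frequency-band importance ranking
#'
#' @param object a [rank_bands()] result
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.band_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$importance)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$top), width = diff(df$f_lo[1:2]) * 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "frequency (Hz)", y = "|compression weight|",
                  title = "Frequency-band importance") +
    ggplot2::theme_minimal()
}

#' Heatmap of a wavelet-coherence map
#'
#' @param wc Q x T coherence matrix from [wavelet_coherence()]
#' @param grid the matching [frequency_grid()]
#' @return a ggplot
#' @export
plot_coherence <- function(wc, grid) {
  df <- expand.grid(t = seq_len(ncol(wc)), f = grid$centers)
  df$coherence <- as.vector(t(wc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$f,
                                   fill = .data$coherence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (samples)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
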