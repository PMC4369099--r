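#' Plot a threshold-versus-count curve
#'
#' Log-log particle count against intensity threshold, with the chosen
#' plateau threshold marked. The flat shelf is the range over which the
#' particle count is insensitive to the cutoff.
#'
#' @param object A [threshold_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.threshold_curve <- function(object, ...) {
  df <- object$curve[object$curve$count > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "intensity threshold", y = "particles above threshold")
  if (!is.na(object$chosen_threshold))
    p <- p + ggplot2::geom_vline(xintercept = object$chosen_threshold,
                                 linetype = "dashed", colour = "red")
  p
}

#' Plot a molecule-count histogram
#'
#' Per-cell count distribution in the standard binning (width 3 up to 50
#' molecules, width 10 from 50 to 300).
#'
#' @param counts Per-cell counts, or a one-row tibble from
#'   [summarize_counts()].
#' @return A ggplot.
#' @export
plot_count_histogram <- function(counts) {
  h <- if (is.data.frame(counts) && "histogram" %in% names(counts))
    counts$histogram[[1]] else count_histogram(counts)
  h$mid <- ifelse(is.finite(h$bin_hi), (h$bin_lo + h$bin_hi) / 2, h$bin_lo + 5)
  h$width <- ifelse(is.finite(h$bin_hi), h$bin_hi - h$bin_lo, 10)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$density,
                                  width = .data$width)) +
    ggplot2::geom_col(fill = "firebrick", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "molecules per cell", y = "fraction of cells")
}

#' Mean-versus-median and CV-versus-mean panels
#'
#' `plot_mean_median()` shows per-gene median against mean counts with the
#' OLS fit and the identity line: unimodal genes hug both, heterogeneous
#' genes fall below. `plot_cv_mean()` shows the coefficient of variation
#' against the mean with the Poisson reference curve `1/sqrt(mean)`.
#'
#' @param summaries Tibble with `mean`, `median`, `cv` columns (one row per
#'   gene-cell-type pair).
#' @return A ggplot.
#' @export
plot_mean_median <- function(summaries) {
  fit <- mean_median_regression(summaries)
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$mean, y = .data$median)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "black") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "mean molecule count", y = "median molecule count",
                  subtitle = sprintf("Y = %.2fX %+.2f, Pearson r = %.2f",
                                     fit$slope, fit$intercept, fit$pearson_r))
}

#' @rdname plot_mean_median
#' @export
plot_cv_mean <- function(summaries) {
  ref <- tibble(mean = exp(seq(log(max(min(summaries$mean), 0.5)),
                               log(max(summaries$mean)), length.out = 100)))
  ref$cv <- poisson_reference(ref$mean)
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$mean, y = .data$cv)) +
    ggplot2::geom_line(data = ref, colour = "black") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean molecule count", y = "coefficient of variation")
}

#' Max-projection of a stack with detected spots overlaid
#'
#' Diagnostic view: the maximum-intensity z-projection of one channel with
#' spot positions (and nuclear status) drawn on top.
#'
#' @param experiment A `fish_experiment` with rendered stacks.
#' @param spots Spot tibble from [detect_spots()].
#' @param channel Channel name to display.
#' @return A ggplot.
#' @export
plot_spot_overlay <- function(experiment, spots, channel = "rna") {
  st <- experiment$stacks[[channel]]
  if (is.null(st)) abort_input(paste("no rendered stack for channel", channel))
  proj <- apply(st, c(2, 3), max)
  df <- tidyr::expand_grid(y = seq_len(nrow(proj)) - 1,
                           x = seq_len(ncol(proj)) - 1)
  df$value <- as.vector(t(proj))
  sp <- spots[spots$channel == channel, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = sp, ggplot2::aes(colour = .data$is_nuclear),
                        shape = 1, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "nuclear")
}
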