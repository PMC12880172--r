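#' Plot a signal track
#'
#' @param object A `signal_track`.
#' @param ... Unused.
#' @return A ggplot: window midpoint vs value, one facet per contig.
#' @export
autoplot.signal_track <- function(object, ...) {
  dat <- as_tibble(object)
  dat$mid <- (dat$start + dat$end) / 2
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$score)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = paste0("signal (", attr(object, "scale"), ")"))
}

#' Plot a peak-centered signal matrix
#'
#' `type = "profile"` draws the average intensity around the peak center;
#' `type = "heatmap"` draws the per-peak rows, ordered by descending row sum
#' (common heatmap practice).
#'
#' @param object A `signal_matrix`.
#' @param type `"profile"` or `"heatmap"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signal_matrix <- function(object, type = c("profile", "heatmap"),
                                   ...) {
  type <- match.arg(type)
  long <- tidy(object)
  if (type == "profile") {
    prof <- long |>
      group_by(.data$position) |>
      summarise(mean_signal = mean(.data$signal), .groups = "drop")
    ggplot2::ggplot(prof, ggplot2::aes(x = .data$position,
                                       y = .data$mean_signal)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "distance from peak center (bp)", y = "mean signal")
  } else {
    ord <- order(rowSums(object$values), decreasing = TRUE)
    long$row <- match(long$peak, ord)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$row,
                                       fill = .data$signal)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "distance from peak center (bp)", y = "peak rank",
                    fill = "signal")
  }
}

#' Cross-sample peak-intensity scatterplot
#'
#' Log-scale scatter of per-peak total signal between two samples — the plot
#' on which a correct normalization places the cloud on the diagonal and a
#' biased one shifts it systematically off it.
#'
#' @param totals_x,totals_y [peak_totals()] tibbles for the same peak list in
#'   two samples.
#' @param labels Axis labels (length 2).
#' @return A ggplot.
#' @export
plot_peak_scatter <- function(totals_x, totals_y,
                              labels = c("sample A", "sample B")) {
  dat <- tibble(x = totals_x$peak_total, y = totals_y$peak_total)
  ggplot2::ggplot(dat, ggplot2::aes(x = log1p(.data$x), y = log1p(.data$y))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = paste0("log1p signal, ", labels[1]),
                  y = paste0("log1p signal, ", labels[2]))
}
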