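#' Composition histogram
#'
#' Figure-style view of a night's SWA composition: per-bin percentage of
#' late-fast (blue, plotted upward) and early-fast (red, downward from 100)
#' coupled events, with gaps where a bin has no coupled events. Requires
#' ggplot2 (suggested dependency).
#'
#' @param bins data.frame from [bin_composition()] or
#'   [normalized_nrem_bins()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_composition <- function(bins, title = "SWA composition") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_composition requires the ggplot2 package")
  b <- bins[!is.na(bins$pct_lf), , drop = FALSE]
  b$t_mid_min <- (b$t_start_s + b$t_end_s) / 2 / 60
  width <- if (NROW(b)) (b$t_end_s[1L] - b$t_start_s[1L]) / 60 * 0.9 else 1
  ggplot2::ggplot(b) +
    ggplot2::geom_col(ggplot2::aes(x = .data$t_mid_min, y = .data$pct_lf),
                      fill = "steelblue4", width = width) +
    ggplot2::geom_col(ggplot2::aes(x = .data$t_mid_min,
                                   y = -(100 - .data$pct_lf)),
                      fill = "firebrick3", width = width) +
    ggplot2::scale_y_continuous(labels = function(v) abs(v),
                                limits = c(-100, 100)) +
    ggplot2::labs(x = "time (min)", y = "% late-fast (up) / % early-fast (down)",
                  title = title) +
    ggplot2::theme_minimal()
}
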