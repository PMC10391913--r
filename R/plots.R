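#' Genome-wide view of windowed divergence statistics
#'
#' FST along the genome with flagged windows highlighted when present.
#'
#' @param windows A [window_stats()] (optionally [select_top_windows()])
#'   tibble.
#' @return A ggplot.
#' @export
plot_windows <- function(windows) {
  d <- dplyr::filter(windows, .data$usable)
  p <- ggplot2::ggplot(d, ggplot2::aes((.data$start + .data$end) / 2e6,
                                       .data$fst)) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST]))
  if ("flagged" %in% names(windows)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 0.6) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                             `TRUE` = "red3"),
                                  name = "top joint quantile")
  } else {
    p + ggplot2::geom_point(size = 0.6, color = "grey40")
  }
}

#' Joint FST / pi-ratio scatter of windows
#'
#' The classic two-axis selection plot: each usable window by its log2
#' pi-ratio (x) and FST (y), with the joint top-quantile corner highlighted
#' when [select_top_windows()] has been applied.
#'
#' @param windows A window tibble.
#' @return A ggplot.
#' @export
plot_fst_pi <- function(windows) {
  d <- dplyr::filter(windows, .data$usable)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$log2_pi_ratio, .data$fst)) +
    ggplot2::labs(x = expression(log[2] ~ pi ~ ratio), y = expression(F[ST]))
  if ("flagged" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$flagged),
                                 size = 0.6) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                             `TRUE` = "red3"),
                                  name = "joint top quantile") +
      ggplot2::geom_hline(yintercept = attr(windows, "fst_threshold"),
                          linetype = "dashed", color = "grey30") +
      ggplot2::geom_vline(xintercept = attr(windows, "ratio_threshold"),
                          linetype = "dashed", color = "grey30")
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, color = "grey40")
  }
  p
}
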