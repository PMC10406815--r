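#' Primary-vs-distant frequency scatter plot
#'
#' Thin ggplot2 wrapper around [site_scatter()]: one point per barcode, with
#' barcodes unique to the primary tumour on the x-axis and dashed reference
#' lines at 1% frequency.
#'
#' @param scatter a data frame from [site_scatter()].
#' @param ref_line reference frequency for the dashed lines (default 0.01).
#' @return a ggplot object.
#' @export
plot_site_scatter <- function(scatter, ref_line = 0.01) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$freq_primary,
                               y = .data$freq_distant,
                               colour = .data$unique_to_primary)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ref_line, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = ref_line, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "frequency in primary tumour",
                  y = "frequency at distant site")
}

#' Observed vs expected clone appearance plot
#'
#' Clones ranked by P0 frequency against the number of tumours containing
#' them: the Monte-Carlo neutral expectation in red, the empirical counts in
#' blue, with dot size showing the appearance fold change.
#'
#' @param summary a data frame from [presence_summary()].
#' @return a ggplot object.
#' @export
plot_presence_summary <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  size <- pmin(ifelse(is.finite(summary$fold_change) & summary$fold_change > 0,
                      summary$fold_change, 1), 10)
  ggplot2::ggplot(summary, ggplot2::aes(y = .data$p0_rank)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$expected), colour = "red",
                        alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(x = .data$observed, size = size),
                        colour = "blue", alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_continuous(name = "fold change", range = c(0.5, 4)) +
    ggplot2::labs(x = "tumours containing the barcode",
                  y = "barcode rank at P0 (1 = most frequent)")
}
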