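#' Plot a regional rate table
#'
#' Bar chart of mean pairwise distances per gene region with bootstrap
#' error bars, one panel per distance method.
#'
#' @param tbl Output of [region_rate_table()].
#' @return A ggplot.
#' @export
plot_region_rates <- function(tbl) {
  long <- tbl |>
    tidyr::pivot_longer(cols = c("jc", "tn"), names_to = "method",
                        values_to = "value") |>
    mutate(se = ifelse(.data$method == "jc", .data$jc_se, .data$tn_se),
           method = toupper(.data$method))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = factor(.data$region,
                                          levels = unique(tbl$region)),
                               y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "mean pairwise distance (subs/site)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
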