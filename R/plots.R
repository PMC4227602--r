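#' Heatmap of pairwise D'
#'
#' @param pairwise Output of [ld_pairwise()].
#' @param marker_order Marker ids in map order.
#' @return A ggplot object.
#' @export
plot_dprime <- function(pairwise, marker_order = NULL) {
  if (is.null(marker_order)) {
    marker_order <- unique(c(pairwise$marker1, pairwise$marker2))
  }
  df <- bind_rows(
    pairwise,
    rename(pairwise, marker1 = "marker2", marker2 = "marker1"),
    tibble(marker1 = marker_order, marker2 = marker_order, dprime = 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$marker1, marker_order),
    factor(.data$marker2, marker_order),
    fill = .data$dprime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "D'") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Association overview plot
#'
#' -log10 allelic p-value per variant, with the significance threshold drawn.
#'
#' @param association Output of [associate()].
#' @param alpha Significance threshold line (default 0.05).
#' @return A ggplot object.
#' @export
plot_association <- function(association, alpha = 0.05) {
  df <- filter(association, .data$complete)
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$id, -.data$allelic_p),
    -log10(.data$allelic_p))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname hap_em
#' @param object A `hap_em` fit.
#' @export
autoplot.hap_em <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$haplotype, .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "haplotype", y = "estimated frequency") +
    ggplot2::theme_minimal()
}
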