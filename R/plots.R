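#' Plot per-site rate-constant summaries
#'
#' Point-and-error-bar display of site means with +/- one standard error,
#' faceted by rate kind (methylation / demethylation differ by ~3 orders of
#' magnitude, so panels have free y scales).
#'
#' @param summary Output of [summarize_site_rates()].
#' @return A ggplot object.
#' @export
plot_site_rates <- function(summary) {
  check_cols(summary, c("site_id", "kind", "mean", "se"), "rate summary")
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$site_id, y = .data$mean)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(rate ~ constant ~ (day^-1))) +
    ggplot2::theme_minimal()
}

#' Stacked relative-abundance bars by taxon
#'
#' @param fractions Output of [relative_abundance()] (optionally after
#'   [lump_rare()]).
#' @return A ggplot object.
#' @export
plot_taxa_bars <- function(fractions) {
  check_cols(fractions, "sample_id", "fraction table")
  long <- tidyr::pivot_longer(
    fractions, -"sample_id",
    names_to = "taxon", values_to = "fraction"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$sample_id, y = .data$fraction, fill = .data$taxon)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn pcoa_ordination Ordination scatter of the first two axes,
#'   optionally coloured by a metadata factor.
#' @param object An `hg_pcoa` object.
#' @param metadata Optional tibble with `sample_id` and `colour_by`.
#' @param colour_by Metadata column to colour points by.
#' @exportS3Method ggplot2::autoplot
autoplot.hg_pcoa <- function(object, metadata = NULL, colour_by = "site", ...) {
  dat <- object$coordinates
  if (!is.null(metadata)) {
    dat <- left_join(dat, metadata, by = "sample_id")
  }
  lab <- function(i) {
    sprintf("PCo%d (%.1f%%)", i, 100 * object$explained_fraction[i])
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  if (!is.null(metadata) && colour_by %in% names(dat)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}
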