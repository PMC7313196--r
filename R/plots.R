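#' Scaffold feature-space plot
#'
#' GC against fold-coverage (log scale) for all profiled scaffolds, point
#' size by length, colored by taxonomy label or bin — the visual on which
#' manual holobiont binning is traditionally done.
#'
#' @param profiles A [profile_scaffolds()] table.
#' @param bins Optional `bin_set`; when given, points are colored by bin.
#' @return A ggplot object.
#' @export
plot_scaffold_profiles <- function(profiles, bins = NULL) {
  d <- profiles
  d$colour <- d$taxonomy_label
  legend <- "taxonomy"
  if (!is.null(bins)) {
    idx <- match(d$scaffold_id, bins$membership$scaffold_id)
    d$colour <- bins$membership$bin_id[idx]
    legend <- "bin"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gc_percent,
                                  y = pmax(.data$coverage, 1e-3),
                                  colour = .data$colour,
                                  size = .data$length)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GC (%)", y = "fold coverage", colour = legend,
                  size = "length (bp)") +
    ggplot2::theme_minimal()
}

#' @method autoplot bin_set
#' @export
autoplot.bin_set <- function(object, profiles, ...) {
  plot_scaffold_profiles(profiles, bins = object)
}

#' @method autoplot relatedness_matrix
#' @export
autoplot.relatedness_matrix <- function(object, ...) {
  d <- object$pairs |>
    tidyr::pivot_longer(c("aai", "ssu_identity"),
                        names_to = "measure", values_to = "identity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genome_a, y = .data$genome_b,
                                  fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
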