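#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pairwise FST table
#'
#' Tile plot of pairwise FST with autosomal values in the upper-right and X
#' values in the lower-left triangle, labelled with `estimate (se)`.
#'
#' @param object An [fst_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fst_table
#' @export
autoplot.fst_table <- function(object, ...) {
  pops <- unique(c(object$pop_a, object$pop_b))
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    ia = match(.data$pop_a, pops), ib = match(.data$pop_b, pops),
    row = ifelse(.data$chrom_set == "autosomes",
                 pmin(.data$ia, .data$ib), pmax(.data$ia, .data$ib)),
    col = ifelse(.data$chrom_set == "autosomes",
                 pmax(.data$ia, .data$ib), pmin(.data$ia, .data$ib)),
    label = sprintf("%.3f\n(%.3f)", .data$fst, .data$se))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$col, seq_along(pops), pops),
                                   y = factor(.data$row, rev(seq_along(pops)),
                                              rev(pops)))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fst), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(F[ST])) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "upper right: autosomes; lower left: X") +
    ggplot2::theme_minimal()
}

#' Plot called ROH segments along chromosomes
#'
#' @param object A segment tibble from [roh_call()] / [roh_filter()].
#' @param ... Unused.
#' @return A ggplot object with one horizontal segment per ROH.
#' @export
plot_roh <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                               y = .data$sample, yend = .data$sample,
                               colour = .data$quality)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "Phred") +
    ggplot2::theme_minimal()
}

#' Plot heterozygosity against ROH burden
#'
#' The classic diagnostic of autozygosity: individual heterozygosity is
#' negatively correlated with the number (and total length) of ROH
#' segments.
#'
#' @param het Tibble from [individual_heterozygosity()].
#' @param roh Segment tibble from [roh_filter()].
#' @return A ggplot object.
#' @export
plot_het_vs_roh <- function(het, roh) {
  burden <- dplyr::count(roh, .data$sample, name = "n_roh")
  df <- dplyr::left_join(het, burden, by = "sample")
  df$n_roh[is.na(df$n_roh)] <- 0L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_roh,
                                   y = .data$heterozygosity * 100,
                                   colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ROH segments", y = "heterozygosity (%)") +
    ggplot2::theme_minimal()
}
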