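#' Graphical-genotype plot
#'
#' Displays donor (blue) and recipient (yellow) genome segments along the
#' chromosomes, haplotype-resolved (two rows per IL), in the style customary
#' for introgression libraries.
#'
#' @param object An `il_population` (or any `il_pop` with a `map` passed).
#' @param ils,chroms Subset of ILs / chromosomes to draw (defaults: all).
#' @param map Genetic map; defaults to `object$map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.il_population <- function(object, ils = seq_len(object$n),
                                   chroms = NULL, map = object$map, ...) {
  gg <- graphical_genotype(object, ils = ils, chroms = chroms, map = map)
  gg$row <- gg$il + (gg$haplotype - 1) * 0.5
  ggplot2::ggplot(gg, ggplot2::aes(x = .data$pos, y = .data$row,
                                   fill = .data$allele)) +
    ggplot2::geom_tile(height = 0.45) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(donor = "#2166AC",
                                          recipient = "#FFD92F")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position (cM)", y = "introgression line",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.il_population
#' @export
plot_graphical_genotype <- function(object, ...) autoplot.il_population(object, ...)

#' Boxplots of the per-replicate Z_S distribution
#'
#' One box per scheme of the donor genome proportion of the target segments
#' (Z_S) across replicates; schemes with unstable target-segment retention
#' show visibly larger boxes.
#'
#' @param x An `il_experiment`.
#' @param schemes Optional subset of scheme names.
#' @return A ggplot object.
#' @export
plot_zs_distribution <- function(x, schemes = NULL) {
  stopifnot(inherits(x, "il_experiment"))
  d <- x$replicates
  if (!is.null(schemes)) d <- dplyr::filter(d, .data$scheme %in% schemes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scheme, y = .data$Z_S)) +
    ggplot2::geom_boxplot(fill = "#2166AC", alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "Z_S (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_zs_distribution
#' @param object,... For the `autoplot()` method.
#' @export
autoplot.il_experiment <- function(object, ...) plot_zs_distribution(object, ...)
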