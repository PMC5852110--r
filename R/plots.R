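#' Heatmap of a Sorensen-Dice matrix
#'
#' Tiles the taxon-by-substructure coefficients with rows and columns in
#' the hierarchical-clustering order computed by [sd_matrix()].
#'
#' @param object An `sd_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sd_matrix <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(taxon = factor(.data$taxon, levels = object$row_order),
                  substructure = factor(.data$substructure,
                                        levels = object$col_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substructure, y = .data$taxon,
                                   fill = .data$sd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Sorensen-Dice") +
    ggplot2::labs(x = "Brain substructure", y = "Taxon",
                  title = paste0("Sorensen-Dice similarity (",
                                 object$item_kind, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' MDS plot of leading-fold-change sample distances
#'
#' @param object A `sample_distances` object from
#'   [leading_fc_distances()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_distances <- function(object, ...) {
  ggplot2::ggplot(object$mds,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               colour = .data$substructure)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Leading log2-FC dim 1", y = "Leading log2-FC dim 2",
                  title = paste0("MDS of sample distances (top ",
                                 object$n_top, " genes)")) +
    ggplot2::theme_minimal()
}

#' Stacked bars of shared-GO counts by slim
#'
#' @param stacked Tibble from [slim_stacked_counts()].
#' @return A ggplot object, one facet per substructure.
#' @export
plot_slim_counts <- function(stacked) {
  ggplot2::ggplot(stacked,
                  ggplot2::aes(x = .data$taxon, y = .data$n_gos,
                               fill = .data$slim)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~substructure) +
    ggplot2::labs(x = "Taxon", y = "Shared GO terms", fill = "Slim") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
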