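#' Heatmap of cut-set gene expression across samples
#'
#' Tile plot of z-scores for the genes of a cut set over the samples of an
#' expression profile, split at the expression-call threshold: the target
#' gene should stay expressed while its partners are silenced in the
#' samples where the cut explains essentiality.
#'
#' @param profile an `expr_profile`.
#' @param genes genes to show (e.g. one gMCS).
#' @param threshold call threshold drawn as the midpoint of the fill scale.
#' @return a ggplot object.
#' @export
plot_expression_heatmap <- function(profile, genes,
                                    threshold = attr(profile, "threshold") %||% 5) {
  smp <- setdiff(names(profile), "gene")
  long <- tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(profile), .data$gene %in% genes),
    cols = dplyr::all_of(smp), names_to = "sample", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$z)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2(midpoint = threshold,
                                  low = "#2166AC", mid = "white",
                                  high = "#B2182B",
                                  name = "z-score") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cut-set gene expression",
                  subtitle = sprintf("white at the call threshold z = %g",
                                     threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Sensitivity versus partner expression
#'
#' Scatter of the per-unit sensitivity score against the partner-gene
#' expression summary, coloured by the "any partner expressed" flag. Units
#' with an expressed escape route are expected to sit high (less
#' sensitive).
#'
#' @param records a [sensitivity_records()] tibble.
#' @return a ggplot object.
#' @export
plot_partner_sensitivity <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$partner_expr, y = .data$score,
                               colour = .data$any_partner_expressed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#B2182B", `FALSE` = "#2166AC"),
      name = "partner expressed") +
    ggplot2::labs(x = "partner expression (summary)",
                  y = "sensitivity score",
                  title = "Escape-route expression vs sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_gmcs_sizes
#' @export
autoplot.gmcs_set <- function(object, ...) plot_gmcs_sizes(object, ...)

#' Bar chart of enumerated cut-set sizes
#'
#' @param object,x a `gmcs_set`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_gmcs_sizes <- function(x, ...) {
  tbl <- tidy.gmcs_set(x)
  tbl$label <- vapply(strsplit(tbl$genes, ","), function(g)
    paste(g, collapse = "\n"), character(1))
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$label,
                                                       .data$size),
                                    y = .data$size,
                                    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes in cut set",
                  title = "Genetic minimal cut sets") +
    ggplot2::theme_minimal()
}
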