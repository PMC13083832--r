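#' Allele-frequency heatmap
#'
#' Tile plot of a long frequency table (alleles on the y axis, groups on x),
#' the standard display for resistance-allele frequencies across populations.
#' Rows and columns follow the co-clustering order of [frequency_matrix()].
#'
#' @param table Output of [allele_frequencies()].
#' @param grouping Metadata columns forming the group axis.
#' @return A ggplot object.
#' @export
plot_frequency_heatmap <- function(table, grouping = c("taxon", "site")) {
  fm <- frequency_matrix(table, grouping = grouping)
  df <- tibble::as_tibble(as.table(fm$matrix), .name_repair = "minimal")
  names(df) <- c("allele", "group", "frequency")
  df$allele <- factor(df$allele,
                      levels = rownames(fm$matrix)[fm$row_order])
  df$group <- factor(df$group, levels = colnames(fm$matrix)[fm$col_order])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$allele,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Diversity statistics panel
#'
#' Bar panel of theta-pi, Watterson's theta and Tajima's D per group.
#'
#' @param stats Output of [diversity_summary()].
#' @param grouping Columns identifying the groups.
#' @return A ggplot object.
#' @export
plot_diversity <- function(stats, grouping = "taxon") {
  df <- stats |>
    dplyr::mutate(group = apply(stats[, grouping, drop = FALSE], 1, paste,
                                collapse = "/")) |>
    tidyr::pivot_longer(cols = c("theta_pi", "theta_w", "tajima_d"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.pca_dosage <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df$colour <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
    ggplot2::labs(colour = NULL)
}

#' @export
autoplot.haplotype_network <- function(object, seed = 42, ...) {
  gr <- as_igraph(object)
  set.seed(seed)
  lay <- igraph::layout_with_fr(gr, weights = igraph::E(gr)$weight)
  nodes <- tibble::tibble(
    x = lay[, 1], y = lay[, 2],
    count = object$nodes$count,
    is_median = object$nodes$is_median)
  edges <- tibble::tibble(
    x = lay[object$edges$from, 1], y = lay[object$edges$from, 2],
    xend = lay[object$edges$to, 1], yend = lay[object$edges$to, 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = pmax(.data$count, 1),
                                     shape = .data$is_median)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(size = "haplotypes", shape = "median") +
    ggplot2::theme_void()
}
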