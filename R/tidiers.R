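#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pca_dosage <- function(x, ...) x$scores

#' @export
glance.pca_dosage <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = ncol(x$scores) - 1L,
    explained_variance = sum(x$explained_variance))
}

#' @export
tidy.haplotype_network <- function(x, ...) {
  dplyr::mutate(
    x$nodes[, c("id", "key", "count", "is_median")],
    labels = vapply(x$nodes$composition, function(tb)
      paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ";"),
      character(1)))
}

#' @export
glance.haplotype_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_median = sum(x$nodes$is_median),
    n_edges = nrow(x$edges),
    n_shared = nrow(shared_nodes(x)),
    total_count = sum(x$nodes$count),
    epsilon = x$epsilon,
    converged = x$converged)
}

#' @export
tidy.geno_matrix <- function(x, ...) {
  dplyr::mutate(x$variants,
                alts = vapply(x$variants$alts, paste, character(1),
                              collapse = ","))
}

#' @export
glance.geno_matrix <- function(x, ...) {
  seg <- segregating_sites(x)
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_samples = length(x$samples),
    S = seg$S,
    n_multiallelic = seg$n_multiallelic)
}

#' @export
tidy.copy_number_table <- function(x, ...) {
  tidyr::expand_grid(sample_id = x$samples, gene_id = x$genes$gene_id) |>
    dplyr::mutate(copies = as.vector(t(x$copies)))
}
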