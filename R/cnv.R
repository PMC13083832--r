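#' Classify copy numbers into amplification / deletion / normal
#'
#' Baseline ploidy is 2 for autosomal genes; X-chromosome genes use 2 for
#' females, 1 for males, and `x_unknown` for samples of unknown sex (when
#' `x_unknown` is `NULL` those sample-gene pairs are skipped with a warning).
#' A sample is `amp` above its baseline, `del` below, `normal` at it; zero
#' copies additionally raise the complete-deletion flag.
#'
#' @param cnt A [copy_number_table()].
#' @param samples Sample metadata tibble (`sample_id`, `taxon`, `sex`, ...).
#' @param x_unknown Baseline for unknown-sex samples at X-linked genes
#'   (default 2), or `NULL` to skip them.
#' @return A tibble of calls: `sample_id`, `gene_id`, `family`, `chrom`,
#'   `copies`, `baseline`, `state`, `complete_deletion`.
#' @export
classify_cnv <- function(cnt, samples, x_unknown = 2L) {
  stopifnot(inherits(cnt, "copy_number_table"))
  samples <- tibble::as_tibble(samples)
  idx <- match(cnt$samples, samples$sample_id)
  if (anyNA(idx)) {
    stop("copy-number table contains samples absent from the metadata",
         call. = FALSE)
  }
  meta <- samples[idx, , drop = FALSE]
  long <- tidyr::expand_grid(
    s = seq_along(cnt$samples), g = seq_len(nrow(cnt$genes)))
  out <- tibble::tibble(
    sample_id = cnt$samples[long$s],
    gene_id = cnt$genes$gene_id[long$g],
    family = cnt$genes$family[long$g],
    chrom = cnt$genes$chrom[long$g],
    copies = cnt$copies[cbind(long$s, long$g)]
  )
  sex <- if ("sex" %in% names(meta)) meta$sex[long$s] else
    rep("unknown", nrow(long))
  on_x <- out$chrom %in% c("X", "chrX")
  out$baseline <- ifelse(!on_x, 2L,
                         ifelse(sex == "M", 1L, ifelse(sex == "F", 2L, NA_integer_)))
  if (anyNA(out$baseline)) {
    if (is.null(x_unknown)) {
      n_skip <- sum(is.na(out$baseline))
      warning(n_skip, " X-linked sample-gene pair(s) with unknown sex skipped",
              call. = FALSE)
      out <- out[!is.na(out$baseline), , drop = FALSE]
    } else {
      out$baseline[is.na(out$baseline)] <- as.integer(x_unknown)
    }
  }
  out$state <- ifelse(out$copies > out$baseline, "amp",
                      ifelse(out$copies < out$baseline, "del", "normal"))
  out$complete_deletion <- out$copies == 0L
  out
}

#' CNV frequencies per group and gene
#'
#' For each (group, gene) the percentage of assayed samples in each CNV state
#' (`amp`, `del`), plus the maximum copy number observed. Percentages follow
#' the field's reporting convention (0-100).
#'
#' @param calls Output of [classify_cnv()].
#' @param samples Sample metadata tibble.
#' @param grouping Metadata columns to group by (default `c("taxon", "site")`).
#' @return A tibble: grouping columns, `gene_id`, `family`, `chrom`, `state`,
#'   `n_state`, `n_assayed`, `frequency_pct`, `max_copies`.
#' @export
cnv_frequencies <- function(calls, samples, grouping = c("taxon", "site")) {
  stopifnot(nrow(calls) > 0L)
  tbl <- dplyr::inner_join(calls, tibble::as_tibble(samples), by = "sample_id")
  per_gene <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(grouping, "gene_id", "family", "chrom")))) |>
    dplyr::summarise(
      n_assayed = dplyr::n(),
      max_copies = max(.data$copies),
      amp = sum(.data$state == "amp"),
      del = sum(.data$state == "del"),
      .groups = "drop")
  per_gene |>
    tidyr::pivot_longer(cols = c("amp", "del"), names_to = "state",
                        values_to = "n_state") |>
    dplyr::mutate(frequency_pct = round(100 * .data$n_state / .data$n_assayed,
                                        2)) |>
    dplyr::relocate(dplyr::all_of(c(grouping, "gene_id", "family", "chrom",
                                    "state", "n_state", "n_assayed",
                                    "frequency_pct", "max_copies")))
}

#' Count genes carrying CNVs, by chromosome and by family
#'
#' A gene counts once towards the `amp` tally when at least one sample
#' carries an amplification, and once towards `del` when at least one sample
#' carries a deletion — so a gene amplified in some individuals and deleted
#' in others appears in both tallies, while `n_genes_cnv` counts it once.
#'
#' @param calls Output of [classify_cnv()].
#' @param by Gene columns to stratify by (default `"family"`; use
#'   `c("family", "chrom")` for the per-arm breakdown).
#' @return A tibble: `by` columns, `n_genes_cnv`, `n_genes_amp`,
#'   `n_genes_del`, `max_copies`.
#' @export
cnv_gene_counts <- function(calls, by = "family") {
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "gene_id")))) |>
    dplyr::summarise(
      any_amp = any(.data$state == "amp"),
      any_del = any(.data$state == "del"),
      max_copies = max(.data$copies),
      .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_genes_cnv = sum(.data$any_amp | .data$any_del),
      n_genes_amp = sum(.data$any_amp),
      n_genes_del = sum(.data$any_del),
      max_copies = max(.data$max_copies),
      .groups = "drop")
}
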