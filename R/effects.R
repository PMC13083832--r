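#' Codon-aware effect annotation
#'
#' Annotates every alternate allele of every SNP against a transcript model:
#' positions inside the CDS get the affected codon, reference and alternate
#' amino acids (strand-aware: alleles on `-` transcripts are complemented
#' before translation), and a synonymous/nonsynonymous verdict; positions
#' outside the CDS are `non_coding`. A triallelic site yields one record per
#' alternate allele, so the two nucleotide routes to the same substitution
#' (e.g. Val-to-Leu via g>t and g>c at codon 402) stay distinct. Indel alleles
#' are skipped with a warning. Codon numbering is transcript-relative.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alts`).
#' @param model A [read_gene_model()] result carrying the genomic sequence.
#' @return A tibble with one row per (variant, alternate allele): columns
#'   `variant_index`, `allele_index`, `chrom`, `pos`, `ref`, `alt`,
#'   `codon_number`, `ref_aa`, `alt_aa`, `effect`, `aa_label`.
#' @export
annotate_effects <- function(variants, model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(model$seq)) {
    stop("gene model carries no sequence; re-read it with `fasta_path`",
         call. = FALSE)
  }
  chrom_seq <- model$seq[[model$chrom]]
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base_at <- function(p) substr(chrom_seq, p, p)

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    if (variants$chrom[i] != model$chrom) next
    pos <- variants$pos[i]
    ref <- variants$ref[[i]]
    for (k in seq_along(variants$alts[[i]])) {
      alt <- variants$alts[[i]][k]
      if (nchar(ref) != 1L || nchar(alt) != 1L) {
        skipped <- skipped + 1L
        next
      }
      ci <- match(pos, model$cds_pos)
      if (is.na(ci)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variant_index = i, allele_index = k, chrom = variants$chrom[i],
          pos = pos, ref = ref, alt = alt, codon_number = NA_integer_,
          ref_aa = NA_character_, alt_aa = NA_character_,
          effect = "non_coding", aa_label = NA_character_)
        next
      }
      codon_no <- (ci - 1L) %/% 3L + 1L
      in_codon <- (ci - 1L) %% 3L + 1L
      codon_pos <- model$cds_pos[(3L * codon_no - 2L):(3L * codon_no)]
      gen_bases <- vapply(codon_pos, base_at, character(1))
      ref_codon <- if (model$strand == "+") gen_bases else
        unname(comp[gen_bases])
      # VCF alleles are forward-strand; flip onto the transcript strand
      alt_t <- if (model$strand == "+") alt else unname(comp[alt])
      ref_t <- if (model$strand == "+") ref else unname(comp[ref])
      if (ref_codon[in_codon] != ref_t) {
        warning("reference allele at ", variants$chrom[i], ":", pos,
                " disagrees with the model sequence", call. = FALSE)
      }
      alt_codon <- ref_codon
      alt_codon[in_codon] <- alt_t
      ref_aa <- unname(code[paste(ref_codon, collapse = "")])
      alt_aa <- unname(code[paste(alt_codon, collapse = "")])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant_index = i, allele_index = k, chrom = variants$chrom[i],
        pos = pos, ref = ref, alt = alt, codon_number = codon_no,
        ref_aa = ref_aa, alt_aa = alt_aa,
        effect = ifelse(ref_aa == alt_aa, "synonymous", "nonsynonymous"),
        aa_label = paste0(ref_aa, codon_no, alt_aa))
    }
  }
  if (skipped > 0L) {
    warning(skipped, " non-SNP allele(s) skipped", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Per-group allele frequencies with multiallelic decomposition
#'
#' For each group and each alternate allele of each site, the frequency is
#' the count of that allele divided by the number of non-missing chromosomes
#' in the group at that site. Multiallelic sites additionally get a
#' `cumulative` row per group carrying the summed alternate-allele frequency
#' (e.g. 402L(g>t) + 402L(g>c)). Groups with zero non-missing chromosomes at
#' a site get `NA` frequency.
#'
#' @param g A [geno_matrix()].
#' @param samples Sample metadata tibble.
#' @param grouping Metadata columns to group by (default `c("taxon", "site")`).
#' @param named_alleles Optional tibble (`chrom`, `pos`, `allele_index`,
#'   `label`) attaching display names such as `402L(g>t)`; see
#'   [kdr_named_alleles()].
#' @return A long tibble: grouping columns, `chrom`, `pos`, `ref`, `alt`,
#'   `allele_index`, `aa_label`, `frequency`, `n_chromosomes`, and a logical
#'   `cumulative` marking the summed multiallelic rows.
#' @export
allele_frequencies <- function(g, samples, grouping = c("taxon", "site"),
                               named_alleles = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  samples <- tibble::as_tibble(samples)
  groups <- dplyr::distinct(samples[, grouping, drop = FALSE])
  out <- purrr::map(seq_len(nrow(groups)), function(gi) {
    sel <- samples
    for (col in grouping) sel <- sel[sel[[col]] == groups[[col]][gi], ]
    gg <- subset_samples(g, sel$sample_id)
    counts <- site_allele_counts(gg)
    purrr::map(seq_len(nrow(gg$variants)), function(i) {
      alts <- gg$variants$alts[[i]]
      n_chr <- sum(counts[[i]])
      freq <- vapply(seq_along(alts), function(k) {
        if (n_chr == 0L) return(NA_real_)
        ck <- counts[[i]][as.character(k)]
        if (is.na(ck)) 0 else ck / n_chr
      }, numeric(1))
      base <- tibble::tibble(
        groups[gi, ],
        chrom = gg$variants$chrom[i], pos = gg$variants$pos[i],
        ref = gg$variants$ref[[i]], alt = alts,
        allele_index = seq_along(alts),
        frequency = freq, n_chromosomes = n_chr, cumulative = FALSE)
      if (length(alts) > 1L) {
        base <- dplyr::bind_rows(base, tibble::tibble(
          groups[gi, ],
          chrom = gg$variants$chrom[i], pos = gg$variants$pos[i],
          ref = gg$variants$ref[[i]], alt = paste(alts, collapse = "+"),
          allele_index = NA_integer_,
          frequency = if (n_chr == 0L) NA_real_ else sum(freq),
          n_chromosomes = n_chr, cumulative = TRUE))
      }
      base
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$aa_label <- NA_character_
  if (!is.null(named_alleles)) {
    key <- paste(out$chrom, out$pos, out$allele_index)
    nk <- paste(named_alleles$chrom, named_alleles$pos,
                named_alleles$allele_index)
    hit <- match(key, nk)
    out$aa_label <- named_alleles$label[hit]
    cum <- which(out$cumulative)
    if (length(cum)) {
      site_key <- paste(out$chrom, out$pos)
      for (i in cum) {
        labs <- named_alleles$label[paste(named_alleles$chrom,
                                          named_alleles$pos) == site_key[i]]
        if (length(labs)) out$aa_label[i] <- paste(labs, collapse = "+")
      }
    }
  }
  dplyr::relocate(out, "aa_label", .after = "allele_index")
}

#' Display names for the configured kdr alleles
#'
#' Builds the conventional allele names (`995F`, `402L(g>t)`, `402L(g>c)`,
#' `1527T`, ...) from a [kdr_config()], for joining onto frequency tables.
#'
#' @param cfg A [kdr_config()].
#' @return Tibble with `chrom`, `pos`, `allele_index`, `label`.
#' @export
kdr_named_alleles <- function(cfg) {
  purrr::map(seq_len(nrow(cfg$loci)), function(i) {
    alts <- cfg$loci$alts[[i]]
    labs <- cfg$loci$labels[[i]][-1L]
    ref <- cfg$loci$ref[i]
    nm <- vapply(seq_along(alts), function(k) {
      base <- paste0(cfg$loci$locus[i], labs[k])
      if (length(alts) > 1L) {
        paste0(cfg$loci$locus[i], sub("[0-9]+$", "", labs[k]),
               "(", tolower(ref), ">", tolower(alts[k]), ")")
      } else base
    }, character(1))
    tibble::tibble(chrom = cfg$chrom, pos = cfg$loci$pos[i],
                   allele_index = seq_along(alts), label = nm)
  }) |> dplyr::bind_rows()
}

#' Filter a frequency table by minimum frequency
#'
#' Keeps an allele when its frequency strictly exceeds `min_freq` in at least
#' one group (an allele at exactly the threshold is removed). Cumulative rows
#' are filtered on their own summed frequency.
#'
#' @param table Output of [allele_frequencies()].
#' @param min_freq Strict lower threshold (default 0.05).
#' @return The filtered tibble, with attribute `n_surviving` = number of
#'   distinct surviving alleles.
#' @export
filter_by_frequency <- function(table, min_freq = 0.05) {
  key <- paste(table$chrom, table$pos, table$allele_index, table$cumulative)
  keep_keys <- unique(key[!is.na(table$frequency) &
                            table$frequency > min_freq])
  out <- table[key %in% keep_keys, , drop = FALSE]
  attr(out, "n_surviving") <- length(keep_keys)
  out
}

#' Allele-by-group frequency matrix with co-clustering
#'
#' Pivots a long frequency table into an alleles x groups matrix and
#' co-clusters rows and columns by average-linkage hierarchical clustering of
#' Euclidean distances between frequency vectors. Rows and columns are
#' ordered by label before clustering so leaf order is deterministic under
#' ties; `NA` frequencies are treated as 0 for the distance computation.
#'
#' @param table Output of [allele_frequencies()] (cumulative rows excluded
#'   automatically).
#' @param grouping Metadata columns that define the group axis.
#' @return A list: `matrix` (alleles x groups), `row_order`, `col_order`
#'   (integer leaf orders), `row_hclust`, `col_hclust` (`hclust` objects or
#'   `NULL` for single-row/column matrices).
#' @export
frequency_matrix <- function(table, grouping = c("taxon", "site")) {
  stopifnot(nrow(table) > 0L)
  tbl <- table[!table$cumulative, , drop = FALSE]
  tbl$group <- apply(tbl[, grouping, drop = FALSE], 1, paste, collapse = "/")
  tbl$allele <- ifelse(is.na(tbl$aa_label),
                       sprintf("%s:%d:%s>%s", tbl$chrom, tbl$pos, tbl$ref,
                               tbl$alt),
                       tbl$aa_label)
  wide <- tidyr::pivot_wider(
    tbl[, c("allele", "group", "frequency")],
    names_from = "group", values_from = "frequency")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$allele
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  m0 <- m
  m0[is.na(m0)] <- 0
  cl <- function(x) {
    if (nrow(x) < 2L) return(NULL)
    stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  }
  rh <- cl(m0)
  ch <- cl(t(m0))
  list(matrix = m,
       row_order = if (is.null(rh)) seq_len(nrow(m)) else rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(m)) else ch$order,
       row_hclust = rh, col_hclust = ch)
}
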