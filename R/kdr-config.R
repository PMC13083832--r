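#' Configuration of the kdr resistance loci
#'
#' Describes the voltage-gated sodium channel (Vgsc) target-site loci used for
#' diplotype labelling: for each locus a genomic position, the reference
#' allele, 1-2 alternate alleles, and a one-symbol-per-allele label alphabet.
#' The default models the three classic pyrethroid target-site loci:
#'
#' * codon 995 — triallelic in the alphabet: `L` (wild type), `F` (L995F),
#'   `S` (L995S);
#' * codon 402 — a triallelic site where G>T and G>C both encode Val-to-Leu:
#'   `V`, `L1` (g>t), `L2` (g>c);
#' * codon 1527 — biallelic: `I`, `T` (I1527T).
#'
#' Published coordinates for these loci are inconsistent across sources, so
#' positions here are plain configuration, chosen inside the Vgsc span
#' (2L:2,358,158-2,431,617) for the synthetic cohorts; supply your own when
#' analysing real call sets.
#'
#' @param loci A tibble with columns `locus` (display name), `pos`, `ref`,
#'   `alts` (list-column), `labels` (list-column: reference label first, then
#'   one label per alternate allele).
#' @param chrom Chromosome name shared by all loci.
#' @return A `kdr_config` object.
#' @export
kdr_config <- function(loci = NULL, chrom = "2L") {
  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus = c("995", "402", "1527"),
      pos = c(2422652L, 2391228L, 2429556L),
      ref = c("A", "G", "T"),
      alts = list(c("T", "C"), c("T", "C"), "C"),
      labels = list(c("L", "F", "S"), c("V", "L1", "L2"), c("I", "T"))
    )
  }
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("locus", "pos", "ref", "alts", "labels") %in% names(loci)))
  if (anyDuplicated(loci$pos)) stop("kdr loci share a position", call. = FALSE)
  ok <- purrr::map2_lgl(loci$alts, loci$labels,
                        ~ length(.y) == length(.x) + 1L && !anyDuplicated(.y))
  if (!all(ok)) {
    stop("each locus needs one unique label per allele (reference first)",
         call. = FALSE)
  }
  structure(list(loci = loci, chrom = chrom), class = "kdr_config")
}

#' @export
print.kdr_config <- function(x, ...) {
  cat("<kdr_config> ", nrow(x$loci), " loci on ", x$chrom, ": ",
      paste(x$loci$locus, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All haplotype labels expressible under a kdr configuration
#'
#' The label alphabet is the Cartesian product of the per-locus symbols, in
#' configured locus order (e.g. `LVI`, `FVI`, `FL1T`, ...).
#'
#' @param cfg A [kdr_config()].
#' @return Character vector of composite labels.
#' @export
kdr_label_alphabet <- function(cfg) {
  grids <- expand.grid(rev(cfg$loci$labels), stringsAsFactors = FALSE)
  apply(grids[, rev(seq_along(cfg$loci$labels)), drop = FALSE], 1, paste0,
        collapse = "")
}

# Split a composite label into one symbol per locus (greedy, longest first).
split_kdr_label <- function(label, cfg) {
  out <- character(nrow(cfg$loci))
  rest <- label
  for (i in seq_len(nrow(cfg$loci))) {
    syms <- cfg$loci$labels[[i]]
    syms <- syms[order(-nchar(syms))]
    hit <- syms[startsWith(rest, syms)][1]
    if (is.na(hit)) {
      stop("label \"", label, "\" does not decompose over the kdr alphabet",
           call. = FALSE)
    }
    out[i] <- hit
    rest <- substring(rest, nchar(hit) + 1L)
  }
  if (nchar(rest) > 0L) {
    stop("label \"", label, "\" has trailing symbols \"", rest, "\"",
         call. = FALSE)
  }
  out
}

# Composite label -> integer allele indices at the configured loci
# (0 = reference label, k = k-th alternate label), in configured locus order.
kdr_label_alleles <- function(label, cfg) {
  syms <- split_kdr_label(label, cfg)
  purrr::map2_int(syms, cfg$loci$labels, ~ match(.x, .y) - 1L)
}

# Allele indices (configured locus order) -> composite label.
kdr_alleles_label <- function(alleles, cfg) {
  paste0(purrr::map2_chr(alleles, cfg$loci$labels, ~ .y[.x + 1L]),
         collapse = "")
}

# Number of non-reference symbols a composite label carries.
kdr_mutant_load <- function(label, cfg) {
  syms <- split_kdr_label(label, cfg)
  sum(purrr::map2_int(syms, cfg$loci$labels, ~ match(.x, .y) - 1L) > 0L)
}

# Locate the configured loci inside a variant table; errors when a locus is
# absent or its alleles disagree with the table.
match_kdr_loci <- function(variants, cfg) {
  idx <- purrr::map_int(seq_len(nrow(cfg$loci)), function(i) {
    j <- which(variants$chrom == cfg$chrom & variants$pos == cfg$loci$pos[i])
    if (length(j) != 1L) {
      stop("kdr locus ", cfg$loci$locus[i], " (", cfg$chrom, ":",
           cfg$loci$pos[i], ") not found in the variant table", call. = FALSE)
    }
    if (variants$ref[j] != cfg$loci$ref[i] ||
        !identical(variants$alts[[j]], cfg$loci$alts[[i]])) {
      stop("alleles at kdr locus ", cfg$loci$locus[i],
           " disagree with the configuration", call. = FALSE)
    }
    j
  })
  idx
}
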