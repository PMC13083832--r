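#' Read genotypes (and phased haplotypes) from a VCF file
#'
#' Ingests a VCF 4.x file into the package's containers. Multiallelic records
#' are kept as single variant rows, never split; decomposition into per-allele
#' rows happens only downstream in frequency and LD computations. Missing
#' calls (`./.`) become `(-1, -1)` and are propagated, never imputed. A phased
#' haplotype matrix is returned only when every call in the (region-restricted)
#' file uses the `|` separator.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param region Optional `"chrom:start-end"` restriction (1-based inclusive).
#'   A region overlapping nothing yields empty containers, not an error.
#' @return A list with elements `variants` (tibble), `genotypes`
#'   ([geno_matrix()]), and `haplotypes` ([hap_matrix()] or `NULL`).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- if (ncol(gt) > 1L) colnames(gt)[-1L] else character()

  variants <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alts = strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  )
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- variants$chrom == r$chrom & variants$pos >= r$start &
      variants$pos <= r$end
  }
  variants <- variants[keep, , drop = FALSE]
  nv <- nrow(variants)
  ns <- length(samples)

  calls <- array(-1L, dim = c(nv, ns, 2L))
  haps <- matrix(-1L, nrow = nv, ncol = 2L * ns)
  all_phased <- nv > 0L && ns > 0L
  if (nv > 0L && ns > 0L) {
    gt_kept <- gt[keep, -1L, drop = FALSE]
    gt_field <- sub(":.*$", "", gt_kept)
    gt_field[is.na(gt_field)] <- "./." # readers may blank out missing calls
    dim(gt_field) <- dim(gt_kept)
    ok <- grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gt_field)
    dim(ok) <- dim(gt_field)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      stop("malformed GT field at variant ", variants$chrom[bad[1]], ":",
           variants$pos[bad[1]], ", sample ", samples[bad[2]], ": ",
           gt_field[bad[1], bad[2]], call. = FALSE)
    }
    a1 <- sub("^(\\.|[0-9]+)[/|].*$", "\\1", gt_field)
    a2 <- sub("^.*[/|](\\.|[0-9]+)$", "\\1", gt_field)
    to_idx <- function(x) {
      out <- suppressWarnings(as.integer(x))
      out[x == "."] <- -1L
      out
    }
    calls[, , 1L] <- to_idx(a1)
    calls[, , 2L] <- to_idx(a2)
    # a single "/" call demotes the whole matrix to unphased
    all_phased <- all(grepl("|", gt_field, fixed = TRUE)) && all(calls >= 0L)
    haps[, 2L * seq_len(ns) - 1L] <- calls[, , 1L]
    haps[, 2L * seq_len(ns)] <- calls[, , 2L]
  }

  g <- geno_matrix(variants, calls, samples)
  h <- if (all_phased) hap_matrix(variants, haps, samples, phased = TRUE) else NULL
  list(variants = variants, genotypes = g, haplotypes = h)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 file carrying CHROM/POS/ID/REF/ALT and per-sample
#' GT. When `haplotypes` is supplied and phased, calls are written with the
#' `|` separator in haplotype column order; otherwise with `/`.
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @param haplotypes Optional phased [hap_matrix()] over the same sites and
#'   samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, haplotypes = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ns <- length(g$samples)
  fmt_allele <- function(a) ifelse(a < 0L, ".", as.character(a))
  if (!is.null(haplotypes)) {
    stopifnot(inherits(haplotypes, "hap_matrix"), haplotypes$phased)
    a1 <- haplotypes$haps[, 2L * seq_len(ns) - 1L, drop = FALSE]
    a2 <- haplotypes$haps[, 2L * seq_len(ns), drop = FALSE]
    sep <- "|"
  } else {
    a1 <- g$calls[, , 1L, drop = TRUE]
    a2 <- g$calls[, , 2L, drop = TRUE]
    if (is.null(dim(a1))) { a1 <- matrix(a1, nrow = nrow(g$variants)) ; a2 <- matrix(a2, nrow = nrow(g$variants)) }
    sep <- "/"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(g$variants)), function(i) {
    gts <- paste0(fmt_allele(a1[i, ]), sep, fmt_allele(a2[i, ]))
    paste(c(g$variants$chrom[i], g$variants$pos[i], ".", g$variants$ref[i],
            paste(g$variants$alts[[i]], collapse = ","), ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read tab-separated sample metadata
#'
#' Requires columns `sample_id`, `taxon` and `site`; optional columns `zone`,
#' `sex`, `lat`, `lon` are filled with defaults when absent. Taxa outside
#' \{coluzzii, gambiae_ss, arabiensis\} are mapped to `"other"` with a warning;
#' missing sex becomes `"unknown"`. Row order is preserved.
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "taxon", "site")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) {
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  known <- c("coluzzii", "gambiae_ss", "arabiensis")
  unknown <- setdiff(unique(tbl$taxon), c(known, "other"))
  if (length(unknown)) {
    warning("unknown taxa mapped to \"other\": ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  tbl |>
    dplyr::mutate(
      sample_id = as.character(.data$sample_id),
      taxon = ifelse(.data$taxon %in% known, .data$taxon, "other"),
      zone = if ("zone" %in% names(tbl)) as.character(.data$zone) else NA_character_,
      sex = if ("sex" %in% names(tbl)) {
        ifelse(is.na(.data$sex) | .data$sex == "", "unknown",
               as.character(.data$sex))
      } else "unknown",
      lat = if ("lat" %in% names(tbl)) as.numeric(.data$lat) else NA_real_,
      lon = if ("lon" %in% names(tbl)) as.numeric(.data$lon) else NA_real_
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "taxon", "site", "zone", "sex",
                                  "lat", "lon")))
}

#' Assemble a transcript model from a GFF3 file
#'
#' Collects the CDS features whose `Parent` attribute names the transcript and
#' orders them 5' to 3' in transcript orientation (ascending genomic position
#' on `+`, descending on `-`). Coordinates are 1-based inclusive throughout.
#' An optional FASTA provides the genomic sequence the codon-aware effect
#' annotation needs.
#'
#' @param gff3_path Path to a GFF3 file containing CDS features.
#' @param transcript_id Transcript identifier matched against `Parent`.
#' @param fasta_path Optional FASTA of the chromosome(s); sequence names must
#'   match the GFF `seqid`.
#' @return A `gene_model` list: `transcript_id`, `chrom`, `strand`,
#'   `cds_exons` (tibble `start`, `end` in transcript order), `cds_pos`
#'   (genomic positions of CDS bases in transcript order), and `seq` (named
#'   character vector of chromosome sequences, or `NULL`).
#' @export
read_gene_model <- function(gff3_path, transcript_id, fasta_path = NULL) {
  gff <- ape::read.gff(gff3_path)
  pat <- paste0("(^|;)Parent=([^;]*,)?", transcript_id, "(,[^;]*)?(;|$)")
  cds <- gff[gff$type == "CDS" & grepl(pat, gff$attributes), , drop = FALSE]
  if (nrow(cds) == 0L) {
    stop("transcript not found in GFF3: ", transcript_id, call. = FALSE)
  }
  chrom <- as.character(unique(cds$seqid))
  strand <- as.character(unique(cds$strand))
  stopifnot(length(chrom) == 1L, strand %in% c("+", "-"))
  exons <- tibble::tibble(start = as.integer(cds$start), end = as.integer(cds$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("CDS exons overlap for transcript ", transcript_id, call. = FALSE)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  cds_pos <- unlist(purrr::map2(exons$start, exons$end, function(s, e) {
    if (strand == "+") seq.int(s, e) else seq.int(e, s)
  }))
  if (length(cds_pos) %% 3L != 0L) {
    stop("CDS length (", length(cds_pos), ") of ", transcript_id,
         " is not divisible by 3", call. = FALSE)
  }
  seqs <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    if (!chrom %in% names(seqs)) {
      stop("FASTA does not contain sequence for ", chrom, call. = FALSE)
    }
  }
  structure(
    list(transcript_id = transcript_id, chrom = chrom, strand = strand,
         cds_exons = exons, cds_pos = as.integer(cds_pos), seq = seqs),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$transcript_id, " (", x$chrom, x$strand, "), ",
      length(x$cds_pos) / 3L, " codons over ", nrow(x$cds_exons),
      " CDS exon(s)\n", sep = "")
  invisible(x)
}

#' Write a result table to CSV, TSV or JSON
#'
#' Column order follows the input; numeric columns are rounded to a fixed
#' number of significant digits so re-runs diff cleanly across platforms.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"json"`.
#' @param digits Significant digits for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv", "json"),
                        digits = 6) {
  format <- match.arg(format)
  rows <- tibble::as_tibble(rows)
  rows <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.double), ~ signif(.x, digits)))
  switch(format,
    csv = readr::write_csv(rows, path, progress = FALSE),
    tsv = readr::write_tsv(rows, path, progress = FALSE),
    json = jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                                na = "null", pretty = TRUE)
  )
  invisible(path)
}
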