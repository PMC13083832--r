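#' Genotype and haplotype containers
#'
#' `geno_matrix()` wraps a variants-by-samples-by-2 integer array of allele
#' indices (0 = reference, k = k-th alternate, -1 = missing) together with a
#' variant table. `hap_matrix()` stores phased (or arbitrarily ordered)
#' haplotypes as a variants-by-(2 x samples) integer matrix; columns `2i - 1`
#' and `2i` belong to sample `i`.
#'
#' Variant tables are tibbles with columns `chrom`, `pos` (1-based, VCF
#' convention), `ref` and `alts` (a list-column of character vectors, 1-3
#' alternate alleles per site). Multiallelic records are kept as single rows;
#' they are only decomposed inside frequency and LD computations.
#'
#' @param variants Tibble of variant records (`chrom`, `pos`, `ref`, `alts`).
#' @param calls Integer array `[n_variants, n_samples, 2]` of allele indices.
#' @param samples Character vector of sample identifiers.
#' @param haps Integer matrix `[n_variants, 2 * n_samples]` of allele indices.
#' @param phased Logical; `TRUE` when columns carry true chromosomal phase.
#'
#' @return An object of class `geno_matrix` or `hap_matrix`.
#' @name containers
NULL

#' @rdname containers
#' @export
geno_matrix <- function(variants, calls, samples) {
  variants <- validate_variants(variants)
  stopifnot(is.array(calls), length(dim(calls)) == 3L, dim(calls)[3] == 2L)
  if (dim(calls)[1] != nrow(variants)) {
    stop("`calls` has ", dim(calls)[1], " variant rows but `variants` has ",
         nrow(variants), call. = FALSE)
  }
  if (dim(calls)[2] != length(samples)) {
    stop("`calls` sample axis does not match `samples`", call. = FALSE)
  }
  n_alleles <- 1L + lengths(variants$alts)
  mx <- apply(calls, 1, max, na.rm = TRUE)
  if (any(mx >= n_alleles)) {
    stop("allele index out of range at variant row(s): ",
         paste(which(mx >= n_alleles), collapse = ", "), call. = FALSE)
  }
  structure(
    list(variants = variants, calls = calls, samples = as.character(samples)),
    class = "geno_matrix"
  )
}

#' @rdname containers
#' @export
hap_matrix <- function(variants, haps, samples, phased = TRUE) {
  variants <- validate_variants(variants)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (nrow(haps) != nrow(variants)) {
    stop("`haps` rows do not match `variants`", call. = FALSE)
  }
  if (ncol(haps) != 2L * length(samples)) {
    stop("`haps` must have two columns per sample", call. = FALSE)
  }
  if (phased && any(haps < 0L)) {
    stop("phased haplotypes cannot contain missing alleles", call. = FALSE)
  }
  structure(
    list(variants = variants, haps = haps, samples = as.character(samples),
         phased = isTRUE(phased)),
    class = "hap_matrix"
  )
}

validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  req <- c("chrom", "pos", "ref", "alts")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("variant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(variants$alts)) variants$alts <- as.list(variants$alts)
  bad <- purrr::map_lgl(seq_len(nrow(variants)), function(i) {
    a <- variants$alts[[i]]
    length(a) < 1L || anyDuplicated(a) > 0L || any(a == variants$ref[[i]])
  })
  if (any(bad)) {
    stop("invalid alternate alleles at variant row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    stop("variant records must be sorted by (chrom, pos)", call. = FALSE)
  }
  variants$pos <- as.integer(variants$pos)
  variants
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$variants), " variants x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", nrow(x$variants), " variants x ", ncol(x$haps),
      " haplotypes (", if (x$phased) "phased" else "unphased", ")\n", sep = "")
  invisible(x)
}

#' Collapse a haplotype matrix to unphased genotype calls
#'
#' Pairs haplotype columns `2i - 1` and `2i` into the two allele slots of
#' sample `i`, reproducing the genotype view of phased data.
#'
#' @param h A [hap_matrix()].
#' @return A [geno_matrix()].
#' @export
as_geno_matrix <- function(h) {
  stopifnot(inherits(h, "hap_matrix"))
  ns <- length(h$samples)
  calls <- array(NA_integer_, dim = c(nrow(h$variants), ns, 2L))
  calls[, , 1L] <- h$haps[, 2L * seq_len(ns) - 1L, drop = FALSE]
  calls[, , 2L] <- h$haps[, 2L * seq_len(ns), drop = FALSE]
  geno_matrix(h$variants, calls, h$samples)
}

#' Alternate-allele dosage matrix
#'
#' Biallelic-decomposes every site: each (site, alternate allele) pair becomes
#' one column counting copies of that allele per sample (0, 1, 2; `NA` when
#' either call is missing).
#'
#' @param g A [geno_matrix()].
#' @return Numeric matrix, samples x decomposed alleles, with informative
#'   column names `chrom:pos:ref>alt`.
#' @export
dosage_matrix <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  cols <- list()
  nms <- character()
  for (i in seq_len(nrow(g$variants))) {
    alts <- g$variants$alts[[i]]
    a1 <- g$calls[i, , 1L]
    a2 <- g$calls[i, , 2L]
    miss <- a1 < 0L | a2 < 0L
    for (k in seq_along(alts)) {
      d <- (a1 == k) + (a2 == k)
      d[miss] <- NA_real_
      cols[[length(cols) + 1L]] <- d
      nms <- c(nms, sprintf("%s:%d:%s>%s", g$variants$chrom[i],
                            g$variants$pos[i], g$variants$ref[i], alts[k]))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- g$samples
  colnames(m) <- nms
  m
}

#' Restrict a genotype or haplotype matrix to a genomic region
#'
#' @param x A [geno_matrix()] or [hap_matrix()].
#' @param region String `"chrom:start-end"`, 1-based inclusive.
#' @return Object of the same class containing only overlapping sites; an
#'   empty object (zero variants) when nothing overlaps.
#' @export
subset_region <- function(x, region) {
  r <- parse_region(region)
  keep <- x$variants$chrom == r$chrom &
    x$variants$pos >= r$start & x$variants$pos <= r$end
  subset_variants(x, keep)
}

subset_variants <- function(x, keep) {
  x$variants <- x$variants[keep, , drop = FALSE]
  if (inherits(x, "geno_matrix")) {
    x$calls <- x$calls[keep, , , drop = FALSE]
  } else {
    x$haps <- x$haps[keep, , drop = FALSE]
  }
  x
}

#' Restrict a genotype matrix to a subset of samples
#'
#' @param g A [geno_matrix()].
#' @param sample_ids Character vector of sample identifiers to keep.
#' @return A [geno_matrix()] with the sample axis reordered to `sample_ids`.
#' @export
subset_samples <- function(g, sample_ids) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- match(sample_ids, g$samples)
  if (anyNA(idx)) {
    stop("unknown sample id(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  g$calls <- g$calls[, idx, , drop = FALSE]
  g$samples <- g$samples[idx]
  g
}

parse_region <- function(region) {
  m <- stringr::str_match(region, "^([^:]+):([0-9,]+)-([0-9,]+)$")
  if (is.na(m[1, 1])) {
    stop("region must look like \"chrom:start-end\": got ", region,
         call. = FALSE)
  }
  start <- as.integer(gsub(",", "", m[1, 3]))
  end <- as.integer(gsub(",", "", m[1, 4]))
  if (end < start) stop("region end precedes start", call. = FALSE)
  list(chrom = m[1, 2], start = start, end = end)
}
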