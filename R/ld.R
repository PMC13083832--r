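#' EM estimate of a two-locus haplotype frequency from unphased genotypes
#'
#' Both loci are collapsed to a focal-allele indicator (focal vs all other
#' alleles), so the input is a 3 x 3 table of genotype counts indexed by the
#' number of focal-allele copies at each locus (0, 1, 2). Only the double
#' heterozygote cell is phase-ambiguous; the E-step splits it between the
#' coupling (AB/ab) and repulsion (Ab/aB) resolutions in proportion
#' `p_AB p_ab / (p_AB p_ab + p_Ab p_aB)`, and the M-step re-estimates the four
#' haplotype frequencies from expected counts. The likelihood is multimodal
#' when the data are dominated by double heterozygotes, so the EM is run from
#' three starts — linkage equilibrium, full coupling, full repulsion — and the
#' best log-likelihood solution is returned. The log-likelihood is
#' non-decreasing across iterations by construction and is tracked.
#'
#' @param counts 3 x 3 numeric matrix; `counts[i, j]` is the number of
#'   diploids carrying `i - 1` copies of focal allele A and `j - 1` copies of
#'   focal allele B.
#' @param tol Convergence tolerance on the haplotype frequencies.
#' @param max_iter Maximum EM iterations per start.
#' @return List: `p_AB`, `p` (all four haplotype frequencies AB, Ab, aB, ab),
#'   `loglik`, `iterations`, `loglik_trace` (of the winning start).
#' @export
em_haplotype_freq <- function(counts, tol = 1e-10, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype table", call. = FALSE)
  # phase-unambiguous haplotype counts
  base <- c(
    AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
    Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
    aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
    ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
  )
  dh <- counts[2, 2]
  pA <- (base[["AB"]] + base[["Ab"]] + dh) / (2 * n)
  pB <- (base[["AB"]] + base[["aB"]] + dh) / (2 * n)

  loglik_of <- function(p) {
    probs <- matrix(0, 3, 3)
    hap <- c(p[1], p[2], p[3], p[4]) # AB Ab aB ab
    # genotype cell probabilities under random union of haplotypes
    cellp <- function(h1, h2) if (h1 == h2) hap[h1]^2 else 2 * hap[h1] * hap[h2]
    probs[1, 1] <- cellp(4, 4)
    probs[1, 2] <- cellp(4, 3)
    probs[1, 3] <- cellp(3, 3)
    probs[2, 1] <- cellp(4, 2)
    probs[2, 2] <- 2 * (hap[1] * hap[4] + hap[2] * hap[3])
    probs[2, 3] <- cellp(3, 1)
    probs[3, 1] <- cellp(2, 2)
    probs[3, 2] <- cellp(2, 1)
    probs[3, 3] <- cellp(1, 1)
    sum(counts[counts > 0] * log(pmax(probs[counts > 0], 1e-300)))
  }

  run_em <- function(p0) {
    p <- p0
    trace <- loglik_of(p)
    it <- 0L
    repeat {
      it <- it + 1L
      denom <- p[1] * p[4] + p[2] * p[3]
      w <- if (denom > 0) p[1] * p[4] / denom else 0.5
      new_counts <- base + dh * c(w, 1 - w, 1 - w, w)
      p_new <- new_counts / (2 * n)
      trace <- c(trace, loglik_of(p_new))
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol || it >= max_iter) break
    }
    list(p = p, loglik = loglik_of(p), iterations = it, loglik_trace = trace)
  }

  starts <- list(
    equilibrium = c(pA * pB, pA * (1 - pB), (1 - pA) * pB,
                    (1 - pA) * (1 - pB)),
    coupling = (base + dh * c(1, 0, 0, 1)) / (2 * n),
    repulsion = (base + dh * c(0, 1, 1, 0)) / (2 * n)
  )
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  list(p_AB = unname(best$p[1]),
       p = stats::setNames(unname(best$p), c("AB", "Ab", "aB", "ab")),
       loglik = best$loglik, iterations = best$iterations,
       loglik_trace = best$loglik_trace)
}

#' Allele-specific r-squared between two (possibly multiallelic) loci
#'
#' Each locus is collapsed to its focal alternate allele versus everything
#' else — essential at a triallelic site, where each alternate allele (e.g.
#' 402L(g>t) and 402L(g>c)) is analysed as its own focal allele — and the
#' two-locus haplotype frequency is estimated by [em_haplotype_freq()] on
#' complete cases. When either focal allele is absent (or fixed) in the
#' analysed samples, r-squared is undefined and reported as 0 with
#' `defined = FALSE`.
#'
#' @param g A [geno_matrix()].
#' @param pos_a,pos_b Genomic positions of the two loci.
#' @param allele_a,allele_b Focal alternate-allele indices (1-based) at each
#'   locus.
#' @param sample_ids Optional restriction to a sample subset.
#' @param chrom Chromosome; defaults to the single chromosome of `g`.
#' @return A one-row tibble: `allele_a`, `allele_b`, `n`, `p_a`, `p_b`,
#'   `p_ab`, `d_ab`, `r2`, `defined`, `loglik`, `iterations`.
#' @export
allele_r2 <- function(g, pos_a, allele_a, pos_b, allele_b,
                      sample_ids = NULL, chrom = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(sample_ids)) g <- subset_samples(g, sample_ids)
  if (is.null(chrom)) {
    chrom <- unique(g$variants$chrom)
    stopifnot(length(chrom) == 1L)
  }
  ia <- which(g$variants$chrom == chrom & g$variants$pos == pos_a)
  ib <- which(g$variants$chrom == chrom & g$variants$pos == pos_b)
  if (length(ia) != 1L || length(ib) != 1L) {
    stop("locus not found at ", chrom, ":", pos_a, " / ", pos_b, call. = FALSE)
  }
  name_a <- sprintf("%s:%d:%s", chrom, pos_a, g$variants$alts[[ia]][allele_a])
  name_b <- sprintf("%s:%d:%s", chrom, pos_b, g$variants$alts[[ib]][allele_b])
  dos_a <- focal_dosage(g, ia, allele_a)
  dos_b <- focal_dosage(g, ib, allele_b)
  complete <- !is.na(dos_a) & !is.na(dos_b)
  n <- sum(complete)
  undefined <- function() tibble::tibble(
    allele_a = name_a, allele_b = name_b, n = n, p_a = NA_real_,
    p_b = NA_real_, p_ab = NA_real_, d_ab = NA_real_, r2 = 0,
    defined = FALSE, loglik = NA_real_, iterations = NA_integer_)
  if (n < 2L) return(undefined())
  da <- dos_a[complete]
  db <- dos_b[complete]
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(da == i & db == j)
  p_a <- mean(da) / 2
  p_b <- mean(db) / 2
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) return(undefined())
  fit <- em_haplotype_freq(counts)
  d_ab <- fit$p_AB - p_a * p_b
  r2 <- d_ab^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  tibble::tibble(
    allele_a = name_a, allele_b = name_b, n = n, p_a = p_a, p_b = p_b,
    p_ab = fit$p_AB, d_ab = d_ab, r2 = min(max(r2, 0), 1), defined = TRUE,
    loglik = fit$loglik, iterations = fit$iterations)
}

# Per-sample count of a focal alternate allele at one variant row
# (0/1/2, NA when either call is missing).
focal_dosage <- function(g, row, allele_index) {
  a1 <- g$calls[row, , 1L]
  a2 <- g$calls[row, , 2L]
  out <- (a1 == allele_index) + (a2 == allele_index)
  out[a1 < 0L | a2 < 0L] <- NA_real_
  out
}

#' Linkage-disequilibrium table across groups
#'
#' Computes allele-specific r-squared for a set of allele pairs within each
#' sample group, plus a pooled `"global"` row per pair over all the groups'
#' samples (pooling genotypes, not averaging the per-group estimates).
#' Empty groups are omitted.
#'
#' @param g A [geno_matrix()].
#' @param samples Sample metadata tibble.
#' @param pairs Tibble with columns `pos_a`, `allele_a`, `pos_b`, `allele_b`
#'   and optionally `name`.
#' @param grouping Metadata column to stratify by (default `"site"`).
#' @param chrom Chromosome passed through to [allele_r2()].
#' @return A tibble: `group`, `pair`, `n`, `r2`, `defined` (plus the
#'   frequency columns of [allele_r2()]).
#' @export
ld_table <- function(g, samples, pairs, grouping = "site", chrom = NULL) {
  samples <- tibble::as_tibble(samples)
  pairs <- tibble::as_tibble(pairs)
  if (!"name" %in% names(pairs)) {
    pairs$name <- sprintf("%d[%d] vs %d[%d]", pairs$pos_a, pairs$allele_a,
                          pairs$pos_b, pairs$allele_b)
  }
  group_vals <- unique(samples[[grouping]])
  one <- function(ids, label) {
    purrr::map(seq_len(nrow(pairs)), function(i) {
      allele_r2(g, pairs$pos_a[i], pairs$allele_a[i], pairs$pos_b[i],
                pairs$allele_b[i], sample_ids = ids, chrom = chrom) |>
        dplyr::mutate(group = label, pair = pairs$name[i], .before = 1L)
    }) |> dplyr::bind_rows()
  }
  per_group <- purrr::map(group_vals, function(gv) {
    ids <- samples$sample_id[samples[[grouping]] == gv]
    if (!length(ids)) return(NULL)
    one(ids, as.character(gv))
  })
  global <- one(samples$sample_id, "global")
  dplyr::bind_rows(c(per_group, list(global)))
}
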