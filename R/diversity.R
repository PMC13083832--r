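#' Per-site allele counts
#'
#' Tabulates observed allele indices per site over both call slots, ignoring
#' missing calls.
#'
#' @param g A [geno_matrix()].
#' @return List of named integer vectors (names = allele index as character),
#'   one per variant row.
#' @keywords internal
site_allele_counts <- function(g) {
  lapply(seq_len(nrow(g$variants)), function(i) {
    a <- c(g$calls[i, , 1L], g$calls[i, , 2L])
    a <- a[a >= 0L]
    if (!length(a)) return(stats::setNames(integer(), character()))
    tab <- table(a)
    stats::setNames(as.integer(tab), names(tab))
  })
}

#' Count segregating and multiallelic sites
#'
#' A site is segregating when at least two distinct allele indices are
#' observed among non-missing calls, and multiallelic when at least three
#' are; a multiallelic site counts once in `S`. Sites with all calls missing
#' are excluded and reported.
#'
#' @param g A [geno_matrix()].
#' @return List with `S`, `n_multiallelic`, and `n_all_missing`.
#' @export
segregating_sites <- function(g) {
  stopifnot(inherits(g, "geno_matrix"), length(g$samples) >= 1L)
  counts <- site_allele_counts(g)
  k <- lengths(counts)
  list(S = sum(k >= 2L), n_multiallelic = sum(k >= 3L),
       n_all_missing = sum(k == 0L))
}

#' Nucleotide diversity (theta-pi) per base
#'
#' Mean pairwise difference per site: at each site, the mean over all pairs
#' of non-missing allele calls of the indicator that the two alleles differ
#' (any two distinct alleles of a multiallelic site count as one difference),
#' summed over sites and divided by the analysed span. Sites with fewer than
#' two non-missing alleles contribute zero.
#'
#' @param g A [geno_matrix()].
#' @param span_bp Length in bp of the analysed region (>= 1).
#' @return Per-base nucleotide diversity (double).
#' @export
nucleotide_diversity <- function(g, span_bp) {
  stopifnot(span_bp >= 1)
  sum(per_site_pi(g)) / span_bp
}

# Per-site mean pairwise difference; 0 where < 2 non-missing alleles.
per_site_pi <- function(g) {
  vapply(site_allele_counts(g), function(tab) {
    n <- sum(tab)
    if (n < 2L) return(0)
    1 - sum(tab * (tab - 1)) / (n * (n - 1))
  }, numeric(1))
}

# Modal non-missing chromosome count across sites (ties -> largest mode).
modal_chromosomes <- function(g) {
  n_site <- vapply(site_allele_counts(g), sum, integer(1))
  n_site <- n_site[n_site > 0L]
  if (!length(n_site)) return(0L)
  tab <- table(n_site)
  max(as.integer(names(tab)[tab == max(tab)]))
}

#' Watterson's theta per base
#'
#' `theta_w = S / (a * span_bp)` with `a = sum(1 / (1:(m - 1)))`, where `m` is
#' the modal non-missing chromosome count across sites and `S` the segregating
#' site count (multiallelic sites counted once).
#'
#' @inheritParams nucleotide_diversity
#' @return Per-base Watterson estimator (double); 0 when `S = 0`.
#' @export
watterson_theta <- function(g, span_bp) {
  stopifnot(span_bp >= 1)
  S <- segregating_sites(g)$S
  if (S == 0L) return(0)
  m <- modal_chromosomes(g)
  if (m < 2L) stop("need >= 2 non-missing chromosomes", call. = FALSE)
  a <- sum(1 / seq_len(m - 1L))
  S / (a * span_bp)
}

#' Tajima's D
#'
#' The classic scaled difference between mean pairwise diversity and
#' Watterson's estimator, with the standard constants computed from the modal
#' non-missing chromosome count `m`: numerator `k_hat - S / a1`, denominator
#' `sqrt(e1 * S + e2 * S * (S - 1))`. Returns `NA` (not 0) when `S = 0`, where
#' the statistic is undefined; at `m = 2` both numerator and denominator
#' vanish identically and the forced value 0 is returned.
#'
#' @param g A [geno_matrix()].
#' @return Tajima's D (double), or `NA_real_` when not computable.
#' @export
tajima_d <- function(g) {
  S <- segregating_sites(g)$S
  if (S == 0L) return(NA_real_)
  m <- modal_chromosomes(g)
  if (m < 2L) return(NA_real_)
  k_hat <- sum(per_site_pi(g))
  con <- tajima_constants(m)
  num <- k_hat - S / con$a1
  den2 <- con$e1 * S + con$e2 * S * (S - 1)
  if (den2 <= .Machine$double.eps) {
    return(if (abs(num) < 1e-12) 0 else NA_real_)
  }
  num / sqrt(den2)
}

# Tajima (1989) constants for sample size m chromosomes.
tajima_constants <- function(m) {
  a1 <- sum(1 / seq_len(m - 1L))
  a2 <- sum(1 / seq_len(m - 1L)^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Per-group diversity summary
#'
#' Assembles the full panel of diversity statistics per sample group:
#' segregating sites, multiallelic and non-synonymous fractions, variant
#' density, theta-pi, Watterson's theta and Tajima's D.
#'
#' @param g A [geno_matrix()].
#' @param samples Sample metadata tibble aligned with `g` (`sample_id` plus
#'   grouping columns).
#' @param span_bp Analysed region length in bp.
#' @param grouping Character vector of metadata columns to group by (e.g.
#'   `"taxon"` or `c("taxon", "site")`); `NULL` for a single overall group.
#' @param effects Optional effect table from [annotate_effects()]; enables the
#'   non-synonymous fraction.
#' @return A tibble, one row per group, with columns `n_samples`, `S`,
#'   `n_multiallelic`, `frac_multiallelic`, `n_nonsynonymous`,
#'   `frac_nonsynonymous`, `theta_pi`, `theta_w`, `tajima_d`,
#'   `variant_density`, `span_bp`.
#' @export
diversity_summary <- function(g, samples, span_bp, grouping = "taxon",
                              effects = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  samples <- tibble::as_tibble(samples)
  if (is.null(grouping)) {
    groups <- tibble::tibble(.group = "all")
    samples$.group <- "all"
    grouping <- ".group"
  }
  groups <- dplyr::distinct(samples[, grouping, drop = FALSE])
  rows <- purrr::map(seq_len(nrow(groups)), function(i) {
    sel <- samples
    for (col in grouping) sel <- sel[sel[[col]] == groups[[col]][i], ]
    if (nrow(sel) == 0L) {
      warning("group with 0 samples omitted", call. = FALSE)
      return(NULL)
    }
    gg <- subset_samples(g, sel$sample_id)
    seg <- segregating_sites(gg)
    n_nonsyn <- NA_integer_
    if (!is.null(effects)) n_nonsyn <- count_nonsyn_sites(gg, effects)
    tibble::tibble(
      groups[i, ],
      n_samples = nrow(sel),
      S = seg$S,
      n_multiallelic = seg$n_multiallelic,
      frac_multiallelic = ifelse(seg$S > 0, seg$n_multiallelic / seg$S, NA_real_),
      n_nonsynonymous = n_nonsyn,
      frac_nonsynonymous = ifelse(seg$S > 0, n_nonsyn / seg$S, NA_real_),
      theta_pi = nucleotide_diversity(gg, span_bp),
      theta_w = if (seg$S > 0) watterson_theta(gg, span_bp) else 0,
      tajima_d = tajima_d(gg),
      variant_density = seg$S / span_bp,
      span_bp = span_bp
    )
  })
  out <- dplyr::bind_rows(rows)
  if (".group" %in% names(out)) out$.group <- NULL
  out
}

# Segregating sites carrying >= 1 observed non-synonymous alternate allele.
count_nonsyn_sites <- function(g, effects) {
  counts <- site_allele_counts(g)
  seg <- which(lengths(counts) >= 2L)
  if (!length(seg)) return(0L)
  key <- paste(g$variants$chrom, g$variants$pos)
  eff_ns <- effects[effects$effect == "nonsynonymous", , drop = FALSE]
  ns_key <- paste(eff_ns$chrom, eff_ns$pos)
  sum(vapply(seg, function(i) {
    hits <- eff_ns$allele_index[ns_key == key[i]]
    length(hits) > 0L && any(as.character(hits) %in% names(counts[[i]]))
  }, logical(1)))
}
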