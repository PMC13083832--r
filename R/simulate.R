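#' Seed substreams
#'
#' One global integer seed drives every simulator through named substreams,
#' so adding a cohort or replicate never perturbs the draws of another.
#' The derivation is a small multiplicative hash of the stream name folded
#' into the seed, kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return Integer seed for the substream.
#' @keywords internal
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(name))) {
    h <- (h * 48271 + code) %% m
  }
  as.integer(h)
}

#' Neutral coalescent simulator (infinite sites)
#'
#' Simulates replicate genealogies under the standard Kingman coalescent with
#' constant population size and no recombination: while `k` lineages remain,
#' the time to the next coalescence is exponential with rate `k (k - 1) / 2`;
#' mutations fall on each branch as a Poisson count with mean
#' `theta / 2 * branch_length`, and every mutation creates one new segregating
#' column (infinite-sites). Haplotypes are paired into pseudo-diploid samples,
#' so `n_haplotypes` must be even.
#'
#' @param n_haplotypes Even integer >= 2, number of sampled chromosomes.
#' @param theta Scaled mutation rate per locus (`4 N mu`), >= 0.
#' @param n_replicates Number of independent replicates.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of `n_replicates` phased [hap_matrix()] objects (replicates
#'   with zero mutations have zero variant rows).
#' @export
simulate_coalescent <- function(n_haplotypes, theta, n_replicates = 1,
                                seed = 1) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2", call. = FALSE)
  if (n_haplotypes %% 2 != 0) {
    stop("n_haplotypes must be even (haplotypes are paired into samples)",
         call. = FALSE)
  }
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  lapply(seq_len(n_replicates), function(rep) {
    set.seed(substream_seed(seed, paste0("coalescent/", rep)))
    sim_one_genealogy(n_haplotypes, theta)
  })
}

# One replicate: genealogy, branch mutations, hap_matrix assembly.
sim_one_genealogy <- function(n, theta) {
  # active lineages: list of descendant leaf-index vectors + accrued lengths
  desc <- lapply(seq_len(n), identity)
  blen <- numeric(n)
  branches <- list() # closed branches: list(desc=..., len=...)
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t_k
    pair <- sample.int(k, 2L)
    for (j in pair) {
      branches[[length(branches) + 1L]] <- list(desc = desc[[j]],
                                                len = blen[j])
    }
    merged <- sort(c(desc[[pair[1]]], desc[[pair[2]]]))
    desc <- c(desc[-pair], list(merged))
    blen <- c(blen[-pair], 0)
    k <- k - 1L
  }
  n_mut <- vapply(branches, function(b) stats::rpois(1, theta / 2 * b$len),
                  integer(1))
  cols <- list()
  for (i in seq_along(branches)) {
    if (n_mut[i] > 0L) {
      col <- integer(n)
      col[branches[[i]]$desc] <- 1L
      cols <- c(cols, rep(list(col), n_mut[i]))
    }
  }
  s <- length(cols)
  haps <- if (s > 0L) do.call(rbind, cols) else matrix(integer(), 0L, n)
  variants <- tibble::tibble(
    chrom = rep("sim", s), pos = seq_len(s),
    ref = rep("A", s), alts = rep(list("T"), s)
  )
  hap_matrix(variants, haps, sprintf("sim%03d", seq_len(n / 2L)),
             phased = TRUE)
}

#' Specification of a synthetic kdr cohort
#'
#' Declares, per (taxon, site) cohort, a sample size and a haplotype-label
#' frequency table over the kdr alphabet, plus the number and frequency
#' spectrum of neutral background sites. Individuals are formed by drawing two
#' labels i.i.d. from their cohort table (Hardy-Weinberg at the haplotype
#' level); background sites are in linkage equilibrium by construction, so all
#' linkage structure lives in the haplotype table.
#'
#' @param cohorts Tibble with columns `taxon`, `site`, `zone`, `n_samples`,
#'   and `hap_freqs` (list-column of named numeric vectors over kdr labels,
#'   each summing to 1 within 1e-9).
#' @param config A [kdr_config()].
#' @param n_background_sites Number of neutral biallelic background sites.
#' @param background_spectrum Function `n -> n` allele frequencies in (0, 1);
#'   defaults to Uniform(0.05, 0.95).
#' @param region Genomic span the synthetic sites occupy.
#' @return A `kdr_cohort_spec` object.
#' @export
kdr_cohort_spec <- function(cohorts, config = kdr_config(),
                            n_background_sites = 200,
                            background_spectrum = function(n) stats::runif(n, 0.05, 0.95),
                            region = "2L:2358158-2431617") {
  cohorts <- tibble::as_tibble(cohorts)
  stopifnot(all(c("taxon", "site", "n_samples", "hap_freqs") %in% names(cohorts)))
  if (!"zone" %in% names(cohorts)) cohorts$zone <- "unspecified"
  alphabet <- kdr_label_alphabet(config)
  for (i in seq_len(nrow(cohorts))) {
    f <- cohorts$hap_freqs[[i]]
    if (abs(sum(f) - 1) > 1e-9) {
      stop("haplotype frequencies for ", cohorts$taxon[i], "/",
           cohorts$site[i], " sum to ", sum(f), ", not 1", call. = FALSE)
    }
    bad <- setdiff(names(f), alphabet)
    if (length(bad)) {
      stop("labels outside the kdr alphabet: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(cohorts = cohorts, config = config,
         n_background_sites = as.integer(n_background_sites),
         background_spectrum = background_spectrum, region = region),
    class = "kdr_cohort_spec"
  )
}

#' Default study-shaped cohort specification
#'
#' Emulates the structure of a country-wide *An. gambiae* s.l. survey: eight
#' villages spread over three ecological zones, *An. coluzzii* present
#' everywhere with a rich kdr haplotype mixture (995F on the classic
#' background, the 402L(g>t)/402L(g>c) + 1527T backgrounds, and wild type),
#' *An. gambiae* s.s. nearly fixed for the FVI background, and
#' *An. arabiensis* segregating 995F and 995S.
#'
#' @param config A [kdr_config()].
#' @param n_coluzzii,n_gambiae,n_arabiensis Samples per village for each taxon.
#' @return A [kdr_cohort_spec()].
#' @export
default_cohort_spec <- function(config = kdr_config(), n_coluzzii = 60,
                                n_gambiae = 28, n_arabiensis = 25) {
  villages <- tibble::tribble(
    ~site, ~zone,
    "Bana", "Sudanian",
    "Souroukoudinga", "Sudanian",
    "Sideradougou", "Sudanian",
    "Po-Dongo", "Sudanian",
    "Nagare", "Soudano-Sahelian",
    "Gama", "Soudano-Sahelian",
    "Nassan", "Soudano-Sahelian",
    "Ouro-Hesso", "Sahelian"
  )
  # coluzzii table chosen so the 402L/1527T backgrounds imply strong LD for
  # the g>t allele (r2 ~ 0.82) and weak LD for the g>c allele (r2 < 0.1),
  # with 995F segregating at intermediate frequency
  col_freqs <- c(FVI = 0.25, LVI = 0.20, FL1T = 0.10, LL1T = 0.40,
                 LL2T = 0.025, FL2T = 0.015, LVT = 0.01)
  gam_freqs <- c(FVI = 0.97, LVI = 0.03)
  ara_freqs <- c(FVI = 0.45, SVI = 0.25, LVI = 0.30)
  cohorts <- dplyr::bind_rows(
    dplyr::mutate(villages, taxon = "coluzzii", n_samples = n_coluzzii,
                  hap_freqs = list(col_freqs)),
    dplyr::mutate(villages[1:4, ], taxon = "gambiae_ss", n_samples = n_gambiae,
                  hap_freqs = list(gam_freqs)),
    dplyr::mutate(villages[5:7, ], taxon = "arabiensis",
                  n_samples = n_arabiensis, hap_freqs = list(ara_freqs))
  )
  kdr_cohort_spec(cohorts, config = config)
}

#' Simulate a kdr cohort
#'
#' Draws the cohorts declared in a [kdr_cohort_spec()]: two kdr haplotype
#' labels per individual from its cohort's frequency table, expanded to allele
#' indices at the configured loci, plus independent biallelic background sites
#' drawn from the frequency spectrum. The phased haplotype matrix is the
#' ground truth; truth labels are returned for accuracy checks.
#'
#' @param spec A [kdr_cohort_spec()].
#' @param seed Integer seed.
#' @return A list: `samples` (metadata tibble), `genotypes`
#'   ([geno_matrix()]), `haplotypes` (phased [hap_matrix()]), `truth` (tibble
#'   of per-sample true labels).
#' @export
simulate_kdr_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "kdr_cohort_spec"))
  cfg <- spec$config
  r <- parse_region(spec$region)

  # site scaffold: background positions + kdr loci, sorted by position
  set.seed(substream_seed(seed, "cohort/background-sites"))
  avail <- setdiff(seq.int(r$start, r$end), cfg$loci$pos)
  bg_pos <- sort(sample(avail, spec$n_background_sites))
  bg_freq <- spec$background_spectrum(spec$n_background_sites)
  stopifnot(all(bg_freq > 0 & bg_freq < 1))
  variants <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(chrom = cfg$chrom, pos = bg_pos, ref = "A",
                   alts = rep(list("T"), length(bg_pos)),
                   kdr_locus = NA_character_, bg_freq = bg_freq),
    tibble::tibble(chrom = cfg$chrom, pos = cfg$loci$pos, ref = cfg$loci$ref,
                   alts = cfg$loci$alts, kdr_locus = cfg$loci$locus,
                   bg_freq = NA_real_)
  ), .data$pos)
  kdr_rows <- match(cfg$loci$pos, variants$pos)
  bg_rows <- which(is.na(variants$kdr_locus))

  samples <- list(); hap_cols <- list(); truth <- list()
  for (i in seq_len(nrow(spec$cohorts))) {
    co <- spec$cohorts[i, ]
    set.seed(substream_seed(seed, paste0("cohort/", co$taxon, "/", co$site)))
    n <- co$n_samples
    f <- co$hap_freqs[[1]]
    labels <- matrix(sample(names(f), 2L * n, replace = TRUE, prob = f),
                     ncol = 2L)
    ids <- sprintf("%s_%s_%03d", substr(co$taxon, 1, 3),
                   gsub("[^A-Za-z]", "", co$site), seq_len(n))
    samples[[i]] <- tibble::tibble(
      sample_id = ids, taxon = co$taxon, site = co$site, zone = co$zone,
      sex = sample(c("F", "M"), n, replace = TRUE),
      lat = NA_real_, lon = NA_real_
    )
    cols <- matrix(0L, nrow = nrow(variants), ncol = 2L * n)
    for (s in seq_len(n)) {
      for (h in 1:2) {
        j <- 2L * (s - 1L) + h
        cols[kdr_rows, j] <- kdr_label_alleles(labels[s, h], cfg)
      }
    }
    # background: independent per haplotype column
    nb <- length(bg_rows)
    cols[bg_rows, ] <- matrix(
      stats::rbinom(nb * 2L * n, 1L,
                    rep(variants$bg_freq[bg_rows], times = 2L * n)),
      nrow = nb
    )
    hap_cols[[i]] <- cols
    truth[[i]] <- tibble::tibble(
      sample_id = ids, hap1_label = labels[, 1], hap2_label = labels[, 2],
      group_label = vapply(seq_len(n), function(s)
        canonical_pair(labels[s, 1], labels[s, 2], cfg), character(1))
    )
  }
  samples <- dplyr::bind_rows(samples)
  haps <- do.call(cbind, hap_cols)
  vt <- dplyr::select(variants, dplyr::all_of(c("chrom", "pos", "ref", "alts")))
  h <- hap_matrix(vt, haps, samples$sample_id, phased = TRUE)
  list(samples = samples, genotypes = as_geno_matrix(h), haplotypes = h,
       truth = dplyr::bind_rows(truth))
}

#' Copy-number table container
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `family` (one of CYP, COE, GST, ACE1, other).
#' @param copies Integer matrix samples x genes, copy number >= 0.
#' @param samples Character vector of sample ids (rownames of `copies`).
#' @return A `copy_number_table` object.
#' @export
copy_number_table <- function(genes, copies, samples) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "family") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  copies <- as.matrix(copies)
  storage.mode(copies) <- "integer"
  if (any(copies < 0L)) stop("copy numbers must be >= 0", call. = FALSE)
  stopifnot(nrow(copies) == length(samples), ncol(copies) == nrow(genes))
  rownames(copies) <- samples
  colnames(copies) <- genes$gene_id
  structure(list(genes = genes, copies = copies,
                 samples = as.character(samples)),
            class = "copy_number_table")
}

#' @export
print.copy_number_table <- function(x, ...) {
  cat("<copy_number_table> ", length(x$samples), " samples x ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Simulate per-gene copy numbers
#'
#' Independent draws per (sample, gene) from taxon-specific integer
#' copy-number distributions with support in \[0, 12\] (amplifications up to 12
#' copies and complete deletions, matching what coverage-based CNV callers
#' report for detoxification genes). Genes without a configured distribution
#' sit at their baseline ploidy.
#'
#' @param samples Sample metadata tibble (needs `sample_id`, `taxon`, `sex`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `family`).
#' @param dists Tibble with columns `taxon`, `gene_id`, `dist` (list-column of
#'   named numeric vectors: names are copy numbers, values probabilities).
#' @param seed Integer seed.
#' @return A [copy_number_table()].
#' @export
simulate_cnv_table <- function(samples, genes, dists = NULL, seed = 1) {
  genes <- tibble::as_tibble(genes)
  n <- nrow(samples)
  baseline <- cnv_baseline(genes, samples)
  copies <- baseline # matrix n x n_genes
  if (!is.null(dists)) {
    dists <- tibble::as_tibble(dists)
    for (i in seq_len(nrow(dists))) {
      d <- dists$dist[[i]]
      support <- as.integer(names(d))
      if (any(support < 0L) || any(support > 12L)) {
        stop("copy-number support must lie in [0, 12]", call. = FALSE)
      }
      if (abs(sum(d) - 1) > 1e-9) {
        stop("copy-number distribution does not sum to 1", call. = FALSE)
      }
      rows <- which(samples$taxon == dists$taxon[i])
      col <- match(dists$gene_id[i], genes$gene_id)
      if (is.na(col)) stop("unknown gene_id in dists: ", dists$gene_id[i],
                           call. = FALSE)
      if (length(rows)) {
        set.seed(substream_seed(seed, paste0("cnv/", dists$taxon[i], "/",
                                             dists$gene_id[i])))
        copies[rows, col] <- sample(support, length(rows), replace = TRUE,
                                    prob = d)
      }
    }
  }
  copy_number_table(genes, copies, samples$sample_id)
}

# Baseline ploidy matrix: 2 on autosomes; on X, 2 for females, 1 for males,
# `x_unknown` (default 2) when sex is unknown.
cnv_baseline <- function(genes, samples, x_unknown = 2L) {
  n <- nrow(samples)
  base <- matrix(2L, nrow = n, ncol = nrow(genes))
  on_x <- genes$chrom %in% c("X", "chrX")
  if (any(on_x)) {
    sex <- if ("sex" %in% names(samples)) samples$sex else rep("unknown", n)
    per_sample <- ifelse(sex == "M", 1L, ifelse(sex == "F", 2L, x_unknown))
    base[, on_x] <- matrix(per_sample, nrow = n, ncol = sum(on_x))
  }
  base
}
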