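# geno/hap fixtures over the default 3-locus config (pos order: 402 < 995 < 1527)
kdr_fixture_haps <- function(label_pairs, cfg = kdr_config()) {
  loci_pos <- sort(cfg$loci$pos)
  n <- length(label_pairs)
  haps <- matrix(0L, nrow = 3, ncol = 2 * n)
  for (s in seq_len(n)) {
    for (h in 1:2) {
      al <- resistgen:::kdr_label_alleles(label_pairs[[s]][h], cfg)
      # configured order is (995, 402, 1527); variant rows are position-sorted
      haps[match(cfg$loci$pos, loci_pos), 2 * (s - 1) + h] <- al
    }
  }
  variants <- tibble::tibble(
    chrom = cfg$chrom, pos = loci_pos,
    ref = cfg$loci$ref[match(loci_pos, cfg$loci$pos)],
    alts = cfg$loci$alts[match(loci_pos, cfg$loci$pos)])
  hap_matrix(variants, haps, sprintf("m%02d", seq_len(n)), phased = TRUE)
}

test_that("phased diplotype calls read labels off the haplotype columns", {
  cfg <- kdr_config()
  h <- kdr_fixture_haps(list(c("FL1T", "LVI"), c("FVI", "FVI"),
                             c("LVI", "LVI"), c("LVI", "FL1T")))
  calls <- call_diplotypes(h, cfg)
  expect_equal(calls$group_label,
               c("FL1T/LVI", "FVI/FVI", "LVI/LVI", "FL1T/LVI"))
  expect_true(all(calls$phase_source == "phased_input"))
  # symmetric in haplotype order (samples 1 and 4)
  expect_equal(calls$group_label[1], calls$group_label[4])
})

test_that("canonical pair ordering puts the mutant-laden label first", {
  cfg <- kdr_config()
  expect_equal(canonical_pair("LVI", "FL1T", cfg), "FL1T/LVI")
  expect_equal(canonical_pair("FL1T", "LVI", cfg), "FL1T/LVI")
  expect_equal(canonical_pair("FVI", "LVT", cfg), "FVI/LVT") # tie -> lexicographic
  expect_equal(canonical_pair("LL1T", "LL2T", cfg), "LL1T/LL2T")
})

test_that("unphased ambiguity resolves by cohort EM to the dominant pair", {
  cfg <- kdr_config()
  # cohort of unambiguous FL1T/FL1T and LVI/LVI homozygotes plus one triple
  # heterozygote: FL1T/LVI vs (e.g.) FVI/LL1T are genotype-compatible, and
  # the cohort makes FL1T/LVI overwhelmingly more likely
  pairs <- c(rep(list(c("FL1T", "FL1T")), 6), rep(list(c("LVI", "LVI")), 6),
             list(c("FL1T", "LVI")))
  g <- as_geno_matrix(kdr_fixture_haps(pairs))
  calls <- call_diplotypes(g, cfg)
  het <- calls[calls$sample_id == "m13", ]
  expect_equal(het$phase_source, "em_resolved")
  expect_equal(het$group_label, "FL1T/LVI")
  expect_gt(het$posterior, het$runner_up)

  # exhaustive Bayes oracle over the compatible pairs at the EM frequencies
  freqs <- attr(calls, "hap_freqs")
  compat <- resistgen:::compatible_pairs(
    cbind(resistgen:::kdr_label_alleles("FL1T", cfg),
          resistgen:::kdr_label_alleles("LVI", cfg)), cfg)
  w <- freqs[compat$h1] * freqs[compat$h2] *
    ifelse(compat$h1 == compat$h2, 1, 2)
  w[is.na(w)] <- 0
  best <- which.max(w)
  expect_equal(het$group_label,
               canonical_pair(compat$h1[best], compat$h2[best], cfg))
  expect_equal(het$posterior, unname(w[best] / sum(w)), tolerance = 1e-6)
})

test_that("homozygous-consistent genotypes classify without EM", {
  cfg <- kdr_config()
  g <- as_geno_matrix(kdr_fixture_haps(list(c("FVI", "FVI"),
                                            c("FVI", "LVI"))))
  calls <- call_diplotypes(g, cfg)
  expect_equal(calls$group_label, c("FVI/FVI", "FVI/LVI"))
  expect_equal(calls$phase_source, c("unambiguous", "unambiguous"))
})

test_that("missing genotypes at configured loci exclude the sample", {
  cfg <- kdr_config()
  h <- kdr_fixture_haps(list(c("FVI", "FVI"), c("LVI", "LVI")))
  g <- as_geno_matrix(h)
  g$calls[1, 2, ] <- -1L
  calls <- call_diplotypes(g, cfg)
  excl <- attr(calls, "excluded")
  expect_equal(excl$sample_id, "m02")
  expect_equal(nrow(calls), 1L)
})

test_that("diplotype frequencies reproduce the printed-count arithmetic", {
  cfg <- kdr_config()
  pairs <- c(rep(list(c("FVI", "FVI")), 112), list(c("FVI", "LVI")))
  h <- kdr_fixture_haps(pairs)
  calls <- call_diplotypes(h, cfg)
  samples <- tibble::tibble(sample_id = h$samples, taxon = "gambiae_ss",
                            site = "Bana")
  freq <- diplotype_frequencies(calls, samples, grouping = "taxon",
                                min_count = 0)
  fvi <- freq[freq$group_label == "FVI/FVI", ]
  expect_equal(fvi$count, 112L)
  expect_equal(fvi$n_classified, 113L)
  expect_equal(round(fvi$frequency, 3), 0.991)
  expect_equal(sum(freq$frequency), 1)

  # single sample: frequency 1 for its group
  one <- call_diplotypes(kdr_fixture_haps(list(c("LL1T", "LL2T"))), cfg)
  f1 <- diplotype_frequencies(
    one, tibble::tibble(sample_id = "m01", taxon = "coluzzii", site = "x"),
    min_count = 0)
  expect_equal(f1$frequency, 1)

  # rare groups pool into OD
  fod <- diplotype_frequencies(calls, samples, grouping = "taxon",
                               min_count = 3)
  expect_true("OD" %in% fod$group_label)
})

test_that("HWE cohorts recover the expected heterozygote frequency", {
  spec <- kdr_cohort_spec(
    tibble::tibble(taxon = "coluzzii", site = "Bana", n_samples = 500,
                   hap_freqs = list(c(FL1T = 0.4, LVI = 0.6))),
    n_background_sites = 0)
  sim <- simulate_kdr_cohort(spec, seed = 31)
  calls <- call_diplotypes(sim$haplotypes)
  freq <- diplotype_frequencies(calls, sim$samples, grouping = "taxon",
                                min_count = 0)
  het <- freq$frequency[freq$group_label == "FL1T/LVI"]
  p <- 2 * 0.4 * 0.6
  se <- sqrt(p * (1 - p) / 500)
  expect_lt(abs(het - p), 3 * se)
})

test_that("dosage clustering matches exhaustive average-linkage", {
  set.seed(17)
  a1 <- matrix(sample(0:1, 20, TRUE), 4, 5)
  a2 <- matrix(sample(0:1, 20, TRUE), 4, 5)
  g <- toy_geno(a1, a2)
  res <- diplotype_clustering(g)
  d <- dist(dosage_matrix(g), method = "manhattan")
  expect_equal(sort(res$hclust$height), oracle_average_linkage_heights(d),
               tolerance = 1e-12)

  # identical samples merge first at height zero
  a1[, 2] <- a1[, 1]; a2[, 2] <- a2[, 1]
  gid <- toy_geno(a1, a2)
  res2 <- diplotype_clustering(gid)
  expect_equal(min(res2$hclust$height), 0)
  expect_equal(res2$clusters$cluster[1], res2$clusters$cluster[2])
})

test_that("two well-separated backgrounds split into two exact clusters", {
  spec <- kdr_cohort_spec(
    tibble::tibble(taxon = c("coluzzii", "coluzzii"),
                   site = c("Bana", "Nassan"),
                   n_samples = c(20, 20),
                   hap_freqs = list(c(FVI = 1.0), c(LL1T = 1.0))),
    n_background_sites = 0)
  sim <- simulate_kdr_cohort(spec, seed = 41)
  res <- diplotype_clustering(sim$genotypes, k = 2)
  joined <- dplyr::inner_join(res$clusters, sim$truth, by = "sample_id")
  tab <- table(joined$cluster, joined$group_label)
  # each flat cluster is pure and complete for one background
  expect_equal(sort(as.vector(tab)), c(0, 0, 20, 20))
})

test_that("dosage PCA matches the covariance eigendecomposition", {
  set.seed(55)
  a1 <- matrix(sample(0:1, 12, TRUE), 3, 4)
  a2 <- matrix(sample(0:1, 12, TRUE), 3, 4)
  g <- toy_geno(a1, a2)
  p <- pca_dosage(g, n_components = 3)
  d <- dosage_matrix(g)
  ev <- eigen(stats::cov(d))
  # explained variance ratios agree with the covariance spectrum
  expect_equal(p$explained_variance,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  # scores agree up to sign
  ctr <- scale(d, center = TRUE, scale = FALSE)
  for (j in 1:2) {
    sc <- ctr %*% ev$vectors[, j]
    expect_equal(abs(unlist(p$scores[[j + 1]])), abs(as.vector(sc)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # duplicated samples coincide
  gdup <- toy_geno(cbind(a1, a1[, 1]), cbind(a2, a2[, 1]))
  pd <- pca_dosage(gdup)
  expect_equal(unlist(pd$scores[1, -1]), unlist(pd$scores[5, -1]),
               tolerance = 1e-9)

  # antipodal profiles: all variance on PC1
  g2 <- toy_geno(matrix(c(0L, 1L), 3, 2, byrow = FALSE),
                 matrix(c(0L, 1L), 3, 2, byrow = FALSE))
  p2 <- pca_dosage(g2, n_components = 1)
  expect_equal(p2$explained_variance[1], 1)

  # zero-variance input errors
  gz <- toy_geno(matrix(1L, 2, 3), matrix(1L, 2, 3))
  expect_error(pca_dosage(gz), "variance")
})

test_that("phased classification is exact on simulated truth", {
  spec <- default_cohort_spec(n_coluzzii = 15, n_gambiae = 10,
                              n_arabiensis = 8)
  spec$n_background_sites <- 10L
  sim <- simulate_kdr_cohort(spec, seed = 61)
  calls <- call_diplotypes(sim$haplotypes)
  joined <- dplyr::inner_join(calls, sim$truth, by = "sample_id")
  expect_true(all(joined$group_label.x == joined$group_label.y))
})
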