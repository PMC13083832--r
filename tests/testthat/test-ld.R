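test_that("EM equals direct counting when no double heterozygotes exist", {
  # 3x3 counts with an empty double-het cell: haplotypes are fully observed
  counts <- matrix(c(10, 2, 0,
                     3, 0, 1,
                     0, 4, 6), 3, 3, byrow = TRUE)
  fit <- em_haplotype_freq(counts)
  n <- sum(counts)
  # direct haplotype count of AB: unambiguous cells only
  nAB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  expect_equal(fit$p_AB, nAB / (2 * n), tolerance = 1e-9)
  expect_lte(fit$iterations, 2L)
})

test_that("multi-start EM escapes the double-het-only saddle point", {
  counts <- matrix(0, 3, 3)
  counts[2, 2] <- 4 # four double heterozygotes, nothing else
  fit <- em_haplotype_freq(counts)
  oracle <- oracle_ld_grid(counts)
  # two global maxima at r2 = 1; equilibrium (r2 = 0) is a saddle
  expect_equal(oracle$r2, 1, tolerance = 1e-3)
  p <- fit$p
  D <- fit$p_AB - (p[["AB"]] + p[["Ab"]]) * (p[["AB"]] + p[["aB"]])
  r2 <- D^2 / (0.5 * 0.5 * 0.5 * 0.5)
  expect_equal(r2, 1, tolerance = 1e-6)
})

test_that("EM recovers haplotype frequencies drawn from known truth", {
  drawn <- draw_two_locus_counts(c(0.4, 0.1, 0.1, 0.4), n = 200, seed = 5)
  fit <- em_haplotype_freq(drawn$counts)
  se <- sqrt(0.4 * 0.6 / (2 * 200))
  expect_lt(abs(fit$p_AB - 0.4), 3 * se)
  # grid-search oracle agrees with the EM optimum
  oracle <- oracle_ld_grid(drawn$counts)
  expect_equal(fit$p_AB, oracle$p_AB, tolerance = 1e-3)
})

test_that("EM log-likelihood is non-decreasing every iteration", {
  set.seed(19)
  for (rep in 1:10) {
    counts <- matrix(rpois(9, 4), 3, 3)
    fit <- em_haplotype_freq(counts)
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
  }
})

test_that("dosage-identical loci give r2 = 1 and absent alleles report 0", {
  # 32 diploids, mixed 0/1/2 dosages, focal alleles always co-occurring
  dose <- c(rep(0L, 12), rep(1L, 14), rep(2L, 6))
  a1 <- rbind(as.integer(dose >= 1), as.integer(dose >= 1))
  a2 <- rbind(as.integer(dose == 2), as.integer(dose == 2))
  g <- toy_geno(a1, a2, alts = list("T", "C"), pos = c(100L, 200L))
  res <- allele_r2(g, 100L, 1L, 200L, 1L)
  expect_true(res$defined)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$n, 32L)

  # focal allele absent at locus B: undefined, reported as 0
  gz <- toy_geno(rbind(a1[1, ], 0L), rbind(a1[1, ], 0L),
                 alts = list("T", "C"), pos = c(100L, 200L))
  res0 <- allele_r2(gz, 100L, 1L, 200L, 1L)
  expect_false(res0$defined)
  expect_equal(res0$r2, 0)
})

test_that("r2 is invariant to locus order and joint focal relabeling", {
  drawn <- draw_two_locus_counts(c(0.35, 0.2, 0.15, 0.3), n = 150, seed = 23)
  counts <- drawn$counts
  ab <- em_haplotype_freq(counts)
  ba <- em_haplotype_freq(t(counts))
  r2_of <- function(fit, counts) {
    n <- sum(counts)
    pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
    pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
    (fit$p_AB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  expect_equal(r2_of(ab, counts), r2_of(ba, t(counts)), tolerance = 1e-6)
  # relabel focal vs non-focal at both loci simultaneously
  flipped <- counts[3:1, 3:1]
  fl <- em_haplotype_freq(flipped)
  expect_equal(r2_of(ab, counts), r2_of(fl, flipped), tolerance = 1e-6)
})

test_that("EM r2 approaches the truth-phase direct count as n grows", {
  hap_freqs <- c(0.35, 0.15, 0.1, 0.4)
  for (case in list(list(n = 100, tol = 0.1), list(n = 500, tol = 0.05))) {
    drawn <- draw_two_locus_counts(hap_freqs, n = case$n, seed = 29)
    fit <- em_haplotype_freq(drawn$counts)
    counts <- drawn$counts
    n <- sum(counts)
    pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
    pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
    denom <- pA * (1 - pA) * pB * (1 - pB)
    r2_em <- (fit$p_AB - pA * pB)^2 / denom
    # direct count on the true phased haplotypes (the hidden truth the EM
    # has to reconstruct from unphased genotypes)
    r2_direct <- (drawn$true_p_AB - pA * pB)^2 / denom
    expect_lt(abs(r2_em - r2_direct), case$tol)
  }
})

make_village_geno <- function(doses_a, doses_b) {
  a1 <- rbind(as.integer(doses_a >= 1), as.integer(doses_b >= 1))
  a2 <- rbind(as.integer(doses_a == 2), as.integer(doses_b == 2))
  toy_geno(a1, a2, alts = list("T", "C"), pos = c(100L, 200L))
}

test_that("ld_table pools genotypes for the global row", {
  pairs <- tibble::tibble(pos_a = 100L, allele_a = 1L,
                          pos_b = 200L, allele_b = 1L, name = "A vs B")
  # two villages of identical composition: per-village r2 equals global
  dose <- c(rep(0L, 5), rep(1L, 6), rep(2L, 5))
  g <- make_village_geno(c(dose, dose), c(dose, dose))
  samples <- tibble::tibble(sample_id = g$samples,
                            taxon = "coluzzii",
                            site = rep(c("v1", "v2"), each = 16))
  tab <- ld_table(g, samples, pairs, grouping = "site")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$r2[tab$group == "v1"], tab$r2[tab$group == "v2"])
  expect_equal(tab$r2[tab$group == "global"], tab$r2[tab$group == "v1"],
               tolerance = 1e-9)

  # Simpson-style: opposite coupling phases per village, each r2 = 1,
  # pooled r2 < 1 (direct haplotype arithmetic: D of the pool shrinks)
  d1 <- c(rep(0L, 8), rep(2L, 8))
  g2 <- make_village_geno(c(d1, d1), c(d1, 2L - d1))
  samples2 <- tibble::tibble(sample_id = g2$samples, taxon = "coluzzii",
                             site = rep(c("v1", "v2"), each = 16))
  tab2 <- ld_table(g2, samples2, pairs, grouping = "site")
  expect_equal(tab2$r2[tab2$group == "v1"], 1, tolerance = 1e-9)
  expect_equal(tab2$r2[tab2$group == "v2"], 1, tolerance = 1e-9)
  expect_lt(tab2$r2[tab2$group == "global"], 0.1)

  # single village: global equals the village row
  g3 <- make_village_geno(dose, dose)
  samples3 <- tibble::tibble(sample_id = g3$samples, taxon = "coluzzii",
                             site = "only")
  tab3 <- ld_table(g3, samples3, pairs, grouping = "site")
  expect_equal(tab3$r2[tab3$group == "global"],
               tab3$r2[tab3$group == "only"])
})

test_that("simulated cohorts recover the haplotype-table r2 at n = 500", {
  cfg <- kdr_config()
  # FL1T/LL1T carry 402L(g>t); T allele rides on those plus LVT
  freqs <- c(FL1T = 0.25, LL1T = 0.25, LVI = 0.3, FVI = 0.1, LVT = 0.1)
  has_l1 <- grepl("L1", names(freqs))
  has_t <- grepl("T$", names(freqs))
  implied <- table_r2(freqs, has_l1, has_t)
  spec <- kdr_cohort_spec(
    tibble::tibble(taxon = "coluzzii", site = "Bana", n_samples = 500,
                   hap_freqs = list(freqs)),
    config = cfg, n_background_sites = 0)
  sim <- simulate_kdr_cohort(spec, seed = 47)
  p402 <- cfg$loci$pos[cfg$loci$locus == "402"]
  p1527 <- cfg$loci$pos[cfg$loci$locus == "1527"]
  res <- allele_r2(sim$genotypes, p402, 1L, p1527, 1L)
  expect_lt(abs(res$r2 - implied), 0.05)
})
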