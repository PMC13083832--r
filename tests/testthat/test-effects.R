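write_toy_model <- function(strand, seq11_19) {
  gff <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  fas <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(c(
    "##gff-version 3",
    paste(c("chr1", "toy", "CDS", "11", "19", ".", strand, "0",
            "Parent=tx1"), collapse = "\t")
  ), gff)
  writeLines(c(">chr1", paste0(strrep("N", 10), seq11_19, strrep("N", 5))),
             fas)
  read_gene_model(gff, "tx1", fasta_path = fas)
}

test_that("both nucleotide routes to Val->Leu get their own records", {
  gm <- write_toy_model("+", "GTGGGAAAA") # codons GTG GGA AAA
  variants <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "G",
                             alts = list(c("T", "C")))
  eff <- annotate_effects(variants, gm)
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$ref_aa, c("V", "V"))
  expect_equal(eff$alt_aa, c("L", "L")) # TTG and CTG both encode Leu
  expect_equal(eff$effect, c("nonsynonymous", "nonsynonymous"))
  expect_equal(eff$codon_number, c(1L, 1L))
  expect_equal(eff$aa_label, c("V1L", "V1L"))
})

test_that("third-position wobble is synonymous and non-CDS is non_coding", {
  gm <- write_toy_model("+", "GTGGGAAAA")
  variants <- tibble::tibble(
    chrom = "chr1", pos = c(5L, 16L), ref = c("N", "A"),
    alts = list("T", "G"))
  eff <- annotate_effects(variants, gm)
  expect_equal(eff$effect[eff$pos == 5L], "non_coding")
  # GGA -> GGG, Gly -> Gly
  expect_equal(eff$effect[eff$pos == 16L], "synonymous")
  expect_equal(eff$ref_aa[eff$pos == 16L], "G")
})

test_that("minus-strand annotation reverse-complements before translating", {
  # forward 11..19 = ACCATGCAT; minus-strand codons: ATG CAT GGT (M H G)
  gm <- write_toy_model("-", "ACCATGCAT")
  variants <- tibble::tibble(chrom = "chr1", pos = 15L, ref = "T",
                             alts = list("C"))
  eff <- annotate_effects(variants, gm)
  # genomic T>C at codon 2 position 2: CAT -> CGT, His -> Arg (by hand)
  expect_equal(eff$codon_number, 2L)
  expect_equal(eff$ref_aa, "H")
  expect_equal(eff$alt_aa, "R")
  expect_equal(eff$effect, "nonsynonymous")
})

test_that("indel alleles are skipped with a warning", {
  gm <- write_toy_model("+", "GTGGGAAAA")
  variants <- tibble::tibble(chrom = "chr1", pos = 12L, ref = "T",
                             alts = list("TAA"))
  expect_warning(eff <- annotate_effects(variants, gm), "non-SNP")
  expect_equal(nrow(eff), 0L)
})

test_that("allele frequencies use non-missing chromosome denominators", {
  # 120 diploids, one alternate allele: 1/240
  a1 <- matrix(0L, 1, 120); a2 <- matrix(0L, 1, 120)
  a2[1, 1] <- 1L
  g <- toy_geno(a1, a2, alts = list("T"))
  samples <- tibble::tibble(sample_id = g$samples, taxon = "coluzzii",
                            site = "Bana")
  f <- allele_frequencies(g, samples, grouping = "taxon")
  expect_equal(f$frequency, 1 / 240, tolerance = 1e-12)
  expect_equal(f$n_chromosomes, 240L)

  # monomorphic-reference site: frequency 0
  g0 <- toy_geno(matrix(0L, 1, 4), matrix(0L, 1, 4), alts = list("T"))
  s0 <- tibble::tibble(sample_id = g0$samples, taxon = "x", site = "y")
  expect_equal(allele_frequencies(g0, s0, "taxon")$frequency, 0)

  # missing calls shrink the denominator
  a1m <- matrix(c(0L, -1L, 1L), 1, 3); a2m <- matrix(c(0L, -1L, 1L), 1, 3)
  gm <- toy_geno(a1m, a2m, alts = list("T"))
  sm <- tibble::tibble(sample_id = gm$samples, taxon = "x", site = "y")
  fm <- allele_frequencies(gm, sm, "taxon")
  expect_equal(fm$n_chromosomes, 4L)
  expect_equal(fm$frequency, 0.5)
})

test_that("multiallelic sites get per-allele and cumulative rows", {
  # 20 chromosomes: allele 1 at 0.1 (2 copies), allele 2 at 0.35 (7 copies)
  a1 <- matrix(c(rep(1L, 2), rep(2L, 7), rep(0L, 1)), 1, 10)
  a2 <- matrix(0L, 1, 10)
  g <- toy_geno(a1, a2, alts = list(c("T", "C")))
  s <- tibble::tibble(sample_id = g$samples, taxon = "x", site = "y")
  f <- allele_frequencies(g, s, "taxon")
  expect_equal(f$frequency[f$allele_index %in% 1L], 0.1)
  expect_equal(f$frequency[f$allele_index %in% 2L], 0.35)
  cum <- f[f$cumulative, ]
  expect_equal(nrow(cum), 1L)
  expect_equal(cum$frequency, 0.45)
  # ref + alt frequencies account for every chromosome
  expect_equal(sum(f$frequency[!f$cumulative]) , 0.45)
})

test_that("frequency filtering is strict and matches a brute-force scan", {
  set.seed(33)
  tbl <- tibble::tibble(
    taxon = rep(c("g1", "g2"), each = 25),
    chrom = "2L", pos = rep(1:25 * 10L, 2), ref = "A",
    alt = "T", allele_index = 1L, aa_label = NA_character_,
    frequency = round(runif(50, 0, 0.2), 3),
    n_chromosomes = 100L, cumulative = FALSE)
  tbl$frequency[1] <- 0.05  # exactly at threshold in group 1
  tbl$frequency[26] <- 0.04 # and below it in group 2
  tbl$frequency[2] <- 0.051
  kept <- filter_by_frequency(tbl, min_freq = 0.05)
  expect_false(tbl$pos[1] %in% kept$pos[kept$taxon == "g1" & kept$pos == 10])
  expect_true(20L %in% kept$pos)
  # brute force: an allele survives iff any group exceeds the threshold
  surv <- sort(unique(tbl$pos[tbl$frequency > 0.05]))
  expect_equal(sort(unique(kept$pos)), surv)
})

test_that("frequency matrix co-clustering matches exhaustive agglomeration", {
  tbl <- tidyr::expand_grid(
    taxon = c("gA", "gB", "gC"),
    pos = c(10L, 20L, 30L, 40L)) |>
    dplyr::mutate(chrom = "2L", ref = "A", alt = "T", allele_index = 1L,
                  aa_label = NA_character_, n_chromosomes = 50L,
                  cumulative = FALSE,
                  frequency = c(0.9, 0.88, 0.1, 0.12,
                                0.85, 0.9, 0.15, 0.1,
                                0.1, 0.05, 0.95, 0.9))
  fm <- frequency_matrix(tbl, grouping = "taxon")
  expect_equal(dim(fm$matrix), c(4L, 3L))
  oracle <- oracle_average_linkage_heights(
    dist(fm$matrix[order(rownames(fm$matrix)), ]))
  expect_equal(sort(fm$row_hclust$height), oracle, tolerance = 1e-12)

  # identical rows sit adjacent in leaf order
  tbl2 <- tbl
  tbl2$frequency[tbl2$pos == 20L] <- tbl2$frequency[tbl2$pos == 10L]
  fm2 <- frequency_matrix(tbl2, grouping = "taxon")
  leaves <- rownames(fm2$matrix)[fm2$row_order]
  i1 <- which(grepl(":10:", leaves)); i2 <- which(grepl(":20:", leaves))
  expect_equal(abs(i1 - i2), 1L)

  # constant matrix: all distances zero, label order is deterministic
  tbl3 <- dplyr::mutate(tbl, frequency = 0.5)
  fm3a <- frequency_matrix(tbl3, grouping = "taxon")
  fm3b <- frequency_matrix(tbl3[sample(nrow(tbl3)), ], grouping = "taxon")
  expect_identical(rownames(fm3a$matrix)[fm3a$row_order],
                   rownames(fm3b$matrix)[fm3b$row_order])
})

test_that("annotation is involution-consistent", {
  gm <- write_toy_model("+", "GTGGGAAAA")
  variants <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "G",
                             alts = list("T"))
  eff <- annotate_effects(variants, gm)
  # applying the alternate then the reverse substitution restores ref_aa
  gm2 <- write_toy_model("+", "TTGGGAAAA")
  back <- annotate_effects(
    tibble::tibble(chrom = "chr1", pos = 11L, ref = "T", alts = list("G")),
    gm2)
  expect_equal(back$alt_aa, eff$ref_aa)
  expect_equal(back$ref_aa, eff$alt_aa)
})
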