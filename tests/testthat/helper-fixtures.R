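# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written as naive brute-force code, separate from
# any package internals they check.

# Build a geno_matrix from two allele matrices (variants x samples).
toy_geno <- function(a1, a2, alts = NULL, chrom = "2L", pos = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  nv <- nrow(a1)
  if (is.null(pos)) pos <- seq_len(nv) * 10L
  if (is.null(alts)) {
    alts <- lapply(seq_len(nv), function(i) {
      k <- max(c(a1[i, ], a2[i, ]), 1L)
      c("T", "C", "G")[seq_len(max(k, 1L))]
    })
  }
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alts = alts)
  calls <- array(-1L, dim = c(nv, ncol(a1), 2L))
  calls[, , 1L] <- as.integer(a1)
  calls[, , 2L] <- as.integer(a2)
  geno_matrix(variants, calls, sprintf("s%02d", seq_len(ncol(a1))))
}

# Build a phased hap_matrix from a haplotypes-in-columns matrix.
toy_haps <- function(haps, alts = NULL, chrom = "2L", pos = NULL) {
  haps <- as.matrix(haps)
  nv <- nrow(haps)
  if (is.null(pos)) pos <- seq_len(nv) * 10L
  if (is.null(alts)) {
    alts <- lapply(seq_len(nv), function(i) {
      k <- max(haps[i, ], 1L)
      c("T", "C", "G")[seq_len(max(k, 1L))]
    })
  }
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = "A", alts = alts)
  hap_matrix(variants, haps, sprintf("s%02d", seq_len(ncol(haps) / 2L)),
             phased = TRUE)
}

# --- diversity oracles ------------------------------------------------------

# Exhaustive per-site oracle for S, multiallelic count, and total mean
# pairwise difference, enumerating every pair of non-missing alleles.
oracle_diversity <- function(g) {
  nv <- nrow(g$variants)
  S <- 0L; multi <- 0L; pi_total <- 0
  for (i in seq_len(nv)) {
    a <- c(g$calls[i, , 1L], g$calls[i, , 2L])
    a <- a[a >= 0L]
    u <- unique(a)
    if (length(u) >= 2L) S <- S + 1L
    if (length(u) >= 3L) multi <- multi + 1L
    if (length(a) >= 2L) {
      pairs <- utils::combn(length(a), 2L)
      diffs <- sum(a[pairs[1, ]] != a[pairs[2, ]])
      pi_total <- pi_total + diffs / ncol(pairs)
    }
  }
  list(S = S, n_multiallelic = multi, pi_total = pi_total)
}

# Independent Tajima's D evaluation (direct 1989 constants, written from the
# published definitions, not from the package code path).
oracle_tajima <- function(g) {
  od <- oracle_diversity(g)
  if (od$S == 0L) return(NA_real_)
  counts <- apply(g$calls, 1, function(m) sum(m >= 0L))
  counts <- counts[counts > 0L]
  tb <- table(counts)
  m <- max(as.integer(names(tb)[tb == max(tb)]))
  i <- seq_len(m - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1)); b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  den2 <- e1 * od$S + e2 * od$S * (od$S - 1)
  num <- od$pi_total - od$S / a1
  if (den2 <= 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / sqrt(den2)
}

# --- clustering oracle ------------------------------------------------------

# Naive agglomerative average-linkage: returns sorted merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# --- LD oracles -------------------------------------------------------------

# Grid search of the two-locus likelihood over p_AB at fixed allele
# frequencies (the EM's profile direction).
oracle_ld_grid <- function(counts, n_grid = 20001) {
  n <- sum(counts)
  pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
  pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, function(pAB) {
    hap <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(hap < -1e-12)) return(-Inf)
    hap <- pmax(hap, 1e-300)
    probs <- matrix(0, 3, 3)
    cp <- function(h1, h2) if (h1 == h2) hap[h1]^2 else 2 * hap[h1] * hap[h2]
    probs[1, 1] <- cp(4, 4); probs[1, 2] <- cp(4, 3); probs[1, 3] <- cp(3, 3)
    probs[2, 1] <- cp(4, 2); probs[2, 3] <- cp(3, 1)
    probs[2, 2] <- 2 * (hap[1] * hap[4] + hap[2] * hap[3])
    probs[3, 1] <- cp(2, 2); probs[3, 2] <- cp(2, 1); probs[3, 3] <- cp(1, 1)
    sum(counts[counts > 0] * log(probs[counts > 0]))
  }, numeric(1))
  best <- grid[which.max(ll)]
  D <- best - pA * pB
  list(p_AB = best, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Genotype counts for diploids drawn from four haplotype frequencies
# (AB, Ab, aB, ab); the truth-phase oracle keeps the haplotype draws.
draw_two_locus_counts <- function(hap_freqs, n, seed) {
  set.seed(seed)
  haps <- sample(1:4, 2 * n, replace = TRUE, prob = hap_freqs)
  h1 <- haps[seq_len(n) * 2 - 1]; h2 <- haps[seq_len(n) * 2]
  a_copies <- (h1 <= 2) + (h2 <= 2)
  b_copies <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
  counts <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    counts[a_copies[i] + 1, b_copies[i] + 1] <-
      counts[a_copies[i] + 1, b_copies[i] + 1] + 1
  }
  list(counts = counts, true_p_AB = mean(haps == 1))
}

# r2 implied by a haplotype-label frequency table for two focal alleles.
table_r2 <- function(freqs, has_a, has_b) {
  pA <- sum(freqs[has_a]); pB <- sum(freqs[has_b])
  pAB <- sum(freqs[has_a & has_b])
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# --- spanning-tree oracle ---------------------------------------------------

hamming_dist_m <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i, j] <- sum(m[i, ] != m[j, ])
  d
}

# Exhaustive minimum spanning tree weight over a complete weighted graph
# (enumerates all edge subsets of size n-1; fine for n <= 7).
oracle_mst_weight <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n == 1L) return(0)
  edges <- t(utils::combn(n, 2L))
  w <- d[edges]
  best <- Inf
  for (sel in utils::combn(nrow(edges), n - 1L, simplify = FALSE)) {
    # spanning check via union-find
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok && length(unique(vapply(seq_len(n), find, integer(1)))) == 1L) {
      best <- min(best, sum(w[sel]))
    }
  }
  best
}

# Two-locus kdr configuration used by several LD/diplotype tests.
two_locus_config <- function() {
  kdr_config(tibble::tibble(
    locus = c("402", "1527"),
    pos = c(100L, 200L),
    ref = c("G", "T"),
    alts = list(c("T", "C"), "C"),
    labels = list(c("V", "L1", "L2"), c("I", "T"))
  ))
}
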