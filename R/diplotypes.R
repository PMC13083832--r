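#' Canonical diplotype pair label
#'
#' Orders the two haplotype labels mutant-heavy first (more non-reference
#' symbols), ties broken lexicographically, and joins them with `/` — the
#' conventional `FL1T/LVI` style. The result is identical for `(h1, h2)` and
#' `(h2, h1)`.
#'
#' @param h1,h2 Composite haplotype labels.
#' @param cfg A [kdr_config()].
#' @return The canonical `"X/Y"` string.
#' @export
canonical_pair <- function(h1, h2, cfg) {
  l1 <- kdr_mutant_load(h1, cfg)
  l2 <- kdr_mutant_load(h2, cfg)
  if (l1 > l2 || (l1 == l2 && h1 <= h2)) paste0(h1, "/", h2)
  else paste0(h2, "/", h1)
}

#' Classify samples into kdr diplotypes
#'
#' Phased input reads the labels straight off the two haplotype columns
#' (`phase_source = "phased_input"`). Unphased input enumerates every
#' haplotype-label pair consistent with the genotypes at the configured loci;
#' a sample with a unique compatible pair is `unambiguous`, and remaining
#' ambiguity is resolved by maximising the product of cohort haplotype-label
#' frequencies estimated by EM over the whole cohort (`em_resolved`), with
#' the runner-up posterior recorded. Samples with a missing genotype at any
#' configured locus are excluded and reported in the `excluded` attribute.
#'
#' @param data A phased [hap_matrix()] or a [geno_matrix()].
#' @param cfg A [kdr_config()]; all configured loci must be present.
#' @param tol,max_iter EM convergence controls.
#' @return A tibble of calls: `sample_id`, `hap1_label`, `hap2_label`,
#'   `group_label`, `phase_source`, `posterior`, `runner_up`. Attribute
#'   `excluded` is a tibble (`sample_id`, `reason`); attribute `hap_freqs`
#'   carries the EM label-frequency estimates when EM ran.
#' @export
call_diplotypes <- function(data, cfg = kdr_config(), tol = 1e-10,
                            max_iter = 500) {
  if (inherits(data, "hap_matrix") && data$phased) {
    idx <- match_kdr_loci(data$variants, cfg)
    ns <- length(data$samples)
    calls <- purrr::map(seq_len(ns), function(s) {
      h1 <- kdr_alleles_label(data$haps[idx, 2L * s - 1L], cfg)
      h2 <- kdr_alleles_label(data$haps[idx, 2L * s], cfg)
      grp <- canonical_pair(h1, h2, cfg)
      ord <- strsplit(grp, "/", fixed = TRUE)[[1]]
      tibble::tibble(sample_id = data$samples[s], hap1_label = ord[1],
                     hap2_label = ord[2], group_label = grp,
                     phase_source = "phased_input", posterior = 1,
                     runner_up = 0)
    }) |> dplyr::bind_rows()
    attr(calls, "excluded") <- tibble::tibble(sample_id = character(),
                                              reason = character())
    return(calls)
  }
  g <- if (inherits(data, "hap_matrix")) as_geno_matrix(data) else data
  stopifnot(inherits(g, "geno_matrix"))
  idx <- match_kdr_loci(g$variants, cfg)
  ns <- length(g$samples)

  geno <- lapply(seq_len(ns), function(s) {
    cbind(g$calls[idx, s, 1L], g$calls[idx, s, 2L])
  })
  has_missing <- vapply(geno, function(m) any(m < 0L), logical(1))
  excluded <- tibble::tibble(
    sample_id = g$samples[has_missing],
    reason = "missing genotype at a configured kdr locus")

  compat <- lapply(which(!has_missing), function(s) {
    compatible_pairs(geno[[s]], cfg)
  })
  kept <- which(!has_missing)

  # EM over cohort haplotype-label frequencies (uniform start over the labels
  # that appear in at least one compatible pair)
  labels <- sort(unique(unlist(lapply(compat, function(p) c(p$h1, p$h2)))))
  freqs <- stats::setNames(rep(1 / length(labels), length(labels)), labels)
  iterations <- 0L
  if (length(kept)) {
    repeat {
      iterations <- iterations + 1L
      counts <- stats::setNames(numeric(length(labels)), labels)
      for (p in compat) {
        w <- freqs[p$h1] * freqs[p$h2] * ifelse(p$h1 == p$h2, 1, 2)
        if (sum(w) == 0) w <- rep(1, length(w))
        w <- w / sum(w)
        for (j in seq_along(w)) {
          counts[p$h1[j]] <- counts[p$h1[j]] + w[j]
          counts[p$h2[j]] <- counts[p$h2[j]] + w[j]
        }
      }
      new <- counts / sum(counts)
      delta <- max(abs(new - freqs))
      freqs <- new
      if (delta < tol || iterations >= max_iter) break
    }
  }

  calls <- purrr::map(seq_along(kept), function(i) {
    p <- compat[[i]]
    w <- freqs[p$h1] * freqs[p$h2] * ifelse(p$h1 == p$h2, 1, 2)
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
    best <- order(-w, p$h1, p$h2)[1]
    grp <- canonical_pair(p$h1[best], p$h2[best], cfg)
    ord <- strsplit(grp, "/", fixed = TRUE)[[1]]
    tibble::tibble(
      sample_id = g$samples[kept[i]], hap1_label = ord[1], hap2_label = ord[2],
      group_label = grp,
      phase_source = if (length(w) == 1L) "unambiguous" else "em_resolved",
      posterior = unname(w[best]),
      runner_up = if (length(w) == 1L) 0 else unname(sort(w, decreasing = TRUE)[2]))
  }) |> dplyr::bind_rows()
  attr(calls, "excluded") <- excluded
  attr(calls, "hap_freqs") <- freqs
  attr(calls, "em_iterations") <- iterations
  calls
}

# All unordered haplotype-label pairs consistent with a sample's genotypes
# at the configured loci. `geno` is a loci x 2 matrix of allele indices.
compatible_pairs <- function(geno, cfg) {
  # per locus: list of (allele_h1, allele_h2) orientations
  per_locus <- lapply(seq_len(nrow(geno)), function(i) {
    a <- geno[i, 1L]; b <- geno[i, 2L]
    if (a == b) list(c(a, b)) else list(c(a, b), c(b, a))
  })
  combos <- expand.grid(lapply(per_locus, seq_along))
  h1 <- character(nrow(combos)); h2 <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    al1 <- vapply(seq_along(per_locus),
                  function(i) per_locus[[i]][[combos[r, i]]][1], integer(1))
    al2 <- vapply(seq_along(per_locus),
                  function(i) per_locus[[i]][[combos[r, i]]][2], integer(1))
    h1[r] <- kdr_alleles_label(al1, cfg)
    h2[r] <- kdr_alleles_label(al2, cfg)
  }
  key <- ifelse(h1 <= h2, paste(h1, h2), paste(h2, h1))
  keep <- !duplicated(key)
  list(h1 = h1[keep], h2 = h2[keep])
}

#' Diplotype group frequencies
#'
#' Counts each diplotype group within each sample group and divides by the
#' classified samples of that group. Groups observed fewer than `min_count`
#' times over the whole call set are pooled into an `"OD"` (other diplotypes)
#' bucket before the per-group tallies.
#'
#' @param calls Output of [call_diplotypes()].
#' @param samples Sample metadata tibble.
#' @param grouping Metadata columns to group by (default `"taxon"`).
#' @param min_count Pool diplotype groups seen fewer than this many times
#'   (default 3) into `"OD"`; `0` disables pooling.
#' @return A tibble: grouping columns, `group_label`, `count`, `n_classified`,
#'   `frequency`.
#' @export
diplotype_frequencies <- function(calls, samples, grouping = "taxon",
                                  min_count = 3) {
  stopifnot(nrow(calls) > 0L)
  tbl <- dplyr::inner_join(calls, tibble::as_tibble(samples),
                           by = "sample_id")
  if (min_count > 0) {
    tot <- table(tbl$group_label)
    rare <- names(tot)[tot < min_count]
    tbl$group_label[tbl$group_label %in% rare] <- "OD"
  }
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(n_classified = dplyr::n()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "group_label",
                                                  "n_classified")))) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(frequency = .data$count / .data$n_classified) |>
    dplyr::relocate(dplyr::all_of(c(grouping, "group_label", "count",
                                    "n_classified", "frequency")))
}

#' Hierarchical clustering of samples on allele dosage
#'
#' Manhattan distance between per-sample alternate-allele dosage vectors over
#' biallelic-decomposed sites (optionally restricted to a region), average
#' linkage. Samples are ordered by identifier before clustering so tied
#' merges are deterministic. Flat clusters come from cutting the tree at
#' `height` (or into `k` groups).
#'
#' @param g A [geno_matrix()] with >= 2 samples.
#' @param region Optional `"chrom:start-end"` restriction.
#' @param height Cut height for flat clusters (Manhattan units).
#' @param k Alternative: number of flat clusters.
#' @return A list: `hclust` (the tree), `clusters` (tibble `sample_id`,
#'   `cluster`), `distance` (the `dist` object).
#' @export
diplotype_clustering <- function(g, region = NULL, height = NULL, k = NULL) {
  stopifnot(inherits(g, "geno_matrix"), length(g$samples) >= 2L)
  if (!is.null(region)) g <- subset_region(g, region)
  g <- subset_samples(g, sort(g$samples))
  d <- dosage_matrix(g)
  d[is.na(d)] <- 0
  dd <- stats::dist(d, method = "manhattan")
  hc <- stats::hclust(dd, method = "average")
  cl <- if (!is.null(k)) stats::cutree(hc, k = k)
  else if (!is.null(height)) stats::cutree(hc, h = height)
  else stats::cutree(hc, h = max(hc$height) / 2)
  list(hclust = hc,
       clusters = tibble::tibble(sample_id = names(cl), cluster = unname(cl)),
       distance = dd)
}

#' Principal components of allele dosage
#'
#' Mean-centred alternate-allele dosage matrix decomposed by SVD. Missing
#' dosages are replaced by the site mean (i.e. contribute zero after
#' centring). Components are ordered by variance; each component's sign is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param g A [geno_matrix()] with >= 2 samples and >= 1 polymorphic site.
#' @param n_components Number of components to return.
#' @return An object of class `pca_dosage`: `scores` (tibble `sample_id`,
#'   `PC1`, ...), `loadings`, `explained_variance` (proportions), `sdev`.
#' @export
pca_dosage <- function(g, n_components = 2) {
  stopifnot(inherits(g, "geno_matrix"), length(g$samples) >= 2L)
  d <- dosage_matrix(g)
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  v <- apply(d, 2, stats::var)
  if (all(v < .Machine$double.eps)) {
    stop("dosage matrix has zero variance; nothing to decompose",
         call. = FALSE)
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = tibble::tibble(sample_id = g$samples,
                                 tibble::as_tibble(sco)),
         loadings = rot,
         explained_variance = ev[seq_len(n_components)],
         sdev = pc$sdev[seq_len(n_components)]),
    class = "pca_dosage")
}

#' @export
print.pca_dosage <- function(x, ...) {
  cat("<pca_dosage> ", nrow(x$scores), " samples, ",
      ncol(x$scores) - 1L, " components (",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
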