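#' Default detoxification-gene panel for the CNV simulator
#'
#' A small panel shaped like the detoxification families surveyed in CNV
#' scans of *An. gambiae*: carboxylesterases (COE), glutathione
#' S-transferases (GST), cytochrome P450s (CYP) and Ace1, with
#' taxon-specific copy-number mixtures covering amplifications up to 12
#' copies and complete deletions. Gene coordinates are synthetic
#' placeholders.
#'
#' @return A list: `genes` (tibble) and `dists` (tibble of taxon x gene
#'   copy-number distributions).
#' @export
default_cnv_panel <- function() {
  genes <- tibble::tribble(
    ~gene_id, ~chrom, ~start, ~end, ~family,
    "COEAE60", "2R", 28540000L, 28542000L, "COE",
    "COEJHE3E", "2L", 37280000L, 37282000L, "COE",
    "GSTD5", "2R", 25210000L, 25211500L, "GST",
    "GSTE2", "3R", 28597000L, 28598500L, "GST",
    "CYP6AA1", "2R", 28480000L, 28482000L, "CYP",
    "CYP9K1", "X", 15240000L, 15242000L, "CYP",
    "CYP12F2", "3R", 11120000L, 11122000L, "CYP",
    "ACE1", "2R", 3484107L, 3495790L, "ACE1"
  )
  dists <- tibble::tribble(
    ~taxon, ~gene_id, ~dist,
    "coluzzii", "COEAE60", c(`2` = 0.2, `3` = 0.2, `5` = 0.3, `8` = 0.2, `12` = 0.1),
    "coluzzii", "GSTD5", c(`0` = 0.35, `1` = 0.3, `2` = 0.35),
    "coluzzii", "CYP6AA1", c(`2` = 0.5, `4` = 0.4, `6` = 0.1),
    "coluzzii", "CYP12F2", c(`0` = 0.2, `1` = 0.6, `2` = 0.2),
    "coluzzii", "ACE1", c(`2` = 0.85, `3` = 0.1, `4` = 0.05),
    "gambiae_ss", "GSTD5", c(`0` = 1.0),
    "gambiae_ss", "CYP9K1", c(`2` = 0.1, `3` = 0.5, `4` = 0.4),
    "gambiae_ss", "ACE1", c(`2` = 0.8, `3` = 0.15, `4` = 0.05),
    "arabiensis", "GSTD5", c(`0` = 1.0),
    "arabiensis", "COEJHE3E", c(`2` = 0.45, `3` = 0.35, `4` = 0.2),
    "arabiensis", "CYP12F2", c(`0` = 0.3, `1` = 0.5, `2` = 0.2)
  )
  list(genes = genes, dists = dists)
}

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = "results",
    vcf = NULL, metadata = NULL, cnv_table = NULL,
    gff3 = NULL, fasta = NULL, transcript_id = NULL,
    region = "2L:2358158-2431617",
    grouping = c("taxon", "site"),
    min_freq = 0.05,
    n_background_sites = 200,
    n_coluzzii = 60, n_gambiae = 28, n_arabiensis = 25,
    hapnet_epsilon = 0,
    hapnet_kdr_only = TRUE,
    od_min_count = 3,
    log_level = "info"
  )
}

#' Run the analysis pipeline
#'
#' Single entry point exposing every stage as a subcommand over a shared
#' YAML/JSON configuration: `simulate` writes a synthetic cohort (VCF,
#' metadata TSV, copy-number CSV), and `diversity`, `freqs`, `diplotypes`,
#' `ld`, `hapnet` and `cnv` run the corresponding analyses on the configured
#' inputs; `all` chains simulate and every analysis. One global seed governs
#' all stochastic stages through named substreams, so re-running a single
#' subcommand reproduces its slice of a full run. A run manifest (config
#' hash, package version, input checksums) is written alongside the results,
#' and outputs are deterministic given identical config and seed.
#'
#' @param subcommand One of `"simulate"`, `"diversity"`, `"freqs"`,
#'   `"diplotypes"`, `"ld"`, `"hapnet"`, `"cnv"`, `"all"`.
#' @param config A named list, or path to a YAML/JSON file. Unknown keys are
#'   an error; missing input files error before any computation.
#' @param overrides Named list overriding config values (e.g. from CLI
#'   flags).
#' @return Invisibly, a character vector of files written.
#' @export
run_pipeline <- function(subcommand = "all", config = list(),
                         overrides = list()) {
  subcommands <- c("simulate", "diversity", "freqs", "diplotypes", "ld",
                   "hapnet", "cnv", "all")
  subcommand <- match.arg(subcommand, subcommands)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- pipeline_defaults()
  for (src in list(config, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(src)] <- src
  }
  log_msg <- function(...) {
    if (cfg$log_level != "quiet") message("[resistgen] ", ...)
  }

  stages <- if (subcommand == "all") {
    c("simulate", "diversity", "freqs", "diplotypes", "ld", "hapnet", "cnv")
  } else subcommand
  needs_inputs <- setdiff(stages, "simulate")
  simulating <- "simulate" %in% stages

  # pre-flight: every analysis stage needs the genotype inputs
  if (length(needs_inputs) && !simulating) {
    for (key in c("vcf", "metadata")) {
      if (is.null(cfg[[key]])) {
        stop("config key `", key, "` is required for subcommand(s): ",
             paste(needs_inputs, collapse = ", "), call. = FALSE)
      }
      if (!file.exists(cfg[[key]])) {
        stop("input file not found: ", cfg[[key]], call. = FALSE)
      }
    }
    if ("cnv" %in% needs_inputs &&
        (is.null(cfg$cnv_table) || !file.exists(cfg$cnv_table))) {
      stop("config key `cnv_table` must name an existing file for `cnv`",
           call. = FALSE)
    }
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  written <- character()
  emit <- function(tbl, name) {
    write_table(tbl, out(name), format = "csv")
    written <<- c(written, out(name))
  }
  kcfg <- kdr_config()

  if (simulating) {
    log_msg("simulating cohort (seed ", cfg$seed, ")")
    spec <- default_cohort_spec(config = kcfg, n_coluzzii = cfg$n_coluzzii,
                                n_gambiae = cfg$n_gambiae,
                                n_arabiensis = cfg$n_arabiensis)
    spec$n_background_sites <- as.integer(cfg$n_background_sites)
    sim <- simulate_kdr_cohort(spec, seed = cfg$seed)
    write_vcf(sim$genotypes, out("cohort.vcf"), haplotypes = sim$haplotypes)
    readr::write_tsv(sim$samples, out("samples.tsv"), progress = FALSE)
    panel <- default_cnv_panel()
    cnt <- simulate_cnv_table(sim$samples, panel$genes, panel$dists,
                              seed = cfg$seed)
    emit(tidy(cnt), "copy_numbers.csv")
    emit(dplyr::mutate(panel$genes, family = as.character(.data$family)),
         "cnv_genes.csv")
    emit(sim$truth, "truth.csv")
    written <- c(written, out("cohort.vcf"), out("samples.tsv"))
    cfg$vcf <- out("cohort.vcf")
    cfg$metadata <- out("samples.tsv")
    cfg$cnv_table <- out("copy_numbers.csv")
    cfg$cnv_genes <- panel$genes
  }

  if (length(setdiff(stages, "simulate"))) {
    vcf <- read_vcf(cfg$vcf, region = cfg$region)
    samples <- read_sample_metadata(cfg$metadata)
    span <- {
      r <- parse_region(cfg$region)
      r$end - r$start + 1L
    }
  }

  if ("diversity" %in% stages) {
    log_msg("diversity statistics")
    effects <- NULL
    if (!is.null(cfg$gff3) && !is.null(cfg$fasta) &&
        !is.null(cfg$transcript_id)) {
      model <- read_gene_model(cfg$gff3, cfg$transcript_id, cfg$fasta)
      effects <- annotate_effects(vcf$variants, model)
    }
    emit(diversity_summary(vcf$genotypes, samples, span, grouping = "taxon",
                           effects = effects), "diversity.csv")
  }

  if ("freqs" %in% stages) {
    log_msg("allele frequencies")
    freqs <- allele_frequencies(vcf$genotypes, samples,
                                grouping = cfg$grouping,
                                named_alleles = kdr_named_alleles(kcfg))
    kdr_freqs <- freqs[!is.na(freqs$aa_label), , drop = FALSE]
    emit(kdr_freqs, "kdr_frequencies.csv")
    kept <- filter_by_frequency(freqs, min_freq = cfg$min_freq)
    emit(kept, "frequencies_filtered.csv")
    fm <- frequency_matrix(kdr_freqs, grouping = cfg$grouping)
    mat <- tibble::as_tibble(fm$matrix, rownames = "allele")
    emit(mat[fm$row_order, c(1L, 1L + fm$col_order)], "frequency_matrix.csv")
  }

  if ("diplotypes" %in% stages) {
    log_msg("diplotype classification")
    input <- if (!is.null(vcf$haplotypes)) vcf$haplotypes else vcf$genotypes
    calls <- call_diplotypes(input, kcfg)
    emit(calls, "diplotype_calls.csv")
    emit(diplotype_frequencies(calls, samples, grouping = "taxon",
                               min_count = cfg$od_min_count),
         "diplotype_frequencies.csv")
    pca <- pca_dosage(vcf$genotypes, n_components = 2)
    emit(tidy(pca), "pca_coordinates.csv")
  }

  if ("ld" %in% stages) {
    log_msg("linkage disequilibrium")
    loci <- kcfg$loci
    p402 <- loci$pos[loci$locus == "402"]
    p1527 <- loci$pos[loci$locus == "1527"]
    pairs <- tibble::tibble(
      pos_a = c(p402, p402), allele_a = c(1L, 2L),
      pos_b = c(p1527, p1527), allele_b = c(1L, 1L),
      name = c("402L(g>t) vs 1527T", "402L(g>c) vs 1527T"))
    col_samples <- samples[samples$taxon == "coluzzii", , drop = FALSE]
    g_col <- subset_samples(vcf$genotypes, col_samples$sample_id)
    emit(ld_table(g_col, col_samples, pairs, grouping = "site",
                  chrom = kcfg$chrom), "ld_table.csv")
  }

  if ("hapnet" %in% stages) {
    log_msg("haplotype network")
    if (is.null(vcf$haplotypes)) {
      warning("hapnet skipped: input VCF is not fully phased", call. = FALSE)
    } else {
      h <- vcf$haplotypes
      if (isTRUE(cfg$hapnet_kdr_only)) {
        keep <- h$variants$pos %in% kcfg$loci$pos
        h <- subset_variants(h, keep)
      }
      lab <- samples$taxon[match(h$samples, samples$sample_id)]
      net <- median_joining(collapse_haplotypes(h, lab),
                            epsilon = cfg$hapnet_epsilon)
      emit(tidy(net), "hapnet_nodes.csv")
      emit(net$edges, "hapnet_edges.csv")
      export_network(net, out("hapnet.graphml"), format = "graphml")
      written <- c(written, out("hapnet.graphml"))
    }
  }

  if ("cnv" %in% stages) {
    log_msg("copy-number summaries")
    genes <- if (!is.null(cfg$cnv_genes)) cfg$cnv_genes else {
      gene_file <- file.path(dirname(cfg$cnv_table), "cnv_genes.csv")
      if (!file.exists(gene_file)) {
        stop("gene table not found next to cnv_table: ", gene_file,
             call. = FALSE)
      }
      readr::read_csv(gene_file, show_col_types = FALSE, progress = FALSE)
    }
    long <- readr::read_csv(cfg$cnv_table, show_col_types = FALSE,
                            progress = FALSE)
    wide <- tidyr::pivot_wider(long, names_from = "gene_id",
                               values_from = "copies")
    copies <- as.matrix(wide[, genes$gene_id, drop = FALSE])
    cnt <- copy_number_table(genes, copies, wide$sample_id)
    calls <- classify_cnv(cnt, samples)
    emit(calls, "cnv_calls.csv")
    emit(cnv_frequencies(calls, samples, grouping = cfg$grouping),
         "cnv_frequencies.csv")
    emit(cnv_gene_counts(calls, by = c("family", "chrom")),
         "cnv_gene_counts.csv")
  }

  manifest <- list(
    subcommand = subcommand,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("resistgen")),
    seed = cfg$seed,
    inputs = {
      ins <- purrr::compact(cfg[c("vcf", "metadata", "cnv_table")])
      ins <- Filter(function(p) is.character(p) && file.exists(p), ins)
      lapply(ins, function(p) unname(tools::md5sum(p)))
    },
    outputs = basename(written)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(written)
}
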