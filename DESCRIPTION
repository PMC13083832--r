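Package: resistgen
Title: Population Genomics of Insecticide Resistance in Malaria Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for population-genomic surveillance of
    insecticide resistance in Anopheles gambiae sensu lato. Reads VCF genotypes,
    sample metadata, transcript models and per-gene copy-number tables; computes
    multiallelic-aware diversity statistics (segregating sites, nucleotide
    diversity, Watterson's theta, Tajima's D), codon-aware effect annotation and
    per-population allele frequencies with triallelic decomposition, kdr
    diplotype classification with EM phase resolution, allele-specific linkage
    disequilibrium r-squared by maximum likelihood on unphased genotypes,
    median-joining haplotype networks, and amplification/deletion summaries of
    detoxification-gene copy number. Ships coalescent and cohort simulators so
    the whole pipeline is testable without access to cohort sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
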