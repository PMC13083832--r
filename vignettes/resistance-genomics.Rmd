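---
title: "Methods: population genomics of insecticide resistance with resistgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of insecticide resistance with resistgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`resistgen` implements the analysis chain used in genomic surveillance of
insecticide resistance in the *Anopheles gambiae* species complex: diversity
statistics over a resistance gene, codon-aware effect annotation and
population allele frequencies, kdr diplotype classification, allele-specific
linkage disequilibrium, median-joining haplotype networks and
detoxification-gene copy-number summaries. This vignette records the models,
the tunable parameters and the design decisions, in enough detail that a
reader can audit every number the package produces.

## Data model

Genotypes live in a `geno_matrix`: variants × samples × 2 allele indices,
with 0 the reference, *k* the *k*-th alternate and −1 missing. Multiallelic
records are **never split** at ingest — the triallelic codon-402 site is one
variant row with two alternates — and missing genotypes are propagated,
never imputed. Decomposition into per-allele views happens only inside the
frequency and LD computations, which is what keeps "402L(g>t)" and
"402L(g>c)" analysable both separately and cumulatively. Phased haplotypes
(`hap_matrix`) put columns 2i−1 and 2i against sample i; a VCF yields a
phased matrix only when *every* call uses the `|` separator. All coordinates
are 1-based inclusive (VCF/GFF convention) throughout.

The kdr loci are configuration, not constants: `kdr_config()` carries, per
locus, a position, reference and alternate alleles, and a one-symbol label
alphabet (995: L/F/S; 402: V/L1/L2; 1527: I/T). Published coordinates for
these loci are typographically inconsistent across sources, so the defaults
are explicit placeholders inside the *Vgsc* span (2L:2,358,158–2,431,617)
meant for the synthetic cohorts; analyses of real call sets should supply
verified positions.

## Diversity statistics

A site is *segregating* when ≥ 2 distinct allele indices are observed among
non-missing calls, *multiallelic* when ≥ 3; a multiallelic site counts once
in S. Nucleotide diversity treats any two distinct alleles as one
difference (categorical mismatch), so triallelic sites need no splitting:
per site, the mean over all pairs of non-missing alleles of the
"differs" indicator, summed and divided by the analysed span.

Two conventions needed a decision:

* **Denominator.** θπ and θw are divided by the analysed region length (the
  gene span), not an accessibility-masked length. This matches the
  published variant-density arithmetic (5121 sites over 73,460 bp ≈
  0.07 bp⁻¹); a masked denominator can be emulated by passing the masked
  length as `span_bp`.
* **Missing data.** Per-site pair counts use the per-site non-missing allele
  count; Watterson's harmonic constant uses the *modal* non-missing
  chromosome count m across sites (ties resolved to the larger m) rather
  than a per-site harmonic correction — simpler, and exact on complete
  data.

Tajima's D uses the standard constants computed from m, the numerator
π − S/a₁ (π here the total mean pairwise difference, not per-base) and
denominator √(e₁S + e₂S(S−1)). S = 0 returns `NA` — "not computable" is
distinguished from 0. At m = 2 both numerator and denominator vanish
identically and the forced value 0 is returned.

**Known property.** Under neutrality Tajima's D has a small negative mean
in finite samples (the normalisation fixes the variance near 1, not the
mean): our coalescent replicates at n = 10, θ = 5 average ≈ −0.07 (and an
independent msprime run reproduces this). A calibration check that expects
the replicate mean within Monte-Carlo error of exactly 0 therefore sits on
the statistic's own bias once the replicate count passes ~2000; the
package reports the mean rather than hiding it.

## Effect annotation and allele frequencies

`annotate_effects()` maps each SNP allele through a CDS transcript model
built from GFF3 (`read_gene_model()`, exons ordered 5′→3′ in transcript
orientation, CDS length must divide by 3) plus a FASTA sequence. On `-`
transcripts both the codon bases and the VCF (forward-strand) alleles are
complemented before translation; codon numbering is transcript-relative.
Each alternate allele gets its own record, so the two nucleotide routes to
Val→Leu at codon 402 stay distinct. Indels are skipped with a warning.

Frequencies are counts over **non-missing chromosomes per group per site**;
a group with no non-missing chromosomes yields `NA`, not 0. Multiallelic
sites additionally emit a cumulative row (sum of alternate frequencies),
reproducing the "402L(g>t)+402L(g>c)" bookkeeping. The published
frequency filter is strict: an allele at exactly 0.05 is removed; one above
0.05 in at least one group survives. The frequency cluster map uses
average-linkage hierarchical clustering of Euclidean distances between
frequency vectors, with rows and columns pre-sorted by label so tied merges
are deterministic.

## Diplotypes

A diplotype is the unordered pair of kdr haplotype labels an individual
carries. The canonical pair string orders the mutant-heavier label first
(count of non-reference symbols), ties broken lexicographically —
reproducing the conventional "FL1T/LVI" naming. Phased input is read
directly (`phase_source = "phased_input"`, deterministic and total).
Unphased input enumerates all label pairs consistent with the genotypes;
heterozygosity at k loci leaves up to 2^(k−1) pairs. A unique pair is
`unambiguous`; otherwise the cohort's label frequencies are estimated by EM
(E-step: posterior over each sample's compatible pairs proportional to
p(h₁)p(h₂), doubled for heterozygous pairs; M-step: expected label counts),
and the maximum-posterior pair is reported (`em_resolved`) together with
the runner-up posterior. Samples missing a genotype at any configured locus
are excluded with a reason, not guessed.

Rare groups pool into an "OD" (other diplotypes) bucket below a count
threshold (default 3, set to the smallest count that still leaves a
nameable group). Dosage clustering uses Manhattan distance on
biallelic-decomposed alternate-allele dosages and average linkage, samples
pre-sorted by identifier for tie determinism. Dosage PCA mean-centres,
replaces missing dosages by the site mean (zero after centring), decomposes
by SVD and fixes each component's sign so its largest-magnitude loading is
positive.

## Allele-specific LD by EM

r² between two focal alleles collapses each locus to focal-vs-rest — the
decisive convention at the triallelic 402 site. From the 3 × 3 table of
focal-dosage genotype counts, only the double-heterozygote cell is
phase-ambiguous; the EM splits it by p_AB·p_ab / (p_AB·p_ab + p_Ab·p_aB)
and re-estimates the four haplotype frequencies from expected counts. The
likelihood is bimodal when double heterozygotes dominate (the equilibrium
point is a saddle), so the EM runs from three starts — linkage equilibrium,
full coupling, full repulsion — and keeps the best log-likelihood solution;
the log-likelihood trace is exposed and is non-decreasing by construction.
Convergence: tolerance 1e-10 on the frequencies, at most 1000 iterations.

A monomorphic focal allele leaves r² undefined; it is reported as 0 with
`defined = FALSE`, preserving the distinction machine-readably while
matching how such cells are conventionally printed. Missing genotypes are
handled by complete-case analysis per pair. The per-group table adds a
pooled "global" row that pools genotypes across groups (not an average of
per-group r²) — the two differ exactly when coupling phase flips between
villages, and the test suite carries a Simpson-style fixture documenting
this.

## Median-joining networks

Unique haplotypes (multiallelic sites one-hot encoded) are connected by an
ε-relaxed minimum spanning network under Hamming distance: an edge is kept
when its length is within ε of the level at which its endpoints' components
first connect (single-linkage merge height), which at ε = 0 reduces to the
classic minimum spanning network with all tied edges retained. Each round
then adds the site-wise majority vectors of connected triples as candidate
median (Steiner) nodes, until no novel median appears (at most
`max_rounds`, default 20, with a warning on non-convergence). Finally,
median nodes not on any shortest path between observed haplotypes are
pruned and the network rebuilt. ε defaults to 0 — the least-connected,
most parsimonious network — and all tie-breaks are lexicographic in the
haplotype key, so the construction is deterministic and invariant to input
order. Node annotations carry observed counts and label composition;
"sharing" is any node whose composition spans ≥ 2 labels.

## Copy-number summaries

CNV discovery is upstream (coverage-based callers); the package consumes
integer copy numbers. Baselines: 2 on autosomes; on X, 2 for females and 1
for males, with a configurable fallback (default 2) or skip-with-warning
for unknown sex. `amp` is strictly above baseline, `del` strictly below;
zero copies raises a complete-deletion flag. Frequencies are percentages of
assayed samples per (group, gene, state). Gene-level tallies count a gene
once per state across carriers, so a gene amplified in one mosquito and
deleted in another contributes to both the amp and del totals but once to
the gene total — the arithmetic style used when a CNV census reports more
state events than genes.

## The simulators, and what passing tests mean

`simulate_coalescent()` is a constant-size Kingman coalescent with
infinite-sites mutation and no recombination: exponential waiting times
with rate k(k−1)/2, Poisson mutations with mean (θ/2)·branch length, one
new column per mutation. Haplotypes are paired into pseudo-diploids, so the
haplotype count must be even. It exists to calibrate the estimators
(E[S] = θ·a_{n−1}, E[π] = θ), not to model *Anopheles* demography.

`simulate_kdr_cohort()` draws, per (taxon, village) cohort, two haplotype
labels per individual i.i.d. from a label-frequency table (Hardy–Weinberg
at the haplotype level), expands labels to alleles at the configured loci
and adds independent biallelic background sites from a frequency spectrum
(default Uniform(0.05, 0.95)). All linkage structure therefore lives in the
label table; background sites are in linkage equilibrium by construction.
The default cohort emulates a country-wide survey: eight villages across
three ecological zones, *An. coluzzii* everywhere (60/village), *An.
gambiae* s.s. in the four Sudanian villages (28/village, nearly fixed for
the FVI background), *An. arabiensis* in three Soudano-Sahelian villages
(25/village, segregating 995F and 995S) — ~667 mosquitoes. The coluzzii
label table was solved once so the implied two-locus structure matches the
surveyed populations: r²(402L(g>t), 1527T) ≈ 0.82 from the table
arithmetic, r²(402L(g>c), 1527T) ≈ 0.03, and 995F at intermediate
frequency. One global seed feeds named substreams (one per cohort,
replicate or gene), so adding a cohort never perturbs another's draws and
partial re-runs match full runs.

What the generator does **not** emulate: recombination and physical linkage
decay along the gene, selection, demography and migration, sequencing and
phasing error, genotype missingness patterns, and accessibility masks.
Passing tests therefore demonstrate that the estimators recover the
parameters of this idealised process at the simulated sample sizes — they
do not validate robustness to the artefacts of real call sets.

Problem sizes used by the test suite and acceptance script — chosen to keep
Monte-Carlo error well inside the asserted tolerances: 2000 coalescent
replicates at n = 10, θ = 5; LD recovery cohorts of 500 diploids; diplotype
cohorts of 400–667; CNV recovery at 500 samples.

## Known limitations

* Watterson's θ uses the modal chromosome count, which under-corrects when
  missingness varies strongly across sites.
* The EM phase resolver assumes random mating within the cohort it is run
  on; running it across strongly structured cohorts can bias posteriors
  (run per taxon or per village instead).
* Median-joining complexity grows with the number of unique haplotypes;
  the pipeline defaults to the kdr loci (`hapnet_kdr_only`) and expects a
  masked/subset region for genome-scale input.
* Tajima's D carries its intrinsic small negative mean under neutrality
  (see above); calibration checks should compare against that property,
  not against exactly zero.
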