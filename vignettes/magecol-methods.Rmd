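---
title: "Genome-resolved ecology with magecol: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved ecology with magecol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magecol)
options(magecol.verbose = FALSE)
```

## The analysis this package implements

Nitrifying bacteria of the genus *Nitrospira* — both canonical nitrite
oxidizers and complete ammonia oxidizers (comammox, clades A and B of lineage
II) — are surveyed by assembling genomes (MAGs) from metagenomes and then
asking ecological questions with those genomes as the unit of observation.
`magecol` implements that workflow as reusable, tested components:

1. **Species delimitation.** Pairwise average nucleotide identity (ANI)
   between genomes of one genus is empirically bimodal: conspecific pairs sit
   near 97–99% and heterospecific pairs below ~93%, with a sparse valley
   between. `detect_discontinuity()` places the species cutoff at that valley
   and `cluster_species()` cuts an average-linkage dendrogram there; one
   representative per species is chosen by assembly quality.
2. **Abundance and richness.** Metagenomic reads are recruited to a database
   of 15 universal single-copy genes (USCGs) from the species
   representatives. A species is *present* in a metagenome when at least 8
   reads map to its markers; *richness* is computed after subsampling every
   metagenome to 5 million reads (3 independent draws, presence when the mean
   mapped count is at least 8), so deeply and shallowly sequenced samples are
   comparable.
3. **Pangenomics.** All-vs-all protein similarity, filtered by the minbit
   heuristic at 0.3, clustered with the Markov Cluster algorithm (MCL), and
   each gene cluster classified as core / comammox-enriched / clade-specific
   / unique by prevalence thresholds.
4. **Compositional statistics.** Abundances are compositional, so analyses
   run on centred log-ratio (CLR) transformed data after multiplicative zero
   replacement; association between species uses the proportionality
   statistic rho with a permutation FDR; group differences use
   Kruskal–Wallis/Dunn or rank-sum tests.
5. **Ecology vs phylogeny.** Mantel permutation tests relate habitat
   similarity (correlation of CLR abundance profiles) to genetic similarity
   (AAI, concatenated single-copy-gene identity, or identities of the
   nitrification enzymes AmoA/HaoA/NxrB), and distance-decay analysis relates
   community dissimilarity (Jaccard) to geographic distance with
   short-distance exclusion.

Every stage consumes standard formats (FASTA/FASTQ/TSV) and every stochastic
step takes an explicit seed.

## Models and formulas

**ANI estimation.** Genomes are sketched with bottom-`s` MinHash over
canonical 21-mers (`s = 5000`); the sketch Jaccard `J` maps to identity with
the Mash formula

$$\mathrm{ANI} = 100\left(1 + \frac{1}{k}\ln\frac{2J}{1+J}\right),$$

clamped to `[0, 100]`. An exact (unsketched) mode exists for small genomes
and cross-checks; the sketched estimate agrees with it within ±0.5 identity
points on ≥50 kb genomes. Alignment-based ANI is out of scope: the k-mer
estimator reproduces the decision-relevant bimodality, which is all the
species cutoff needs.

**Discontinuity detection.** A Gaussian kernel density (Silverman bandwidth)
is fit to the off-diagonal ANI values in `[90, 100]`; the cutoff is the
density minimum inside `[94, 99]`. A candidate minimum counts as a valley
only if the density rises to at least twice its value on both sides —
otherwise near-zero tail wiggles of a unimodal sample would masquerade as
discontinuities — and a unimodal sample falls back to the configured default
(96) with a warning.

**Representative selection** maximizes `completeness − 5 × contamination`
(the conventional MAG quality score), with ties broken by assembly length
then lexicographic id.

**Read recruitment.** Candidate markers for a read are found by exact shared
15-mers (seeded every 8 bp plus the final window; one error-free seed
suffices, so at 1% error virtually every read retains several seeds), then
the ungapped identity of the read on each candidate diagonal is computed.
The read counts for the best-identity species iff identity ≥ 95% (species
mode) or 75% (genus mode); identity ties between species discard the read.
Recruitment is forward-strand, matching the simulator's reads; real reads
would be oriented upstream. Length-normalized coverage (as species
profilers report) is a non-goal — presence and richness rules operate on raw
counts.

**Subsampled richness.** Because recruitment is deterministic per read,
subsampling a metagenome to 5 million reads and re-recruiting is equivalent
to a multivariate hypergeometric draw on the per-species mapped counts;
`richness_resampled()` therefore draws counts directly (sequential
conditional `rhyper`), which is exact and fast. Samples shallower than the
target depth are used in full and flagged.

**Minbit and MCL.** An edge survives when
`bits(i,j) / min(self_i, self_j) ≥ 0.3`. Raw Smith–Waterman scores
(BLOSUM62, gap open 11 / extend 1, via Biostrings) become bitscores with the
standard gapped Karlin–Altschul constants (λ = 0.267, K = 0.041). MCL
iterates expansion (matrix squaring) and inflation (elementwise power 2.0,
column renormalization), pruning entries below 1e-6, until the largest
change is below 1e-8 or 100 iterations (then it warns and interprets the
current state). Clusters are read off attractor rows; overlap resolves to
the attractor with larger mass, ties to the lexicographically smallest id.
The name "minbit" is used for the self-score-ratio filter; pangenome
workflows sometimes print the same heuristic as "maxbit".

**Gene-cluster classification** applies, in first-match-wins order:
core (≥ 80% of all genomes, inclusive), comammox-enriched (> 60% of comammox
genomes, strict; ≥ 40% of clade A and of clade B, inclusive; absent in > 90%
of non-comammox, strict), clade-specific for A, B, A1, A2 in that order
(≥ 55% of the clade, inclusive; absent from every other genome — strict
zero, which users of low-completeness genomes should note), unique (exactly
one genome), else unclassified. The precedence order is this package's own
resolution of overlapping definitions.

**Compositional transforms.** Zero replacement is per-sample multiplicative:
zeros become `δ = 0.65 / total` (0.65 of the count detection limit — the
conventional choice) and non-zeros shrink by `(1 − z·δ)`, preserving all
non-zero ratios. On non-count scales (RPM) the detection limit `1/total` can
be so large that `z·δ ≥ 1`; δ is then capped at `0.65/z` to keep all parts
positive. CLR is `log(p_i / g(p))`. Proportionality is
`ρ = 1 − var(clr_i − clr_j)/(var(clr_i) + var(clr_j))`; its permutation FDR
permutes each species across samples independently and averages
`#{|ρ*| > t} / max(1, #{|ρ| > t})`. PCA is a column-centred SVD with the
sign convention that each component's largest-magnitude loading is positive.

**Mantel machinery.** The statistic is the Pearson correlation of unmasked
upper-triangle entries; significance is two-sided,
`p = (1 + \#\{|r^*| \ge |r|\})/(B + 1)` over `B` random joint
row/column permutations of one matrix. When `n! ≤ B` the permutation
distribution is enumerated exhaustively and `p` is exact. For masked tests
(distance decay with short-distance exclusion) the mask stays fixed at its
matrix positions — geography is treated as fixed, community labels are
permuted. Habitat similarity uses Pearson correlation on CLR profiles
(Spearman available), so Mantel cells correlate similarity with similarity
and positive `r` reads as "ecologically similar species are genetically
similar". The concatenated single-copy similarity at simulation scale is the
mean of per-marker global-alignment identities over the shared marker set;
marker identities come from fresh pairwise Needleman–Wunsch alignments
(terminal gaps excluded from the identity denominator) rather than a reused
multiple alignment — for well-conserved single-copy markers the difference
is negligible and no external aligner is needed.

## What the simulators emulate — and what they do not

`simulate_genome_set()` plants a species structure under a substitution-only
model: species ancestors diverge `(d_between − d_within)/2` from a root and
members `d_within/2` from their ancestor, so expected pairwise identity has
the closed form `100(1 − d)` within and across species, and the ANI
histogram is bimodal by construction. No indels, rearrangements, HGT, or
contamination chimeras — so ANI recovery here is an easier problem than on
real MAGs, and passing tests validate the estimator and clustering logic,
not robustness to assembly artefacts.

`simulate_markers_and_reads()` gives every species one diverged copy of each
of 15 shared family ancestors (default 5% divergence from the family
ancestor, so copies of two species differ by ~10% while families differ
completely), then draws reads multinomially from a known composition with
independent per-base errors; off-target reads are random sequence. Real
USCGs have conserved and variable regions, uneven lengths and biased error
profiles; none of that is modelled.

`simulate_pangenome()` plants each class's presence pattern with margin
(core ~90% prevalence, enriched ~75% of each comammox clade, specific ~75%
of the clade) and draws background clusters iid Bernoulli(0.35), redrawing
any background pattern that would match a class definition. Planting
A1-/A2-specific clusters requires both subclades present; unique clusters
require their clade to hold ≥ 2 genomes (otherwise one genome is 100% ≥ 55%
of its clade and the pattern is clade-specific instead) — impossible
requests error out rather than silently degrade.

`simulate_community_matrix()` builds species habitat preferences as
`β · (genetically shared latent) + independent component`, where the shared
latent is drawn with covariance proportional to the genetic similarity
matrix (eigenvalue-clamped to PSD), adds a per-species spatial Gaussian
field with exponential correlation `exp(−d/range)` over sample coordinates
and iid noise on the log scale, exponentiates, and truncates below a
detection floor of 1.6 RPM — the 8-reads-in-5-million equivalent, so
presence/absence tests downstream are non-trivial. β = 0 gives a clean
Mantel null; increasing β increases the recovered Mantel r monotonically in
the median.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:
12 species × 3 genomes of 200 kb for dereplication; mixtures of 10^6
150-bp reads over 6 species at 1% error for abundance recovery (mean
relative error ~0.2%, comfortably within the 20% band the recruiter is
required to meet for species at ≥1% abundance); 15-id matrices × 499
permutations × 200–500 replicates for Mantel calibration; 30–40 samples for
community simulations. A survey-scale dataset (hundreds of genomes and
metagenomes) runs through the same code paths; only the all-vs-all protein
stage would benefit from enabling the 5-mer prefilter in
`all_vs_all_scores(prefilter = TRUE)`.

Numerical conventions worth knowing:

* ANI sketches hash canonical k-mers to 53-bit values (exact in doubles);
  contigs are joined with an `N` spacer so no junction k-mers arise.
* `cluster_species()` sorts genomes lexicographically before building the
  dendrogram, making the partition invariant to input order; raising the
  cutoff only ever splits clusters.
* MCL adds self-loops equal to each node's maximum incident weight
  (isolated nodes get 1); dead columns after pruning are revived as
  self-attractors.
* The Mantel p-value with enumerated permutations includes the identity
  permutation, so `p ≥ 1/n!` and is never 0; the sampled version uses the
  standard `(1 + b)/(B + 1)` estimator.
* Jaccard dissimilarity between two empty communities is 0 by convention and
  flagged; geographic distances use a 6371 km sphere.
* Dunn's z uses the standard tie correction `Σ(t³−t)/(12(N−1))`; the compact
  letter display is a greedy insert–absorb pass over the Holm-adjusted
  significance graph.

## Open choices this package had to make

* The species cutoff default is **96%** ANI (the discontinuity-derived
  value); 95% — the generic bacterial species boundary — is one config field
  away (`magecol_config(species_ani_cutoff = 95)`).
* The **8-read presence rule** sums reads over the 15 marker families per
  species. Both the raw-count rule (`call_presence()`, used for detection
  maps) and the depth-normalized rule (`richness_resampled()`, used for
  richness) are implemented, since both are legitimate readings of the
  workflow.
* **CLR before or after the co-occurrence filter**: both orders are
  supported; proportionality analyses conventionally transform the filtered
  table (the filter defines the analysis universe), while PCA transforms the
  full table. The choice is the caller's — `clr_table()` composes with
  either.
* Average linkage for species clustering follows the documented default of
  the standard dereplication tool; the linkage criterion is not otherwise
  constrained by the ANI model.

## Known limitations

* Recruitment identity is read-level ungapped identity, not genome-level
  ANI; the 75% "genus mode" is a read-level stand-in for the genus-level
  mapping cutoff described for survey re-analyses.
* AAI uses reciprocal best hits under a single aligner configuration
  (identity ≥ 30%, coverage ≥ 70% of the shorter sequence); paralog-rich
  proteomes can bias RBH-based AAI slightly upward.
* The permutation FDR for rho depends strongly on sample count: with ~30
  simulated samples the |ρ| > 0.15 cutoff is far less stringent than with
  hundreds of metagenomes, and the acceptance report shows exactly that.
* Tree-based phylogenetic-signal statistics (Pagel's λ, Blomberg's K) and
  partial Mantel tests are out of scope; the Mantel framework here treats
  genetic similarity matrices as the phylogenetic summary.
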