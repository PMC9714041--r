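# magecol — genome-resolved ecology of nitrifying bacteria from metagenomes

`magecol` is an R package for the genome-resolved ecology workflow used in
surveys of *Nitrospira*, the genus that contains both canonical nitrite
oxidizers and complete ammonia oxidizers (comammox). It is written for
microbial ecologists who have a collection of genomes (MAGs) and a stack of
metagenomes and want to go from sequences to ecological statements —
which species exist, where they occur, what genes set clades apart, and
whether ecological preference tracks phylogeny — with every step tested and
reproducible.

## What it computes

**Species delimitation by ANI discontinuity.** Pairwise average nucleotide
identity within a genus is bimodal; the package estimates ANI from MinHash
sketches of canonical 21-mers via the Mash transform
`ANI = 100·(1 + ln(2J/(1+J))/k)`, locates the density valley in the
94–99% window, cuts an average-linkage dendrogram there (default 96%), and
picks each species' representative by `completeness − 5·contamination`.

**Marker-gene abundance profiling.** Reads are recruited to a database of 15
universal single-copy genes per species representative (best ungapped
identity ≥ 95%, or 75% in genus mode; ties discarded). A species is present
when ≥ 8 reads map to its markers; richness is computed after subsampling
each metagenome to 5 million reads (3 draws, mean count ≥ 8); the
co-occurrence analysis keeps species with ≥ 1 RPM in ≥ 6 metagenomes.

**Pangenomics.** All-vs-all Smith–Waterman bitscores (BLOSUM62, 11/1),
minbit filtering at `bits/min(self) ≥ 0.3`, Markov clustering (inflation 2),
and threshold classification of gene clusters: core ≥ 80% of genomes;
comammox-enriched > 60% of comammox, ≥ 40% per clade, absent in > 90% of the
rest; clade-specific ≥ 55% of one clade and absent elsewhere; unique.

**Compositional statistics.** Multiplicative zero replacement
(δ = 0.65 of the detection limit), centred log-ratio transform, PCA,
proportionality `ρ = 1 − var(clr_i − clr_j)/(var(clr_i)+var(clr_j))` with a
permutation FDR, Kruskal–Wallis + Dunn (Holm-adjusted, compact letters) and
rank-sum tests.

**Ecology vs phylogeny.** Mantel permutation tests (two-sided, 99,999
permutations by default, exact enumeration on small id sets) between habitat
similarity — the correlation of CLR abundance profiles — and genetic
similarity (AAI, mean single-copy-gene identity, AmoA/HaoA/NxrB identity),
plus Jaccard distance decay against haversine geographic distance with
short-distance exclusion.

**Simulators with known truth** generate every input the pipeline consumes:
genome sets with planted bimodal ANI, marker-read mixtures of known
composition, pangenome matrices with planted class labels, and
sample×species tables with tunable phylogenetic habitat signal and spatial
autocorrelation.

## Worked example

Simulate a 5-species genome set, rebuild the species catalog from ANI alone,
then profile two read mixtures of opposite composition:

```r
library(magecol)

sim <- simulate_genome_set(n_species = 5, members_per_species = 3,
                           genome_length = 5e4, within_divergence = 0.02,
                           between_divergence = 0.08, seed = 7)
catal <- species_catalog(sim$genomes, sketch_size = 2000)
catal$cutoff
#> [1] 94.38
length(catal$clusters)
#> [1] 5
catal$representatives
#> species_1 species_2 species_3 species_4 species_5
#> "s01_g01" "s02_g01" "s03_g03" "s04_g03" "s05_g01"
```

The detected cutoff (94.4%) falls in the valley between the planted
within-species mode (~98% identity) and the between-species mode (~92%), and
the 15 genomes resolve into exactly the 5 planted species.

```r
ms <- simulate_markers_and_reads(5,
        cbind(s1 = c(.4, .3, .15, .1, .05), s2 = c(.05, .1, .15, .3, .4)),
        depth = 2e5, error_rate = 0.01, seed = 8)
db <- build_marker_db(ms$markers)
counts <- sapply(ms$reads, function(r) rowSums(recruit_reads(r, db, 95)$counts))
tab <- abundance_table(counts, c(s1 = 2e5, s2 = 2e5))
round(tab$rpm)
#>          s1     s2
#> sp01 398700  49575
#> sp02 299175 100625
#> sp03 149870 149745
#> sp04 100795 299615
#> sp05  51340 400275
tab$richness
#> s1 s2
#>  5  5
```

RPM tracks the planted compositions (40/30/15/10/5% in sample 1, mirrored in
sample 2) to within a fraction of a percent. Downstream,
`clr_table()` + `habitat_similarity()` + `mantel()` test whether such
abundance profiles correlate with a genetic similarity matrix, and
`distance_decay()` relates Jaccard community dissimilarity to geographic
distance.

## Layout

- `R/` — implementation (I/O, simulators, genome catalog, marker
  quantification, pangenome, compositional statistics, ecology/phylogeny).
- `src/` — Rcpp kernels for k-mer sketching and read recruitment.
- `tests/testthat/` — unit, property and end-to-end tests with independent
  oracles (dense-matrix MCL, dynamic-programming alignment, exact k-mer
  Jaccard, exhaustive Mantel enumeration).
- `vignettes/magecol-methods.Rmd` — the models, parameter choices, simulator
  assumptions and known limitations, in detail.
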