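#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' The defaults are the published workflow's operating values: species are
#' delimited at 96% ANI, a species is called present in a metagenome when at
#' least 8 reads map to its 15 universal single-copy marker genes, richness
#' uses 3 independent subsamplings to 5 million reads, the co-occurrence
#' analysis keeps species reaching 1 RPM in at least 6 metagenomes, the
#' protein-similarity graph is filtered at minbit 0.3 and clustered with MCL
#' inflation 2.0, gene clusters are core at 80% prevalence / comammox-enriched
#' at >60% (>=40% per clade, absent in >90% of non-comammox) / clade-specific
#' at 55%, proportionality uses the |rho| > 0.15 cutoff, Mantel significance
#' uses 99,999 permutations, and read recruitment runs at 95% identity
#' (species mode) or 75% (genus mode).
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of class `magecol_config`.
#' @examples
#' cfg <- magecol_config(species_ani_cutoff = 95)
#' cfg$presence_min_reads
#' @export
magecol_config <- function(...) {
  cfg <- list(
    species_ani_cutoff = 96,
    presence_min_reads = 8,
    normalization_depth = 5e6,
    normalization_reps = 3,
    cooccur_min_rpm = 1,
    cooccur_min_samples = 6,
    minbit = 0.3,
    mcl_inflation = 2.0,
    core_fraction = 0.80,
    enriched_in_fraction = 0.60,
    enriched_per_clade_fraction = 0.40,
    enriched_absent_fraction = 0.90,
    clade_specific_fraction = 0.55,
    rho_cutoff = 0.15,
    mantel_permutations = 99999,
    read_identity_species = 95,
    read_identity_genus = 75,
    rng_seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  fracs <- c("minbit", "core_fraction", "enriched_in_fraction",
             "enriched_per_clade_fraction", "enriched_absent_fraction",
             "clade_specific_fraction")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  for (p in c("species_ani_cutoff", "read_identity_species", "read_identity_genus"))
    if (cfg[[p]] < 0 || cfg[[p]] > 100) stop(p, " must be a percent in [0,100]")
  for (n in c("presence_min_reads", "normalization_depth", "normalization_reps",
              "cooccur_min_samples", "mantel_permutations"))
    if (cfg[[n]] < 0) stop(n, " must be non-negative")
  if (cfg$mcl_inflation <= 1) stop("mcl_inflation must be > 1")
  class(cfg) <- "magecol_config"
  cfg
}

# valid clade labels for Nitrospira genomes; comammox = clades A (A1 u A2) + B
clade_levels <- function() {
  c("lineage_I", "lineage_II_canonical", "comammox_A1", "comammox_A2",
    "comammox_B", "lineage_IV_A", "lineage_IV_B", "other")
}

comammox_clades <- function() c("comammox_A1", "comammox_A2", "comammox_B")
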