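#' Simulate a genome set with bimodal pairwise identity
#'
#' Generates `n_species` species ancestors from a shared root sequence and
#' `members_per_species` members per ancestor under a substitution-only
#' mutation model (no indels). Species ancestors diverge
#' `(between_divergence - within_divergence) / 2` from the root and members
#' `within_divergence / 2` from their ancestor, so the expected pairwise
#' identity is about `100 * (1 - within_divergence)` within a species and
#' `100 * (1 - between_divergence)` across species — the two modes of the
#' genetic discontinuum that ANI-based dereplication exploits.
#'
#' @param n_species,members_per_species counts (both >= 1).
#' @param genome_length bp per genome.
#' @param within_divergence,between_divergence expected pairwise substitution
#'   fractions; `within_divergence < between_divergence`, between in (0, 0.3).
#' @param completeness_range,contamination_range uniform sampling ranges for
#'   the quality metadata.
#' @param clade_labels optional vector recycled over species.
#' @param seed RNG seed.
#' @return list with `genomes` (named list of [genome_record()]) and `truth`
#'   (`species_assignment`: genome_id -> species_id).
#' @export
simulate_genome_set <- function(n_species, members_per_species, genome_length = 2e5,
                                within_divergence = 0.02, between_divergence = 0.08,
                                completeness_range = c(70, 98),
                                contamination_range = c(0, 5),
                                clade_labels = "other", seed = 1) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (members_per_species < 1) stop("members_per_species must be >= 1")
  if (within_divergence >= between_divergence)
    stop("within_divergence must be smaller than between_divergence")
  if (within_divergence < 0 || between_divergence <= 0 || between_divergence >= 0.3)
    stop("divergences must satisfy 0 <= within < between < 0.3")
  clade_labels <- rep_len(clade_labels, n_species)
  with_seed(seed, {
    root <- random_dna(genome_length)
    ancestors <- cpp_mutate_seqs(rep(root, n_species),
                                 (between_divergence - within_divergence) / 2)
    genomes <- list()
    assignment <- character(0)
    for (s in seq_len(n_species)) {
      members <- cpp_mutate_seqs(rep(ancestors[s], members_per_species),
                                 within_divergence / 2)
      for (m in seq_len(members_per_species)) {
        gid <- sprintf("s%02d_g%02d", s, m)
        genomes[[gid]] <- genome_record(
          genome_id = gid, contigs = members[m],
          completeness = runif(1, completeness_range[1], completeness_range[2]),
          contamination = runif(1, contamination_range[1], contamination_range[2]),
          clade_label = clade_labels[s])
        assignment[gid] <- sprintf("species_%02d", s)
      }
    }
    log_stage("simulate_genome_set", n_species = n_species,
              n_genomes = length(genomes), genome_length = genome_length)
    list(genomes = genomes, truth = list(species_assignment = assignment))
  })
}

#' Simulate marker genes and metagenomic read mixtures of known composition
#'
#' Each species carries one diverged copy of each of `marker_count` shared
#' marker-gene family ancestors, so families are homologous across species
#' (they share an ancestor) yet species-discriminative (pairwise copies differ
#' by about `2 * marker_divergence`). Reads are drawn from the markers with
#' multinomial counts `depth * (1 - off_target_fraction) * composition`,
#' uniform family and start position, independent per-base substitution
#' errors; off-target reads are random sequence.
#'
#' @param n_species number of species (ids `sp01`, `sp02`, ...).
#' @param composition matrix of per-sample species proportions
#'   (species x samples, columns sum to 1) or a single vector.
#' @param depth reads per sample.
#' @param marker_count marker families per species.
#' @param marker_length,read_length bp.
#' @param marker_divergence per-species divergence from each family ancestor.
#' @param error_rate per-base sequencing error probability.
#' @param off_target_fraction fraction of reads drawn as random sequence,
#'   in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `markers` (data.frame: species_id, family, sequence),
#'   `reads` (list of character vectors, one per sample) and `truth`
#'   (the composition matrix and per-sample on-target species counts).
#' @export
simulate_markers_and_reads <- function(n_species, composition, depth = 1e5,
                                       marker_count = 15, marker_length = 1000,
                                       read_length = 150, marker_divergence = 0.05,
                                       error_rate = 0.01, off_target_fraction = 0,
                                       seed = 1) {
  if (read_length > marker_length) stop("read_length must not exceed marker_length")
  if (off_target_fraction < 0 || off_target_fraction >= 1)
    stop("off_target_fraction must be in [0, 1)")
  composition <- as.matrix(composition)
  if (nrow(composition) != n_species) stop("composition must have n_species rows")
  if (any(abs(colSums(composition) - 1) > 1e-8))
    stop("per-sample compositions must sum to 1")
  species_ids <- sprintf("sp%02d", seq_len(n_species))
  rownames(composition) <- species_ids
  n_samples <- ncol(composition)
  if (is.null(colnames(composition)))
    colnames(composition) <- sprintf("sample%02d", seq_len(n_samples))
  with_seed(seed, {
    ancestors <- random_dna(marker_length, marker_count)
    markers <- do.call(rbind, lapply(seq_len(n_species), function(s) {
      data.frame(species_id = species_ids[s], family = seq_len(marker_count),
                 sequence = as.character(
                   cpp_mutate_seqs(ancestors, marker_divergence)),
                 stringsAsFactors = FALSE)
    }))
    reads <- vector("list", n_samples)
    names(reads) <- colnames(composition)
    on_counts <- matrix(0L, n_species, n_samples,
                        dimnames = list(species_ids, colnames(composition)))
    max_start <- marker_length - read_length + 1L
    for (j in seq_len(n_samples)) {
      n_off <- rbinom(1, depth, off_target_fraction)
      n_on <- depth - n_off
      cnt <- as.integer(rmultinom(1, n_on, composition[, j]))
      on_counts[, j] <- cnt
      sp_idx <- rep.int(seq_len(n_species), cnt)
      fam_idx <- sample.int(marker_count, n_on, replace = TRUE)
      row_idx <- (sp_idx - 1L) * marker_count + fam_idx
      starts <- sample.int(max_start, n_on, replace = TRUE)
      on_reads <- substring(markers$sequence[row_idx], starts,
                            starts + read_length - 1L)
      if (error_rate > 0) on_reads <- cpp_mutate_seqs(on_reads, error_rate)
      off_reads <- if (n_off > 0) random_dna(read_length, n_off) else character(0)
      rd <- c(on_reads, off_reads)
      reads[[j]] <- rd[sample.int(length(rd))]
    }
    log_stage("simulate_markers_and_reads", n_species = n_species,
              n_samples = n_samples, depth = depth)
    list(markers = markers, reads = reads,
         truth = list(composition = composition, on_target_counts = on_counts))
  })
}

#' Simulate a pangenome presence/absence matrix with planted classes
#'
#' Plants gene clusters (GCs) whose presence patterns satisfy the defining
#' thresholds of each class with margin: core GCs in ~90% of all genomes,
#' comammox-enriched GCs in ~75% of comammox genomes (>= half of each clade,
#' absent from all non-comammox), clade-specific GCs in ~75% of their clade
#' and nowhere else, unique GCs in a single genome, and background GCs drawn
#' independently per genome and redrawn until they match no class.
#'
#' @param genomes_per_clade named integer vector over [clade_levels()].
#' @param n_gc total gene clusters.
#' @param class_mix named fractions summing to 1 over
#'   `core`, `enriched`, `specific`, `unique`, `background`.
#' @param specific_clades which clade-specific flavours to plant, cycled over
#'   the `specific` quota; defaults to every comammox clade present plus
#'   `cladeA` when both A1 and A2 genomes exist.
#' @param seed RNG seed.
#' @return list with `presence` (logical matrix gc x genome), `clade_labels`
#'   (named vector) and `truth` (planted label per gc).
#' @export
simulate_pangenome <- function(genomes_per_clade, n_gc = 100,
                               class_mix = c(core = 0.3, enriched = 0.2,
                                             specific = 0.2, unique = 0.1,
                                             background = 0.2),
                               specific_clades = NULL, seed = 1) {
  full_mix <- setNames(numeric(5), c("core", "enriched", "specific", "unique",
                                     "background"))
  bad <- setdiff(names(class_mix), names(full_mix))
  if (length(bad)) stop("unknown class_mix entries: ", paste(bad, collapse = ", "))
  full_mix[names(class_mix)] <- class_mix
  class_mix <- full_mix
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  stopifnot(all(names(genomes_per_clade) %in% clade_levels()))
  genomes_per_clade <- genomes_per_clade[genomes_per_clade > 0]
  clade_labels <- rep(names(genomes_per_clade), genomes_per_clade)
  gids <- sprintf("%s_g%02d", clade_labels, unlist(lapply(genomes_per_clade, seq_len)))
  names(clade_labels) <- gids
  n <- length(gids)
  is_cmx <- clade_labels %in% comammox_clades()
  is_A <- clade_labels %in% c("comammox_A1", "comammox_A2")
  is_B <- clade_labels == "comammox_B"

  spec_map <- c(cladeA = "cladeA_specific", cladeB = "cladeB_specific",
                cladeA1 = "cladeA1_specific", cladeA2 = "cladeA2_specific")
  spec_members <- list(
    cladeA_specific = gids[is_A], cladeB_specific = gids[is_B],
    cladeA1_specific = gids[clade_labels == "comammox_A1"],
    cladeA2_specific = gids[clade_labels == "comammox_A2"])
  if (is.null(specific_clades)) {
    specific_clades <- character(0)
    if (any(clade_labels == "comammox_A1") && any(clade_labels == "comammox_A2"))
      specific_clades <- c(specific_clades, "cladeA", "cladeA1", "cladeA2")
    else if (any(is_A)) specific_clades <- c(specific_clades, "cladeA")
    if (any(is_B)) specific_clades <- c(specific_clades, "cladeB")
  }

  n_per <- round(class_mix * n_gc)
  n_per["background"] <- n_gc - sum(n_per[setdiff(names(n_per), "background")])
  if (n_per["background"] < 0) stop("class_mix rounding leaves no room; adjust n_gc")

  plant <- function(members_in) {
    pres <- rep(FALSE, n); names(pres) <- gids
    pres[members_in] <- TRUE
    pres
  }
  with_seed(seed, {
    out <- list(); labels <- character(0)
    if (n_per["core"] > 0) {
      m <- ceiling(0.9 * n)
      if (m / n < 0.8) stop("cannot plant core GCs with margin in this genome set")
      for (i in seq_len(n_per["core"])) {
        out[[length(out) + 1]] <- plant(sample(gids, m))
        labels <- c(labels, "core")
      }
    }
    if (n_per["enriched"] > 0) {
      if (!any(is_A) || !any(is_B) || !any(!is_cmx))
        stop("enriched GCs need clade A, clade B and non-comammox genomes")
      for (i in seq_len(n_per["enriched"])) {
        mA <- sample(gids[is_A], ceiling(0.75 * sum(is_A)))
        mB <- sample(gids[is_B], ceiling(0.75 * sum(is_B)))
        memb <- c(mA, mB)
        if (length(memb) / sum(is_cmx) <= 0.6 || length(memb) / n >= 0.8)
          stop("cannot plant enriched GCs with margin in this genome set")
        out[[length(out) + 1]] <- plant(memb)
        labels <- c(labels, "comammox_enriched")
      }
    }
    if (n_per["specific"] > 0) {
      if (length(specific_clades) == 0) stop("no clade available for specific GCs")
      flavours <- rep_len(spec_map[specific_clades], n_per["specific"])
      for (lab in flavours) {
        pool <- spec_members[[lab]]
        m <- ceiling(0.75 * length(pool))
        if (m / length(pool) < 0.55)
          stop("cannot plant ", lab, " GCs with margin")
        memb <- sample(pool, m)
        pattern <- plant(memb)
        if (classify_presence_pattern(pattern, clade_labels) != lab)
          stop("cannot plant ", lab,
               " GCs: pattern matches an earlier class in this genome set")
        out[[length(out) + 1]] <- pattern
        labels <- c(labels, lab)
      }
    }
    if (n_per["unique"] > 0) {
      ok_pool <- gids[clade_labels %in%
                        names(genomes_per_clade)[genomes_per_clade >= 2]]
      if (length(ok_pool) == 0)
        stop("unique GCs need a clade with at least 2 genomes")
      for (i in seq_len(n_per["unique"])) {
        out[[length(out) + 1]] <- plant(sample(ok_pool, 1))
        labels <- c(labels, "unique")
      }
    }
    if (n_per["background"] > 0) {
      for (i in seq_len(n_per["background"])) {
        repeat {
          pattern <- runif(n) < 0.35
          names(pattern) <- gids
          if (sum(pattern) >= 2 &&
              classify_presence_pattern(pattern, clade_labels) == "unclassified")
            break
        }
        out[[length(out) + 1]] <- pattern
        labels <- c(labels, "unclassified")
      }
    }
    presence <- do.call(rbind, out)
    rownames(presence) <- sprintf("GC%04d", seq_len(nrow(presence)))
    names(labels) <- rownames(presence)
    log_stage("simulate_pangenome", n_gc = nrow(presence), n_genomes = n)
    list(presence = presence, clade_labels = clade_labels,
         truth = list(gc_labels = labels))
  })
}

#' Simulate a sample-by-species abundance table with tunable ecology
#'
#' Each species' habitat preference is a weighted sum of a clade-shared
#' latent preference (weight `habitat_signal_beta`, shared across species in
#' proportion to their genetic similarity) and an independent component.
#' Expected log abundance adds the preference for the sample's habitat, a
#' spatially autocorrelated Gaussian field with exponential correlation range
#' `spatial_range_km`, and iid noise; RPM below `detection_floor_rpm`
#' (default the 8-reads-in-5M equivalent, 1.6 RPM) are truncated to zero.
#'
#' @param n_species,n_samples counts.
#' @param habitats character vector of habitat labels, one per sample.
#' @param genetic_similarity [pairwise_matrix()] of percent similarity over
#'   species (or plain symmetric matrix in `[0, 100]`).
#' @param habitat_signal_beta weight of the genetically shared preference
#'   component (0 = no phylogenetic habitat signal).
#' @param spatial_range_km e-folding range of the spatial field; 0 disables
#'   spatial autocorrelation.
#' @param coords data.frame with `lat`, `lon` per sample; random coordinates
#'   in a ~700 km box when `NULL`.
#' @param noise_sd iid log-scale noise.
#' @param spatial_sd,pref_sd standard deviations of the spatial field and of
#'   the independent preference component.
#' @param base_log_rpm mean log RPM before ecology terms.
#' @param detection_floor_rpm truncation threshold producing structural zeros.
#' @param seed RNG seed.
#' @return list with `rpm` (species x samples matrix), `coords`, `habitats`
#'   and `truth` (preference matrix, spatial field, parameters).
#' @export
simulate_community_matrix <- function(n_species, n_samples, habitats,
                                      genetic_similarity, habitat_signal_beta = 1,
                                      spatial_range_km = 0, coords = NULL,
                                      noise_sd = 0.5, spatial_sd = 1, pref_sd = 1,
                                      base_log_rpm = log(20),
                                      detection_floor_rpm = 1.6, seed = 1) {
  habitats <- rep_len(as.character(habitats), n_samples)
  S <- if (inherits(genetic_similarity, "pairwise_matrix"))
    genetic_similarity$values else as.matrix(genetic_similarity)
  if (nrow(S) != n_species) stop("genetic_similarity must be n_species x n_species")
  if (min(S) < 0 || max(S) > 100) stop("genetic_similarity must be in [0, 100]")
  species_ids <- rownames(S)
  if (is.null(species_ids)) species_ids <- sprintf("sp%02d", seq_len(n_species))
  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  C <- S / 100
  diag(C) <- 1
  Lc <- psd_chol(C)
  with_seed(seed, {
    if (is.null(coords))
      coords <- data.frame(lat = runif(n_samples, 42, 48),
                           lon = runif(n_samples, 0, 8))
    hab_types <- unique(habitats)
    pref <- matrix(0, n_species, length(hab_types),
                   dimnames = list(species_ids, hab_types))
    for (h in seq_along(hab_types)) {
      shared <- as.vector(Lc %*% rnorm(n_species))
      pref[, h] <- habitat_signal_beta * shared + pref_sd * rnorm(n_species)
    }
    field <- matrix(0, n_species, n_samples)
    if (spatial_range_km > 0 && spatial_sd > 0) {
      D <- geo_distance_km(coords$lat, coords$lon)
      Ls <- psd_chol(exp(-D / spatial_range_km))
      for (i in seq_len(n_species))
        field[i, ] <- spatial_sd * as.vector(Ls %*% rnorm(n_samples))
    }
    loga <- base_log_rpm + pref[, match(habitats, hab_types), drop = FALSE] +
      field + noise_sd * matrix(rnorm(n_species * n_samples), n_species)
    rpm <- exp(loga)
    rpm[rpm < detection_floor_rpm] <- 0
    dimnames(rpm) <- list(species_ids, sample_ids)
    log_stage("simulate_community_matrix", n_species = n_species,
              n_samples = n_samples, beta = habitat_signal_beta,
              range_km = spatial_range_km)
    list(rpm = rpm, coords = coords, habitats = setNames(habitats, sample_ids),
         truth = list(preference = pref, spatial_field = field,
                      habitat_signal_beta = habitat_signal_beta,
                      spatial_range_km = spatial_range_km))
  })
}

# lower-triangular factor of a symmetric matrix, repaired to the nearest PSD
# by eigenvalue clamping (simulation covariances built from similarity
# matrices are not guaranteed PSD)
psd_chol <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

# plain haversine matrix used inside the simulator (km)
geo_distance_km <- function(lat, lon) {
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- geosphere::distHaversine(cbind(lon[i], lat[i]),
                                       cbind(lon, lat), r = 6371)
  }
  (D + t(D)) / 2
}
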