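#' Build the universal single-copy marker database
#'
#' Collects one nucleotide sequence per (species, marker family) from the
#' species representatives. Species contributing more than one sequence for a
#' family are rejected (markers are single-copy by definition); species with
#' more than `max_missing` missing families are dropped with a warning.
#'
#' @param markers data.frame with columns `species_id`, `family` (integer
#'   1..n_families) and `sequence`.
#' @param n_families expected family count (15 for the standard panel).
#' @param max_missing maximum tolerated missing families per species.
#' @return list of class `marker_db`: the validated `entries` data.frame and
#'   the family/species index vectors used by the recruiter.
#' @export
build_marker_db <- function(markers, n_families = 15, max_missing = 7) {
  stopifnot(is.data.frame(markers),
            all(c("species_id", "family", "sequence") %in% names(markers)))
  if (nrow(markers) == 0) stop("empty marker input")
  key <- paste(markers$species_id, markers$family)
  if (anyDuplicated(key))
    stop("duplicate (species, family) marker entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  n_fam <- tapply(markers$family, markers$species_id, length)
  drop <- names(n_fam)[n_fam < n_families - max_missing]
  if (length(drop)) {
    warning("species missing more than ", max_missing, " marker families dropped: ",
            paste(drop, collapse = ", "))
    markers <- markers[!markers$species_id %in% drop, ]
  }
  if (nrow(markers) == 0) stop("no species with sufficient markers")
  species_ids <- sort(unique(markers$species_id))
  log_stage("build_marker_db", n_species = length(species_ids),
            n_entries = nrow(markers))
  structure(list(entries = markers, species_ids = species_ids,
                 n_families = n_families),
            class = "marker_db")
}

#' Recruit reads to marker genes by best identity
#'
#' Candidate markers for each read are found by exact shared 15-mers, then
#' the ungapped identity of the read placed on each candidate diagonal is
#' computed (positions off the marker count as mismatches). The read is
#' counted for the species of its best-identity marker iff the identity
#' reaches `identity_cutoff`; an identity tie between two species discards
#' the read; each read is counted at most once.
#'
#' @param reads character vector of read sequences (or a [read_fastq()]
#'   result).
#' @param db a [build_marker_db()] database.
#' @param identity_cutoff percent; 95 for species-level recruitment, 75 for
#'   genus-level.
#' @param seed_k k-mer size of the candidate lookup.
#' @param seed_stride spacing of seed positions along the read.
#' @return list with `counts` (species x family matrix of read counts) and
#'   `assignment` (per-read 0/species index, for resampling).
#' @export
recruit_reads <- function(reads, db, identity_cutoff = 95, seed_k = 15,
                          seed_stride = 8) {
  stopifnot(inherits(db, "marker_db"))
  if (is.list(reads) && !is.null(reads$reads)) reads <- reads$reads
  reads <- as.character(reads)
  sp_idx <- match(db$entries$species_id, db$species_ids)
  res <- cpp_recruit(reads, db$entries$sequence, sp_idx,
                     as.integer(db$entries$family), as.integer(seed_k),
                     identity_cutoff / 100, as.integer(seed_stride))
  counts <- matrix(0L, length(db$species_ids), db$n_families,
                   dimnames = list(db$species_ids,
                                   paste0("family", seq_len(db$n_families))))
  hit <- res$species > 0
  if (any(hit)) {
    tab <- table(factor(res$species[hit], levels = seq_along(db$species_ids)),
                 factor(res$family[hit], levels = seq_len(db$n_families)))
    counts[] <- as.integer(tab)
  }
  log_stage("recruit_reads", n_reads = length(reads), n_mapped = sum(hit),
            cutoff = identity_cutoff)
  list(counts = counts, assignment = res$species)
}

#' Presence call from marker-mapped read counts
#'
#' A species is present in a metagenome when at least `min_reads` reads map
#' to its 15 universal single-copy genes (summed over families).
#'
#' @param mapped_reads numeric vector (or scalar) of per-species total mapped
#'   reads.
#' @param min_reads detection threshold (default 8).
#' @return logical vector.
#' @export
call_presence <- function(mapped_reads, min_reads = 8) {
  if (any(mapped_reads < 0)) stop("mapped read counts must be non-negative")
  mapped_reads >= min_reads
}

#' Depth-normalized presence and richness by repeated subsampling
#'
#' Richness is computed at a common sequencing depth: each metagenome is
#' subsampled without replacement to `depth` reads `reps` times, and a
#' species is present iff its mean mapped-read count across the draws is at
#' least `min_reads`. Because read recruitment is deterministic per read,
#' subsampling reads and re-recruiting is equivalent to a multivariate
#' hypergeometric draw on the per-species mapped counts, which is what is
#' done here. Samples with fewer than `depth` reads are used in full and
#' flagged.
#'
#' @param mapped_counts named numeric vector of per-species mapped reads in
#'   the sample.
#' @param total_reads total reads in the sample (mapped + unmapped).
#' @param depth normalization depth (default 5e6).
#' @param reps number of independent subsamplings (default 3).
#' @param min_reads presence threshold on the mean subsampled count.
#' @param seed RNG seed.
#' @return list with `mean_counts`, `presence`, `richness` and `subsampled`
#'   (FALSE when the sample was shallower than `depth`).
#' @export
richness_resampled <- function(mapped_counts, total_reads, depth = 5e6,
                               reps = 3, min_reads = 8, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  if (reps < 1) stop("reps must be >= 1")
  if (sum(mapped_counts) > total_reads)
    stop("mapped counts exceed total reads")
  if (total_reads <= depth) {
    mean_counts <- mapped_counts
    sub <- FALSE
  } else {
    draws <- with_seed(seed, vapply(seq_len(reps), function(r)
      mvhyper_draw(mapped_counts, total_reads, depth), numeric(length(mapped_counts))))
    mean_counts <- rowMeans(matrix(draws, nrow = length(mapped_counts)))
    names(mean_counts) <- names(mapped_counts)
    sub <- TRUE
  }
  presence <- call_presence(mean_counts, min_reads)
  list(mean_counts = mean_counts, presence = presence,
       richness = sum(presence), subsampled = sub)
}

# one multivariate hypergeometric draw: how many of each species' mapped
# reads land in a without-replacement subsample of `depth` from `total`
mvhyper_draw <- function(counts, total, depth) {
  out <- numeric(length(counts))
  remaining_other <- total
  remaining_draw <- depth
  for (i in seq_along(counts)) {
    remaining_other <- remaining_other - counts[i]
    out[i] <- rhyper(1, counts[i], remaining_other, remaining_draw)
    remaining_draw <- remaining_draw - out[i]
  }
  out
}

#' Assemble the species-by-sample abundance table
#'
#' @param counts species x samples matrix of marker-mapped read counts.
#' @param total_reads named vector of per-sample total read counts.
#' @param min_reads presence threshold (default 8, applied to raw counts).
#' @return list of class `abundance_table` with `counts`, `rpm`
#'   (`1e6 * counts / total_reads`), `presence`, per-sample `richness` and
#'   `total_reads`.
#' @export
abundance_table <- function(counts, total_reads, min_reads = 8) {
  counts <- as.matrix(counts)
  if (is.null(names(total_reads))) names(total_reads) <- colnames(counts)
  total_reads <- total_reads[colnames(counts)]
  if (any(is.na(total_reads)) || any(total_reads <= 0))
    stop("total_reads must be positive for every sample")
  rpm <- sweep(counts, 2, total_reads, "/") * 1e6
  presence <- counts >= min_reads
  structure(list(counts = counts, rpm = rpm, presence = presence,
                 richness = colSums(presence), total_reads = total_reads),
            class = "abundance_table")
}

#' Co-occurrence analysis filter
#'
#' Keeps species with at least `min_rpm` reads per million in at least
#' `min_samples` metagenomes — the admission rule for the proportionality and
#' habitat-similarity analyses.
#'
#' @param tab an [abundance_table()] (or a plain RPM matrix).
#' @param min_rpm,min_samples thresholds (defaults 1 RPM, 6 samples).
#' @return character vector of retained species ids.
#' @export
cooccurrence_filter <- function(tab, min_rpm = 1, min_samples = 6) {
  rpm <- if (inherits(tab, "abundance_table")) tab$rpm else as.matrix(tab)
  keep <- rowSums(rpm >= min_rpm) >= min_samples
  log_stage("cooccurrence_filter", n_in = nrow(rpm), n_kept = sum(keep))
  rownames(rpm)[keep]
}
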