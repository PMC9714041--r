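#' Filter genomes on assembly quality
#'
#' Keeps genomes with completeness >= 70% and contamination <= 5% (both
#' boundaries inclusive), the standard medium-to-high-quality MAG admission
#' rule.
#'
#' @param genomes list of [genome_record()].
#' @param min_completeness,max_contamination percent thresholds.
#' @return the retained sublist.
#' @export
filter_quality <- function(genomes, min_completeness = 70, max_contamination = 5) {
  comp <- vapply(genomes, function(g) g$completeness, numeric(1))
  cont <- vapply(genomes, function(g) g$contamination, numeric(1))
  if (anyNA(comp) || anyNA(cont))
    stop("completeness/contamination missing for: ",
         paste(names(genomes)[is.na(comp) | is.na(cont)], collapse = ", "))
  keep <- comp >= min_completeness & cont <= max_contamination
  log_stage("filter_quality", n_in = length(genomes), n_kept = sum(keep))
  genomes[keep]
}

#' Estimate ANI between two genomes from k-mer sketches
#'
#' MinHash-style bottom sketch of canonical k-mers; the sketch Jaccard J is
#' mapped to average nucleotide identity with the Mash formula
#' `ANI = 100 * (1 + log(2J / (1 + J)) / k)`, clamped to `[0, 100]`.
#' With `exact = TRUE` the full (unsketched) k-mer sets are used instead of
#' sketches — slower but deterministic to the last digit, for small genomes
#' and cross-checks.
#'
#' @param genomeA,genomeB [genome_record()] objects or character vectors of
#'   contig sequences.
#' @param k odd k-mer size in `[15, 31]`.
#' @param sketch_size number of hashes retained per genome.
#' @param exact use exact k-mer Jaccard instead of sketching.
#' @return ANI percent in `[0, 100]`.
#' @export
compute_ani <- function(genomeA, genomeB, k = 21, sketch_size = 5000, exact = FALSE) {
  if (k %% 2 == 0 || k < 15 || k > 31) stop("k must be odd and in [15, 31]")
  sa <- genome_seq(genomeA); sb <- genome_seq(genomeB)
  if (nchar(sa) < k || nchar(sb) < k) stop("sequence shorter than k")
  J <- if (exact) {
    cpp_exact_kmer_jaccard(sa, sb, k)
  } else {
    cpp_sketch_jaccard(cpp_kmer_sketch(sa, k, sketch_size),
                       cpp_kmer_sketch(sb, k, sketch_size), sketch_size)
  }
  jaccard_to_ani(J, k)
}

# concatenate contigs with an N spacer so no artefactual junction k-mers form
genome_seq <- function(g) {
  contigs <- if (inherits(g, "genome_record")) g$contigs else as.character(g)
  paste(contigs, collapse = "N")
}

jaccard_to_ani <- function(J, k) {
  if (J <= 0) return(0)
  max(0, min(100, 100 * (1 + log(2 * J / (1 + J)) / k)))
}

#' All-vs-all ANI matrix
#'
#' @param genomes named list of [genome_record()].
#' @inheritParams compute_ani
#' @return an `ani_matrix`: list with `genome_ids`, symmetric `values`
#'   (percent, diagonal 100) and `method`.
#' @export
ani_matrix <- function(genomes, k = 21, sketch_size = 5000, exact = FALSE) {
  n <- length(genomes)
  if (n == 0) stop("empty genome set")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  vals <- matrix(100, n, n, dimnames = list(ids, ids))
  if (exact) {
    seqs <- lapply(genomes, genome_seq)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      vals[i, j] <- vals[j, i] <- jaccard_to_ani(
        cpp_exact_kmer_jaccard(seqs[[i]], seqs[[j]], k), k)
    }
  } else {
    sketches <- lapply(genomes, function(g)
      cpp_kmer_sketch(genome_seq(g), k, sketch_size))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      vals[i, j] <- vals[j, i] <- jaccard_to_ani(
        cpp_sketch_jaccard(sketches[[i]], sketches[[j]], sketch_size), k)
    }
  }
  log_stage("ani_matrix", n_genomes = n, k = k,
            method = if (exact) "kmer_exact" else "kmer_mash")
  structure(list(genome_ids = ids, values = vals,
                 method = if (exact) "kmer_exact" else "kmer_mash"),
            class = "ani_matrix")
}

#' Detect the species-level discontinuity in an ANI distribution
#'
#' Pairwise ANI values between genomes of a mixed-species set are bimodal:
#' a within-species mode near 97-99% and a between-species mode below ~93%.
#' The species cutoff is placed at the valley of a Gaussian kernel density
#' estimate (Silverman bandwidth) of the values, searched within
#' `[window[1], window[2]]` percent. When no interior valley exists (the
#' density is unimodal over the window) the configured default is returned
#' with a warning.
#'
#' @param ani_values numeric vector of off-diagonal ANI percent values;
#'   values outside `[90, 100]` are dropped before estimation.
#' @param window percent range searched for the valley.
#' @param default fallback cutoff when no discontinuity is found.
#' @return cutoff percent.
#' @export
detect_discontinuity <- function(ani_values, window = c(94, 99), default = 96) {
  ani_values <- ani_values[!is.na(ani_values)]
  ani_values <- ani_values[ani_values >= 90 & ani_values <= 100]
  if (length(ani_values) < 10)
    stop("need at least 10 ANI values in [90,100] to locate a discontinuity")
  d <- density(ani_values, bw = "nrd0", from = 90, to = 100, n = 1024)
  in_win <- d$x >= window[1] & d$x <= window[2]
  y <- d$y
  # interior local minima of the full-range density
  is_min <- c(FALSE, y[2:(length(y) - 1)] < y[1:(length(y) - 2)] &
                     y[2:(length(y) - 1)] <= y[3:length(y)], FALSE)
  # a genuine valley must have a substantially higher density peak on each
  # side; this rejects numerical wiggles in near-zero tails of a unimodal
  # distribution
  cand <- which(is_min & in_win)
  cand <- cand[vapply(cand, function(i) {
    left_peak <- max(y[seq_len(i - 1)])
    right_peak <- max(y[seq(i + 1, length(y))])
    min(left_peak, right_peak) >= 2 * y[i] + 1e-12
  }, logical(1))]
  if (length(cand) == 0) {
    warning("ANI density is unimodal in the search window; using default cutoff ",
            default)
    return(default)
  }
  cutoff <- d$x[cand[which.min(y[cand])]]
  log_stage("detect_discontinuity", n_values = length(ani_values),
            cutoff = round(cutoff, 2))
  cutoff
}

#' Cluster genomes into species at an ANI cutoff
#'
#' Average-linkage hierarchical clustering on the distance
#' `(100 - ANI) / 100`, cut at height `(100 - cutoff) / 100`. The result is
#' invariant to the input order of genomes; cluster numbering follows the
#' lexicographically smallest member id.
#'
#' @param ani an `ani_matrix` from [ani_matrix()].
#' @param cutoff species ANI cutoff percent.
#' @return named integer vector: genome_id -> species cluster index.
#' @export
cluster_species <- function(ani, cutoff = 96) {
  stopifnot(inherits(ani, "ani_matrix"))
  n <- length(ani$genome_ids)
  if (n == 0) stop("empty ANI matrix")
  if (n == 1) return(setNames(1L, ani$genome_ids))
  # canonical genome order makes the dendrogram (and any tie-breaking inside
  # hclust) independent of input permutation
  ord <- order(ani$genome_ids)
  vals <- ani$values[ord, ord]
  dd <- as.dist((100 - vals) / 100)
  hc <- hclust(dd, method = "average")
  memb <- cutree(hc, h = (100 - cutoff) / 100)
  # renumber clusters by smallest member id (already sorted order)
  memb <- setNames(as.integer(factor(memb, levels = unique(memb))), names(memb))
  log_stage("cluster_species", n_genomes = n, cutoff = cutoff,
            n_species = max(memb))
  memb[ani$genome_ids]
}

#' Choose the representative genome of a species cluster
#'
#' Quality score is `completeness - 5 * contamination`; ties broken by larger
#' total assembly length, then lexicographically smallest id.
#'
#' @param cluster_ids genome ids in the cluster.
#' @param genomes named list of [genome_record()].
#' @return the representative genome id.
#' @export
select_representative <- function(cluster_ids, genomes) {
  if (length(cluster_ids) == 0) stop("empty cluster")
  score <- vapply(cluster_ids, function(id) {
    g <- genomes[[id]]
    g$completeness - 5 * g$contamination
  }, numeric(1))
  len <- vapply(cluster_ids, function(id)
    sum(nchar(genomes[[id]]$contigs)), numeric(1))
  ord <- order(-score, -len, cluster_ids)
  cluster_ids[ord[1]]
}

#' Build a species catalog: cluster, pick representatives
#'
#' @param genomes named list of [genome_record()].
#' @param ani an `ani_matrix`; computed from `genomes` when `NULL`.
#' @param cutoff ANI percent cutoff; when `NULL`, detected from the data via
#'   [detect_discontinuity()].
#' @param ... passed to [ani_matrix()] when it must be computed.
#' @return list of class `species_catalog`: `cutoff`, `clusters`
#'   (list of genome-id vectors), `membership`, `representatives`.
#' @export
species_catalog <- function(genomes, ani = NULL, cutoff = NULL, ...) {
  if (is.null(ani)) ani <- ani_matrix(genomes, ...)
  if (is.null(cutoff)) {
    off <- ani$values[upper.tri(ani$values)]
    cutoff <- detect_discontinuity(off)
  }
  memb <- cluster_species(ani, cutoff)
  clusters <- split(names(memb), memb)
  names(clusters) <- paste0("species_", names(clusters))
  reps <- vapply(clusters, select_representative, character(1), genomes = genomes)
  structure(list(cutoff = cutoff, clusters = clusters, membership = memb,
                 representatives = reps),
            class = "species_catalog")
}
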