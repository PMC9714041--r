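#' Habitat-preference similarity between species
#'
#' Entry (i, j) is the Pearson correlation of the two species' CLR abundance
#' profiles across all samples — species that rise and fall together across
#' habitats are ecologically similar. Zero-variance species get `NA` rows.
#'
#' @param clr_mat species x samples CLR matrix (>= 3 samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a [pairwise_matrix()] of kind `habitat_similarity` (diagonal 1).
#' @export
habitat_similarity <- function(clr_mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  clr_mat <- as.matrix(clr_mat)
  if (ncol(clr_mat) < 3) stop("need at least 3 samples")
  v <- apply(clr_mat, 1, var)
  cc <- suppressWarnings(cor(t(clr_mat), method = method))
  cc[v == 0, ] <- NA
  cc[, v == 0] <- NA
  diag(cc) <- ifelse(v == 0, NA, 1)
  if (any(v == 0))
    message("zero-variance species flagged missing: ",
            paste(rownames(clr_mat)[v == 0], collapse = ", "))
  cc[is.na(cc)] <- NA
  pairwise_matrix(cc, kind = "habitat_similarity", ids = rownames(clr_mat))
}

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal best hits under Smith-Waterman local alignment (BLOSUM62, gap
#' open 11 / extend 1); hits are kept at >= `min_identity` percent identity
#' and >= `min_coverage` coverage of the shorter sequence, and AAI is the
#' mean percent identity over the reciprocal pairs. Symmetric by
#' construction.
#'
#' @param proteinsA,proteinsB named character vectors of amino-acid
#'   sequences.
#' @param min_identity,min_coverage percent filters (30 and 70).
#' @return AAI percent, or `NA` (with a warning) when no reciprocal pair
#'   qualifies.
#' @export
aai <- function(proteinsA, proteinsB, min_identity = 30, min_coverage = 70) {
  if (length(proteinsA) == 0 || length(proteinsB) == 0)
    stop("both protein sets must be non-empty")
  A <- Biostrings::AAStringSet(proteinsA)
  B <- Biostrings::AAStringSet(proteinsB)
  hits <- function(X, Y) { # best hit in Y for each X: index, identity, coverage
    t(vapply(seq_along(X), function(i) {
      al <- Biostrings::pairwiseAlignment(rep(X[i], length(Y)), Y,
                                          type = "local",
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(al)
      j <- which.max(sc)
      short <- min(Biostrings::width(X[i]), Biostrings::width(Y[j]))
      cov <- 100 * min(Biostrings::width(Biostrings::pattern(al[j])),
                       Biostrings::width(Biostrings::subject(al[j]))) / short
      c(j, Biostrings::pid(al[j], type = "PID1"), cov)
    }, numeric(3)))
  }
  ab <- hits(A, B)
  ba <- hits(B, A)
  rbh <- which(ba[ab[, 1], 1] == seq_along(A))
  ok <- rbh[ab[rbh, 2] >= min_identity & ab[rbh, 3] >= min_coverage]
  if (length(ok) == 0) {
    warning("no qualifying reciprocal best hits; AAI undefined")
    return(NA_real_)
  }
  mean(ab[ok, 2])
}

#' Percent identity of two homologous proteins by global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity is matches over aligned columns, excluding terminal-gap columns
#' so that a trailing extension does not dilute the identity.
#'
#' @param seqA,seqB amino-acid sequences (single strings).
#' @return percent identity in `[0, 100]`.
#' @export
marker_identity <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | ps == "-"
  first <- match(FALSE, gap)
  last <- length(gap) + 1 - match(FALSE, rev(gap))
  # drop leading/trailing columns that are part of a terminal gap run
  run <- rep(TRUE, length(gap))
  run[first:last] <- FALSE
  keep <- !run
  100 * sum(pa[keep] == ps[keep]) / sum(keep)
}

#' Mantel permutation test between two pairwise matrices
#'
#' The Mantel statistic r is the Pearson correlation of the unmasked
#' off-diagonal upper-triangle entries. Significance is two-sided by
#' permutation: one matrix's ids are permuted jointly over rows and columns,
#' the mask staying fixed at its matrix positions, and
#' `p = (1 + #{|r*| >= |r|}) / (permutations + 1)`.
#'
#' @param matA,matB [pairwise_matrix()] objects over the same ids in the
#'   same order (>= 4 ids); their masks are merged by union.
#' @param permutations permutation count (default 99,999).
#' @param seed RNG seed.
#' @return list of class `mantel_result`: `r`, `p`, `permutations`,
#'   `n_pairs_used`.
#' @export
mantel <- function(matA, matB, permutations = 99999, seed = 1) {
  stopifnot(inherits(matA, "pairwise_matrix"), inherits(matB, "pairwise_matrix"))
  if (!identical(matA$ids, matB$ids))
    stop("matrices must share the same ids in the same order")
  n <- length(matA$ids)
  if (n < 4) stop("need at least 4 ids")
  ut <- upper.tri(matA$values)
  mask <- ut
  if (!is.null(matA$mask)) mask <- mask & !matA$mask
  if (!is.null(matB$mask)) mask <- mask & !matB$mask
  keep_na <- !is.na(matA$values) & !is.na(matB$values)
  mask <- mask & keep_na
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("fewer than 3 unmasked pairs")
  va <- matA$values[mask]
  B <- matB$values
  r_obs <- cor(va, B[mask])
  perm_r <- function(perm) cor(va, B[cbind(perm[idx[, 1]], perm[idx[, 2]])])
  if (factorial(n) <= permutations) {
    # small id sets: enumerate every permutation, p is exact
    perms <- all_perms(n)
    exceed <- sum(vapply(perms, function(pp)
      abs(perm_r(pp)) >= abs(r_obs) - 1e-12, logical(1)))
    p <- exceed / length(perms)
    n_perm <- length(perms)
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(permutations), function(k)
        abs(perm_r(sample.int(n))) >= abs(r_obs) - 1e-12, logical(1)))
    })
    p <- (1 + exceed) / (permutations + 1)
    n_perm <- permutations
  }
  structure(list(r = r_obs, p = p,
                 permutations = n_perm, n_pairs_used = nrow(idx)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.5g (%d permutations, %d pairs)\n",
              x$r, x$p, x$permutations, x$n_pairs_used))
  invisible(x)
}

#' Jaccard dissimilarity between samples
#'
#' `d(s, t) = 1 - |P_s intersect P_t| / |P_s union P_t|` on presence sets.
#' Pairs of samples whose union is empty get `d = 0` by convention and are
#' flagged with a message.
#'
#' @param presence logical species x samples matrix.
#' @return a [pairwise_matrix()] of kind `jaccard_dissimilarity` over
#'   samples.
#' @export
jaccard_dissimilarity <- function(presence) {
  presence <- as.matrix(presence) > 0
  # vegdist warns on empty communities; those pairs are handled below
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(t(presence), method = "jaccard", binary = TRUE)))
  if (any(is.nan(d))) {
    message("sample pairs with empty union set to dissimilarity 0")
    d[is.nan(d)] <- 0
  }
  diag(d) <- 0
  pairwise_matrix(d, kind = "jaccard_dissimilarity", ids = colnames(presence))
}

#' Great-circle distances between samples
#'
#' Haversine distance on a sphere of radius 6371 km. Samples with missing
#' coordinates are excluded (with a message).
#'
#' @param samples data.frame with `sample_id`, `lat`, `lon`.
#' @return a [pairwise_matrix()] of kind `geo_distance_km` over the samples
#'   with coordinates.
#' @export
geo_distance <- function(samples) {
  stopifnot(all(c("sample_id", "lat", "lon") %in% names(samples)))
  ok <- !is.na(samples$lat) & !is.na(samples$lon)
  if (any(!ok))
    message("samples without coordinates excluded: ",
            paste(samples$sample_id[!ok], collapse = ", "))
  s <- samples[ok, ]
  D <- geo_distance_km(s$lat, s$lon)
  pairwise_matrix(D, kind = "geo_distance_km", ids = s$sample_id)
}

#' Distance decay of community similarity
#'
#' Mantel correlation between community dissimilarity and geographic
#' distance, recomputed after masking all sample pairs closer than each
#' exclusion threshold — separating true biogeographic signal from the
#' trivial similarity of co-located samples.
#'
#' @param jaccard,geo [pairwise_matrix()] objects over the same samples.
#' @param exclusion_thresholds_km distances below which pairs are masked.
#' @param permutations,seed passed to [mantel()].
#' @return data.frame with `threshold_km`, `r`, `p`, `n_pairs` (`NA` rows
#'   where fewer than 3 pairs survive the mask).
#' @export
distance_decay <- function(jaccard, geo, exclusion_thresholds_km = c(0, 50, 100),
                           permutations = 999, seed = 1) {
  stopifnot(identical(jaccard$ids, geo$ids))
  out <- lapply(exclusion_thresholds_km, function(t) {
    mask <- geo$values < t
    diag(mask) <- FALSE
    g <- pairwise_matrix(geo$values, kind = "geo_distance_km", ids = geo$ids,
                         mask = if (t > 0) mask else NULL)
    res <- tryCatch(mantel(jaccard, g, permutations = permutations, seed = seed),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(threshold_km = t, r = NA_real_, p = NA_real_, n_pairs = NA_integer_)
    else
      data.frame(threshold_km = t, r = res$r, p = res$p, n_pairs = res$n_pairs_used)
  })
  do.call(rbind, out)
}

#' Phylogenetic signal in habitat preference across species subsets
#'
#' For each species subset (all, comammox, canonical, canonical lineages
#' I+II) and each genetic-similarity matrix (e.g. whole-genome AAI,
#' concatenated single-copy gene identity, AmoA/HaoA/NxrB identity), runs a
#' Mantel test of habitat similarity against genetic similarity. Species
#' absent from a genetic matrix are dropped from that cell; cells left with
#' fewer than 4 species are reported `NA` (as for canonical species, which
#' carry no ammonia-oxidation genes).
#'
#' @param habitat_sim [pairwise_matrix()] of habitat similarity over species.
#' @param genetic_mats named list of [pairwise_matrix()] objects (ids may be
#'   subsets of the habitat matrix ids).
#' @param clade_labels named vector over species, values from
#'   [clade_levels()].
#' @param permutations,seed passed to [mantel()].
#' @return data.frame with one row per (subset, marker): `subset`, `marker`,
#'   `r`, `p`, `n_species`, `significance` (stars at 0.05 / 0.01 / 0.001).
#' @export
table2_analysis <- function(habitat_sim, genetic_mats, clade_labels,
                            permutations = 99999, seed = 1) {
  stopifnot(inherits(habitat_sim, "pairwise_matrix"), is.list(genetic_mats))
  species <- habitat_sim$ids
  labs <- clade_labels[species]
  if (anyNA(labs)) stop("every species needs a clade label")
  cmx <- species[labs %in% comammox_clades()]
  subsets <- list(
    all = species,
    comammox = cmx,
    canonical = setdiff(species, cmx),
    canonical_I_II = species[labs %in% c("lineage_I", "lineage_II_canonical")])
  rows <- list()
  for (sn in names(subsets)) for (mn in names(genetic_mats)) {
    gm <- genetic_mats[[mn]]
    ids <- intersect(subsets[[sn]], gm$ids)
    ids <- ids[!is.na(diag(gm$values[ids, ids, drop = FALSE]))]
    if (length(ids) < 4) {
      rows[[length(rows) + 1]] <- data.frame(subset = sn, marker = mn,
                                             r = NA_real_, p = NA_real_,
                                             n_species = length(ids),
                                             significance = "")
      next
    }
    res <- mantel(pm_subset(habitat_sim, ids), pm_subset(gm, ids),
                  permutations = permutations, seed = seed)
    stars <- if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
             else if (res$p < 0.05) "*" else ""
    rows[[length(rows) + 1]] <- data.frame(subset = sn, marker = mn,
                                           r = res$r, p = res$p,
                                           n_species = length(ids),
                                           significance = stars)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
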