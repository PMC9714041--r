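#' All-vs-all protein similarity graph
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) between
#' every pair of proteins sharing at least one 5-mer; raw scores are
#' converted to bitscores with the standard gapped Karlin-Altschul constants
#' (`lambda = 0.267`, `K = 0.041`): `bits = (lambda * S - ln K) / ln 2`.
#' Edges are kept only for raw score > 0. With `prefilter = TRUE` pairs
#' sharing no 5-mer are skipped without alignment (never a pair that does
#' share one) — useful on large protein sets.
#'
#' @param proteins data.frame with `protein_id`, `genome_id`, `sequence`
#'   (amino acids).
#' @param prefilter skip pairs sharing no exact 5-mer (default FALSE: align
#'   every pair).
#' @return list of class `similarity_graph`: `nodes` (the proteins
#'   data.frame), `edges` (`from`, `to`, `score`, `bitscore`) and
#'   `self_scores` (named bitscore vector).
#' @export
all_vs_all_scores <- function(proteins, prefilter = FALSE) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "genome_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein ids")
  if (any(grepl("[^ARNDCQEGHILKMFPSTWYVBZX*]", proteins$sequence)))
    stop("invalid amino-acid residue in protein sequences")
  n <- nrow(proteins)
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$protein_id))
  self_raw <- vapply(seq_len(n), function(i) sw_score(aa[[i]], aa[[i]]), numeric(1))
  pairs <- if (prefilter) {
    # candidate pairs: share at least one 5-mer
    kmer_sets <- lapply(proteins$sequence, function(s) {
      L <- nchar(s)
      if (L < 5) return(character(0))
      unique(substring(s, 1:(L - 4), 5:L))
    })
    by_kmer <- split(rep(seq_len(n), lengths(kmer_sets)), unlist(kmer_sets))
    unique(do.call(rbind, lapply(by_kmer, function(idx) {
      if (length(idx) < 2) return(NULL)
      t(utils::combn(sort(idx), 2))
    })))
  } else if (n >= 2) t(utils::combn(n, 2)) else NULL
  edges <- data.frame(from = character(0), to = character(0),
                      score = numeric(0), bitscore = numeric(0))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    sc <- vapply(seq_len(nrow(pairs)), function(r)
      sw_score(aa[[pairs[r, 1]]], aa[[pairs[r, 2]]]), numeric(1))
    keep <- sc > 0
    edges <- data.frame(from = proteins$protein_id[pairs[keep, 1]],
                        to = proteins$protein_id[pairs[keep, 2]],
                        score = sc[keep], bitscore = bitscore(sc[keep]),
                        stringsAsFactors = FALSE)
  }
  log_stage("all_vs_all_scores", n_proteins = n, n_edges = nrow(edges))
  structure(list(nodes = proteins, edges = edges,
                 self_scores = setNames(bitscore(self_raw), proteins$protein_id)),
            class = "similarity_graph")
}

sw_score <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 11, gapExtension = 1,
                                scoreOnly = TRUE)
}

bitscore <- function(raw, lambda = 0.267, K = 0.041) {
  (lambda * raw - log(K)) / log(2)
}

#' Filter weak protein matches by the minbit heuristic
#'
#' An edge survives iff its bitscore is at least `minbit` times the smaller
#' of the two endpoint self-alignment bitscores. An edge between identical
#' sequences (ratio 1) is therefore never removed.
#'
#' @param graph a [all_vs_all_scores()] similarity graph.
#' @param minbit fraction in `[0, 1]` (default 0.3), boundary inclusive.
#' @return the graph with filtered `edges`.
#' @export
minbit_filter <- function(graph, minbit = 0.3) {
  stopifnot(inherits(graph, "similarity_graph"))
  e <- graph$edges
  s1 <- graph$self_scores[e$from]
  s2 <- graph$self_scores[e$to]
  if (anyNA(s1) || anyNA(s2)) stop("missing self score for some edge endpoint")
  ratio <- e$bitscore / pmin(s1, s2)
  graph$edges <- e[ratio >= minbit, , drop = FALSE]
  log_stage("minbit_filter", n_in = nrow(e), n_kept = nrow(graph$edges),
            minbit = minbit)
  graph
}

#' Markov clustering of a similarity graph
#'
#' Builds a column-stochastic matrix from the edge weights with self-loops
#' (each node's loop weight is its maximum incident edge weight, 1 for
#' isolated nodes), then iterates expansion (matrix squaring) and inflation
#' (elementwise power `inflation`, column renormalization), pruning entries
#' below `prune` after each inflation, until the largest elementwise change
#' falls below `tol` or `max_iter` iterations (then a warning is issued and
#' the current state is interpreted). Clusters are read off the attractor
#' rows of the limit matrix; every node lands in exactly one cluster, with
#' overlap resolved to the attractor holding the larger mass (ties broken by
#' lexicographically smallest attractor id).
#'
#' @param graph a `similarity_graph`, or a symmetric numeric adjacency matrix
#'   with dimnames.
#' @param inflation inflation exponent (default 2).
#' @param prune,tol,max_iter numerical controls.
#' @return named integer vector: node -> cluster index (clusters numbered by
#'   their lexicographically smallest member).
#' @export
mcl <- function(graph, inflation = 2, prune = 1e-6, tol = 1e-8, max_iter = 100) {
  A <- if (inherits(graph, "similarity_graph")) {
    ids <- sort(graph$nodes$protein_id)
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    e <- graph$edges
    if (nrow(e)) {
      M[cbind(e$from, e$to)] <- e$bitscore
      M[cbind(e$to, e$from)] <- e$bitscore
    }
    M
  } else {
    M <- as.matrix(graph)
    if (nrow(M) == 0) stop("empty graph")
    if (is.null(rownames(M))) dimnames(M) <- list(paste0("n", seq_len(nrow(M))),
                                                  paste0("n", seq_len(nrow(M))))
    ord <- order(rownames(M))
    M[ord, ord]
  }
  if (nrow(A) == 0) stop("empty graph")
  if (max(abs(A - t(A))) > 1e-9) stop("adjacency must be symmetric")
  ids <- rownames(A)
  diag(A) <- 0
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) { diag(M2)[dead] <- 1; cs[dead] <- 1 }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current state")
  # attractors: nodes retaining mass on their own column
  attractors <- which(diag(M) > 0)
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (j in seq_along(ids)) {
    cand <- attractors[M[attractors, j] > 0]
    if (length(cand) == 0) next # numerically orphaned: stays a singleton
    best <- cand[order(-M[cand, j], ids[cand])][1]
    union_(best, j)
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  # ids are in sorted order and union keeps the smallest index as root, so
  # first-occurrence numbering orders clusters by smallest member id
  cl <- as.integer(factor(roots, levels = unique(roots)))
  log_stage("mcl", n_nodes = length(ids), n_clusters = max(cl),
            iterations = it)
  setNames(cl, ids)
}

#' Gene-cluster presence matrix from an MCL partition
#'
#' @param clusters named vector from [mcl()] (protein_id -> cluster).
#' @param protein_genomes named vector protein_id -> genome_id.
#' @return logical matrix gene cluster x genome; `TRUE` where some member
#'   protein of the cluster belongs to the genome.
#' @export
gc_presence_matrix <- function(clusters, protein_genomes) {
  genomes <- sort(unique(protein_genomes))
  gcs <- sort(unique(clusters))
  pres <- matrix(FALSE, length(gcs), length(genomes),
                 dimnames = list(sprintf("GC%04d", gcs), genomes))
  pres[cbind(match(clusters, gcs),
             match(protein_genomes[names(clusters)], genomes))] <- TRUE
  pres
}

# classify one presence pattern; precedence core -> enriched -> specific
# (A, B, A1, A2) -> unique -> unclassified, first match wins
classify_presence_pattern <- function(pattern, clade_labels,
                                      core_fraction = 0.80,
                                      enriched_in_fraction = 0.60,
                                      enriched_per_clade_fraction = 0.40,
                                      enriched_absent_fraction = 0.90,
                                      clade_specific_fraction = 0.55) {
  frac <- function(idx) if (sum(idx) == 0) NA_real_ else mean(pattern[idx])
  ge <- function(x, t) !is.na(x) && x >= t
  gt <- function(x, t) !is.na(x) && x > t
  if (mean(pattern) >= core_fraction) return("core")
  is_cmx <- clade_labels %in% comammox_clades()
  is_A <- clade_labels %in% c("comammox_A1", "comammox_A2")
  is_B <- clade_labels == "comammox_B"
  absent_non <- if (sum(!is_cmx) == 0) 1 else mean(!pattern[!is_cmx])
  if (gt(frac(is_cmx), enriched_in_fraction) &&
      ge(frac(is_A), enriched_per_clade_fraction) &&
      ge(frac(is_B), enriched_per_clade_fraction) &&
      absent_non > enriched_absent_fraction) return("comammox_enriched")
  spec <- list(cladeA_specific = is_A, cladeB_specific = is_B,
               cladeA1_specific = clade_labels == "comammox_A1",
               cladeA2_specific = clade_labels == "comammox_A2")
  for (lab in names(spec)) {
    idx <- spec[[lab]]
    if (ge(frac(idx), clade_specific_fraction) && !any(pattern[!idx]))
      return(lab)
  }
  if (sum(pattern) == 1) return("unique")
  "unclassified"
}

#' Classify gene clusters by prevalence thresholds
#'
#' Labels each gene cluster from its presence pattern across clade-labelled
#' genomes, with first-match-wins precedence:
#' * `core`: present in at least 80% of all genomes (inclusive);
#' * `comammox_enriched`: present in more than 60% of comammox genomes
#'   (strict), at least 40% of clade A and of clade B genomes (inclusive),
#'   and absent in more than 90% of the non-comammox genomes (strict);
#' * `cladeA/B/A1/A2_specific`: present in at least 55% of that clade's
#'   genomes (inclusive) and absent from every other genome;
#' * `unique`: present in exactly one genome;
#' * `unclassified` otherwise.
#'
#' @param presence logical matrix gene cluster x genome.
#' @param clade_labels named vector over the genome columns, values from
#'   [clade_levels()]; comammox = clades A (A1 and A2) and B.
#' @param config a [magecol_config()] supplying the thresholds.
#' @return named character vector of labels per gene cluster.
#' @export
classify_gene_clusters <- function(presence, clade_labels,
                                   config = magecol_config()) {
  presence <- as.matrix(presence)
  if (is.null(colnames(presence))) stop("presence matrix must have genome columns")
  labs <- clade_labels[colnames(presence)]
  if (anyNA(labs) || !all(labs %in% clade_levels()))
    stop("every genome must carry a valid clade label")
  out <- vapply(seq_len(nrow(presence)), function(i)
    classify_presence_pattern(presence[i, ] > 0, labs,
                              config$core_fraction, config$enriched_in_fraction,
                              config$enriched_per_clade_fraction,
                              config$enriched_absent_fraction,
                              config$clade_specific_fraction),
    character(1))
  names(out) <- rownames(presence)
  log_stage("classify_gene_clusters", n_gc = nrow(presence),
            n_core = sum(out == "core"))
  out
}
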