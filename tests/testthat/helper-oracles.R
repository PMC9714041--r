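options(magecol.verbose = FALSE)

# ---- independent dynamic-programming alignment oracle (Gotoh, affine gaps) --
# local (Smith-Waterman) score with BLOSUM62, gap open 11 / extend 1;
# a gap of length L costs open + L * extend.
sw_oracle <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a (move along b)
  F <- matrix(-Inf, n + 1, m + 1) # gap in b
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[av[i - 1], bv[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# ---- independent dense-matrix MCL oracle ------------------------------------
# plain expansion/inflation iteration without pruning; clusters read as
# connected components of the nonzero structure of the limit matrix
mcl_oracle <- function(A, inflation = 2) {
  A <- as.matrix(A)
  if (is.null(rownames(A)))
    dimnames(A) <- list(paste0("n", seq_len(nrow(A))), paste0("n", seq_len(nrow(A))))
  diag(A) <- 0
  loops <- apply(A, 1, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:300) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-12) { M <- M2; break }
    M <- M2
  }
  B <- (M > 1e-6) | t(M > 1e-6)
  n <- nrow(B)
  comp <- rep(0L, n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (comp[x] > 0) next
      comp[x] <- k
      queue <- c(queue, which(B[x, ] & comp == 0))
    }
  }
  stats::setNames(comp, rownames(A))
}

# two clusterings over the same elements induce the same partition?
same_partition <- function(a, b) {
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# adjusted Rand index between two labelled clusterings (aligned on names)
ari <- function(a, b) {
  b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}

# ---- exact canonical k-mer Jaccard, pure-R oracle ---------------------------
kmer_jaccard_oracle <- function(seqA, seqB, k) {
  canon <- function(s) {
    L <- nchar(s)
    km <- substring(s, 1:(L - k + 1), k:L)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
  }
  a <- canon(seqA); b <- canon(seqB)
  length(intersect(a, b)) / length(union(a, b))
}

mash_ani_oracle <- function(J, k) {
  if (J <= 0) 0 else max(0, min(100, 100 * (1 + log(2 * J / (1 + J)) / k)))
}

# small deterministic DNA fixture
fix_dna <- function(length, seed = 1) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

# tiny genome_record builder
fix_genome <- function(id, seq, completeness = 90, contamination = 1,
                       clade = "other") {
  genome_record(id, seq, completeness = completeness,
                contamination = contamination, clade_label = clade)
}
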