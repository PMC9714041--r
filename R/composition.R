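#' Count-zero-multiplicative replacement
#'
#' Converts a non-negative count vector to strictly positive proportions.
#' Zeros are imputed at `delta = delta_fraction / total` (a fraction of the
#' count detection limit `1/total`) and the non-zero proportions are shrunk
#' multiplicatively by `(1 - n_zeros * delta)`, which preserves every ratio
#' between non-zero parts exactly and keeps the vector on the simplex.
#' On non-count scales (e.g. RPM) the detection limit `1/total` can be large
#' enough that `n_zeros * delta >= 1`; delta is therefore capped at
#' `delta_fraction / n_zeros`, which keeps every part strictly positive
#' without affecting count-scale behaviour.
#'
#' @param counts non-negative numeric vector with positive total.
#' @param delta_fraction multiplier on the detection limit, in `(0, 1)`
#'   (default 0.65).
#' @return strictly positive proportion vector summing to 1.
#' @export
czm_replace <- function(counts, delta_fraction = 0.65) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("all-zero vector cannot be replaced")
  if (delta_fraction <= 0 || delta_fraction >= 1)
    stop("delta_fraction must be in (0, 1)")
  p <- counts / total
  z <- sum(counts == 0)
  if (z == 0) return(p)
  delta <- min(delta_fraction / total, delta_fraction / z)
  out <- p * (1 - z * delta)
  out[counts == 0] <- delta
  out
}

#' Centred log-ratio transform
#'
#' `clr_i = log(p_i / g(p))` with `g` the geometric mean; the output sums
#' to zero and is invariant to positive rescaling of the input.
#'
#' @param p strictly positive numeric vector (any positive scale).
#' @return numeric vector summing to 0.
#' @export
clr <- function(p) {
  if (any(p <= 0)) stop("clr requires strictly positive entries")
  lp <- log(p)
  lp - mean(lp)
}

#' CLR-transform an abundance table
#'
#' Applies [czm_replace()] then [clr()] per sample (column).
#'
#' @param counts species x samples matrix of counts or RPM.
#' @param delta_fraction passed to [czm_replace()].
#' @return species x samples matrix of CLR values (columns sum to 0).
#' @export
clr_table <- function(counts, delta_fraction = 0.65) {
  counts <- as.matrix(counts)
  out <- apply(counts, 2, function(x) clr(czm_replace(x, delta_fraction)))
  dimnames(out) <- dimnames(counts)
  out
}

#' PCA of a CLR-transformed table
#'
#' Column-centred singular value decomposition of the samples-by-species CLR
#' matrix. The sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param clr_mat samples x species numeric matrix (at least 2 of each).
#' @return list with `scores` (samples x PCs), `loadings` (species x PCs)
#'   and `variance_fraction`.
#' @export
pca_clr <- function(clr_mat) {
  clr_mat <- as.matrix(clr_mat)
  if (nrow(clr_mat) < 2 || ncol(clr_mat) < 2)
    stop("need at least 2 samples and 2 species")
  if (all(abs(sweep(clr_mat, 2, colMeans(clr_mat))) < 1e-12))
    stop("constant matrix has no principal components")
  pc <- prcomp(clr_mat, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, variance_fraction = vf)
}

#' Proportionality rho between species
#'
#' `rho(i, j) = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j))`, the
#' compositionally valid association measure computed on CLR-transformed
#' abundances; sample variances are taken across samples. Species with zero
#' variance have undefined rho and are flagged missing (`NA`).
#'
#' @param clr_mat species x samples CLR matrix (>= 3 samples).
#' @return list of class `proportionality_matrix` with symmetric `rho`
#'   (diagonal 1) and the ids.
#' @export
rho_matrix <- function(clr_mat) {
  clr_mat <- as.matrix(clr_mat)
  if (ncol(clr_mat) < 3) stop("need at least 3 samples")
  v <- apply(clr_mat, 1, var)
  n <- nrow(clr_mat)
  # var(x - y) = var x + var y - 2 cov(x, y)
  cv <- cov_rows(clr_mat)
  denom <- outer(v, v, "+")
  rho <- 1 - (denom - 2 * cv) / denom
  rho[v == 0, ] <- NA
  rho[, v == 0] <- NA
  diag(rho) <- ifelse(v == 0, NA, 1)
  dimnames(rho) <- list(rownames(clr_mat), rownames(clr_mat))
  structure(list(ids = rownames(clr_mat), rho = rho), class = "proportionality_matrix")
}

cov_rows <- function(m) {
  mc <- m - rowMeans(m)
  (mc %*% t(mc)) / (ncol(m) - 1)
}

#' Permutation FDR for proportionality cutoffs
#'
#' For each candidate cutoff `t`, the false discovery rate is the mean over
#' permutations of `#{|rho*| > t} / max(1, #{|rho| > t})`, where `rho*` is
#' recomputed after independently permuting each species' values across
#' samples (destroying association, preserving marginals). Off-diagonal
#' upper-triangle pairs only.
#'
#' @param clr_mat species x samples CLR matrix.
#' @param cutoffs candidate |rho| cutoffs.
#' @param permutations number of permutations (>= 10).
#' @param seed RNG seed.
#' @return data.frame with `cutoff`, `n_pairs` (observed exceedances), `fdr`.
#' @export
rho_fdr_cutoff <- function(clr_mat, cutoffs = seq(0.05, 0.95, by = 0.05),
                           permutations = 100, seed = 1) {
  if (permutations < 10) stop("need at least 10 permutations")
  clr_mat <- as.matrix(clr_mat)
  obs <- abs(rho_matrix(clr_mat)$rho[upper.tri(diag(nrow(clr_mat)))])
  n_obs <- vapply(cutoffs, function(t) sum(obs > t, na.rm = TRUE), numeric(1))
  perm_counts <- with_seed(seed, {
    vapply(seq_len(permutations), function(p) {
      shuf <- t(apply(clr_mat, 1, sample))
      r <- abs(rho_matrix(shuf)$rho[upper.tri(diag(nrow(clr_mat)))])
      vapply(cutoffs, function(t) sum(r > t, na.rm = TRUE), numeric(1))
    }, numeric(length(cutoffs)))
  })
  fdr <- rowMeans(matrix(perm_counts, nrow = length(cutoffs))) / pmax(1, n_obs)
  data.frame(cutoff = cutoffs, n_pairs = n_obs, fdr = fdr)
}

#' Rank-based group comparisons with compact letter display
#'
#' For more than two groups: Kruskal-Wallis omnibus test (tie-corrected)
#' followed by Dunn's pairwise z tests with Holm-Bonferroni adjustment, and a
#' compact letter display in which groups sharing a letter are not
#' significantly different at `alpha`. For exactly two groups: two-sided
#' Mann-Whitney-Wilcoxon rank-sum test (normal approximation with continuity
#' correction at larger n, exact when available).
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups, each >= 2 obs).
#' @param alpha significance level for the letter display.
#' @return list with `omnibus_p`, `pairwise` (data.frame: groups, z, p,
#'   p_adjusted) and `letters` (named per-group).
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 observations")
  gl <- names(tab)
  if (length(gl) == 2) {
    w <- wilcox.test(values[groups == gl[1]], values[groups == gl[2]],
                     alternative = "two.sided", correct = TRUE)
    p <- w$p.value
    letters <- if (p < alpha) c("a", "b") else c("a", "a")
    return(list(omnibus_p = p,
                pairwise = data.frame(group1 = gl[1], group2 = gl[2],
                                      z = NA_real_, p = p, p_adjusted = p),
                letters = setNames(letters, gl)))
  }
  kw <- kruskal.test(values, factor(groups))
  pw <- dunn_test(values, groups)
  pw$p_adjusted <- p.adjust(pw$p, method = "holm")
  letters <- compact_letters(gl, pw$group1, pw$group2, pw$p_adjusted < alpha)
  list(omnibus_p = kw$p.value, pairwise = pw, letters = letters)
}

#' Dunn's pairwise rank test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis analysis, with
#' the standard tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @return data.frame with `group1`, `group2`, `z`, `p` (two-sided, unadjusted).
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)[gl]
  n <- tapply(r, groups, length)[gl]
  pairs <- utils::combn(gl, 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    (rbar[i] - rbar[j]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
  }, numeric(1))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
}

# greedy insert-absorb compact letter display: groups sharing a letter are
# not significantly different
compact_letters <- function(groups, g1, g2, significant) {
  sig <- matrix(FALSE, length(groups), length(groups),
                dimnames = list(groups, groups))
  sig[cbind(g1, g2)] <- significant
  sig <- sig | t(sig)
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(sig[g, sets[[k]]])) { sets[[k]] <- c(sets[[k]], g); placed <- TRUE }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) for (b in seq_along(sets))
    if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]))
      keep[a] <- FALSE
  sets <- sets[keep]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}
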