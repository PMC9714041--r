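#' Square pairwise matrix over species or samples
#'
#' Lightweight container for the symmetric matrices the Mantel/PCA/rho
#' machinery operates on: similarities (diagonal = maximum) or
#' dissimilarities/distances (diagonal = 0), with an optional symmetric mask
#' of excluded pairs.
#'
#' @param values square numeric matrix; made symmetric by averaging if
#'   within tolerance, error otherwise.
#' @param kind one of `"habitat_similarity"`, `"aai"`, `"marker_identity"`,
#'   `"jaccard_dissimilarity"`, `"geo_distance_km"`, `"generic_similarity"`,
#'   `"generic_dissimilarity"`.
#' @param ids character ids in matrix order; defaults to the rownames.
#' @param mask optional logical matrix, `TRUE` for pairs to exclude.
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, kind = "generic_similarity", ids = rownames(values),
                            mask = NULL) {
  kinds <- c("habitat_similarity", "aai", "marker_identity",
             "jaccard_dissimilarity", "geo_distance_km",
             "generic_similarity", "generic_dissimilarity")
  kind <- match.arg(kind, kinds)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("pairwise matrix must be symmetric")
  values <- (values + t(values)) / 2
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in pairwise matrix")
  dimnames(values) <- list(ids, ids)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) stop("mask dimensions must match values")
    mask <- mask | t(mask)
    dimnames(mask) <- dimnames(values)
  }
  structure(list(ids = ids, values = values, kind = kind, mask = mask),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix [%s] over %d ids", x$kind, length(x$ids)))
  if (!is.null(x$mask)) cat(sprintf(", %d masked pairs",
                                    sum(x$mask[upper.tri(x$mask)])))
  cat("\n")
  print(head(x$values[seq_len(min(5, nrow(x$values))),
                      seq_len(min(5, ncol(x$values))), drop = FALSE]))
  invisible(x)
}

#' Subset a pairwise matrix to a set of ids
#'
#' @param x a [pairwise_matrix()].
#' @param ids character ids to keep, in the requested order.
#' @return a `pairwise_matrix` over `ids`.
#' @export
pm_subset <- function(x, ids) {
  stopifnot(inherits(x, "pairwise_matrix"))
  missing <- setdiff(ids, x$ids)
  if (length(missing)) stop("ids not in matrix: ", paste(missing, collapse = ", "))
  pairwise_matrix(x$values[ids, ids, drop = FALSE], kind = x$kind, ids = ids,
                  mask = if (is.null(x$mask)) NULL else x$mask[ids, ids, drop = FALSE])
}

# upper-triangle entries of a pairwise_matrix excluding masked pairs;
# returns list(values, keep_index) against the full upper triangle
pm_upper <- function(x) {
  ut <- upper.tri(x$values)
  keep <- if (is.null(x$mask)) ut else ut & !x$mask
  list(values = x$values[keep], keep = keep)
}

# run expr under an explicit seed without disturbing the caller's RNG;
# seed = NULL leaves the current RNG stream in place
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

# stage logging: config snapshot + input/output dimensions, silenced via
# options(magecol.verbose = FALSE)
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("magecol.verbose", TRUE))) return(invisible(NULL))
  info <- paste(sprintf("%s=%s", names(c(...)), c(...)), collapse = " ")
  message(sprintf("[magecol] %s: %s", stage, info))
  invisible(NULL)
}

# all permutations of 1..n (n small), as a list of integer vectors
all_perms <- function(n) {
  gen <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  gen(seq_len(n))
}

# random DNA string(s); uses the current RNG stream
random_dna <- function(length, n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    character(1))
}
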