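pm_from <- function(m, ids = rownames(m), kind = "generic_similarity")
  pairwise_matrix(m, kind = kind, ids = ids)

test_that("habitat similarity is the correlation of CLR profiles", {
  clr_mat <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8) / 3, c = c(4, 3, 2, 1))
  hs <- habitat_similarity(clr_mat)
  expect_equal(hs$values["a", "b"], 1)   # duplicated profile up to scale
  expect_equal(hs$values["a", "c"], -1)  # mirrored profile
  expect_equal(unname(diag(hs$values)), rep(1, 3))
  # 4-sample hand check
  x <- c(0.2, 1.4, -0.3, 2.2); y <- c(1.1, 0.4, 0.9, -0.2)
  hs2 <- habitat_similarity(rbind(x = x, y = y, z = rnorm(4)))
  expect_equal(hs2$values["x", "y"], cor(x, y))
  # zero-variance species flagged
  expect_message(hs3 <- habitat_similarity(rbind(a = 1:4, k = rep(1, 4))),
                 "zero-variance")
  expect_true(is.na(hs3$values["k", "a"]))
})

test_that("AAI is 100 for self, symmetric, and tracks planted divergence", {
  withr::local_seed(111)
  aa_alpha <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  prots <- vapply(1:8, function(i)
    paste(sample(aa_alpha, 120, replace = TRUE), collapse = ""), character(1))
  names(prots) <- paste0("p", 1:8)
  expect_equal(aai(prots, prots), 100)
  # ~10% diverged proteome
  mutate_aa <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- sample(aa_alpha, sum(hit), replace = TRUE)
    paste(v, collapse = "")
  }
  protsB <- vapply(prots, mutate_aa, character(1), rate = 0.105) # ~10% diff
  a_ab <- aai(prots, protsB)
  expect_gt(a_ab, 86); expect_lt(a_ab, 94)
  expect_equal(a_ab, aai(protsB, prots), tolerance = 0.2)
  # unrelated proteomes: no qualifying reciprocal hits
  protsC <- vapply(1:5, function(i)
    paste(sample(aa_alpha, 60, replace = TRUE), collapse = ""), character(1))
  expect_warning(miss <- aai(prots[1:2], protsC[1:2]), "no qualifying")
  expect_true(is.na(miss))
  expect_error(aai(character(0), prots), "non-empty")
})

test_that("marker identity excludes terminal gaps and matches closed forms", {
  expect_equal(marker_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  # terminal extension does not dilute identity
  expect_equal(marker_identity("ACDEFG", "ACDEFGH"), 100)
  expect_equal(marker_identity("ACDEFGH", "ACDEFG"), 100)
  # equal-length high-similarity pair: global alignment is gap-free, identity
  # equals the Hamming closed form
  withr::local_seed(112)
  aa_alpha <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  a <- paste(sample(aa_alpha, 80, replace = TRUE), collapse = "")
  v <- strsplit(a, "")[[1]]
  idx <- sample(80, 6)
  v[idx] <- vapply(v[idx], function(ch) sample(setdiff(aa_alpha, ch), 1), character(1))
  b <- paste(v, collapse = "")
  expect_equal(marker_identity(a, b), 100 * (80 - 6) / 80)
  expect_error(marker_identity("", "ACD"), "empty")
})

test_that("mantel returns r = 1 on identical matrices and exact small-n p", {
  withr::local_seed(113)
  m <- matrix(runif(25), 5); m <- (m + t(m)) / 2; diag(m) <- 0
  pm <- pm_from(m, ids = letters[1:5])
  res <- mantel(pm, pm, permutations = 999, seed = 1)
  expect_equal(res$r, 1)
  # 4-id fixture: p must equal exhaustive enumeration over all 24 permutations
  m1 <- matrix(runif(16), 4); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- matrix(runif(16), 4); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  pa <- pm_from(m1, letters[1:4]); pb <- pm_from(m2, letters[1:4])
  res4 <- mantel(pa, pb, permutations = 999, seed = 1)
  ut <- upper.tri(m1)
  va <- m1[ut]
  r_obs <- cor(va, m2[ut])
  perms <- magecol:::all_perms(4)
  r_all <- vapply(perms, function(p) cor(va, m2[p, p][ut]), numeric(1))
  expect_equal(res4$r, r_obs)
  expect_equal(res4$p, mean(abs(r_all) >= abs(r_obs) - 1e-12))
  expect_error(mantel(pm_from(m1[1:3, 1:3], letters[1:3]),
                      pm_from(m2[1:3, 1:3], letters[1:3])), "4 ids")
})

test_that("mantel r is invariant to monotone linear transforms", {
  withr::local_seed(114)
  m1 <- matrix(runif(64), 8); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- matrix(runif(64), 8); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  ids <- letters[1:8]
  r0 <- mantel(pm_from(m1, ids), pm_from(m2, ids), permutations = 99, seed = 2)
  r1 <- mantel(pm_from(3 * m1 + 2, ids), pm_from(m2, ids), permutations = 99, seed = 2)
  expect_equal(r0$r, r1$r, tolerance = 1e-12)
  expect_equal(r0$p, r1$p)
  # cross-check the statistic against vegan's implementation
  vg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 0)
  expect_equal(r0$r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("jaccard dissimilarity follows set arithmetic with the 0 convention", {
  pres <- cbind(s1 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                s2 = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                s3 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                s4 = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  rownames(pres) <- paste0("sp", 1:5)
  jd <- jaccard_dissimilarity(pres)
  expect_equal(jd$values["s1", "s2"], 0.5)  # {A,B,C} vs {B,C,D}
  expect_equal(jd$values["s1", "s3"], 0)    # identical communities
  expect_equal(jd$values["s1", "s4"], 1)    # disjoint non-empty
  # empty-union pairs get 0 with a message
  pres0 <- cbind(e1 = c(FALSE, FALSE), e2 = c(FALSE, FALSE))
  rownames(pres0) <- c("x", "y")
  expect_message(jd0 <- jaccard_dissimilarity(pres0), "empty union")
  expect_equal(jd0$values["e1", "e2"], 0)
})

test_that("geographic distances use the 6371 km haversine sphere", {
  s <- data.frame(sample_id = c("a", "b", "c"),
                  lat = c(0, 0, NA), lon = c(0, 180, 5))
  expect_message(gd <- geo_distance(s), "excluded")
  expect_equal(gd$values["a", "b"], pi * 6371, tolerance = 0.1)
  expect_equal(gd$values["a", "a"], 0)
  expect_equal(gd$values, t(gd$values))
  expect_false("c" %in% gd$ids)
})

test_that("distance decay at threshold 0 equals the plain Mantel test", {
  withr::local_seed(115)
  n <- 12
  coords <- data.frame(lat = runif(n, 40, 45), lon = runif(n, 0, 5))
  geo <- pairwise_matrix(magecol:::geo_distance_km(coords$lat, coords$lon),
                         kind = "geo_distance_km", ids = paste0("s", 1:n))
  pres <- matrix(runif(8 * n) < 0.5, 8, dimnames = list(paste0("sp", 1:8),
                                                        paste0("s", 1:n)))
  jac <- jaccard_dissimilarity(pres)
  dd <- distance_decay(jac, geo, exclusion_thresholds_km = c(0, 100),
                       permutations = 99, seed = 3)
  plain <- mantel(jac, geo, permutations = 99, seed = 3)
  expect_equal(dd$r[dd$threshold_km == 0], plain$r)
  expect_equal(dd$p[dd$threshold_km == 0], plain$p)
  expect_lt(dd$n_pairs[2], dd$n_pairs[1])
  # an impossible threshold flags not-computable
  dd2 <- distance_decay(jac, geo, exclusion_thresholds_km = c(1e6),
                        permutations = 99, seed = 3)
  expect_true(is.na(dd2$r))
})

test_that("table2 analysis self-test gives r = 1 and marks missing markers NA", {
  withr::local_seed(116)
  n <- 10
  ids <- sprintf("sp%02d", 1:n)
  labs <- setNames(c(rep("comammox_A1", 3), rep("comammox_B", 3),
                     rep("lineage_I", 2), rep("lineage_II_canonical", 2)), ids)
  m <- matrix(runif(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1
  hs <- pairwise_matrix(m, kind = "habitat_similarity", ids = ids)
  # self-test: genetic matrix == habitat matrix -> r = 1 everywhere computable
  gen <- list(aai = hs, amoA = pm_subset(hs, ids[1:6]))
  out <- table2_analysis(hs, gen, labs, permutations = 99, seed = 4)
  self_cells <- out[!is.na(out$r), ]
  expect_true(all(abs(self_cells$r - 1) < 1e-12))
  # canonical species have no AmoA: cell reported NA
  expect_true(is.na(out$r[out$subset == "canonical" & out$marker == "amoA"]))
  expect_true(is.na(out$r[out$subset == "canonical_I_II" & out$marker == "amoA"]))
  expect_false(is.na(out$r[out$subset == "comammox" & out$marker == "amoA"]))
  expect_equal(out$n_species[out$subset == "all" & out$marker == "aai"], n)
})
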