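test_that("genome simulation is deterministic and respects zero divergence", {
  a <- simulate_genome_set(3, 2, genome_length = 5000, seed = 121)
  b <- simulate_genome_set(3, 2, genome_length = 5000, seed = 121)
  expect_identical(lapply(a$genomes, `[[`, "contigs"),
                   lapply(b$genomes, `[[`, "contigs"))
  # within_divergence 0: members of a species are identical (ANI 100)
  z <- simulate_genome_set(2, 2, genome_length = 5000, within_divergence = 0,
                           between_divergence = 0.08, seed = 122)
  expect_identical(z$genomes$s01_g01$contigs, z$genomes$s01_g02$contigs)
  expect_equal(compute_ani(z$genomes$s01_g01, z$genomes$s01_g02, exact = TRUE), 100)
  expect_error(simulate_genome_set(0, 3), "n_species")
  expect_error(simulate_genome_set(2, 2, within_divergence = 0.1,
                                   between_divergence = 0.05), "smaller")
})

test_that("planted divergences appear as a bimodal identity structure", {
  sim <- simulate_genome_set(5, 3, genome_length = 3e4, within_divergence = 0.02,
                             between_divergence = 0.08, seed = 123)
  am <- ani_matrix(sim$genomes, exact = TRUE)
  truth <- sim$truth$species_assignment[am$genome_ids]
  same <- outer(truth, truth, "==")
  ut <- upper.tri(am$values)
  within_vals <- am$values[ut & same]
  cross_vals <- am$values[ut & !same]
  # alignment-free oracle view of the planted modes: ~98 within, lower across
  expect_gt(mean(within_vals), 97)
  expect_lt(mean(within_vals), 99.2)
  expect_lt(max(cross_vals), min(within_vals))
  expect_lt(mean(cross_vals), 94)
})

test_that("read mixtures honour composition, error and off-target settings", {
  # pure composition, no error, no off-target: every read matches a marker of A
  ms <- simulate_markers_and_reads(2, cbind(c(1, 0)), depth = 200,
                                   marker_length = 400, read_length = 80,
                                   error_rate = 0, seed = 131)
  markersA <- ms$markers$sequence[ms$markers$species_id == "sp01"]
  hits <- vapply(ms$reads[[1]], function(r)
    any(vapply(markersA, function(m) grepl(r, m, fixed = TRUE), logical(1))),
    logical(1))
  expect_true(all(hits))
  # multinomial split: expected 7:3 within binomial tolerance
  ms2 <- simulate_markers_and_reads(2, cbind(c(0.7, 0.3)), depth = 20000,
                                    marker_length = 400, read_length = 80,
                                    error_rate = 0, seed = 132)
  frac <- ms2$truth$on_target_counts[1, 1] / 20000
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 20000))
  # off-target fraction materialises and boundary/validation rules hold
  ms3 <- simulate_markers_and_reads(2, cbind(c(0.5, 0.5)), depth = 1000,
                                    marker_length = 400, read_length = 80,
                                    off_target_fraction = 0.4, seed = 133)
  expect_lt(sum(ms3$truth$on_target_counts[, 1]), 1000)
  expect_error(simulate_markers_and_reads(2, cbind(c(1, 0)), read_length = 2000,
                                          marker_length = 1000), "read_length")
  expect_error(simulate_markers_and_reads(2, cbind(c(1, 0)),
                                          off_target_fraction = 1), "off_target")
  expect_error(simulate_markers_and_reads(2, cbind(c(0.6, 0.6))), "sum to 1")
  # determinism
  ms4 <- simulate_markers_and_reads(2, cbind(c(0.5, 0.5)), depth = 500, seed = 134)
  ms5 <- simulate_markers_and_reads(2, cbind(c(0.5, 0.5)), depth = 500, seed = 134)
  expect_identical(ms4$reads, ms5$reads)
})

test_that("pangenome planting satisfies each class's thresholds with margin", {
  gpc <- c(lineage_I = 5, comammox_A1 = 4, comammox_A2 = 4, comammox_B = 5)
  pg <- simulate_pangenome(gpc, n_gc = 60, seed = 141)
  labs <- pg$truth$gc_labels
  pres <- pg$presence
  cl <- pg$clade_labels
  is_cmx <- cl %in% c("comammox_A1", "comammox_A2", "comammox_B")
  for (gc in names(labs)) {
    p <- pres[gc, ]
    if (labs[gc] == "core") expect_gte(mean(p), 0.8)
    if (labs[gc] == "comammox_enriched") {
      expect_gt(mean(p[is_cmx]), 0.6)
      expect_true(all(!p[!is_cmx]))
    }
    if (labs[gc] == "cladeB_specific") {
      expect_gte(mean(p[cl == "comammox_B"]), 0.55)
      expect_true(all(!p[cl != "comammox_B"]))
    }
    if (labs[gc] == "unique") expect_equal(sum(p), 1)
  }
  # all-core mix: every GC present in >= 80% of genomes
  pg2 <- simulate_pangenome(gpc, n_gc = 10, class_mix = c(core = 1), seed = 142)
  expect_true(all(rowMeans(pg2$presence) >= 0.8))
  # impossible margins error out
  expect_error(simulate_pangenome(c(comammox_A1 = 1), n_gc = 5,
                                  class_mix = c(unique = 1)), "at least 2")
  expect_error(simulate_pangenome(c(lineage_I = 4), n_gc = 5,
                                  class_mix = c(enriched = 1)), "enriched")
})

test_that("community matrix responds to its planted ecological knobs", {
  n_sp <- 12; n_sa <- 24
  S <- matrix(60, n_sp, n_sp); diag(S) <- 100
  habs <- rep(c("dwtp", "wwtp", "soil"), length.out = n_sa)
  cm <- simulate_community_matrix(n_sp, n_sa, habs, S, habitat_signal_beta = 1,
                                  seed = 151)
  expect_equal(dim(cm$rpm), c(n_sp, n_sa))
  expect_true(all(cm$rpm >= 0))
  expect_true(all(cm$rpm == 0 | cm$rpm >= 1.6))
  # determinism
  cm2 <- simulate_community_matrix(n_sp, n_sa, habs, S, habitat_signal_beta = 1,
                                   seed = 151)
  expect_identical(cm$rpm, cm2$rpm)
  # dimension validation
  expect_error(simulate_community_matrix(5, 10, "h", S), "n_species")
  expect_error(simulate_community_matrix(n_sp, 10, "h", S - 200), "\\[0, 100\\]")
})

test_that("median recovered Mantel r rises with the planted habitat signal", {
  n_sp <- 14; n_sa <- 30
  withr::local_seed(152)
  blocks <- sample(1:2, n_sp, replace = TRUE)
  S <- 60 + 35 * outer(blocks, blocks, "==") # two related species groups
  diag(S) <- 100
  gen <- pairwise_matrix(S, ids = sprintf("sp%02d", 1:n_sp))
  habs <- rep(c("dwtp", "wwtp", "soil"), length.out = n_sa)
  rec <- function(beta, seed) {
    cm <- simulate_community_matrix(n_sp, n_sa, habs, S, habitat_signal_beta = beta,
                                    noise_sd = 0.3, seed = seed)
    rpm <- cm$rpm[, colSums(cm$rpm) > 0, drop = FALSE] # drop empty samples
    hs <- habitat_similarity(clr_table(rpm))
    mantel(hs, gen, permutations = 99, seed = seed)$r
  }
  med <- vapply(c(0, 1.5, 4), function(b)
    median(vapply(1:8, function(s) rec(b, 1000 + s), numeric(1))), numeric(1))
  expect_lt(abs(med[1]), 0.25) # null is near zero
  expect_true(all(diff(med) > 0))
})
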