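test_that("segregation test evaluates the 1:1 chi-square", {
  st <- segregation_test(c(56, 47))
  expect_equal(st$chisq, 81 / 103, tolerance = 1e-12)
  expect_equal(round(st$chisq, 2), 0.79)
  expect_true(st$consistent_1to1)
  expect_equal(segregation_test(c(50, 50))$chisq, 0)
  st2 <- segregation_test(c(109, 0))
  expect_equal(st2$chisq, 109)
  expect_false(st2$consistent_1to1)
  expect_error(segregation_test(character(0)))
  # vector input drops non-G1/G2 labels
  st3 <- segregation_test(c(rep("G1", 56), rep("G2", 47), rep("unknown", 3)))
  expect_equal(st3$n_g1, 56)
  expect_equal(st3$n_g2, 47)
})

# A hand-built three-bin maternal group: the middle marker co-segregates
# with the trait, the outer markers carry 1 and 5 recombinants.
make_flank_fixture <- function(n = 103) {
  set.seed(10)
  trait01 <- rbinom(n, 1, 0.5)
  ids <- sprintf("I%03d", seq_len(n))
  upper <- trait01; upper[1] <- 1L - upper[1]
  lower <- trait01; lower[2:6] <- 1L - lower[2:6]
  # pad with distal markers so the flanking bins are interior
  far_u <- upper; far_u[10:25] <- 1L - far_u[10:25]
  far_l <- lower; far_l[30:45] <- 1L - far_l[30:45]
  P <- rbind(A_farup = far_u, B_upper = upper, C_mid = trait01,
             D_lower = lower, E_farlow = far_l)
  colnames(P) <- ids
  list(P = P, trait = stats::setNames(ifelse(trait01 == 1, "G1", "G2"), ids))
}

test_that("a marker identical to the phenotype co-segregates with zero recombinants", {
  fx <- make_flank_fixture()
  map <- build_parent_map(gm_from_patterns(fx$P), "mother",
                          mapping_params(), smooth = FALSE)
  rep <- map_trait(fx$trait, map)
  expect_true(rep$linked)
  expect_equal(rep$cosegregating$representative, "C_mid")
  expect_equal(rep$upper_flank$n_recombinants, 1)
  expect_equal(rep$lower_flank$n_recombinants, 5)
  expect_equal(rep$upper_flank$recombinant_ids, "I001")
  expect_setequal(rep$lower_flank$recombinant_ids, sprintf("I%03d", 2:6))
  expect_equal(rep$span_cM,
               abs(rep$lower_flank$pos_cM - rep$upper_flank$pos_cM))
  fs <- flank_support(rep)
  expect_equal(fs$n_recombinants, c(1L, 5L))
  expect_equal(fs$individuals[1], "I001")
})

test_that("one flipped phenotype produces exactly one recombinant", {
  fx <- make_flank_fixture()
  tr <- fx$trait
  tr["I050"] <- if (tr["I050"] == "G1") "G2" else "G1"
  map <- build_parent_map(gm_from_patterns(fx$P), "mother",
                          mapping_params(), smooth = FALSE)
  rep <- map_trait(tr, map)
  row_mid <- rep$test[rep$test$representative == "C_mid", ]
  expect_equal(row_mid$recombinants, 1)
})

test_that("the report is invariant to individual order", {
  fx <- make_flank_fixture()
  map <- build_parent_map(gm_from_patterns(fx$P), "mother",
                          mapping_params(), smooth = FALSE)
  r1 <- map_trait(fx$trait, map)
  r2 <- map_trait(sample(fx$trait), map)
  expect_equal(r1$lg, r2$lg)
  expect_equal(r1$span_cM, r2$span_cM)
  expect_setequal(r1$lower_flank$recombinant_ids,
                  r2$lower_flank$recombinant_ids)
})

test_that("zero recombinants genome-wide leaves the flanks open-ended", {
  set.seed(11)
  t01 <- rbinom(60, 1, 0.5)
  P <- rbind(only = t01, twin = t01)
  colnames(P) <- sprintf("I%02d", 1:60)
  map <- build_parent_map(gm_from_patterns(P), "mother",
                          mapping_params(), smooth = FALSE)
  rep <- map_trait(stats::setNames(ifelse(t01 == 1, "G1", "G2"),
                                   colnames(P)), map)
  expect_true(rep$linked)
  expect_null(rep$upper_flank)
  expect_null(rep$lower_flank)
  expect_true(is.na(rep$span_cM))
  fs <- flank_support(rep)
  expect_true(all(fs$individuals == "open-ended"))
})

test_that("an unrelated phenotype is reported unlinked", {
  fx <- make_flank_fixture()
  map <- build_parent_map(gm_from_patterns(fx$P), "mother",
                          mapping_params(), smooth = FALSE)
  set.seed(12)
  junk <- stats::setNames(sample(c("G1", "G2"), 103, replace = TRUE),
                          colnames(fx$P))
  rep <- map_trait(junk, map)
  expect_false(rep$linked)
  expect_error(flank_support(rep), "unlinked")
})

test_that("missing genotypes are skipped in recombinant counts", {
  fx <- make_flank_fixture()
  P <- fx$P
  # blank the co-segregating marker for one unremarkable individual
  P["C_mid", "I050"] <- NA_integer_
  map <- build_parent_map(gm_from_patterns(P), "mother",
                          mapping_params(), smooth = FALSE)
  rep <- map_trait(fx$trait, map)
  row_mid <- rep$test[rep$test$representative == "C_mid", ]
  expect_equal(row_mid$n_informative, 102)
  expect_equal(row_mid$recombinants, 0)
})

test_that("the inferred trait phase matches the maternal S haplotype", {
  cfg <- small_cfg(n_chromosomes = 2, female_chrom_lengths = c(80, 80),
                   markers_per_chromosome = 60, n_offspring = 150,
                   dsi_chromosome = 2, dsi_position = 40,
                   seg_class_mix = c(1, 0, 0), seed = 18)
  sim <- simulate_cross(cfg)
  # pattern at the marker nearest the locus: phase relative to S follows the
  # maternal transmission truth in an error-free world
  mk <- sim$markers[sim$markers$chrom == 2, ]
  near <- mk$marker[which.min(abs(mk$pos_female - 40))]
  pat_hap <- sim$geno[near, ] - (mk$father_h1[mk$marker == near] +
                                   mk$father_h2[mk$marker == near]) / 2
  s_carried <- sim$individuals$dsi_maternal == "S"
  # transmitted allele is perfectly in phase (or anti-phase) with S up to
  # the recombinants between marker and locus
  agree <- mean((pat_hap == 1) == s_carried)
  expect_true(agree > 0.9 || agree < 0.1)
})

test_that("gametic selection against one allele shows up as linked distortion", {
  cfg <- small_cfg(n_chromosomes = 2, female_chrom_lengths = c(80, 80),
                   markers_per_chromosome = 40, n_offspring = 400,
                   dsi_chromosome = 2, dsi_position = 40,
                   seg_class_mix = c(1, 0, 0), seed = 19)
  res <- sim_gm(cfg)
  sim <- res$sim
  # emulate selection: keep S carriers preferentially (drop half of the
  # s-carrying offspring), then scan for distortion
  keep <- sim$individuals$dsi_maternal == "S" |
    seq_len(nrow(sim$individuals)) %% 2 == 0
  gm <- res$gm
  gm$calls <- gm$calls[, keep]
  sc <- distortion_scan(gm, mapping_params())
  chr <- sim$markers$chrom[match(sc$marker, sim$markers$marker)]
  near_locus <- chr == 2 &
    abs(sim$markers$pos_female[match(sc$marker, sim$markers$marker)] - 40) < 20
  expect_gt(mean(sc$flagged[near_locus]), 0.8)
  expect_lt(mean(sc$flagged[chr == 1]), 0.3)
})
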