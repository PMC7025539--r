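test_that("Kosambi function matches closed forms and round-trips", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.25), 25 * log(3), tolerance = 1e-12)
  # small-r limit d ~ 100 r
  expect_equal(kosambi_cM(0.01), 1.000133, tolerance = 1e-4)
  expect_error(kosambi_cM(0.5))
  expect_error(kosambi_cM(-0.1))
  r <- seq(0, 0.49, by = 0.005)
  expect_equal(kosambi_inv(kosambi_cM(r)), r, tolerance = 1e-9)
  expect_true(all(diff(kosambi_cM(r)) > 0))
})

test_that("two-point estimates match direct evaluation", {
  a <- rep(c(0L, 1L), 50)
  est <- pairwise_rf_lod(a, a)
  expect_equal(est$r, 0)
  expect_equal(est$lod, 100 * log10(2), tolerance = 1e-9)
  expect_equal(est$phase, "coupling")

  # fully complementary patterns resolve to repulsion phase with r = 0
  est2 <- pairwise_rf_lod(a, 1L - a)
  expect_equal(est2$r, 0)
  expect_equal(est2$phase, "repulsion")
  expect_equal(est2$lod, 100 * log10(2), tolerance = 1e-9)

  # 10 offspring, 2 recombinants: cross-checked against a likelihood grid
  b <- a[1:10]; b2 <- b; b2[c(3, 7)] <- 1L - b2[c(3, 7)]
  est3 <- pairwise_rf_lod(b, b2)
  expect_equal(est3$r, 0.2)
  expect_equal(est3$lod, 8 * log10(1.6) + 2 * log10(0.4), tolerance = 1e-9)
  grid <- seq(0.001, 0.5, by = 1e-4)
  loglik <- 8 * log10(1 - grid) + 2 * log10(grid)
  expect_equal(grid[which.max(loglik)], 0.2, tolerance = 1e-3)
  expect_false(pairwise_rf_lod(b[1:5], b2[1:5])$reliable)
})

test_that("grouping applies both thresholds transitively", {
  set.seed(1)
  base1 <- rbinom(200, 1, 0.5)
  base2 <- rbinom(200, 1, 0.5)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 1L - x[i]; x }
  P <- rbind(a1 = base1, a2 = flip(base1, 6), a3 = flip(base1, 10),
             b1 = base2, b2 = flip(base2, 8))
  grp <- group_markers(rf_lod_matrix(P), mapping_params())
  expect_equal(length(grp$groups), 2)
  expect_setequal(grp$groups[[which(vapply(grp$groups, function(g) "a1" %in% g, TRUE))]],
                  c("a1", "a2", "a3"))

  # r = 0.25 with huge LOD still separates (rf_max violated)
  Q <- rbind(x = rep(c(0L, 1L), 100), y = flip(rep(c(0L, 1L), 100), 50))
  est <- pairwise_rf_lod(Q["x", ], Q["y", ])
  expect_equal(est$r, 0.25)
  expect_gt(est$lod, 10)
  g2 <- group_markers(rf_lod_matrix(Q), mapping_params())
  expect_equal(length(g2$groups), 0)
  expect_setequal(g2$singletons, c("x", "y"))

  g0 <- group_markers(rf_lod_matrix(P[0, , drop = FALSE]), mapping_params())
  expect_equal(length(g0$groups), 0)
})

test_that("bin collapsing merges identical-segregation markers only", {
  set.seed(2)
  p <- rbinom(60, 1, 0.5)
  q <- p; q[10] <- 1L - q[10]
  P <- rbind(m1 = p, m2 = p, m3 = q)
  bins <- collapse_bins(P)
  expect_equal(length(bins), 2)
  expect_setequal(bins[[1]]$members, c("m1", "m2"))

  # complementary pattern (repulsion phase) joins the same bin
  P2 <- rbind(m1 = p, m2 = 1L - p)
  expect_equal(length(collapse_bins(P2)), 1)

  # representative: fewest missing, ties broken lexicographically
  pm <- p; pm[1:5] <- NA
  P3 <- rbind(zz = p, aa = p, mm = pm)
  b3 <- collapse_bins(P3)
  expect_equal(b3[[1]]$representative, "aa")
})

test_that("bin count equals the brute-force distinct-pattern count", {
  res <- sim_gm(small_cfg(markers_per_chromosome = 40, n_offspring = 150,
                          mean_depth = 200, seed = 12))
  tp <- testcross_patterns(res$gm, "mother")
  # duplicate a third of the markers under fresh ids
  dup <- tp$patterns[seq(1, nrow(tp$patterns), by = 3), , drop = FALSE]
  rownames(dup) <- paste0(rownames(dup), "_dup")
  P <- rbind(tp$patterns, dup)
  grp <- group_markers(rf_lod_matrix(P), mapping_params())
  n_bins <- sum(vapply(grp$groups, function(g)
    length(collapse_bins(P[g, , drop = FALSE])), 0L))
  # oracle: canonicalise each complete pattern (phase-free) and count
  # distinct ones within each group
  n_distinct <- sum(vapply(grp$groups, function(g) {
    pats <- apply(P[g, , drop = FALSE], 1, function(x) {
      if (x[!is.na(x)][1] == 1L) x <- 1L - x
      paste(ifelse(is.na(x), "N", x), collapse = "")
    })
    length(unique(pats))
  }, 0L))
  expect_equal(n_bins, n_distinct)
})

test_that("ordering matches exhaustive search on small bin sets", {
  set.seed(3)
  # three bins along a gradient: adjacent recombinants 3 and 4, ends 7
  p1 <- rbinom(100, 1, 0.5)
  p2 <- p1; p2[1:3] <- 1L - p2[1:3]
  p3 <- p2; p3[4:7] <- 1L - p3[4:7]
  P <- rbind(b1 = p1, b2 = p2, b3 = p3)
  bins <- order_markers(collapse_bins(P))
  expect_equal(length(bins), 3)
  expect_equal(names(bins), c("b1", "b2", "b3"))
  expect_equal(attr(bins, "objective"), 7)
  # exhaustive: all 3 distinct orders
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  R <- function(i, j) sum(P[i, ] != P[j, ])
  objs <- vapply(perms, function(o) R(o[1], o[2]) + R(o[2], o[3]), 0)
  expect_equal(min(objs), 7)

  # single bin passes through unchanged
  b1 <- collapse_bins(P[1, , drop = FALSE])
  expect_equal(length(order_markers(b1)), 1)
})

test_that("2-opt refinement never worsens and orientation is canonical", {
  res <- sim_gm(small_cfg(n_chromosomes = 1, female_chrom_lengths = 90,
                          markers_per_chromosome = 40, n_offspring = 150,
                          dsi_chromosome = 1, dsi_position = 45,
                          seg_class_mix = c(1, 0, 0), seed = 13))
  tp <- testcross_patterns(res$gm, "mother")
  bins <- collapse_bins(tp$patterns)
  ord <- order_markers(bins)
  # objective is the minimum over 200 random permutations (sanity bound)
  BP <- do.call(rbind, lapply(ord, `[[`, "pattern"))
  cnt_R <- function(o) {
    s <- 0
    for (k in seq_len(length(o) - 1)) {
      est <- pairwise_rf_lod(BP[o[k], ], BP[o[k + 1], ])
      s <- s + est$r * est$n_informative
    }
    s
  }
  base <- cnt_R(seq_len(nrow(BP)))
  set.seed(99)
  rand <- replicate(200, cnt_R(sample(nrow(BP))))
  expect_lte(base, min(rand))
  expect_true(names(ord)[1] < names(ord)[length(ord)])
})

test_that("map distances accumulate Kosambi-transformed adjacent fractions", {
  # identical bins: zero length
  p <- rep(c(0L, 1L), 60)
  expect_equal(nrow(map_distances(collapse_bins(rbind(m1 = p, m2 = p)))), 1)

  # 3 bins with adjacent r = 0.1 each: length 2 * 25 * ln(1.2/0.8)
  q1 <- rep(c(0L, 1L), 100)
  q2 <- q1; q2[1:20] <- 1L - q2[1:20]
  q3 <- q2; q3[21:40] <- 1L - q3[21:40]
  bins <- order_markers(collapse_bins(rbind(a = q1, b = q2, c = q3)))
  md <- map_distances(bins)
  expect_equal(max(md$pos_cM), 2 * 25 * log(1.2 / 0.8), tolerance = 1e-9)
  expect_true(all(diff(md$pos_cM) >= 0))
})

test_that("distortion scan flags the chi-square exceedances", {
  mkcalls <- function(a, b, n = 103) c(rep("A", a), rep("H", b),
                                       rep("-", n - a - b))
  calls <- rbind(ok = mkcalls(56, 47), even = mkcalls(50, 50),
                 bad = mkcalls(70, 30))
  colnames(calls) <- sprintf("i%03d", seq_len(ncol(calls)))
  gm <- genotype_matrix(calls, rep("H", 3), rep("A", 3),
                        calling_thresholds(min_called_progeny = 0))
  sc <- distortion_scan(gm, mapping_params())
  expect_equal(sc$chisq[sc$marker == "ok"], (56 - 47)^2 / 103, tolerance = 1e-12)
  expect_equal(round(sc$chisq[sc$marker == "ok"], 2), 0.79)
  expect_false(sc$flagged[sc$marker == "ok"])
  expect_equal(sc$chisq[sc$marker == "even"], 0)
  expect_equal(sc$chisq[sc$marker == "bad"], 16)
  expect_true(sc$flagged[sc$marker == "bad"])
})

test_that("distortion flag rate on undistorted simulations is near alpha", {
  # one marker per chromosome so the tested markers are unlinked and the
  # binomial error model for the flag rate holds
  flags <- unlist(lapply(1:10, function(s) {
    res <- sim_gm(small_cfg(n_chromosomes = 23,
                            female_chrom_lengths = rep(100, 23),
                            markers_per_chromosome = 1, n_offspring = 150,
                            dsi_chromosome = 1, dsi_position = 50,
                            mean_depth = 200, seed = 1000 + s))
    sc <- distortion_scan(res$gm, mapping_params())
    sc$flagged[sc$test == "1:1"]
  }))
  rate <- mean(flags)
  se <- sqrt(0.05 * 0.95 / length(flags))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("scrub removes nothing from well-separated error-free data", {
  # constructed dense group: 30 markers, 80 individuals, one crossover per
  # individual at a uniform position (well separated by construction)
  set.seed(4)
  n_mk <- 30; n_ind <- 80
  P <- matrix(0L, n_mk, n_ind,
              dimnames = list(sprintf("m%02d", 1:n_mk), sprintf("i%02d", 1:n_ind)))
  for (j in seq_len(n_ind)) {
    cut <- sample(0:n_mk, 1)
    start <- sample(0:1, 1)
    P[, j] <- c(rep(start, cut), rep(1 - start, n_mk - cut))
  }
  sm <- smooth_correct(P, mapping_params())
  expect_equal(sm$n_removed, 0)
  expect_identical(sm$patterns, P)

  # one injected singleton flip is removed in iteration 1
  P2 <- P
  P2["m15", "i40"] <- 1L - P2["m15", "i40"]
  sm2 <- smooth_correct(P2, mapping_params())
  expect_equal(sm2$removals$marker, "m15")
  expect_equal(sm2$removals$individual, "i40")
  expect_equal(sm2$removals$iteration, 1L)
})

test_that("scrub removes injected errors with low collateral and deflates inflated maps", {
  cfg_err <- small_cfg(n_chromosomes = 1, female_chrom_lengths = 100,
                       markers_per_chromosome = 120, n_offspring = 150,
                       dsi_chromosome = 1, dsi_position = 50,
                       seg_class_mix = c(1, 0, 0),
                       genotyping_error_rate = 0.01, seed = 15)
  res <- sim_gm(cfg_err)
  tp <- testcross_patterns(res$gm, "mother")
  grp <- group_markers(rf_lod_matrix(tp$patterns), mapping_params())
  P <- tp$patterns[grp$groups[[1]], , drop = FALSE]
  sm <- smooth_correct(P, mapping_params())
  errs <- res$reads$error_log
  obs <- !is.na(P[cbind(match(errs$marker, rownames(P)),
                        match(errs$individual, colnames(P)))])
  obs[is.na(obs)] <- FALSE
  errs <- errs[obs, ]
  key <- function(m, i) paste(m, i)
  hit_rate <- mean(key(errs$marker, errs$individual) %in%
                     key(sm$removals$marker, sm$removals$individual))
  collateral <- sum(!(key(sm$removals$marker, sm$removals$individual) %in%
                        key(errs$marker, errs$individual)))
  n_correct <- sum(!is.na(P)) - nrow(errs)
  expect_gte(hit_rate, 0.8)
  expect_lt(collateral / n_correct, 0.01)

  # errors inflate the map; scrubbing moves the length back toward truth
  len_err <- map_stats(build_parent_map(res$gm, "mother", smooth = FALSE))$length_cM
  len_scrub <- map_stats(build_parent_map(res$gm, "mother", smooth = TRUE))$length_cM
  cfg0 <- small_cfg(n_chromosomes = 1, female_chrom_lengths = 100,
                    markers_per_chromosome = 120, n_offspring = 150,
                    dsi_chromosome = 1, dsi_position = 50,
                    seg_class_mix = c(1, 0, 0),
                    genotyping_error_rate = 0, seed = 15)
  len_true <- map_stats(build_parent_map(sim_gm(cfg0)$gm, "mother",
                                         smooth = FALSE))$length_cM
  expect_gt(len_err, len_true)
  expect_lt(abs(len_scrub - len_true), abs(len_err - len_true))
})

test_that("map summary statistics add up per linkage group", {
  res <- sim_gm(small_cfg(markers_per_chromosome = 40, n_offspring = 150,
                          seed = 16))
  m <- build_parent_map(res$gm, "mother", smooth = FALSE)
  st <- map_stats(m)
  expect_equal(st$markers, sum(st$per_lg$markers))
  expect_equal(st$bins, sum(st$per_lg$bins))
  expect_equal(st$mean_bin_spacing, round(st$length_cM / st$bins, 2))
  expect_true(all(vapply(m$lgs, function(l) !is.unsorted(l$table$pos_cM), TRUE)))
})

test_that("synteny comparison is order- and label-faithful", {
  res <- sim_gm(small_cfg(markers_per_chromosome = 50, n_offspring = 200,
                          seg_class_mix = c(0.25, 0.25, 0.5), seed = 17))
  mf <- build_parent_map(res$gm, "mother", smooth = FALSE)
  mm <- build_parent_map(res$gm, "father", smooth = FALSE)
  rep0 <- compare_maps(mf, mm, res$gm$markers)
  expect_equal(nrow(rep0$pairs), 3)
  expect_true(all(abs(rep0$pairs$order_cor) > 0.95))
  expect_equal(nrow(rep0$translocations), 0)
  # collinear parents: no inversion candidate spanning more than local noise
  if (nrow(rep0$inversions) > 0) {
    expect_lt(max(rep0$inversions$span_female_cM), 10)
  }

  # an injected 30 cM male inversion is recovered on its linkage group
  cfg_inv <- small_cfg(markers_per_chromosome = 50, n_offspring = 200,
                       seg_class_mix = c(0.25, 0.25, 0.5), seed = 17,
                       male_inversions = list(list(chrom = 1, start = 30,
                                                   end = 60)))
  res_i <- sim_gm(cfg_inv)
  mfi <- build_parent_map(res_i$gm, "mother", smooth = FALSE)
  mmi <- build_parent_map(res_i$gm, "father", smooth = FALSE)
  rep1 <- compare_maps(mfi, mmi, res_i$gm$markers)
  big <- rep1$inversions[rep1$inversions$span_female_cM > 10, , drop = FALSE]
  expect_equal(nrow(big), 1)
  expect_gte(big$n_anchors, 3)
  # every anchor of the reported segment lies inside the injected interval
  # (the anchor span necessarily undershoots the 30 cM segment itself)
  anch <- strsplit(big$anchors, ";")[[1]]
  truth <- res_i$sim$markers
  pos <- truth$pos_female[match(paste0(anch, "a"), truth$marker)]
  expect_true(all(pos >= 30 & pos <= 60))
  expect_gte(big$span_female_cM, 15)
})
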