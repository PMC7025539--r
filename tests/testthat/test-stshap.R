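test_that("the haplotype catalog has the published shape", {
  cat5 <- dsi_catalog()
  expect_equal(nrow(cat5$alleles), 5)
  expect_equal(ncol(cat5$alleles), 14)
  expect_setequal(rownames(cat5$alleles), c("S-A", "S-B", "s-a", "s-b", "s-c"))
  expect_equal(cat5$positions,
               c(36L, 47L, 63L, 77L, 103L, 106L, 142L, 155L, 171L, 173L,
                 198L, 217L, 218L, 283L))
  expect_setequal(cat5$dominant, c("S-A", "S-B"))
  # parental subset: 11 polymorphic positions; full set: 12 SNPs + 2 indels
  par4 <- catalog_polymorphism(cat5, c("S-A", "s-a", "s-b", "s-c"))
  expect_equal(par4$polymorphic, 11)
  full <- catalog_polymorphism(cat5)
  expect_equal(full$substitutions, 12)
  expect_equal(full$indels, 2)
})

test_that("amplicon sequences carry the catalog alleles and indels", {
  cat5 <- dsi_catalog()
  expect_equal(nchar(amplicon_sequence("S-A")), 476)
  expect_equal(nchar(amplicon_sequence("s-a")), 476)
  expect_equal(nchar(amplicon_sequence("S-B")), 473)  # 2 + 1 bp deletions
  sa <- amplicon_sequence("S-A")
  expect_equal(substr(sa, 1, 20), dsi_catalog()$forward_primer)
  expect_equal(substr(sa, 63, 63), "T")
  expect_equal(substr(sa, 283, 283), "T")
})

test_that("extract_amplicon_genotype reads homozygotes, clones and consensus", {
  cat5 <- dsi_catalog()
  g_hom <- extract_amplicon_genotype(amplicon_sequence("S-A"), cat5)
  for (k in seq_along(cat5$positions)) {
    expect_equal(sort(g_hom[[k]]),
                 sort(rep(cat5$alleles["S-A", k], 2)),
                 label = paste("position", cat5$positions[k]))
  }

  g2 <- extract_amplicon_genotype(c(amplicon_sequence("s-a"),
                                    amplicon_sequence("s-b")), cat5)
  expect_setequal(g2[["63"]], c("T", "G"))
  expect_setequal(g2[["283"]], c("C", "T"))

  # unphased consensus with an ambiguity code: Y at 283, plain T at 63
  cons <- amplicon_sequence("S-A")
  substr(cons, 283, 283) <- "Y"
  g3 <- extract_amplicon_genotype(cons, cat5)
  expect_equal(g3[["63"]], c("T", "T"))
  expect_setequal(g3[["283"]], c("C", "T"))

  expect_error(extract_amplicon_genotype(paste(rep("A", 476), collapse = "")),
               "frame not found")
  # reverse-complement input is re-oriented, not rejected
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amplicon_sequence("s-c"))))
  g4 <- extract_amplicon_genotype(rc, cat5)
  expect_equal(g4[["63"]], c("G", "G"))
})

test_that("indel alleles are read through the alignment", {
  cat5 <- dsi_catalog()
  gb <- extract_amplicon_genotype(amplicon_sequence("S-B"), cat5)
  expect_equal(gb[["106"]], c("-", "-"))
  expect_equal(gb[["218"]], c("-", "-"))
  het <- extract_amplicon_genotype(c(amplicon_sequence("S-B"),
                                     amplicon_sequence("s-b")), cat5)
  expect_setequal(het[["106"]], c("-", "TT"))
  expect_setequal(het[["218"]], c("-", "T"))
})

test_that("haplotype resolution enumerates the published combinations", {
  pairs_str <- function(p) sort(paste(p$hap1, p$hap2, sep = "/"))
  p1 <- resolve_haplotypes(diagnostic_genotype("TG", "CT"))
  expect_equal(pairs_str(p1), c("s-a/s-b", "s-a/s-c"))
  p2 <- resolve_haplotypes(diagnostic_genotype("TT", "TT"))
  expect_equal(pairs_str(p2), c("S-A/S-A", "S-A/S-B", "S-B/S-B"))
  p3 <- resolve_haplotypes(diagnostic_genotype(NA, NA))
  expect_equal(nrow(p3), 15)  # vacuous constraint admits all pairs
  # full-genotype resolution pins the exact pair
  g <- extract_amplicon_genotype(c(amplicon_sequence("S-B"),
                                   amplicon_sequence("s-a")))
  p4 <- resolve_haplotypes(g)
  expect_equal(pairs_str(p4), "S-B/s-a")
})

test_that("classification reproduces the diagnostic-genotype table", {
  tab <- load_table_fixtures()$diagnostic_genotypes
  for (k in seq_len(nrow(tab))) {
    cl <- classify_dsi(g63 = tab$genotype_63[k], g283 = tab$genotype_283[k])
    expect_equal(cl$group, tab$group[k],
                 label = paste("row", tab$haplotype_combination[k]))
    expect_equal(cl$homozygous_or_null, tab$homozygous_or_null[k] == "yes",
                 label = paste("hom-or-null, row", k))
  }
  cl_bad <- classify_dsi(g63 = "GG", g283 = "CC")
  expect_equal(cl_bad$group, "inconsistent")
  expect_true(cl_bad$novel_haplotype)
})

test_that("the diagnostic two-SNP space is never ambiguous", {
  # every one of the 15 catalog pairs classifies to its dominance class from
  # the two diagnostic positions alone
  cat5 <- dsi_catalog()
  haps <- rownames(cat5$alleles)
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    g63 <- paste0(cat5$alleles[haps[i], "63"], cat5$alleles[haps[j], "63"])
    g283 <- paste0(cat5$alleles[haps[i], "283"], cat5$alleles[haps[j], "283"])
    cl <- classify_dsi(g63 = g63, g283 = g283)
    truth <- if (any(c(haps[i], haps[j]) %in% cat5$dominant)) "G1" else "G2"
    expect_equal(cl$group, truth, label = paste(haps[i], haps[j]))
  }
  # exhaustive diploid sweep over {T,G} x {T,C}: every genotype is either a
  # published row or inconsistent; none is ambiguous
  tab <- load_table_fixtures()$diagnostic_genotypes
  norm <- function(g) paste(sort(strsplit(g, "")[[1]]), collapse = "")
  published <- unique(paste(vapply(tab$genotype_63, norm, ""),
                            vapply(tab$genotype_283, norm, "")))
  for (g63 in c("TT", "TG", "GG")) for (g283 in c("TT", "TC", "CC")) {
    cl <- classify_dsi(g63 = g63, g283 = g283)
    key <- paste(norm(g63), norm(g283))
    if (key %in% published) {
      expect_true(cl$group %in% c("G1", "G2"), label = key)
    } else {
      expect_equal(cl$group, "inconsistent", label = key)
    }
  }
})

test_that("classification is symmetric in allele and pair order", {
  a <- classify_dsi(g63 = "TG", g283 = "CT")
  b <- classify_dsi(g63 = "GT", g283 = "TC")
  expect_equal(a$group, b$group)
  expect_equal(a$pairs, b$pairs)
})

test_that("cross inheritance checking partitions offspring", {
  p1 <- c("S-A", "s-a"); p2 <- c("s-b", "s-c")
  offs <- list(
    ok_g1 = diagnostic_genotype("TG", "TT"),   # S-A/s-b or S-A/s-c
    ok_g2 = diagnostic_genotype("TG", "CT"),   # s-a/s-b or s-a/s-c
    bad = extract_amplicon_genotype(c(amplicon_sequence("S-B"),
                                      amplicon_sequence("s-a")))
  )
  res <- verify_cross_haplotypes(p1, p2, offs)
  expect_equal(res$valid, c(TRUE, TRUE, FALSE))
  expect_equal(res$group[1:2], c("G1", "G2"))
  expect_true(res$flagged[3])

  # full-length clone pairs give unique combinations
  offs2 <- list(a = extract_amplicon_genotype(c(amplicon_sequence("S-A"),
                                                amplicon_sequence("s-b"))),
                b = extract_amplicon_genotype(c(amplicon_sequence("s-a"),
                                                amplicon_sequence("s-c"))))
  res2 <- verify_cross_haplotypes(p1, p2, offs2)
  expect_equal(res2$combination, c("S-A/s-b", "s-a/s-c"))
  expect_equal(res2$group, c("G1", "G2"))
})
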