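Package: dsimap
Title: Pseudo-Testcross Linkage Mapping of a Diallelic Self-Incompatibility Locus
Version: 1.0.0
Authors@R: person("dsimap", "maintainers", email = "dsimap@example.org", role = c("aut", "cre"))
Description: Tools for mapping a diallelic self-incompatibility (DSI) locus in an
    outcrossing F1 progeny of two heterozygous parents. Includes a synthetic-cross
    simulator with sex-specific recombination and read-count genotyping, threshold
    based genotype calling with pseudo-testcross segregation classification,
    Mendelian-exclusion parentage checking, per-parent linkage-map construction
    (two-point grouping, genetic-bin collapsing, minimum-spanning-tree marker
    ordering, neighbourhood-based genotyping-error removal, Kosambi distances,
    segregation-distortion scanning, cross-parent synteny comparison), binary-trait
    co-segregation mapping with flanking-recombinant interval support, and a
    sequence-tagged-site haplotype classifier that predicts incompatibility group
    (G1 or G2) from two diagnostic SNPs of a 476-bp amplicon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
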