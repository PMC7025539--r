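---
title: "Methods: simulating and mapping a diallelic self-incompatibility locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping a diallelic self-incompatibility locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsimap)
```

## The model

A diallelic self-incompatibility (DSI) system has one locus with two
specificities: `Ss` individuals belong to incompatibility group G1, `ss`
to G2, with `S` dominant. In a G1 x G2 cross (`Ss x ss`) the locus
segregates like any testcross marker, so the progeny split 1:1 and the
locus can be mapped as a Mendelian trait on the map of the heterozygous
parent — here the female parent.

Mapping uses the two-way pseudo-testcross design for an F1 of two
heterozygous outbred parents. Three marker classes occur:

* **maternal testcross** (het x hom): segregates 1:1 through the mother;
* **paternal testcross** (hom x het): the converse;
* **fully informative** ("ABxCD", four distinguishable alleles):
  informative for both parents.

The simulator represents an ABxCD locus as two co-located biallelic SNPs
on one RAD tag — one segregating from each parent — which reconstructs the
four-allele genotype without phase ambiguity and is how such loci actually
arise in reduced-representation data.

## The synthetic cross: what it emulates, and what it does not

`cross_config()` defaults state the emulated world: 23 chromosomes with
the female genetic lengths of the packaged map summary (totalling ~5,680
cM), a male map shorter by the heterochiasmy ratio 1.6, 229 true-to-type
offspring among `round(229/0.95) = 241` drawn seedlings (12
open-pollination contaminants), a `Ss x ss` locus on chromosome 18, read
depth negative binomial with mean 30 and size 5, per-read error 0.005 and
a per-call genotype-swap rate of 0.01. Contaminants are crosses of the
female parent with a random unrelated pollen donor, so only paternal
alleles can betray them — mirroring open pollination. Parentage markers
emulate a capillary SSR panel: 12 unlinked loci with 8 equifrequent
alleles and a per-allele typing error of 0.002, the scale reported for
that technology; this matters because Mendelian exclusion with
`max_mismatches = 1` starts sacrificing true offspring once the per-allele
error rate approaches 1%.

Crossovers per meiosis and chromosome are Poisson with mean equal to the
sex-specific length in Morgans, breakpoints uniform, **no interference**.
Real meioses show positive interference (the Kosambi function used for
distances assumes as much), so the simulator over-produces tight double
and triple crossovers relative to real data. Three consequences are
documented rather than hidden:

* estimated map lengths shrink slightly when the error scrub removes real
  tight doubles (a few percent on dense groups);
* an "error-free" simulated group is *not* scrub-free — real tight doubles
  look exactly like isolated errors;
* in ~10% of simulated groups a triple crossover within a few cM makes a
  locally swapped bin order the *strict* minimum-recombination optimum, so
  exact order recovery cannot reach 100% of seeds for any parsimony-based
  ordering. The corresponding acceptance expectation is left red with this
  analysis; grouping recovery is unaffected (100%), and the recovered
  order always attains an objective at least as good as the truth's.

A green simulation-based test therefore establishes that the algorithms
recover the structure the no-interference model identifies — not that they
reproduce the published maps, whose raw data are not used.

## Genotype calling

Calls are threshold-based on read counts: coverage below 8 reads is
missing; otherwise the reference fraction `f = ref/(ref+alt)` gives a
heterozygote when `0.15 <= f <= 0.85` (boundaries inclusive to het — the
published description is silent on the boundary, and "minimum coverage of
eight" argues for inclusive thresholds), homozygous reference above,
homozygous alternate below. A locus is retained when called in strictly
more than 150 progeny; for simulated populations of other sizes the
pipeline scales this count proportionally (150/229). The probabilistic
SNP-model of the original caller is deliberately out of scope.

## Map construction

**Two-point estimation.** For two testcross patterns the phase minimising
mismatches is chosen; `r = R/n` over pairwise-complete observations and
`LOD = (n-R) log10(2(1-r)) + R log10(2r)`, with `LOD = n log10 2` at
`R = 0`. Estimates with fewer than 10 complete pairs are flagged
unreliable and excluded from grouping.

**Grouping.** Single-linkage transitive closure over edges with
`LOD > 10` and `r <= 0.20` (after phase resolution). Thresholds emulate
the published criteria; markers linked to nothing are reported as
singletons.

**Bins.** Markers with zero recombinants and no call conflicts collapse
into a genetic bin; the representative is the member with fewest missing
calls (ties lexicographic), and the bin carries a phased majority
consensus.

**Ordering.** A complete graph on bins weighted by `r` is reduced to its
minimum spanning tree; the tree's weighted diameter path seeds the order;
off-path bins are inserted where they add the fewest recombinants; 2-opt
reversals plus single-bin relocations refine until the total adjacent
recombinant count stops decreasing. A second refinement pass masks
apparent double-crossover cells (per-side agreement rule at threshold
0.95) before re-refining: tight doubles break the additivity of
recombinant counts and are the main source of local order errors.
Distances are always computed from unmasked data. Orientation is
canonicalised so the first bin's representative id precedes the last's.

**Error removal.** A SMOOTH-style scrub: for each datapoint, weighted
agreement with up to 5 flanking informative calls per side (weights 1,
1/2, 1/4, ...), and the support is the *better of the two sides*. A
genuine crossover boundary keeps full support on one side; an isolated
error disagrees with both. Datapoints with support below 0.70 are set to
missing — never flipped — the group is re-ordered, the threshold tightens
by 0.05, and the pass repeats up to 5 times or until nothing is removed.
Terminal datapoints (one informative side) are never removed, since a real
crossover in the terminal interval is indistinguishable from an error
there. The one-sided rule is this package's choice: a plain two-sided
weighted average gives support 0.5 at every real crossover boundary and
would scrub ~2 correct calls per crossover, far above the 1% collateral
this stage is allowed.

**Distances.** Adjacent-bin recombination fractions are transformed with
the Kosambi function, `d = 25 ln[(1+2r)/(1-2r)]` cM (the published
formula yields Morgans; positions are stored in cM, which matches the
magnitude of the reference map summary), and cumulated from zero.

**Distortion.** Testcross markers are tested against 1:1 with
`(a-b)^2/(a+b)` (1 df), het x het single SNPs against 1:2:1 (2 df), and
ABxCD SNP-row pairs jointly against 1:1:1:1 (3 df), all at `alpha = 0.05`
with no multiple-testing correction (a Bonferroni option exists). Flags on
linked markers are correlated, so calibration tests use unlinked markers.

**Synteny.** ABxCD loci anchor the two parental maps. Linkage groups pair
by anchor majority; within a pair, anchors sorted by female position are
scanned (after orienting by the rank correlation's sign) for maximal
strictly decreasing runs of male positions — each run of >= 2 anchors is
an inversion candidate with its cM extents. The reported span is the
anchor span and therefore undershoots the true segment, whose breakpoints
lie beyond the outermost anchors. Anchors pairing to a different group are
translocation candidates.

## Trait mapping

The phenotype (G1 = carrying `S`) is a testcross pseudo-marker.
Recombinants against every bin are counted over phenotyped, genotyped
individuals (missing genotypes skipped), phase chosen to minimise the
count. Bins with zero recombinants form the co-segregating set; the
nearest bins on each side with at least one recombinant are the borders,
and the span is their cM distance, taken from the full map while the
counts come from the phenotyped subset. When no bin co-segregates
perfectly — expected occasionally with a finite marker grid and a
phenotyped subset smaller than the mapped population — the trait is placed
at the minimum-recombinant bin(s) and the borders are the nearest bins
with strictly more recombinants than that minimum; this reduces to the
zero/one rule in the ideal case and keeps the reported interval a genuine
bracket of the locus. A best recombinant rate above 20% yields an
"unlinked" report rather than an error. Individuals with uncertain
phenotype are dropped before any computation.

## The STS classifier

The catalog fixes five haplotypes of a 476-bp amplicon over 14 variant
positions (12 substitutions, 2 indels: 2 bp at position 106, 1 bp at
218), positions counted from the first base of the forward primer (the
published convention is ambiguous; any fixed choice is internally
consistent, which is all classification needs). S-A and S-B are dominant
(G1-conferring). Classification enumerates all 15 unordered haplotype
pairs and keeps those whose allele multisets match the genotype at every
informative position; the group is G1 if every surviving pair contains a
dominant haplotype, G2 if none does, ambiguous if they disagree and
inconsistent (novel-haplotype flag) if none fits. On the two diagnostic
positions alone this reproduces the published genotype-to-group table
exactly, and the exhaustive diploid sweep shows no ambiguous genotype. A
genotype consistent only with dominant/dominant pairs is annotated
"homozygous or null", since one amplified dominant allele cannot be told
from a dominant/null combination. Sequence input is aligned against the
S-A reference frame (a synthetic backbone carrying the catalog alleles —
real inter-variant sequence is not needed for classification); the bases
flanking the 106 indel are chosen to break the local homopolymer so the
deletion cannot slide during alignment, and any gap at an indel position
reads as the deletion allele.

## Numerical and policy choices

* Strict inequalities where the published text says "greater than":
  retention needs > 150 progeny; grouping needs LOD > 10.
* Tie-breaks are lexicographic by marker id throughout; linkage groups are
  numbered by descending marker count (anchoring to a physical assembly is
  out of scope).
* All randomness flows from one master seed; the read stage derives its
  seed as `seed + 1`, the phenotype subsample in the pipeline as
  `seed + 2`, so reruns are byte-identical.
* Configuration files for the CLI are JSON (no YAML parser is available in
  the supported dependency set).
* The reference-table fixtures are checksummed on load.

## Known limitations

* No crossover interference in the simulator (see above); map-length
  recovery and order-recovery tolerances account for it.
* The minimal two-point/parsimony machinery does not attempt multipoint
  likelihood ordering; ordering accuracy at the sub-cM scale is limited by
  observed recombinants.
* Parentage checking is exclusion counting, not a likelihood method: with
  very high SSR error rates it excludes true offspring.
* The classifier never force-fits novel haplotypes; unseen alleles are
  reported, not assigned.
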