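#' The STS amplicon haplotype catalog
#'
#' Catalog of the five haplotypes of the 476-bp diagnostic amplicon
#' (Oe-DSI-locus-fragment-A) over its 14 variant positions: 12 nucleotide
#' substitutions and 2 small indels (a 2-bp indel at position 106 with
#' alleles `"TT"`/`"-"` and a 1-bp indel at position 218 with alleles
#' `"T"`/`"-"`). Positions are 1-based offsets in the amplicon frame, with
#' position 1 the first base of the forward primer. Haplotypes S-A and S-B
#' carry the dominant determinant (incompatibility group G1); s-a, s-b and
#' s-c are recessive (G2 when homozygous or in recessive combination).
#' Positions 63 and 283 alone are diagnostic for the group.
#'
#' @return Object of class `haplotype_catalog`: list with `positions`
#'   (integer vector of 14), `alleles` (5 x 14 character matrix, haplotypes
#'   x positions), `dominant` (names of G1-conferring haplotypes),
#'   `indel_positions`, `diagnostic_positions` (63 and 283), `accessions`,
#'   `amplicon_length` (476), `forward_primer`, `reverse_primer`.
#' @export
dsi_catalog <- function() {
  fx <- load_table_fixtures()$haplotypes
  al <- as.matrix(fx[, grep("^p", names(fx))])
  rownames(al) <- fx$haplotype
  colnames(al) <- sub("^p", "", colnames(al))
  structure(list(
    positions = as.integer(colnames(al)),
    alleles = al,
    dominant = c("S-A", "S-B"),
    indel_positions = c(106L, 218L),
    diagnostic_positions = c(63L, 283L),
    accessions = stats::setNames(fx$accession, fx$haplotype),
    amplicon_length = 476L,
    forward_primer = "TTTTGGGTGCGAATTGTCCA",
    reverse_primer = "AGGCCACTGTATTTCTAACTCG"
  ), class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("<haplotype_catalog>\n")
  cat(sprintf("  %d haplotypes x %d variant positions of a %d-bp amplicon\n",
              nrow(x$alleles), ncol(x$alleles), x$amplicon_length))
  print(x$alleles)
  invisible(x)
}

#' Count polymorphic columns of a haplotype subset
#'
#' @param catalog A [dsi_catalog()].
#' @param haplotypes Haplotype names to restrict to (default all five).
#' @return List: `polymorphic` (number of variant columns segregating in the
#'   subset), `substitutions`, `indels`.
#' @export
catalog_polymorphism <- function(catalog = dsi_catalog(),
                                 haplotypes = rownames(catalog$alleles)) {
  al <- catalog$alleles[haplotypes, , drop = FALSE]
  poly <- apply(al, 2, function(col) length(unique(col)) > 1)
  is_indel <- as.integer(colnames(al)) %in% catalog$indel_positions
  list(polymorphic = sum(poly),
       substitutions = sum(poly & !is_indel),
       indels = sum(poly & is_indel))
}

# Reference amplicon frame: the S-A haplotype over a fixed synthetic
# backbone (real inter-variant sequence is not needed for classification;
# only the variant positions and primer anchors matter). The backbone
# cycles ACGT so it can never contain a spurious primer match.
amplicon_reference <- function(catalog = dsi_catalog()) {
  L <- catalog$amplicon_length
  fwd <- strsplit(catalog$forward_primer, "")[[1]]
  rev_rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(catalog$reverse_primer))), "")[[1]]
  seq <- rep(c("A", "C", "G", "T"), length.out = L)
  seq[seq_along(fwd)] <- fwd
  seq[(L - length(rev_rc) + 1):L] <- rev_rc
  # keep the bases flanking the 2-bp indel distinct from its TT allele so a
  # deletion cannot slide along a homopolymer during alignment
  seq[105] <- "C"; seq[108] <- "A"
  sa <- catalog$alleles["S-A", ]
  for (k in seq_along(catalog$positions)) {
    p <- catalog$positions[k]
    a <- strsplit(sa[[k]], "")[[1]]
    seq[p:(p + length(a) - 1)] <- a
  }
  paste(seq, collapse = "")
}

#' Construct the full amplicon sequence of a catalog haplotype
#'
#' Builds the haplotype sequence over the synthetic reference backbone:
#' substitution alleles are written at their positions and deletion alleles
#' (`"-"`) remove the corresponding bases, so S-B is 3 bp shorter than the
#' 476-bp frame.
#'
#' @param haplotype One of the catalog haplotype names.
#' @param catalog A [dsi_catalog()].
#' @return A character scalar DNA sequence.
#' @export
amplicon_sequence <- function(haplotype, catalog = dsi_catalog()) {
  stopifnot(haplotype %in% rownames(catalog$alleles))
  seq <- strsplit(amplicon_reference(catalog), "")[[1]]
  al <- catalog$alleles[haplotype, ]
  del <- integer(0)
  for (k in seq_along(catalog$positions)) {
    p <- catalog$positions[k]
    a <- al[[k]]
    ref_len <- if (p %in% catalog$indel_positions && p == 106L) 2L else 1L
    if (a == "-") {
      del <- c(del, p:(p + ref_len - 1))
    } else {
      seq[p:(p + nchar(a) - 1)] <- strsplit(a, "")[[1]]
    }
  }
  if (length(del)) seq <- seq[-del]
  paste(seq, collapse = "")
}

IUPAC_PAIRS <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C")
)

# Map reference positions to query characters via a global alignment.
aligned_query_chars <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global", gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- rep(NA_character_, nchar(ref))
  rp <- 0L
  for (i in seq_along(sa)) {
    if (sa[i] != "-") {
      rp <- rp + 1L
      out[rp] <- pa[i]
    }
  }
  out
}

#' Read a diploid amplicon genotype from one or two sequences
#'
#' Anchors the coordinate frame at the first base of the forward primer
#' (position 1), aligns each sequence against the S-A reference frame and
#' reads the alleles at the 14 catalog positions. A single sequence is
#' treated as an unphased consensus: IUPAC ambiguity codes expand to the two
#' alleles of a heterozygous site. Two sequences (cloned haplotype reads)
#' each contribute one allele. Indel alleles are detected as alignment gaps
#' at the indel positions.
#'
#' @param sequences Character vector of one or two DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param catalog A [dsi_catalog()].
#' @return Object of class `amplicon_genotype`: named list keyed by variant
#'   position, each a length-2 character vector of alleles (`NA` where
#'   unread).
#' @export
extract_amplicon_genotype <- function(sequences, catalog = dsi_catalog()) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- toupper(sequences)
  stopifnot(length(sequences) %in% c(1L, 2L))
  ref <- amplicon_reference(catalog)
  read_one <- function(s) {
    hit <- regexpr(catalog$forward_primer, s, fixed = TRUE)
    if (hit < 0) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      hit <- regexpr(catalog$forward_primer, rc, fixed = TRUE)
      if (hit < 0) stop("frame not found: forward primer absent from sequence")
      s <- rc
    }
    s <- substring(s, hit)
    if (abs(nchar(s) - catalog$amplicon_length) > 10) {
      warning("sequence length inconsistent with the amplicon frame")
    }
    chars <- aligned_query_chars(s, ref)
    al <- stats::setNames(vector("list", length(catalog$positions)),
                          catalog$positions)
    for (k in seq_along(catalog$positions)) {
      p <- catalog$positions[k]
      if (p == 106L) {
        two <- chars[c(106L, 107L)]
        al[[k]] <- if (anyNA(two)) NA_character_
          else if (any(two == "-")) "-"   # deletion, wherever the gap lands
          else paste(two, collapse = "")
      } else {
        ch <- chars[p]
        al[[k]] <- if (is.na(ch)) NA_character_
          else if (ch == "-" && p %in% catalog$indel_positions) "-"
          else ch
      }
    }
    al
  }
  reads <- lapply(sequences, read_one)
  geno <- stats::setNames(vector("list", length(catalog$positions)),
                          catalog$positions)
  for (k in seq_along(catalog$positions)) {
    if (length(reads) == 2) {
      pick <- function(a) if (is.na(a)) NA_character_
        else if (a %in% names(IUPAC_PAIRS)) IUPAC_PAIRS[[a]][1] else a
      geno[[k]] <- c(pick(reads[[1]][[k]]), pick(reads[[2]][[k]]))
    } else {
      a <- reads[[1]][[k]]
      geno[[k]] <- if (is.na(a)) c(NA_character_, NA_character_)
        else if (a %in% names(IUPAC_PAIRS)) IUPAC_PAIRS[[a]]
        else c(a, a)
    }
  }
  structure(geno, class = "amplicon_genotype")
}

#' Build a diploid genotype from the two diagnostic positions
#'
#' @param g63,g283 Two-character genotype strings at positions 63 and 283
#'   (e.g. `"TG"`, `"TC"`); `NA` or `"--"` leaves the position missing.
#' @return An `amplicon_genotype` restricted to positions 63 and 283.
#' @export
diagnostic_genotype <- function(g63, g283) {
  split2 <- function(g) {
    if (is.na(g) || g == "--") return(c(NA_character_, NA_character_))
    stopifnot(nchar(g) == 2)
    strsplit(g, "")[[1]]
  }
  structure(list(`63` = split2(g63), `283` = split2(g283)),
            class = "amplicon_genotype")
}

#' Enumerate catalog haplotype pairs consistent with a genotype
#'
#' All 15 unordered pairs (with repetition) of the five catalog haplotypes
#' are checked against the genotype: a pair is consistent when, at every
#' position where the genotype is informative, the pair's allele multiset
#' matches the observed alleles (a position with a single known allele only
#' requires that allele to be present).
#'
#' @param genotype An `amplicon_genotype`.
#' @param catalog A [dsi_catalog()].
#' @return data.frame with columns `hap1`, `hap2` (hap1 <= hap2), one row
#'   per consistent pair; zero rows means no catalog pair fits.
#' @export
resolve_haplotypes <- function(genotype, catalog = dsi_catalog()) {
  haps <- rownames(catalog$alleles)
  pos <- names(genotype)
  pairs <- list()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    ok <- TRUE
    for (p in pos) {
      g <- genotype[[p]]
      if (all(is.na(g))) next
      k <- match(p, colnames(catalog$alleles))
      if (is.na(k)) next
      hp <- c(catalog$alleles[haps[i], k], catalog$alleles[haps[j], k])
      if (any(is.na(g))) {
        if (!(g[!is.na(g)][1] %in% hp)) { ok <- FALSE; break }
      } else if (!identical(sort(g), sort(hp))) { ok <- FALSE; break }
    }
    if (ok) pairs[[length(pairs) + 1]] <- c(haps[i], haps[j])
  }
  if (!length(pairs)) {
    return(data.frame(hap1 = character(0), hap2 = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  data.frame(hap1 = out[, 1], hap2 = out[, 2], stringsAsFactors = FALSE)
}

#' Classify a diploid amplicon genotype into an incompatibility group
#'
#' The incompatibility group is G1 when every catalog-consistent haplotype
#' pair contains at least one dominant haplotype, G2 when none does,
#' `"ambiguous"` when consistent pairs disagree and `"inconsistent"` (with
#' the novel-haplotype flag) when no catalog pair fits. A G1 genotype whose
#' consistent pairs are all dominant/dominant is annotated
#' `homozygous_or_null`, since a single amplified dominant haplotype cannot
#' be told apart from a dominant/null combination.
#'
#' @param genotype An `amplicon_genotype` (at minimum the two diagnostic
#'   positions), or missing if `g63`/`g283` are given.
#' @param catalog A [dsi_catalog()].
#' @param g63,g283 Optional diagnostic genotype strings (see
#'   [diagnostic_genotype()]).
#' @return Object of class `dsi_classification`: list with `group`
#'   (`"G1"`, `"G2"`, `"ambiguous"`, `"inconsistent"`), `pairs` (consistent
#'   pair data.frame), `novel_haplotype`, `homozygous_or_null`.
#' @export
classify_dsi <- function(genotype = NULL, catalog = dsi_catalog(),
                         g63 = NULL, g283 = NULL) {
  if (is.null(genotype)) genotype <- diagnostic_genotype(g63, g283)
  pairs <- resolve_haplotypes(genotype, catalog)
  if (nrow(pairs) == 0) {
    return(structure(list(group = "inconsistent", pairs = pairs,
                          novel_haplotype = TRUE,
                          homozygous_or_null = FALSE),
                     class = "dsi_classification"))
  }
  has_dom <- pairs$hap1 %in% catalog$dominant | pairs$hap2 %in% catalog$dominant
  both_dom <- pairs$hap1 %in% catalog$dominant & pairs$hap2 %in% catalog$dominant
  group <- if (all(has_dom)) "G1" else if (!any(has_dom)) "G2" else "ambiguous"
  structure(list(group = group, pairs = pairs, novel_haplotype = FALSE,
                 homozygous_or_null = group == "G1" && all(both_dom)),
            class = "dsi_classification")
}

#' @export
print.dsi_classification <- function(x, ...) {
  cat(sprintf("<dsi_classification> group: %s%s%s\n", x$group,
              if (x$homozygous_or_null) " (homozygous or null second allele)" else "",
              if (x$novel_haplotype) " [novel haplotype]" else ""))
  if (nrow(x$pairs)) {
    cat("  consistent pairs:",
        paste(x$pairs$hap1, x$pairs$hap2, sep = "/", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Check haplotype inheritance in a cross
#'
#' Given the catalog haplotype pairs of the two parents, verifies that each
#' offspring genotype is consistent with inheriting one haplotype from each
#' parent, partitions offspring into the expected combinations, and reports
#' the implied incompatibility group per offspring.
#'
#' @param parent1,parent2 Character vectors of two catalog haplotype names
#'   (e.g. `c("S-A", "s-a")` and `c("s-b", "s-c")`).
#' @param offspring A list of `amplicon_genotype` objects (optionally
#'   named).
#' @param catalog A [dsi_catalog()].
#' @return data.frame: `id`, `valid`, `combination` (e.g. `"S-A/s-b"`, `NA`
#'   when ambiguous among valid combinations), `group`, `flagged` (TRUE when
#'   no parental combination fits).
#' @export
verify_cross_haplotypes <- function(parent1, parent2, offspring,
                                    catalog = dsi_catalog()) {
  stopifnot(length(parent1) == 2, length(parent2) == 2,
            all(c(parent1, parent2) %in% rownames(catalog$alleles)))
  ids <- names(offspring)
  if (is.null(ids)) ids <- sprintf("off%03d", seq_along(offspring))
  rows <- lapply(seq_along(offspring), function(k) {
    pairs <- resolve_haplotypes(offspring[[k]], catalog)
    valid <- pairs[(pairs$hap1 %in% parent1 & pairs$hap2 %in% parent2) |
                   (pairs$hap1 %in% parent2 & pairs$hap2 %in% parent1), ,
                   drop = FALSE]
    combo <- if (nrow(valid) == 1) paste(valid$hap1, valid$hap2, sep = "/")
      else NA_character_
    grp <- if (nrow(valid) == 0) NA_character_ else {
      dom <- valid$hap1 %in% catalog$dominant | valid$hap2 %in% catalog$dominant
      if (all(dom)) "G1" else if (!any(dom)) "G2" else "ambiguous"
    }
    data.frame(id = ids[k], valid = nrow(valid) > 0, combination = combo,
               group = grp, flagged = nrow(valid) == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
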