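#' Genotype-calling thresholds
#'
#' Thresholds for converting read counts to genotype calls: a minimum total
#' coverage, a symmetric allele-ratio window inside which a site is called
#' heterozygous, and the minimum number of progeny with non-missing calls a
#' locus needs in order to be retained.
#'
#' @param min_coverage Minimum total reads for a call (default 8; a site with
#'   exactly 8 reads is callable).
#' @param het_ratio_low,het_ratio_high Reference-allele fraction window for a
#'   heterozygous call (defaults 0.15 and 0.85; boundary values inclusive).
#' @param min_called_progeny A locus is retained only if called in strictly
#'   more than this many progeny (default 150).
#' @return An object of class `calling_thresholds`.
#' @export
calling_thresholds <- function(min_coverage = 8L,
                               het_ratio_low = 0.15,
                               het_ratio_high = 0.85,
                               min_called_progeny = 150L) {
  stopifnot(min_coverage >= 1,
            het_ratio_low > 0, het_ratio_high < 1,
            het_ratio_low < het_ratio_high)
  structure(list(min_coverage = as.integer(min_coverage),
                 het_ratio_low = het_ratio_low,
                 het_ratio_high = het_ratio_high,
                 min_called_progeny = as.integer(min_called_progeny)),
            class = "calling_thresholds")
}

#' Call a genotype from reference and alternate read counts
#'
#' Vectorised. Total coverage below `min_coverage` gives a missing call;
#' otherwise the reference fraction `f = ref/(ref+alt)` is compared with the
#' heterozygous window: `f` within `[het_ratio_low, het_ratio_high]`
#' (inclusive) is heterozygous, above is homozygous reference, below is
#' homozygous alternate.
#'
#' @param ref,alt Non-negative read counts (recycled to a common length).
#' @param thresholds A [calling_thresholds()] object.
#' @return Character vector of calls coded `"A"` (hom ref), `"H"` (het),
#'   `"B"` (hom alt), `"-"` (missing).
#' @export
call_genotype <- function(ref, alt, thresholds = calling_thresholds()) {
  stopifnot(all(ref >= 0, na.rm = TRUE), all(alt >= 0, na.rm = TRUE))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  tot <- ref + alt
  f <- ifelse(tot > 0, ref / tot, NA_real_)
  out <- rep("-", n)
  ok <- !is.na(tot) & tot >= thresholds$min_coverage
  out[ok & f >= thresholds$het_ratio_low & f <= thresholds$het_ratio_high] <- "H"
  out[ok & f > thresholds$het_ratio_high] <- "A"
  out[ok & f < thresholds$het_ratio_low] <- "B"
  out
}

#' Call a genotype matrix from read-count matrices
#'
#' @param counts A `read_counts` object (matrices `ref` and `alt`).
#' @param thresholds A [calling_thresholds()] object.
#' @return Character matrix of calls with the input dimnames.
#' @export
call_matrix <- function(counts, thresholds = calling_thresholds()) {
  out <- matrix(call_genotype(as.vector(counts$ref), as.vector(counts$alt),
                              thresholds),
                nrow(counts$ref), ncol(counts$ref),
                dimnames = dimnames(counts$ref))
  out
}

#' Locus retention by progeny call count
#'
#' A locus is retained only if its number of non-missing progeny calls
#' strictly exceeds `min_called_progeny`.
#'
#' @param calls Character vector of progeny calls (`"A"/"H"/"B"/"-"`).
#' @param thresholds A [calling_thresholds()] object.
#' @return Logical scalar.
#' @export
retain_locus <- function(calls, thresholds = calling_thresholds()) {
  sum(calls != "-") > thresholds$min_called_progeny
}

#' Classify marker segregation from the two parental calls
#'
#' Pseudo-testcross classification: heterozygous mother x homozygous father
#' is a maternal testcross (segregates 1:1 through the female), the converse
#' a paternal testcross, het x het is fully informative, hom x hom is
#' uninformative. Vectorised.
#'
#' @param mother_call,father_call Parental calls (`"A"/"H"/"B"`); a missing
#'   parental call is an error (such markers must be excluded upstream).
#' @return Character vector of classes: `"maternal_testcross"`,
#'   `"paternal_testcross"`, `"fully_informative"`, `"uninformative"`.
#' @export
classify_segregation <- function(mother_call, father_call) {
  n <- max(length(mother_call), length(father_call))
  mother_call <- rep_len(mother_call, n)
  father_call <- rep_len(father_call, n)
  if (any(mother_call == "-" | father_call == "-")) {
    stop("missing parental call: marker(s) must be excluded before classification")
  }
  m_het <- mother_call == "H"
  f_het <- father_call == "H"
  out <- rep("uninformative", n)
  out[m_het & !f_het] <- "maternal_testcross"
  out[!m_het & f_het] <- "paternal_testcross"
  out[m_het & f_het] <- "fully_informative"
  out
}

#' Assemble a genotype matrix object from calls
#'
#' Combines progeny calls with parental calls, classifies segregation,
#' excludes markers with a missing parental call (logged), and applies the
#' retention filter.
#'
#' @param calls Character matrix of progeny calls, markers x individuals.
#' @param mother_call,father_call Parental call vectors aligned to rows.
#' @param thresholds A [calling_thresholds()] object.
#' @param locus Optional vector of locus ids (for ABxCD SNP-row pairs);
#'   defaults to the marker id.
#' @return Object of class `genotype_matrix`: list with `calls` (retained
#'   informative markers only), `markers` data.frame (`marker`, `locus`,
#'   `mother`, `father`, `class`), and `excluded` data.frame with reasons.
#' @export
genotype_matrix <- function(calls, mother_call, father_call,
                            thresholds = calling_thresholds(),
                            locus = rownames(calls)) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)))
  ids <- rownames(calls)
  stopifnot(length(mother_call) == length(ids),
            length(father_call) == length(ids))
  excluded <- data.frame(marker = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop_parent <- mother_call == "-" | father_call == "-"
  if (any(drop_parent)) {
    excluded <- rbind(excluded, data.frame(marker = ids[drop_parent],
                                           reason = "missing parental call"))
  }
  keep <- !drop_parent
  cls <- rep(NA_character_, length(ids))
  cls[keep] <- classify_segregation(mother_call[keep], father_call[keep])
  drop_uninf <- keep & cls == "uninformative"
  if (any(drop_uninf)) {
    excluded <- rbind(excluded, data.frame(marker = ids[drop_uninf],
                                           reason = "uninformative"))
  }
  keep <- keep & !drop_uninf
  n_called <- rowSums(calls != "-")
  drop_thin <- keep & !(n_called > thresholds$min_called_progeny)
  if (any(drop_thin)) {
    excluded <- rbind(excluded, data.frame(marker = ids[drop_thin],
                                           reason = "called in too few progeny"))
  }
  keep <- keep & !drop_thin
  structure(list(
    calls = calls[keep, , drop = FALSE],
    markers = data.frame(marker = ids[keep],
                         locus = locus[keep],
                         mother = mother_call[keep],
                         father = father_call[keep],
                         class = cls[keep],
                         stringsAsFactors = FALSE),
    excluded = excluded,
    thresholds = thresholds
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>\n")
  cat(sprintf("  %d retained markers x %d individuals (%d excluded)\n",
              nrow(x$calls), ncol(x$calls), nrow(x$excluded)))
  print(table(x$markers$class))
  invisible(x)
}

#' Mendelian-exclusion parentage check
#'
#' Validates each offspring against the declared parent pair using unlinked
#' multi-allelic markers. At each marker the offspring genotype must admit an
#' assignment of one allele to the mother and the other to the father; a
#' marker where no such assignment exists (the paternal-side allele is absent
#' from the declared father) counts as a mismatch. Offspring with more than
#' `max_mismatches` mismatching markers are excluded. This is an exclusion
#' count, not a likelihood-based assignment.
#'
#' @param offspring 3-d integer array markers x individuals x 2 of allele
#'   codes (as produced by [simulate_cross()]), or a character matrix of
#'   `"a/b"` genotype strings.
#' @param mother,father Integer matrices markers x 2 of parental alleles.
#' @param max_mismatches Maximum tolerated mismatching markers (default 1,
#'   absorbing a single genotyping error).
#' @param max_missing_frac Offspring with more than this fraction of missing
#'   parentage markers are flagged `"unresolvable"` (default 0.5).
#' @return data.frame with `id`, `mismatches`, `n_markers_used`, `status`
#'   in `{"validated", "excluded", "unresolvable"}`.
#' @export
check_parentage <- function(offspring, mother, father, max_mismatches = 1L,
                            max_missing_frac = 0.5) {
  if (is.matrix(offspring) && is.character(offspring)) {
    sp <- strsplit(offspring, "/", fixed = TRUE)
    a1 <- matrix(suppressWarnings(as.integer(vapply(sp, `[`, "", 1))),
                 nrow(offspring), ncol(offspring), dimnames = dimnames(offspring))
    a2 <- matrix(suppressWarnings(as.integer(vapply(sp, `[`, "", 2))),
                 nrow(offspring), ncol(offspring), dimnames = dimnames(offspring))
    offspring <- array(c(a1, a2), dim = c(nrow(a1), ncol(a1), 2),
                       dimnames = c(dimnames(a1), list(NULL)))
  }
  npm <- dim(offspring)[1]
  ni <- dim(offspring)[2]
  ids <- dimnames(offspring)[[2]]
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(ni))
  res <- data.frame(id = ids, mismatches = NA_integer_,
                    n_markers_used = NA_integer_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_len(ni)) {
    x <- offspring[, j, 1]; y <- offspring[, j, 2]
    usable <- !is.na(x) & !is.na(y)
    n_used <- sum(usable)
    mism <- 0L
    for (i in which(usable)) {
      ok <- (x[i] %in% mother[i, ] && y[i] %in% father[i, ]) ||
            (y[i] %in% mother[i, ] && x[i] %in% father[i, ])
      if (!ok) mism <- mism + 1L
    }
    res$mismatches[j] <- mism
    res$n_markers_used[j] <- n_used
    res$status[j] <- if (n_used < ceiling((1 - max_missing_frac) * npm)) {
      "unresolvable"
    } else if (mism > max_mismatches) "excluded" else "validated"
  }
  res
}
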