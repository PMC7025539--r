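#' Chi-square test of 1:1 phenotype segregation
#'
#' `chisq = (nG1 - nG2)^2 / (nG1 + nG2)` on 1 df. Individuals with phenotype
#' other than `"G1"`/`"G2"` (discarded, unknown) are excluded first.
#'
#' @param phenotypes Character vector of `"G1"`/`"G2"` (other values
#'   ignored), or a length-2 numeric vector of counts `c(nG1, nG2)`.
#' @param alpha Significance level (default 0.05).
#' @return List: `n_g1`, `n_g2`, `chisq`, `p`, `consistent_1to1`.
#' @export
segregation_test <- function(phenotypes, alpha = 0.05) {
  if (is.numeric(phenotypes) && length(phenotypes) == 2) {
    a <- phenotypes[1]; b <- phenotypes[2]
  } else {
    a <- sum(phenotypes == "G1"); b <- sum(phenotypes == "G2")
  }
  if (a + b == 0) stop("no phenotyped individuals")
  chisq <- (a - b)^2 / (a + b)
  p <- stats::pchisq(chisq, 1, lower.tail = FALSE)
  list(n_g1 = a, n_g2 = b, chisq = chisq, p = p,
       consistent_1to1 = p >= alpha)
}

# Recombinant count of a binary trait vector against one bin pattern,
# phased to minimise recombinants; individuals missing either value skip.
trait_bin_recombinants <- function(trait, pattern) {
  ok <- !is.na(trait) & !is.na(pattern)
  n <- sum(ok)
  mism <- sum(trait[ok] != pattern[ok])
  flip <- mism > n - mism
  R <- min(mism, n - mism)
  ids <- names(pattern)[ok]
  rec <- if (flip) ids[trait[ok] == pattern[ok]] else ids[trait[ok] != pattern[ok]]
  list(R = R, n = n, flip = flip, recombinants = rec)
}

#' Map a binary trait by co-segregation on one parental map
#'
#' The trait is encoded as a testcross pseudo-marker (G1 = carrying the
#' dominant allele transmitted by the mapped parent) and recombinants are
#' counted against every genetic bin over the phenotyped, genotyped
#' individuals, phase resolved per linkage group. Bins with zero
#' recombinants form the co-segregating set; the nearest bins on each side
#' with at least one recombinant are the flanking borders and the interval
#' span is the cM distance between them. When no bin co-segregates
#' perfectly (possible with a finite marker grid and a phenotyped subset),
#' the trait is placed at the minimum-recombinant bin(s) and the borders
#' are the nearest bins carrying strictly more recombinants than that
#' minimum; the co-segregating set is then empty and `min_recombinants`
#' records the residual count.
#'
#' @param phenotypes Named character vector (`"G1"`/`"G2"`, others dropped)
#'   or a data.frame with columns `id` and `group`.
#' @param map A `genetic_map` (normally the map of the parent heterozygous
#'   for the trait).
#' @param min_linked_rate A trait whose best bin shows a recombinant rate at
#'   or above this value is declared unlinked (default 0.20).
#' @return Object of class `trait_interval_report`: list with `linked`,
#'   `lg`, `position_cM`, `cosegregating` (bin table rows with zero
#'   recombinants and their marker ids), `upper_flank` / `lower_flank`
#'   (bin id, position, recombinant count and individual ids; `NULL` when
#'   open-ended), `span_cM`, `test` (per-bin recombinant counts on the
#'   trait LG), `n_phenotyped`.
#' @export
map_trait <- function(phenotypes, map, min_linked_rate = 0.20) {
  if (is.data.frame(phenotypes)) {
    phenotypes <- stats::setNames(phenotypes$group, phenotypes$id)
  }
  phenotypes <- phenotypes[phenotypes %in% c("G1", "G2")]
  if (length(phenotypes) < 2) stop("need at least two phenotyped individuals")
  best <- NULL
  for (nm in names(map$lgs)) {
    pat <- map$lgs[[nm]]$patterns
    inds <- colnames(pat)
    trait <- rep(NA_integer_, length(inds))
    names(trait) <- inds
    common <- intersect(inds, names(phenotypes))
    trait[common] <- ifelse(phenotypes[common] == "G1", 1L, 0L)
    res <- lapply(seq_len(nrow(pat)), function(k)
      trait_bin_recombinants(trait, pat[k, ]))
    rates <- vapply(res, function(z) if (z$n > 0) z$R / z$n else NA_real_, 0)
    k_best <- which.min(rates)
    if (length(k_best) && (is.null(best) || rates[k_best] < best$rate)) {
      best <- list(lg = nm, rate = rates[k_best], res = res, rates = rates)
    }
  }
  if (is.null(best) || is.na(best$rate) || best$rate >= min_linked_rate) {
    return(structure(list(linked = FALSE, lg = NA_character_,
                          position_cM = NA_real_, cosegregating = NULL,
                          upper_flank = NULL, lower_flank = NULL,
                          span_cM = NA_real_, test = NULL,
                          n_phenotyped = length(phenotypes)),
                     class = "trait_interval_report"))
  }
  lg <- best$lg
  tab <- map$lgs[[lg]]$table
  Rs <- vapply(best$res, `[[`, 0, "R")
  ns <- vapply(best$res, `[[`, 0L, "n")
  test <- cbind(tab[, c("bin", "representative", "n_markers", "pos_cM")],
                recombinants = Rs, n_informative = ns)
  # trait bins: the minimum-recombinant bins (zero in the ideal Mendelian
  # case; with a finite marker grid and a phenotyped subset the minimum can
  # be positive, in which case the same bracketing logic applies with the
  # flanks required to carry strictly more recombinants than the minimum)
  min_r <- min(Rs[ns > 0])
  trait_idx <- which(Rs == min_r & ns > 0)
  cose_idx <- which(Rs == 0 & ns > 0)
  pos <- mean(tab$pos_cM[trait_idx])
  flank <- function(side) {
    idx <- if (side == "upper") rev(seq_len(min(trait_idx) - 1)) else
      seq(max(trait_idx) + 1, nrow(tab))
    for (k in idx) {
      if (ns[k] > 0 && Rs[k] > min_r) {
        return(list(bin = tab$bin[k], representative = tab$representative[k],
                    pos_cM = tab$pos_cM[k], n_recombinants = Rs[k],
                    recombinant_ids = best$res[[k]]$recombinants))
      }
    }
    NULL
  }
  upper <- if (min(trait_idx) > 1) flank("upper") else NULL
  lower <- if (max(trait_idx) < nrow(tab)) flank("lower") else NULL
  span <- if (!is.null(upper) && !is.null(lower)) {
    abs(lower$pos_cM - upper$pos_cM)
  } else NA_real_
  structure(list(
    linked = TRUE, lg = lg, position_cM = pos,
    cosegregating = test[cose_idx, , drop = FALSE],
    min_recombinants = min_r,
    upper_flank = upper, lower_flank = lower, span_cM = span,
    test = test, n_phenotyped = length(phenotypes)
  ), class = "trait_interval_report")
}

#' @export
print.trait_interval_report <- function(x, ...) {
  cat("<trait_interval_report>\n")
  if (!x$linked) {
    cat("  trait unlinked to the supplied map\n")
    return(invisible(x))
  }
  cat(sprintf("  trait on %s at %.2f cM; %d co-segregating bin(s); %d phenotyped\n",
              x$lg, x$position_cM,
              if (is.null(x$cosegregating)) 0L else nrow(x$cosegregating),
              x$n_phenotyped))
  if (!is.na(x$span_cM)) {
    cat(sprintf("  interval %.2f cM between %s (%d rec.) and %s (%d rec.)\n",
                x$span_cM, x$upper_flank$representative,
                x$upper_flank$n_recombinants, x$lower_flank$representative,
                x$lower_flank$n_recombinants))
  } else {
    cat("  interval open-ended on at least one side\n")
  }
  invisible(x)
}

#' Border evidence table for a mapped trait interval
#'
#' Tabulates the recombinant individuals supporting each border of the
#' trait interval, mirroring a recombinant-chromosome diagram as text.
#'
#' @param report A [map_trait()] result with `linked = TRUE`.
#' @return data.frame: `flank` (`"upper"`/`"lower"`), `bin`,
#'   `representative`, `pos_cM`, `n_recombinants`, `individuals`
#'   (semicolon-joined ids). Open-ended flanks yield a row with
#'   `n_recombinants = NA`.
#' @export
flank_support <- function(report) {
  stopifnot(inherits(report, "trait_interval_report"))
  if (!report$linked) stop("trait is unlinked; no flanks to report")
  one <- function(side, fl) {
    if (is.null(fl)) {
      data.frame(flank = side, bin = NA_integer_,
                 representative = NA_character_, pos_cM = NA_real_,
                 n_recombinants = NA_integer_, individuals = "open-ended",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(flank = side, bin = fl$bin,
                 representative = fl$representative, pos_cM = fl$pos_cM,
                 n_recombinants = fl$n_recombinants,
                 individuals = paste(sort(fl$recombinant_ids), collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  }
  rbind(one("upper", report$upper_flank), one("lower", report$lower_flank))
}
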