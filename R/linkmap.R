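#' Linkage-mapping parameters
#'
#' @param lod_min Minimum LOD for two markers to be linked during grouping
#'   (default 10; the comparison is strict, `lod > lod_min`).
#' @param rf_max Maximum recombination fraction for linkage (default 0.20,
#'   applied after phase resolution).
#' @param distortion_alpha Significance level of the segregation-distortion
#'   chi-square test (default 0.05).
#' @param smooth_neighbors Flanking informative calls used per side by the
#'   error-removal pass (default 5).
#' @param smooth_threshold Minimum posterior agreement for an observed call
#'   to be kept (default 0.70, tightened by 0.05 per iteration).
#' @param smooth_max_iter Maximum error-removal iterations (default 5).
#' @param min_pairs Minimum pairwise-complete observations for a two-point
#'   estimate to be considered reliable (default 10).
#' @param bonferroni Apply a Bonferroni correction in the distortion scan
#'   (default FALSE, matching the plain per-marker test).
#' @return Object of class `mapping_params`.
#' @export
mapping_params <- function(lod_min = 10, rf_max = 0.20,
                           distortion_alpha = 0.05,
                           smooth_neighbors = 5L,
                           smooth_threshold = 0.70,
                           smooth_max_iter = 5L,
                           min_pairs = 10L,
                           bonferroni = FALSE) {
  stopifnot(rf_max > 0, rf_max <= 0.5,
            distortion_alpha > 0, distortion_alpha < 1,
            smooth_neighbors >= 1, smooth_threshold > 0, smooth_threshold <= 1)
  structure(list(lod_min = lod_min, rf_max = rf_max,
                 distortion_alpha = distortion_alpha,
                 smooth_neighbors = as.integer(smooth_neighbors),
                 smooth_threshold = smooth_threshold,
                 smooth_max_iter = as.integer(smooth_max_iter),
                 min_pairs = as.integer(min_pairs),
                 bonferroni = bonferroni),
            class = "mapping_params")
}

#' Kosambi map function
#'
#' Converts a recombination fraction to a map distance in centiMorgans under
#' the Kosambi function, `d = 25 ln[(1 + 2r)/(1 - 2r)]` cM. Strictly
#' increasing with `d(0) = 0` and the small-r limit `d ~ 100 r`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' @param d Map distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' Extract per-parent testcross transmission patterns
#'
#' Recodes offspring calls of markers informative for one parent into the
#' transmitted-allele indicator of that parent (0 = reference haplotype
#' allele, 1 = alternate). For maternal-testcross markers the homozygous
#' father fixes the paternal contribution, so the offspring call identifies
#' the maternal allele (and symmetrically for the father). Fully informative
#' het x het single-SNP markers contribute with heterozygous offspring set to
#' `NA` (phase-ambiguous). Calls impossible under the parental genotypes are
#' set to `NA`.
#'
#' @param gm A [genotype_matrix()] object.
#' @param parent `"mother"` or `"father"`.
#' @return List: `patterns` (integer matrix markers x individuals of 0/1/NA)
#'   and `markers` (the corresponding rows of `gm$markers`).
#' @export
testcross_patterns <- function(gm, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  if (parent == "mother") {
    keep <- gm$markers$class %in% c("maternal_testcross", "fully_informative")
    other <- gm$markers$father
  } else {
    keep <- gm$markers$class %in% c("paternal_testcross", "fully_informative")
    other <- gm$markers$mother
  }
  mk <- gm$markers[keep, , drop = FALSE]
  calls <- gm$calls[keep, , drop = FALSE]
  other <- other[keep]
  P <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  homA <- other == "A"
  homB <- other == "B"
  het <- other == "H"
  P[homA & calls == "A"] <- 0L
  P[homA & calls == "H"] <- 1L
  P[homB & calls == "H"] <- 0L
  P[homB & calls == "B"] <- 1L
  P[het & calls == "A"] <- 0L
  P[het & calls == "B"] <- 1L
  list(patterns = P, markers = mk)
}

# Raw pairwise mismatch/overlap counts between 0/1/NA pattern rows.
pattern_counts <- function(P, Q = P) {
  M1 <- (!is.na(P)) * 1
  A1 <- (P == 1L & !is.na(P)) * 1
  A0 <- (P == 0L & !is.na(P)) * 1
  M2 <- (!is.na(Q)) * 1
  B1 <- (Q == 1L & !is.na(Q)) * 1
  B0 <- (Q == 0L & !is.na(Q)) * 1
  mism <- A1 %*% t(B0) + A0 %*% t(B1)
  n <- M1 %*% t(M2)
  list(mism = mism, n = n)
}

rf_from_counts <- function(mism, n) {
  R <- pmin(mism, n - mism)
  r <- ifelse(n > 0, R / n, NA_real_)
  term2 <- ifelse(R > 0, R * log10(2 * r), 0)
  lod <- ifelse(n > 0, (n - R) * log10(2 * (1 - r)) + term2, NA_real_)
  list(r = r, lod = lod, R = R, n = n,
       phase = ifelse(mism > n - mism, "repulsion", "coupling"))
}

#' Two-point recombination fraction and LOD between all marker pairs
#'
#' @param P Pattern matrix (markers x individuals, 0/1/NA) from
#'   [testcross_patterns()].
#' @param params A [mapping_params()] object.
#' @return List of matrices `r`, `lod`, `R` (recombinant counts), `n`
#'   (pairwise-complete observations), `phase`, and logical `reliable`
#'   (`n >= min_pairs`).
#' @export
rf_lod_matrix <- function(P, params = mapping_params()) {
  cnt <- pattern_counts(P)
  est <- rf_from_counts(cnt$mism, cnt$n)
  est$reliable <- est$n >= params$min_pairs
  est
}

#' Two-point estimate between two markers
#'
#' Recombination fraction and LOD score from two transmission patterns,
#' using pairwise-complete observations. The phase minimising the
#' recombinant count is chosen: `r = R/n`, `LOD = (n-R) log10(2(1-r)) +
#' R log10(2r)` (with the `R = 0` convention `LOD = n log10 2`).
#'
#' @param a,b Integer vectors of 0/1/NA transmission indicators.
#' @param params A [mapping_params()] object (for `min_pairs`).
#' @return List: `r`, `lod`, `phase` (`"coupling"`/`"repulsion"`),
#'   `n_informative`, `reliable`.
#' @export
pairwise_rf_lod <- function(a, b, params = mapping_params()) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  mism <- sum(a[ok] != b[ok])
  est <- rf_from_counts(mism, n)
  list(r = unname(est$r), lod = unname(est$lod), phase = unname(est$phase),
       n_informative = n, reliable = n >= params$min_pairs)
}

#' Group markers by two-point linkage
#'
#' Single-linkage transitive closure over edges with `lod > lod_min` and
#' `r <= rf_max` (reliable estimates only). Groups are returned in
#' decreasing size order; markers linked to nothing are singletons.
#'
#' @param est Result of [rf_lod_matrix()] with dimnames, or a pattern matrix
#'   (in which case estimates are computed).
#' @param params A [mapping_params()] object.
#' @return List: `groups` (list of marker-id vectors) and `singletons`.
#' @export
group_markers <- function(est, params = mapping_params()) {
  if (is.matrix(est)) est <- rf_lod_matrix(est, params)
  ids <- rownames(est$n)
  if (is.null(ids) || length(ids) == 0) {
    return(list(groups = list(), singletons = character(0)))
  }
  adj <- est$lod > params$lod_min & est$r <= params$rf_max & est$reliable
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  sizes <- lengths(groups)
  singles <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[sizes > 1]
  ord <- order(-lengths(groups), vapply(groups, min, ""))
  list(groups = unname(groups[ord]),
       singletons = if (is.null(singles)) character(0) else sort(singles))
}

#' Collapse markers of one linkage group into genetic bins
#'
#' Markers whose non-missing calls never conflict and that show zero
#' recombinants (after phase resolution) are merged into one bin. The bin
#' representative is the member with the fewest missing calls, ties broken
#' lexicographically by marker id. Each bin carries a phased consensus
#' pattern (members aligned to the representative; cells filled by majority
#' vote with ties resolved toward the representative).
#'
#' @param P Pattern matrix restricted to one group's markers.
#' @return List of class `genetic_bins`: for each bin `members`,
#'   `representative`, `flip` (per-member phase relative to the
#'   representative) and `pattern` (the consensus).
#' @export
collapse_bins <- function(P) {
  ids <- rownames(P)
  cnt <- pattern_counts(P)
  R <- pmin(cnt$mism, cnt$n - cnt$mism)
  adj <- cnt$n > 0 & R == 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  bins <- lapply(split(seq_along(ids), comp), function(idx) {
    miss <- rowSums(is.na(P[idx, , drop = FALSE]))
    o <- order(miss, ids[idx])
    rep_i <- idx[o[1]]
    flip <- vapply(idx, function(i) {
      n <- cnt$n[i, rep_i]
      n > 0 && cnt$mism[i, rep_i] > n - cnt$mism[i, rep_i]
    }, TRUE)
    aligned <- P[idx, , drop = FALSE]
    aligned[flip, ] <- 1L - aligned[flip, , drop = FALSE]
    ones <- colSums(aligned == 1L, na.rm = TRUE)
    zeros <- colSums(aligned == 0L, na.rm = TRUE)
    consensus <- rep(NA_integer_, ncol(P))
    consensus[ones > zeros] <- 1L
    consensus[zeros > ones] <- 0L
    tie <- ones == zeros & ones > 0
    if (any(tie)) consensus[tie] <- P[rep_i, tie]
    names(consensus) <- colnames(P)
    list(members = ids[idx][order(ids[idx])],
         representative = ids[rep_i],
         flip = stats::setNames(flip, ids[idx]),
         pattern = consensus)
  })
  # stable, deterministic bin order by representative id
  bins <- bins[order(vapply(bins, `[[`, "", "representative"))]
  names(bins) <- vapply(bins, `[[`, "", "representative")
  structure(bins, class = "genetic_bins")
}

bin_pattern_matrix <- function(bins) {
  do.call(rbind, lapply(bins, `[[`, "pattern"))
}

# Objective: total recombinant count between adjacent bins in `ord`.
order_objective <- function(R, ord) {
  if (length(ord) < 2) return(0)
  sum(R[cbind(ord[-length(ord)], ord[-1])])
}

# Local refinement of an order on the adjacent recombinant count: 2-opt
# segment reversals plus single-bin relocations (the latter rescue a lone
# misplaced bin, which no sequence of improving reversals can move).
refine_order <- function(ord, Rm) {
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    L <- length(ord)
    for (i in seq_len(L - 1)) {
      for (j in seq(i + 1, L)) {
        left <- if (i > 1) Rm[ord[i - 1], ord[j]] - Rm[ord[i - 1], ord[i]] else 0
        right <- if (j < L) Rm[ord[i], ord[j + 1]] - Rm[ord[j], ord[j + 1]] else 0
        if (left + right < -1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    for (i in seq_len(L)) {
      v <- ord[i]
      rest <- ord[-i]
      gain_rm <- (if (i > 1) Rm[ord[i - 1], v] else 0) +
        (if (i < L) Rm[v, ord[i + 1]] else 0) -
        (if (i > 1 && i < L) Rm[ord[i - 1], ord[i + 1]] else 0)
      cost <- numeric(L)
      cost[1] <- Rm[v, rest[1]]
      cost[L] <- Rm[rest[L - 1], v]
      if (L > 2) {
        ins <- seq_len(L - 2)
        cost[ins + 1] <- Rm[rest[ins], v] + Rm[v, rest[ins + 1]] -
          Rm[cbind(rest[ins], rest[ins + 1])]
      }
      kbest <- which.min(cost)
      if (cost[kbest] < gain_rm - 1e-12) {
        ord <- append(rest, v, after = kbest - 1)
        improved <- TRUE
      }
    }
  }
  ord
}

#' Order genetic bins within a linkage group
#'
#' Minimum-spanning-tree seeded linearisation: a complete graph on bins
#' weighted by the pairwise recombination fraction is reduced to its MST,
#' the tree's weighted longest path gives the backbone order, off-path bins
#' are inserted at the adjacent position minimising the added recombinant
#' count, and the order is refined by 2-opt moves until the total adjacent
#' recombinant count stops decreasing. The orientation is canonicalised so
#' the first bin's representative id is lexicographically smaller than the
#' last's.
#'
#' @param bins A [collapse_bins()] result.
#' @param params A [mapping_params()] object.
#' @return The input bins, reordered; attribute `objective` holds the final
#'   adjacent recombinant count.
#' @export
order_markers <- function(bins, params = mapping_params()) {
  B <- length(bins)
  if (B <= 1) return(bins)
  BP <- bin_pattern_matrix(bins)
  cnt <- pattern_counts(BP)
  Rm <- pmin(cnt$mism, cnt$n - cnt$mism)
  r <- ifelse(cnt$n > 0, Rm / cnt$n, NA_real_)
  if (any(is.na(r[upper.tri(r)]))) {
    bad <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
    g0 <- igraph::graph_from_adjacency_matrix(!is.na(r), mode = "max")
    comp <- igraph::components(g0)$membership
    if (max(comp) > 1) {
      sets <- split(names(bins), comp)
      stop("estimate graph is disconnected; unlinked bin subsets: ",
           paste(vapply(sets, paste, "", collapse = ","), collapse = " | "))
    }
    r[is.na(r)] <- 0.5  # connected overall; penalise unseen pairs
    Rm[is.na(Rm)] <- max(Rm, na.rm = TRUE) + 1
  }
  g <- igraph::graph_from_adjacency_matrix(r, mode = "upper", weighted = TRUE,
                                           diag = FALSE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  path <- as.integer(igraph::get_diameter(tree,
                                          weights = igraph::E(tree)$weight))
  ord <- path
  off <- setdiff(seq_len(B), ord)
  for (v in off[order(names(bins)[off])]) {
    L <- length(ord)
    cost <- numeric(L + 1)
    cost[1] <- Rm[v, ord[1]]
    cost[L + 1] <- Rm[ord[L], v]
    if (L > 1) {
      ins <- seq_len(L - 1)
      cost[ins + 1] <- Rm[ord[ins], v] + Rm[v, ord[ins + 1]] -
        Rm[cbind(ord[ins], ord[ins + 1])]
    }
    k <- which.min(cost)
    ord <- append(ord, v, after = k - 1)
  }
  ord <- refine_order(ord, Rm)
  # second pass: mask apparent double-crossover cells relative to the
  # current order and re-refine. Tight double crossovers (real under a
  # no-interference model) break the additivity of recombinant counts and
  # can make a locally flipped order score better; masking them restores
  # additivity for the ordering objective. Distances are still computed
  # from the unmasked patterns by map_distances().
  if (length(ord) > 3) {
    X <- BP[ord, , drop = FALSE]
    prev <- X[1, ]
    for (k in 2:nrow(X)) {
      cur <- X[k, ]
      ok <- !is.na(prev) & !is.na(cur)
      if (sum(ok) > 0 && sum(prev[ok] != cur[ok]) > sum(ok) / 2) {
        X[k, ] <- 1L - X[k, ]
      }
      prev <- X[k, ]
    }
    masked <- smooth_pass(X, 3L, 0.95)
    if (any(masked)) {
      BPm <- BP
      idx <- which(masked, arr.ind = TRUE)
      BPm[cbind(ord[idx[, 1]], idx[, 2])] <- NA_integer_
      cm <- pattern_counts(BPm)
      Rm2 <- pmin(cm$mism, cm$n - cm$mism)
      Rm2[cm$n == 0] <- max(Rm2) + 1
      ord <- refine_order(ord, Rm2)
      Rm <- Rm2
    }
  }
  if (names(bins)[ord[1]] > names(bins)[ord[length(ord)]]) ord <- rev(ord)
  out <- bins[ord]
  class(out) <- "genetic_bins"
  attr(out, "objective") <- order_objective(Rm, ord)
  out
}

#' Cumulative Kosambi positions for ordered bins
#'
#' Adjacent recombination fractions between consecutive bin consensus
#' patterns are transformed with [kosambi_cM()] and cumulated from 0.
#'
#' @param bins Ordered bins from [order_markers()].
#' @return data.frame: `bin`, `representative`, `n_markers`, `pos_cM`,
#'   `adj_r` (recombination fraction to the previous bin; `NA` for the
#'   first).
#' @export
map_distances <- function(bins) {
  B <- length(bins)
  reps <- vapply(bins, `[[`, "", "representative")
  nmk <- vapply(bins, function(b) length(b$members), 0L)
  if (B == 0) {
    return(data.frame(bin = integer(0), representative = character(0),
                      n_markers = integer(0), pos_cM = numeric(0),
                      adj_r = numeric(0)))
  }
  adj_r <- rep(NA_real_, B)
  if (B > 1) {
    BP <- bin_pattern_matrix(bins)
    for (k in 2:B) {
      est <- pairwise_rf_lod(BP[k - 1, ], BP[k, ])
      adj_r[k] <- min(est$r, 0.4999)  # guard the Kosambi domain
    }
  }
  d <- c(0, kosambi_cM(adj_r[-1]))
  data.frame(bin = seq_len(B), representative = reps, n_markers = nmk,
             pos_cM = cumsum(d), adj_r = adj_r, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Phase-align the marker-level patterns of one ordered group so each
# individual's column reads as a haplotype mosaic along the map.
align_group_patterns <- function(P, bins) {
  BP <- bin_pattern_matrix(bins)
  B <- length(bins)
  bin_flip <- logical(B)
  if (B > 1) {
    prev <- BP[1, ]
    for (k in 2:B) {
      cur <- BP[k, ]
      ok <- !is.na(prev) & !is.na(cur)
      if (sum(ok) > 0 && sum(prev[ok] != cur[ok]) > sum(ok) / 2) {
        bin_flip[k] <- TRUE
        cur <- 1L - cur
      }
      prev <- cur
    }
  }
  rows <- list(); flips <- logical(0)
  for (k in seq_len(B)) {
    b <- bins[[k]]
    for (m in b$members) {
      rows[[m]] <- P[m, ]
      flips <- c(flips, xor(b$flip[[m]], bin_flip[k]))
    }
  }
  X <- do.call(rbind, rows)
  X[flips, ] <- 1L - X[flips, , drop = FALSE]
  X
}

smooth_pass <- function(X, k, threshold) {
  nr <- nrow(X); nc <- ncol(X)
  removals <- matrix(FALSE, nr, nc, dimnames = dimnames(X))
  w <- 0.5^(0:(k - 1))
  # weighted agreement with the k preceding observed values of v
  up_agree <- function(v) {
    m <- length(v)
    E <- embed(c(rep(NA_integer_, k), v), k + 1)[, -1, drop = FALSE]
    agree <- sweep(E == v, 2, w, `*`)
    have <- sweep(!is.na(E), 2, w, `*`)
    tot <- rowSums(have)
    out <- rowSums(agree, na.rm = TRUE) / tot
    out[tot == 0] <- NA_real_
    out
  }
  for (j in seq_len(nc)) {
    x <- X[, j]
    obs <- which(!is.na(x))
    if (length(obs) < 2) next
    v <- x[obs]
    # a call is supported by whichever side agrees best: a genuine
    # crossover boundary has full support on one side, while an isolated
    # (double-recombinant-looking) error disagrees with both sides;
    # terminal datapoints (one informative side only) are never removed,
    # since a real crossover in the terminal interval is indistinguishable
    # from an error there
    pa <- up_agree(v)
    pb <- rev(up_agree(rev(v)))
    drop <- !is.na(pa) & !is.na(pb) & pmax(pa, pb) < threshold
    removals[obs[drop], j] <- TRUE
  }
  removals
}

#' Remove likely genotyping errors along an ordered linkage group
#'
#' Neighbourhood-consensus scrub in the spirit of the SMOOTH algorithm: for
#' each datapoint, agreement with up to `smooth_neighbors` flanking
#' informative calls of the same individual is computed per side, with
#' weights halving per successive neighbour, and the predicted probability
#' of the observed call being correct is the better of the two sides (a
#' genuine crossover boundary keeps full support on one side, while an
#' isolated error disagrees with both). Observations whose support falls
#' below `smooth_threshold` are set to missing (never flipped). Bins are re-built
#' and re-ordered, the threshold tightened by 0.05, and the pass repeated up
#' to `smooth_max_iter` times or until no datapoint is removed.
#'
#' @param P Pattern matrix of one linkage group (markers x individuals).
#' @param params A [mapping_params()] object.
#' @return List: `patterns` (cleaned matrix), `removals` (data.frame
#'   `marker`, `individual`, `iteration`), `n_removed`.
#' @export
smooth_correct <- function(P, params = mapping_params()) {
  removals <- data.frame(marker = character(0), individual = character(0),
                         iteration = integer(0), stringsAsFactors = FALSE)
  threshold <- params$smooth_threshold
  for (it in seq_len(params$smooth_max_iter)) {
    bins <- order_markers(collapse_bins(P), params)
    X <- align_group_patterns(P, bins)  # rows in map order
    rem <- smooth_pass(X, params$smooth_neighbors, threshold)
    if (!any(rem)) break
    idx <- which(rem, arr.ind = TRUE)
    removals <- rbind(removals, data.frame(
      marker = rownames(rem)[idx[, 1]],
      individual = colnames(rem)[idx[, 2]],
      iteration = it, stringsAsFactors = FALSE))
    P[cbind(match(rownames(rem)[idx[, 1]], rownames(P)),
            match(colnames(rem)[idx[, 2]], colnames(P)))] <- NA_integer_
    threshold <- min(1, threshold + 0.05)
  }
  list(patterns = P, removals = removals, n_removed = nrow(removals))
}

#' Build one parent's linkage map
#'
#' Full per-parent flow: transmission patterns, two-point estimates,
#' grouping, optional error scrubbing, bin collapsing, MST ordering and
#' Kosambi positions. Linkage groups are numbered by decreasing marker
#' count.
#'
#' @param gm A [genotype_matrix()] object.
#' @param parent `"mother"` or `"father"`.
#' @param params A [mapping_params()] object.
#' @param smooth Run [smooth_correct()] on each group (default TRUE).
#' @return Object of class `genetic_map`: list with `parent`, `lgs` (per LG:
#'   `table` from [map_distances()], `bins`, `patterns` bin x individual
#'   consensus matrix), `singletons`, `removals`, `params`.
#' @export
build_parent_map <- function(gm, parent = c("mother", "father"),
                             params = mapping_params(), smooth = TRUE) {
  parent <- match.arg(parent)
  tp <- testcross_patterns(gm, parent)
  est <- rf_lod_matrix(tp$patterns, params)
  grp <- group_markers(est, params)
  removals <- data.frame(marker = character(0), individual = character(0),
                         iteration = integer(0), stringsAsFactors = FALSE)
  lgs <- list()
  for (g in grp$groups) {
    P <- tp$patterns[g, , drop = FALSE]
    if (smooth) {
      sm <- smooth_correct(P, params)
      P <- sm$patterns
      removals <- rbind(removals, sm$removals)
    }
    bins <- order_markers(collapse_bins(P), params)
    tab <- map_distances(bins)
    tab$markers <- vapply(bins, function(b) paste(b$members, collapse = ";"), "")
    lgs[[length(lgs) + 1]] <- list(table = tab, bins = bins,
                                   patterns = bin_pattern_matrix(bins))
  }
  nmk <- vapply(lgs, function(l) sum(l$table$n_markers), 0L)
  lgs <- lgs[order(-nmk)]
  names(lgs) <- sprintf("LG%02d", seq_along(lgs))
  structure(list(parent = parent, lgs = lgs, singletons = grp$singletons,
                 removals = removals, params = params,
                 marker_info = tp$markers),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> parent: %s\n", x$parent))
  st <- map_stats(x)
  print(st$per_lg)
  cat(sprintf("  total: %d markers, %.1f cM, %d bins; %d singletons; %d calls scrubbed\n",
              st$markers, st$length_cM, st$bins,
              length(x$singletons), nrow(x$removals)))
  invisible(x)
}

#' Segregation-distortion scan
#'
#' Testcross markers are tested against 1:1 with the 1-df chi-square
#' `(a - b)^2 / (a + b)`; het x het single-SNP markers against 1:2:1 (2 df);
#' for ABxCD loci represented as a maternal/paternal SNP-row pair the four
#' gamete combinations are additionally tested against 1:1:1:1 (3 df).
#' Markers with `p < distortion_alpha` are flagged; no multiple-testing
#' correction is applied unless `params$bonferroni` is set.
#'
#' @param gm A [genotype_matrix()] object.
#' @param params A [mapping_params()] object.
#' @return data.frame: `marker`, `class`, `test`, `chisq`, `df`, `p`,
#'   `flagged`.
#' @export
distortion_scan <- function(gm, params = mapping_params()) {
  rows <- list()
  calls <- gm$calls
  mk <- gm$markers
  for (i in seq_len(nrow(mk))) {
    cl <- mk$class[i]
    x <- calls[i, ]
    if (cl %in% c("maternal_testcross", "paternal_testcross")) {
      het_parent_other <- if (cl == "maternal_testcross") mk$father[i] else mk$mother[i]
      lv <- if (het_parent_other == "A") c("A", "H") else c("H", "B")
      a <- sum(x == lv[1]); b <- sum(x == lv[2])
      chisq <- if (a + b > 0) (a - b)^2 / (a + b) else NA_real_
      df <- 1L; test <- "1:1"
    } else if (cl == "fully_informative") {
      o <- c(sum(x == "A"), sum(x == "H"), sum(x == "B"))
      n <- sum(o)
      e <- n * c(1, 2, 1) / 4
      chisq <- if (n > 0) sum((o - e)^2 / e) else NA_real_
      df <- 2L; test <- "1:2:1"
    } else next
    p <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, df, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      marker = mk$marker[i], class = cl, test = test,
      chisq = chisq, df = df, p = p, stringsAsFactors = FALSE)
  }
  # ABxCD loci: joint 1:1:1:1 across the co-located SNP-row pair
  dup <- split(seq_len(nrow(mk)), mk$locus)
  for (idx in dup[lengths(dup) == 2]) {
    cls <- mk$class[idx]
    if (!setequal(cls, c("maternal_testcross", "paternal_testcross"))) next
    im <- idx[cls == "maternal_testcross"]; ip <- idx[cls == "paternal_testcross"]
    m <- calls[im, ]; p_ <- calls[ip, ]
    lv_m <- if (mk$father[im] == "A") c("A", "H") else c("H", "B")
    lv_p <- if (mk$mother[ip] == "A") c("A", "H") else c("H", "B")
    ok <- m %in% lv_m & p_ %in% lv_p
    if (sum(ok) == 0) next
    o <- as.vector(table(factor(m[ok], lv_m), factor(p_[ok], lv_p)))
    n <- sum(o)
    chisq <- sum((o - n / 4)^2 / (n / 4))
    pval <- stats::pchisq(chisq, 3, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      marker = mk$locus[im], class = "abxcd_locus", test = "1:1:1:1",
      chisq = chisq, df = 3L, p = pval, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  alpha <- params$distortion_alpha
  if (params$bonferroni) alpha <- alpha / nrow(out)
  out$flagged <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Per-map summary statistics
#'
#' Per linkage group and in total: marker count, map length in cM and bin
#' count, plus the mean adjacent-bin spacing (total length / total bins,
#' reported to 2 decimals). The data.frame method summarises a packaged
#' parental-map summary table (columns `female_markers`, `female_cM`,
#' `female_bins`, `male_*`) and reports both parents plus the combined
#' marker total.
#'
#' @param x A `genetic_map` or a map-summary data.frame.
#' @param ... Unused.
#' @return For a `genetic_map`: list with `per_lg`, `markers`, `length_cM`,
#'   `bins`, `mean_bin_spacing`. For a summary table: list with `female`,
#'   `male` (same fields) and `combined_markers`.
#' @export
map_stats <- function(x, ...) UseMethod("map_stats")

#' @export
map_stats.genetic_map <- function(x, ...) {
  per <- do.call(rbind, lapply(names(x$lgs), function(nm) {
    tab <- x$lgs[[nm]]$table
    data.frame(lg = nm, markers = sum(tab$n_markers),
               length_cM = if (nrow(tab)) max(tab$pos_cM) else 0,
               bins = nrow(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(lg = character(0), markers = integer(0),
                      length_cM = numeric(0), bins = integer(0))
  }
  tot_len <- sum(per$length_cM); tot_bins <- sum(per$bins)
  list(per_lg = per, markers = sum(per$markers), length_cM = tot_len,
       bins = tot_bins,
       mean_bin_spacing = if (tot_bins > 0) round(tot_len / tot_bins, 2) else NA_real_)
}

#' @export
map_stats.data.frame <- function(x, ...) {
  one <- function(prefix) {
    mk <- sum(x[[paste0(prefix, "_markers")]])
    len <- sum(x[[paste0(prefix, "_cM")]])
    bins <- sum(x[[paste0(prefix, "_bins")]])
    list(markers = mk, length_cM = len, bins = bins,
         mean_bin_spacing = round(len / bins, 2))
  }
  f <- one("female"); m <- one("male")
  list(female = f, male = m, combined_markers = f$markers + m$markers)
}

# Position of each marker in a genetic_map: data.frame marker, lg, pos.
map_marker_positions <- function(map) {
  do.call(rbind, lapply(names(map$lgs), function(nm) {
    tab <- map$lgs[[nm]]$table
    do.call(rbind, lapply(seq_len(nrow(tab)), function(k) {
      mk <- strsplit(tab$markers[k], ";", fixed = TRUE)[[1]]
      data.frame(marker = mk, lg = nm, bin = k, pos_cM = tab$pos_cM[k],
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Compare the two parental maps through shared fully-informative anchors
#'
#' ABxCD loci place one SNP row on each parental map; such loci act as
#' anchors. Linkage groups are paired by anchor majority, anchor order is
#' compared by rank correlation, maximal runs of reversed order (>= 2
#' anchors) are reported as inversion candidates with their cM extents, and
#' anchors whose two rows fall on non-paired groups are reported as
#' translocation candidates.
#'
#' @param map_female,map_male `genetic_map` objects for the two parents.
#' @param markers A marker table carrying `marker`, `locus` and `class`
#'   columns (e.g. `gm$markers`); defaults to the tables stored in the maps.
#' @return Object of class `synteny_report`: list with `pairs` (LG pairing
#'   with anchor counts and order correlation), `anchors`, `inversions`
#'   (`lg_female`, `lg_male`, `n_anchors`, `span_female_cM`,
#'   `span_male_cM`, anchor ids), `translocations`, `unalignable`.
#' @export
compare_maps <- function(map_female, map_male, markers = NULL) {
  if (is.null(markers)) {
    markers <- rbind(map_female$marker_info, map_male$marker_info)
    markers <- markers[!duplicated(markers$marker), ]
  }
  posf <- map_marker_positions(map_female)
  posm <- map_marker_positions(map_male)
  mk <- markers[, c("marker", "locus")]
  pf <- merge(posf, mk, by = "marker")
  pm <- merge(posm, mk, by = "marker")
  anchors <- merge(pf, pm, by = "locus", suffixes = c("_f", "_m"))
  anchors <- anchors[anchors$marker_f != anchors$marker_m, ]
  anchors <- anchors[order(anchors$locus), ]
  if (nrow(anchors) == 0) {
    return(structure(list(pairs = NULL, anchors = anchors,
                          inversions = NULL, translocations = NULL,
                          unalignable = character(0)),
                     class = "synteny_report"))
  }
  tab <- table(anchors$lg_f, anchors$lg_m)
  pair_m <- colnames(tab)[apply(tab, 1, which.max)]
  pairs <- data.frame(lg_female = rownames(tab), lg_male = pair_m,
                      n_anchors = mapply(function(f, m) tab[f, m],
                                         rownames(tab), pair_m),
                      stringsAsFactors = FALSE)
  unalignable <- pairs$lg_female[pairs$n_anchors < 2]
  pairs <- pairs[pairs$n_anchors >= 2, , drop = FALSE]
  inversions <- list(); translocs <- list()
  pairs$order_cor <- NA_real_
  for (k in seq_len(nrow(pairs))) {
    lf <- pairs$lg_female[k]; lm <- pairs$lg_male[k]
    sub <- anchors[anchors$lg_f == lf, ]
    tr <- sub[sub$lg_m != lm, ]
    if (nrow(tr) > 0) translocs[[length(translocs) + 1]] <- tr
    sub <- sub[sub$lg_m == lm, ]
    sub <- sub[order(sub$pos_cM_f, sub$locus), ]
    if (nrow(sub) < 2) next
    rho <- suppressWarnings(stats::cor(sub$pos_cM_f, sub$pos_cM_m,
                                       method = "spearman"))
    pairs$order_cor[k] <- rho
    y <- sub$pos_cM_m
    if (!is.na(rho) && rho < 0) y <- -y  # orient, then look for reversals
    run_start <- 1
    for (i in seq_len(nrow(sub))) {
      end_run <- i == nrow(sub) || !(y[i + 1] < y[i])
      if (end_run) {
        if (i > run_start) {  # strictly decreasing run of >= 2 anchors
          seg <- sub[run_start:i, ]
          inversions[[length(inversions) + 1]] <- data.frame(
            lg_female = lf, lg_male = lm, n_anchors = nrow(seg),
            span_female_cM = max(seg$pos_cM_f) - min(seg$pos_cM_f),
            span_male_cM = max(seg$pos_cM_m) - min(seg$pos_cM_m),
            anchors = paste(seg$locus, collapse = ";"),
            stringsAsFactors = FALSE)
        }
        run_start <- i + 1
      }
    }
  }
  structure(list(
    pairs = pairs, anchors = anchors,
    inversions = if (length(inversions)) do.call(rbind, inversions) else
      data.frame(lg_female = character(0), lg_male = character(0),
                 n_anchors = integer(0), span_female_cM = numeric(0),
                 span_male_cM = numeric(0), anchors = character(0)),
    translocations = if (length(translocs)) do.call(rbind, translocs) else
      anchors[0, ],
    unalignable = unalignable
  ), class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat("<synteny_report>\n")
  if (!is.null(x$pairs)) print(x$pairs)
  cat(sprintf("  %d inversion candidate(s), %d translocation candidate(s)\n",
              if (is.null(x$inversions)) 0L else nrow(x$inversions),
              if (is.null(x$translocations)) 0L else nrow(x$translocations)))
  invisible(x)
}
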