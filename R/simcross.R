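#' Configuration for a synthetic pseudo-testcross population
#'
#' Builds and validates the parameter set for [simulate_cross()]. The defaults
#' describe an olive-scale biparental design: 23 chromosomes whose female
#' genetic lengths follow the packaged parental map summary, a male map
#' shortened by the heterochiasmy ratio (female/male total map length of about
#' 1.6), a dominant Ss x ss self-incompatibility locus on chromosome 18
#' segregating 1:1, 229 true-to-type offspring and about 5% contaminant
#' seedlings from open pollination.
#'
#' @param n_chromosomes Number of chromosomes (default 23).
#' @param female_chrom_lengths Genetic length in cM of each chromosome in
#'   female meiosis. Default: the female column of the packaged parental map
#'   summary (23 chromosomes totalling ~5,680 cM).
#' @param male_chrom_lengths Genetic length in cM of each chromosome in male
#'   meiosis. Default: `female_chrom_lengths / heterochiasmy_ratio`.
#' @param heterochiasmy_ratio Ratio of female to male map length (default 1.6).
#' @param markers_per_chromosome Marker loci simulated per chromosome
#'   (default 30; desk-scale stand-in for the hundreds of RAD tags per
#'   chromosome in a real experiment).
#' @param seg_class_mix Named proportions of marker loci that are maternal
#'   testcross (het x hom), paternal testcross (hom x het) and fully
#'   informative "ABxCD" loci. Must sum to 1. The default mirrors the
#'   relative abundance of the three classes in a cross of two heterozygous
#'   parents where the male parent is the more heterozygous one.
#' @param dsi_chromosome Chromosome carrying the self-incompatibility locus
#'   (default 18).
#' @param dsi_position Position of the locus on the female genetic scale in
#'   cM. Default: the midpoint of `dsi_chromosome`.
#' @param n_offspring Number of true-to-type F1 offspring (default 229).
#' @param contaminant_fraction Fraction of drawn seedlings that are
#'   contaminants from open pollination (default 0.05). The total number of
#'   seedlings drawn is `round(n_offspring / (1 - contaminant_fraction))`.
#' @param genotyping_error_rate Per-call probability that the generating
#'   genotype is swapped before reads are simulated (default 0.01).
#' @param mean_depth Mean sequencing depth per marker per individual
#'   (default 30).
#' @param depth_dispersion Negative-binomial size parameter for depth
#'   overdispersion (default 5; smaller is noisier).
#' @param seq_error Per-read probability of reading the wrong allele
#'   (default 0.005).
#' @param n_parentage_markers Number of unlinked multi-allelic (SSR-like)
#'   markers used for parentage validation (default 12).
#' @param parentage_n_alleles Number of equifrequent alleles per parentage
#'   marker in the pollen-donor population (default 8).
#' @param parentage_error_rate Per-allele genotyping error rate at parentage
#'   markers (default 0.002, the scale typical of capillary SSR typing).
#' @param donor_s_freq Frequency of the dominant S allele among unrelated
#'   pollen donors (default 0.25, i.e. roughly half the donor population is
#'   Ss as expected under balancing selection on a diallelic system).
#' @param male_inversions Optional list of structural inversions carried
#'   homozygously by the male parent relative to the female: each element
#'   `list(chrom =, start =, end =)` reflects the male genetic positions of
#'   the markers inside `[start, end]` (female-scale cM), so the two
#'   parental maps disagree in marker order over that segment.
#' @param seed Master seed; every stochastic draw flows from it.
#' @return An object of class `cross_config` (a validated list).
#' @seealso [simulate_cross()], [simulate_reads()]
#' @export
cross_config <- function(n_chromosomes = 23,
                         female_chrom_lengths = NULL,
                         male_chrom_lengths = NULL,
                         heterochiasmy_ratio = 1.6,
                         markers_per_chromosome = 30,
                         seg_class_mix = c(maternal_testcross = 0.33,
                                           paternal_testcross = 0.51,
                                           fully_informative = 0.16),
                         dsi_chromosome = 18,
                         dsi_position = NULL,
                         n_offspring = 229,
                         contaminant_fraction = 0.05,
                         genotyping_error_rate = 0.01,
                         mean_depth = 30,
                         depth_dispersion = 5,
                         seq_error = 0.005,
                         n_parentage_markers = 12,
                         parentage_n_alleles = 8,
                         parentage_error_rate = 0.002,
                         donor_s_freq = 0.25,
                         male_inversions = list(),
                         seed = 1L) {
  if (is.null(female_chrom_lengths)) {
    tab <- load_table_fixtures()$map_summary
    female_chrom_lengths <- tab$female_cM[seq_len(min(n_chromosomes, nrow(tab)))]
    if (n_chromosomes > nrow(tab)) {
      female_chrom_lengths <- rep_len(female_chrom_lengths, n_chromosomes)
    }
  }
  if (is.null(male_chrom_lengths)) {
    male_chrom_lengths <- female_chrom_lengths / heterochiasmy_ratio
  }
  if (is.null(dsi_position)) {
    dsi_position <- female_chrom_lengths[dsi_chromosome] / 2
  }
  if (is.null(names(seg_class_mix)) && length(seg_class_mix) == 3) {
    names(seg_class_mix) <- c("maternal_testcross", "paternal_testcross",
                              "fully_informative")
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    female_chrom_lengths = as.numeric(female_chrom_lengths),
    male_chrom_lengths = as.numeric(male_chrom_lengths),
    heterochiasmy_ratio = heterochiasmy_ratio,
    markers_per_chromosome = as.integer(markers_per_chromosome),
    seg_class_mix = seg_class_mix,
    dsi_chromosome = as.integer(dsi_chromosome),
    dsi_position = dsi_position,
    n_offspring = as.integer(n_offspring),
    contaminant_fraction = contaminant_fraction,
    genotyping_error_rate = genotyping_error_rate,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    seq_error = seq_error,
    n_parentage_markers = as.integer(n_parentage_markers),
    parentage_n_alleles = as.integer(parentage_n_alleles),
    parentage_error_rate = parentage_error_rate,
    donor_s_freq = donor_s_freq,
    male_inversions = male_inversions,
    seed = as.integer(seed)
  )
  validate_cross_config(cfg)
  class(cfg) <- "cross_config"
  cfg
}

validate_cross_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1,
    length(cfg$female_chrom_lengths) == cfg$n_chromosomes,
    length(cfg$male_chrom_lengths) == cfg$n_chromosomes,
    all(cfg$female_chrom_lengths > 0),
    all(cfg$male_chrom_lengths > 0),
    cfg$heterochiasmy_ratio > 0,
    cfg$markers_per_chromosome >= 1,
    length(cfg$seg_class_mix) == 3,
    all(cfg$seg_class_mix >= 0), all(cfg$seg_class_mix <= 1),
    abs(sum(cfg$seg_class_mix) - 1) < 1e-8,
    cfg$dsi_chromosome >= 1, cfg$dsi_chromosome <= cfg$n_chromosomes,
    cfg$dsi_position >= 0,
    cfg$dsi_position <= cfg$female_chrom_lengths[cfg$dsi_chromosome],
    cfg$n_offspring >= 1,
    cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1,
    cfg$genotyping_error_rate >= 0, cfg$genotyping_error_rate < 1,
    cfg$mean_depth >= 0, cfg$depth_dispersion > 0,
    cfg$seq_error >= 0, cfg$seq_error < 1,
    cfg$donor_s_freq >= 0, cfg$donor_s_freq <= 1
  )
  invisible(cfg)
}

#' @export
print.cross_config <- function(x, ...) {
  cat("<cross_config>\n")
  cat(sprintf("  %d chromosomes, %d markers each; female map %.0f cM, male map %.0f cM\n",
              x$n_chromosomes, x$markers_per_chromosome,
              sum(x$female_chrom_lengths), sum(x$male_chrom_lengths)))
  cat(sprintf("  DSI locus: chromosome %d at %.1f cM (female scale)\n",
              x$dsi_chromosome, x$dsi_position))
  cat(sprintf("  %d offspring + contaminant fraction %.2f; seed %d\n",
              x$n_offspring, x$contaminant_fraction, x$seed))
  invisible(x)
}

# One meiosis of one chromosome: Poisson crossover count with mean L/100,
# breakpoints uniform on the genetic scale, no interference. Returns the
# transmitted haplotype index (1 or 2) at each queried position.
meiosis_chromosome <- function(positions, length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  bp <- sort(stats::runif(k, 0, length_cM))
  start <- sample(c(1L, 2L), 1L)
  idx <- (start - 1L + findInterval(positions, bp)) %% 2L + 1L
  list(hap_index = idx, breakpoints = bp, start = start)
}

# Draw one gamete across all chromosomes of a phased diploid genome.
# genome: list per chromosome with matrix `haps` (markers x 2) of alleles.
# positions: list per chromosome of marker positions on this parent's scale.
draw_gamete <- function(genome, positions, lengths) {
  n_chr <- length(genome)
  alleles <- vector("list", n_chr)
  xo <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    m <- meiosis_chromosome(positions[[ch]], lengths[ch])
    alleles[[ch]] <- genome[[ch]][cbind(seq_along(m$hap_index), m$hap_index)]
    xo[[ch]] <- list(breakpoints = m$breakpoints, start = m$start)
  }
  list(alleles = alleles, crossovers = xo)
}

#' Simulate an F1 pseudo-testcross population with a DSI locus
#'
#' Generates phased parental genomes and a full-sib F1 progeny. Crossovers per
#' meiosis and chromosome are Poisson with mean equal to the sex-specific
#' genetic length in Morgans, breakpoints uniform on the genetic scale, with
#' no interference. The self-incompatibility locus is transmitted like any
#' other locus: the female parent is Ss, the male parent ss, so offspring
#' phenotypes segregate 1:1 (G1 carries S, G2 does not). Contaminant
#' offspring are produced by crossing the female parent with an unrelated
#' random pollen donor, so they are detectable only through paternal alleles.
#'
#' Fully informative "ABxCD" loci are emitted as two co-located biallelic SNP
#' rows (suffixes `a` and `b` on a shared locus id): one segregating from the
#' mother, one from the father, as in a RAD tag carrying two SNPs. The pair of
#' calls reconstructs the four-allele genotype without phase ambiguity.
#'
#' @param config A [cross_config()] object.
#' @return A list of class `sim_cross` with elements
#'   \describe{
#'     \item{markers}{data.frame of SNP rows: `marker`, `locus`, `chrom`,
#'       `pos_female`, `pos_male`, `class`, `locus_class`, parental haplotype
#'       alleles (`mother_h1`, `mother_h2`, `father_h1`, `father_h2`; 0 =
#'       reference, 1 = alternate).}
#'     \item{geno}{integer matrix of true alternate-allele dosages (0/1/2),
#'       SNP rows x individuals.}
#'     \item{individuals}{data.frame: `id`, `contaminant`, `phenotype`
#'       ("G1"/"G2"), `dsi_maternal` / `dsi_paternal` ("S"/"s").}
#'     \item{parentage}{list with parental allele matrices and offspring
#'       genotype strings at the multi-allelic parentage markers.}
#'     \item{crossovers}{per-individual crossover records.}
#'     \item{mother_s_hap}{which maternal haplotype (1 or 2) carries S.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_cross <- function(config) {
  validate_cross_config(config)
  if (config$markers_per_chromosome < 1) stop("need at least one marker per chromosome")
  if (config$n_offspring < 1) stop("need at least one offspring")
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  mpc <- config$markers_per_chromosome

  # ---- marker layout ----------------------------------------------------
  loci <- do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    pos_f <- sort(stats::runif(mpc, 0, config$female_chrom_lengths[ch]))
    cls <- sample(names(config$seg_class_mix), mpc, replace = TRUE,
                  prob = config$seg_class_mix)
    data.frame(
      locus = sprintf("C%02dL%03d", ch, seq_len(mpc)),
      chrom = ch,
      pos_female = pos_f,
      pos_male = pos_f * config$male_chrom_lengths[ch] /
        config$female_chrom_lengths[ch],
      locus_class = cls,
      stringsAsFactors = FALSE
    )
  }))

  # expand ABxCD loci into a maternal-informative and a paternal-informative
  # SNP row; testcross loci are a single row
  expand_row <- function(i) {
    lc <- loci$locus_class[i]
    base <- loci[i, c("locus", "chrom", "pos_female", "pos_male", "locus_class")]
    if (lc == "fully_informative") {
      out <- rbind(base, base)
      out$marker <- paste0(loci$locus[i], c("a", "b"))
      out$class <- c("maternal_testcross", "paternal_testcross")
    } else {
      out <- base
      out$marker <- loci$locus[i]
      out$class <- lc
    }
    out
  }
  markers <- do.call(rbind, lapply(seq_len(nrow(loci)), expand_row))
  rownames(markers) <- NULL

  # homozygous structural inversions of the male parent: reflect the male
  # genetic position of markers inside each segment (female-scale bounds)
  for (inv in config$male_inversions) {
    sel <- markers$chrom == inv$chrom & markers$pos_female >= inv$start &
      markers$pos_female <= inv$end
    if (any(sel)) {
      scale <- config$male_chrom_lengths[inv$chrom] /
        config$female_chrom_lengths[inv$chrom]
      lo <- inv$start * scale; hi <- inv$end * scale
      markers$pos_male[sel] <- lo + hi - markers$pos_male[sel]
    }
  }

  # parental phased alleles per SNP row; which haplotype carries the
  # alternate allele is randomised so phase must be inferred downstream
  nm <- nrow(markers)
  mat_alt_hap <- sample(c(1L, 2L), nm, replace = TRUE)
  pat_alt_hap <- sample(c(1L, 2L), nm, replace = TRUE)
  hom_alt_m <- sample(c(0L, 1L), nm, replace = TRUE)  # allele of the homozygous parent
  markers$mother_h1 <- markers$mother_h2 <- 0L
  markers$father_h1 <- markers$father_h2 <- 0L
  is_mat <- markers$class == "maternal_testcross"
  is_pat <- markers$class == "paternal_testcross"
  markers$mother_h1[is_mat] <- as.integer(mat_alt_hap[is_mat] == 1L)
  markers$mother_h2[is_mat] <- as.integer(mat_alt_hap[is_mat] == 2L)
  markers$father_h1[is_mat] <- markers$father_h2[is_mat] <- hom_alt_m[is_mat]
  markers$father_h1[is_pat] <- as.integer(pat_alt_hap[is_pat] == 1L)
  markers$father_h2[is_pat] <- as.integer(pat_alt_hap[is_pat] == 2L)
  markers$mother_h1[is_pat] <- markers$mother_h2[is_pat] <- hom_alt_m[is_pat]
  markers <- markers[, c("marker", "locus", "chrom", "pos_female", "pos_male",
                         "class", "locus_class", "mother_h1", "mother_h2",
                         "father_h1", "father_h2")]

  # genomes as per-chromosome haplotype matrices; the DSI locus is appended
  # as a final pseudo-position on its chromosome (S = 1 on one maternal hap)
  mother_s_hap <- sample(c(1L, 2L), 1L)
  split_idx <- split(seq_len(nm), markers$chrom)
  mother_genome <- father_genome <- vector("list", n_chr)
  pos_f_list <- pos_m_list <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    idx <- split_idx[[as.character(ch)]]
    mh <- cbind(markers$mother_h1[idx], markers$mother_h2[idx])
    fh <- cbind(markers$father_h1[idx], markers$father_h2[idx])
    pf <- markers$pos_female[idx]
    pm <- markers$pos_male[idx]
    if (ch == config$dsi_chromosome) {
      s_row <- c(0L, 0L); s_row[mother_s_hap] <- 1L
      mh <- rbind(mh, s_row)
      fh <- rbind(fh, c(0L, 0L))
      pf <- c(pf, config$dsi_position)
      pm <- c(pm, config$dsi_position * config$male_chrom_lengths[ch] /
                config$female_chrom_lengths[ch])
    }
    mother_genome[[ch]] <- mh
    father_genome[[ch]] <- fh
    pos_f_list[[ch]] <- pf
    pos_m_list[[ch]] <- pm
  }

  # ---- offspring --------------------------------------------------------
  cf <- config$contaminant_fraction
  n_total <- if (cf > 0) round(config$n_offspring / (1 - cf)) else config$n_offspring
  n_contam <- n_total - config$n_offspring
  contaminant <- rep(FALSE, n_total)
  if (n_contam > 0) contaminant[sample(n_total, n_contam)] <- TRUE
  ids <- sprintf("F1_%03d", seq_len(n_total))

  geno <- matrix(0L, nm, n_total, dimnames = list(markers$marker, ids))
  dsi_mat <- dsi_pat <- character(n_total)
  crossovers <- vector("list", n_total)

  random_donor <- function() {
    g <- vector("list", n_chr)
    for (ch in seq_len(n_chr)) {
      k <- length(split_idx[[as.character(ch)]])
      extra <- if (ch == config$dsi_chromosome) 1L else 0L
      haps <- matrix(stats::rbinom(2L * (k + extra), 1L, 0.5), ncol = 2)
      if (extra) {
        haps[k + 1L, ] <- stats::rbinom(2L, 1L, config$donor_s_freq)
      }
      g[[ch]] <- haps
    }
    g
  }

  dsi_ch <- config$dsi_chromosome
  for (j in seq_len(n_total)) {
    gm <- draw_gamete(mother_genome, pos_f_list, config$female_chrom_lengths)
    pat_genome <- if (contaminant[j]) random_donor() else father_genome
    gp <- draw_gamete(pat_genome, pos_m_list, config$male_chrom_lengths)
    for (ch in seq_len(n_chr)) {
      idx <- split_idx[[as.character(ch)]]
      k <- length(idx)
      geno[idx, j] <- gm$alleles[[ch]][seq_len(k)] + gp$alleles[[ch]][seq_len(k)]
    }
    k_dsi <- length(split_idx[[as.character(dsi_ch)]])
    dsi_mat[j] <- if (gm$alleles[[dsi_ch]][k_dsi + 1L] == 1L) "S" else "s"
    dsi_pat[j] <- if (gp$alleles[[dsi_ch]][k_dsi + 1L] == 1L) "S" else "s"
    crossovers[[j]] <- list(maternal = gm$crossovers, paternal = gp$crossovers)
  }
  phenotype <- ifelse(dsi_mat == "S" | dsi_pat == "S", "G1", "G2")

  # ---- parentage markers (unlinked, multi-allelic) ----------------------
  npm <- config$n_parentage_markers
  nal <- config$parentage_n_alleles
  parentage <- NULL
  if (npm > 0) {
    pm_ids <- sprintf("SSR%02d", seq_len(npm))
    mom_al <- matrix(sample(nal, 2L * npm, replace = TRUE), npm, 2,
                     dimnames = list(pm_ids, NULL))
    dad_al <- matrix(sample(nal, 2L * npm, replace = TRUE), npm, 2,
                     dimnames = list(pm_ids, NULL))
    off_al <- array(0L, dim = c(npm, n_total, 2),
                    dimnames = list(pm_ids, ids, NULL))
    for (j in seq_len(n_total)) {
      m_allele <- mom_al[cbind(seq_len(npm), sample(c(1L, 2L), npm, TRUE))]
      p_src <- if (contaminant[j]) {
        matrix(sample(nal, 2L * npm, replace = TRUE), npm, 2)
      } else dad_al
      p_allele <- p_src[cbind(seq_len(npm), sample(c(1L, 2L), npm, TRUE))]
      # genotyping error: replace an allele with a uniform draw
      err <- stats::runif(npm) < config$parentage_error_rate
      m_allele[err] <- sample(nal, sum(err), replace = TRUE)
      err2 <- stats::runif(npm) < config$parentage_error_rate
      p_allele[err2] <- sample(nal, sum(err2), replace = TRUE)
      off_al[, j, 1] <- m_allele
      off_al[, j, 2] <- p_allele
    }
    parentage <- list(mother = mom_al, father = dad_al, offspring = off_al)
  }

  structure(list(
    markers = markers,
    geno = geno,
    individuals = data.frame(id = ids, contaminant = contaminant,
                             phenotype = phenotype, dsi_maternal = dsi_mat,
                             dsi_paternal = dsi_pat, stringsAsFactors = FALSE),
    parentage = parentage,
    crossovers = crossovers,
    mother_s_hap = mother_s_hap,
    config = config
  ), class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat("<sim_cross>\n")
  cat(sprintf("  %d SNP rows on %d chromosomes; %d individuals (%d contaminants)\n",
              nrow(x$markers), x$config$n_chromosomes,
              nrow(x$individuals), sum(x$individuals$contaminant)))
  cat(sprintf("  phenotypes: %d G1 / %d G2; DSI on chromosome %d at %.1f cM\n",
              sum(x$individuals$phenotype == "G1"),
              sum(x$individuals$phenotype == "G2"),
              x$config$dsi_chromosome, x$config$dsi_position))
  invisible(x)
}

#' Simulate per-marker read counts from true genotypes
#'
#' Per cell, total depth is negative binomial (`mu = mean_depth`,
#' `size = depth_dispersion`). With probability `genotyping_error_rate` the
#' generating genotype is first swapped for one of the other two genotypes
#' (and the swap logged). Reference read counts are binomial given the
#' generating genotype with per-read miscall probability `seq_error`.
#'
#' @param geno Integer matrix of alternate-allele dosages (0/1/2), markers x
#'   individuals, e.g. the `geno` element of [simulate_cross()].
#' @param config A [cross_config()] (only the depth/error fields are used).
#' @param seed Seed for this stage; defaults to `config$seed + 1` so that a
#'   full pipeline run uses a single documented stream of draws.
#' @return List of class `read_counts`: `ref` and `alt` integer matrices and
#'   `error_log`, a data.frame of injected genotype swaps (`marker`,
#'   `individual`, `true`, `observed_source`).
#' @export
simulate_reads <- function(geno, config, seed = config$seed + 1L) {
  set.seed(seed)
  nm <- nrow(geno); ni <- ncol(geno)
  depth <- matrix(stats::rnbinom(nm * ni, size = config$depth_dispersion,
                                 mu = config$mean_depth), nm, ni)
  gen <- geno
  err <- matrix(stats::runif(nm * ni) < config$genotyping_error_rate, nm, ni)
  if (any(err)) {
    idx <- which(err)
    # swap to one of the other two genotypes, uniformly
    shift <- sample(c(1L, 2L), length(idx), replace = TRUE)
    gen[idx] <- (gen[idx] + shift) %% 3L
  }
  p_ref_true <- 1 - gen / 2
  e <- config$seq_error
  p_ref <- p_ref_true * (1 - e) + (1 - p_ref_true) * e
  ref <- matrix(stats::rbinom(nm * ni, size = depth, prob = p_ref), nm, ni,
                dimnames = dimnames(geno))
  alt <- depth - ref
  dimnames(alt) <- dimnames(geno)
  log_idx <- which(err, arr.ind = TRUE)
  error_log <- data.frame(
    marker = rownames(geno)[log_idx[, 1]],
    individual = colnames(geno)[log_idx[, 2]],
    true = geno[err],
    observed_source = gen[err],
    stringsAsFactors = FALSE
  )
  structure(list(ref = ref, alt = alt, error_log = error_log),
            class = "read_counts")
}

#' Read counts for parents at simulated markers
#'
#' Convenience wrapper producing error-free, high-depth parental "reads" so a
#' simulated experiment can be genotype-called end to end. Parents in a real
#' experiment are sequenced at much higher depth and their genotypes are
#' effectively known; modelling parental miscalls is not the point here.
#'
#' @param sim A [simulate_cross()] result.
#' @param depth Fixed parental depth (default 100).
#' @return A `read_counts` object with two columns, `mother` and `father`.
#' @export
parental_reads <- function(sim, depth = 100L) {
  g <- cbind(mother = sim$markers$mother_h1 + sim$markers$mother_h2,
             father = sim$markers$father_h1 + sim$markers$father_h2)
  rownames(g) <- sim$markers$marker
  ref <- (2L - g) * depth %/% 2L
  alt <- g * depth %/% 2L
  structure(list(ref = ref, alt = alt,
                 error_log = data.frame(marker = character(0),
                                        individual = character(0),
                                        true = integer(0),
                                        observed_source = integer(0))),
            class = "read_counts")
}
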