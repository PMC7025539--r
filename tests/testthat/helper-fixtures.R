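# Small, fast cross configurations used across tests.

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    n_chromosomes = 3,
    female_chrom_lengths = c(100, 80, 120),
    markers_per_chromosome = 60,
    n_offspring = 200,
    dsi_chromosome = 3,
    dsi_position = 60,
    contaminant_fraction = 0,
    genotyping_error_rate = 0,
    seq_error = 0,
    mean_depth = 60,
    seed = 1L
  )
  defaults[names(args)] <- args
  do.call(cross_config, defaults)
}

# Simulate, generate reads and call genotypes in one go.
sim_gm <- function(cfg, thresholds = NULL) {
  sim <- simulate_cross(cfg)
  reads <- simulate_reads(sim$geno, cfg)
  if (is.null(thresholds)) {
    thresholds <- calling_thresholds(
      min_called_progeny = round(0.6 * nrow(sim$individuals)))
  }
  pc <- call_matrix(parental_reads(sim), thresholds)
  calls <- call_matrix(reads, thresholds)
  gm <- genotype_matrix(calls, pc[, "mother"], pc[, "father"], thresholds,
                        locus = sim$markers$locus[match(rownames(calls),
                                                        sim$markers$marker)])
  list(sim = sim, reads = reads, gm = gm, thresholds = thresholds)
}

# Build a genotype_matrix directly from a 0/1/NA maternal transmission
# matrix (mother het, father hom-ref at every marker).
gm_from_patterns <- function(P) {
  calls <- matrix("-", nrow(P), ncol(P), dimnames = dimnames(P))
  calls[P == 0L] <- "A"
  calls[P == 1L] <- "H"
  genotype_matrix(calls, rep("H", nrow(P)), rep("A", nrow(P)),
                  calling_thresholds(min_called_progeny = 0))
}

# Brute-force oracle: probability that two loci d cM apart recombine in one
# meiosis of a chromosome of length L, under the Poisson crossover model
# (count ~ Poisson(L/100), breakpoints uniform): sum over crossover counts
# of P(odd number falls between the loci).
poisson_rec_prob <- function(d, L, kmax = 120) {
  lambda <- L / 100
  p <- d / L
  k <- 0:kmax
  sum(stats::dpois(k, lambda) * (1 - (1 - 2 * p)^k) / 2)
}
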