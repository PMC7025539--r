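#' Write and read parentage-marker genotypes as TSV
#'
#' One row per multi-allelic parentage marker: `marker`, `mother`, `father`,
#' then one `"a/b"` genotype column per offspring.
#'
#' @param parentage The `parentage` element of a [simulate_cross()] result.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @export
write_parentage_tsv <- function(parentage, path, seed = NA) {
  fmt <- function(m) paste(m[, 1], m[, 2], sep = "/")
  off <- matrix(paste(parentage$offspring[, , 1], parentage$offspring[, , 2],
                      sep = "/"),
                dim(parentage$offspring)[1],
                dimnames = dimnames(parentage$offspring)[1:2])
  df <- data.frame(marker = rownames(parentage$mother),
                   mother = fmt(parentage$mother),
                   father = fmt(parentage$father),
                   off, check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(df, path, seed)
  invisible(path)
}

#' @rdname write_parentage_tsv
#' @export
read_parentage_tsv <- function(path) {
  df <- read_skip_header(path, colClasses = "character")
  parse2 <- function(v) {
    sp <- strsplit(v, "/", fixed = TRUE)
    cbind(as.integer(vapply(sp, `[`, "", 1)),
          as.integer(vapply(sp, `[`, "", 2)))
  }
  mom <- parse2(df$mother); dad <- parse2(df$father)
  rownames(mom) <- rownames(dad) <- df$marker
  ids <- setdiff(names(df), c("marker", "mother", "father"))
  off <- array(NA_integer_, dim = c(nrow(df), length(ids), 2),
               dimnames = list(df$marker, ids, NULL))
  for (j in seq_along(ids)) {
    g <- parse2(df[[ids[j]]])
    off[, j, 1] <- g[, 1]; off[, j, 2] <- g[, 2]
  }
  list(mother = mom, father = dad, offspring = off)
}

# Transmitted parental haplotype index (1/2) at the DSI position, from the
# recorded crossovers of one meiosis.
hap_at_dsi <- function(sim, individual, side = c("maternal", "paternal")) {
  side <- match.arg(side)
  cfg <- sim$config
  ch <- cfg$dsi_chromosome
  xo <- sim$crossovers[[individual]][[side]][[ch]]
  pos <- if (side == "maternal") cfg$dsi_position else {
    cfg$dsi_position * cfg$male_chrom_lengths[ch] / cfg$female_chrom_lengths[ch]
  }
  (xo$start - 1L + sum(xo$breakpoints < pos)) %% 2L + 1L
}

#' Amplicon haplotype pairs implied by the simulated cross
#'
#' Assigns the catalog haplotypes of the reference cross design (mother
#' S-A/s-a, father s-b/s-c) to each non-contaminant offspring from the
#' simulation's transmission truth, yielding the diploid diagnostic
#' genotype each offspring would show at the STS marker.
#'
#' @param sim A [simulate_cross()] result.
#' @param catalog A [dsi_catalog()].
#' @return data.frame: `id`, `maternal_hap`, `paternal_hap`, `g63`, `g283`
#'   (contaminants get `NA` haplotypes).
#' @export
sim_amplicon_genotypes <- function(sim, catalog = dsi_catalog()) {
  al <- catalog$alleles
  rows <- lapply(seq_len(nrow(sim$individuals)), function(j) {
    ind <- sim$individuals[j, ]
    if (ind$contaminant) {
      return(data.frame(id = ind$id, maternal_hap = NA_character_,
                        paternal_hap = NA_character_, g63 = NA_character_,
                        g283 = NA_character_, stringsAsFactors = FALSE))
    }
    mh <- if (ind$dsi_maternal == "S") "S-A" else "s-a"
    ph <- if (hap_at_dsi(sim, j, "paternal") == 1L) "s-b" else "s-c"
    data.frame(id = ind$id, maternal_hap = mh, paternal_hap = ph,
               g63 = paste0(al[mh, "63"], al[ph, "63"]),
               g283 = paste0(al[mh, "283"], al[ph, "283"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full simulated analysis pipeline
#'
#' Executes, in order: cross simulation, read simulation, genotype calling,
#' parentage validation, per-parent map construction, cross-parent synteny
#' comparison, segregation-distortion scan, trait mapping of the
#' incompatibility phenotype on the maternal map, and STS classification of
#' the progeny. Every stage writes its declared artifact into `out_dir`;
#' the run is deterministic for a fixed config seed.
#'
#' @param config A [cross_config()].
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [calling_thresholds()]; by default the progeny-count
#'   retention threshold is scaled to the simulated population size in the
#'   same proportion as 150 of 229.
#' @param params A [mapping_params()].
#' @param n_phenotyped Number of validated offspring with a phenotype
#'   available to trait mapping (default: all validated offspring).
#' @param smooth Run the error-removal pass during map building.
#' @param verbose Print per-stage counts.
#' @return Invisibly, a list with the stage objects (`sim`, `gm`,
#'   `parentage_check`, `map_female`, `map_male`, `synteny`, `distortion`,
#'   `trait_report`, `classifications`) and `paths` to the written files.
#' @export
run_pipeline <- function(config = cross_config(), out_dir,
                         thresholds = NULL, params = mapping_params(),
                         n_phenotyped = NULL, smooth = TRUE,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  p <- function(f) file.path(out_dir, f)
  seed <- config$seed

  sim <- stage("simulate", {
    s <- simulate_cross(config)
    say("simulate: %d SNP rows, %d individuals (%d contaminants)",
        nrow(s$markers), nrow(s$individuals), sum(s$individuals$contaminant))
    s
  })
  reads <- stage("simulate-reads", simulate_reads(sim$geno, config))
  preads <- parental_reads(sim)
  write_counts_tsv(reads, p("read_counts.tsv"), seed)
  write_counts_tsv(preads, p("parent_counts.tsv"), seed)
  write_phenotype_csv(data.frame(id = sim$individuals$id,
                                 group = sim$individuals$phenotype),
                      p("phenotypes.csv"), seed)
  write_truth_json(sim, reads, p("truth.json"))
  if (!is.null(sim$parentage)) {
    write_parentage_tsv(sim$parentage, p("parentage.tsv"), seed)
  }

  if (is.null(thresholds)) {
    n_total <- nrow(sim$individuals)
    thresholds <- calling_thresholds(
      min_called_progeny = round(150 / 229 * n_total))
  }

  pc <- stage("check-parents", {
    res <- check_parentage(sim$parentage$offspring, sim$parentage$mother,
                           sim$parentage$father)
    say("check-parents: %d validated, %d excluded, %d unresolvable of %d",
        sum(res$status == "validated"), sum(res$status == "excluded"),
        sum(res$status == "unresolvable"), nrow(res))
    res
  })
  write_with_header(pc, p("parentage_check.csv"), seed, sep = ",")
  validated <- pc$id[pc$status == "validated"]

  gm <- stage("call", {
    calls <- call_matrix(reads, thresholds)[, validated, drop = FALSE]
    pcalls <- call_matrix(preads, thresholds)
    g <- genotype_matrix(calls, pcalls[, "mother"], pcalls[, "father"],
                         thresholds,
                         locus = sim$markers$locus[match(rownames(calls),
                                                         sim$markers$marker)])
    say("call: %d markers retained, %d excluded, %d individuals",
        nrow(g$calls), nrow(g$excluded), ncol(g$calls))
    g
  })
  write_genotype_tsv(gm, p("genotypes.tsv"), seed)

  map_f <- stage("map-female", build_parent_map(gm, "mother", params, smooth))
  map_m <- stage("map-male", build_parent_map(gm, "father", params, smooth))
  say("map: female %d LGs / %.0f cM, male %d LGs / %.0f cM",
      length(map_f$lgs), map_stats(map_f)$length_cM,
      length(map_m$lgs), map_stats(map_m)$length_cM)
  write_map_tsv(map_f, p("map_female.tsv"), seed)
  write_map_tsv(map_m, p("map_male.tsv"), seed)

  dist <- stage("distortion", distortion_scan(gm, params))
  write_with_header(dist, p("distortion.csv"), seed, sep = ",")

  syn <- stage("compare-maps", compare_maps(map_f, map_m, gm$markers))
  if (!is.null(syn$pairs)) {
    write_with_header(syn$pairs, p("synteny_pairs.csv"), seed, sep = ",")
    write_with_header(syn$inversions, p("synteny_inversions.csv"), seed,
                      sep = ",")
  }

  phen <- stats::setNames(sim$individuals$phenotype, sim$individuals$id)
  phen <- phen[validated]
  if (!is.null(n_phenotyped) && n_phenotyped < length(phen)) {
    set.seed(seed + 2L)
    phen <- phen[sort(sample(length(phen), n_phenotyped))]
  }
  trait <- stage("trait-map", {
    tr <- map_trait(phen, map_f)
    if (tr$linked) {
      say("trait-map: locus on %s at %.1f cM, interval %.2f cM",
          tr$lg, tr$position_cM, tr$span_cM)
    } else say("trait-map: unlinked")
    tr
  })
  write_trait_report_json(trait, p("trait_report.json"))
  if (trait$linked) {
    writeLines(render_trait_diagram(trait, map_f, phen),
               p("trait_diagram.txt"))
  }

  cls <- stage("classify", {
    ag <- sim_amplicon_genotypes(sim)
    ag <- ag[ag$id %in% validated, ]
    res <- lapply(seq_len(nrow(ag)), function(k)
      classify_dsi(g63 = ag$g63[k], g283 = ag$g283[k]))
    names(res) <- ag$id
    res
  })
  write_classification_csv(cls, p("classification.csv"), seed)

  invisible(list(sim = sim, parentage_check = pc, gm = gm,
                 map_female = map_f, map_male = map_m, synteny = syn,
                 distortion = dist, trait_report = trait,
                 classifications = cls,
                 paths = list.files(out_dir, full.names = TRUE)))
}

parse_cli_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2
      } else {
        out[[key]] <- TRUE; i <- i + 1
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1
    }
  }
  out
}

config_from_json <- function(path, seed = NULL) {
  cfg <- if (is.null(path)) list() else jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  do.call(cross_config, cfg)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Supported:
#' `simulate --out DIR [--config FILE.json] [--seed N]`,
#' `run-all --out DIR [--config FILE.json] [--seed N] [--phenotyped N]`,
#' `call --counts F --parents F --out F [--min-coverage N] [--min-progeny N]`,
#' `check-parents --parentage F --out F`,
#' `map --genotypes F [--out-prefix P]`,
#' `compare-maps --genotypes F --out PREFIX`,
#' `map-stats` (packaged parental-map summary),
#' `classify --genotypes FILE.csv --out FILE.csv` (CSV with columns
#' `id`, `g63`, `g283`),
#' `trait-map --genotypes FILE.tsv --phenotypes FILE.csv --out FILE.json`.
#' Configuration files are JSON objects whose keys match [cross_config()]
#' arguments; command-line flags override file values.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly.
#' @export
dsimap_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: dsimap <simulate|run-all|map-stats|classify|trait-map> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  switch(cmd,
    "simulate" = {
      cfg <- config_from_json(opt$config, opt$seed)
      sim <- simulate_cross(cfg)
      reads <- simulate_reads(sim$geno, cfg)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_counts_tsv(reads, file.path(opt$out, "read_counts.tsv"), cfg$seed)
      write_counts_tsv(parental_reads(sim),
                       file.path(opt$out, "parent_counts.tsv"), cfg$seed)
      write_phenotype_csv(data.frame(id = sim$individuals$id,
                                     group = sim$individuals$phenotype),
                          file.path(opt$out, "phenotypes.csv"), cfg$seed)
      write_truth_json(sim, reads, file.path(opt$out, "truth.json"))
      write_parentage_tsv(sim$parentage,
                          file.path(opt$out, "parentage.tsv"), cfg$seed)
    },
    "run-all" = {
      cfg <- config_from_json(opt$config, opt$seed)
      n_ph <- if (!is.null(opt$phenotyped)) as.integer(opt$phenotyped) else NULL
      run_pipeline(cfg, opt$out, n_phenotyped = n_ph)
    },
    "call" = {
      counts <- read_counts_tsv(opt$counts)
      pc <- read_counts_tsv(opt$parents)
      th <- calling_thresholds(
        min_coverage = if (is.null(opt$`min-coverage`)) 8L else
          as.integer(opt$`min-coverage`),
        min_called_progeny = if (is.null(opt$`min-progeny`)) 150L else
          as.integer(opt$`min-progeny`))
      pcalls <- call_matrix(pc, th)
      gm <- genotype_matrix(call_matrix(counts, th),
                            pcalls[, "mother"], pcalls[, "father"], th)
      write_genotype_tsv(gm, opt$out)
    },
    "check-parents" = {
      pg <- read_parentage_tsv(opt$parentage)
      res <- check_parentage(pg$offspring, pg$mother, pg$father)
      write_with_header(res, opt$out, sep = ",")
    },
    "map" = {
      gm <- read_genotype_tsv(opt$genotypes)
      prefix <- if (is.null(opt$`out-prefix`)) "map" else opt$`out-prefix`
      for (par in c("mother", "father")) {
        m <- build_parent_map(gm, par)
        write_map_tsv(m, paste0(prefix, "_", par, ".tsv"))
      }
      write_with_header(distortion_scan(gm), paste0(prefix, "_distortion.csv"),
                        sep = ",")
    },
    "compare-maps" = {
      gm <- read_genotype_tsv(opt$genotypes)
      syn <- compare_maps(build_parent_map(gm, "mother"),
                          build_parent_map(gm, "father"), gm$markers)
      write_with_header(syn$pairs, paste0(opt$out, "_pairs.csv"), sep = ",")
      write_with_header(syn$inversions, paste0(opt$out, "_inversions.csv"),
                        sep = ",")
    },
    "map-stats" = {
      st <- map_stats(load_table_fixtures()$map_summary)
      cat(sprintf("female: %d markers, %.3f cM, %d bins, %.2f cM/bin\n",
                  st$female$markers, st$female$length_cM, st$female$bins,
                  st$female$mean_bin_spacing))
      cat(sprintf("male:   %d markers, %.3f cM, %d bins, %.2f cM/bin\n",
                  st$male$markers, st$male$length_cM, st$male$bins,
                  st$male$mean_bin_spacing))
      cat(sprintf("combined markers: %d\n", st$combined_markers))
    },
    "classify" = {
      df <- utils::read.csv(opt$genotypes, stringsAsFactors = FALSE,
                            colClasses = "character")
      res <- lapply(seq_len(nrow(df)), function(k)
        classify_dsi(g63 = df$g63[k], g283 = df$g283[k]))
      names(res) <- df$id
      write_classification_csv(res, opt$out)
    },
    "trait-map" = {
      gm <- read_genotype_tsv(opt$genotypes)
      phen <- read_phenotype_csv(opt$phenotypes)
      map_f <- build_parent_map(gm, "mother")
      rep <- map_trait(phen, map_f)
      write_trait_report_json(rep, opt$out)
      print(rep)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
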