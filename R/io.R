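FIXTURE_MD5 <- c(
  parental_map_summary.tsv = "4e270fd4f9f72cd6e767c664de96826f",
  sts_diagnostic_genotypes.tsv = "6f2205574dd67e0f337c7f17b4ab56a1",
  sts_haplotypes.tsv = "3340b6679c7cff071c42cede44f49e66"
)

#' Load the packaged reference tables
#'
#' Three small plain-text tables ship with the package: the per-chromosome
#' parental linkage-map summary (marker counts, cM lengths and genetic-bin
#' counts for the female and male maps of an olive biparental cross), the
#' diagnostic-genotype table of the STS classifier, and the five-haplotype
#' catalog of the diagnostic amplicon. File checksums are verified on load.
#'
#' @return List: `map_summary`, `diagnostic_genotypes`, `haplotypes`
#'   (data.frames).
#' @export
load_table_fixtures <- function() {
  dir <- system.file("extdata", package = "dsimap")
  out <- list()
  for (f in names(FIXTURE_MD5)) {
    path <- file.path(dir, f)
    sum <- unname(tools::md5sum(path))
    if (is.na(sum) || sum != FIXTURE_MD5[[f]]) {
      stop("checksum mismatch for packaged table: ", f)
    }
  }
  list(
    map_summary = utils::read.delim(file.path(dir, "parental_map_summary.tsv"),
                                    stringsAsFactors = FALSE),
    diagnostic_genotypes = utils::read.delim(
      file.path(dir, "sts_diagnostic_genotypes.tsv"),
      stringsAsFactors = FALSE, colClasses = "character"),
    haplotypes = utils::read.delim(file.path(dir, "sts_haplotypes.tsv"),
                                   stringsAsFactors = FALSE,
                                   colClasses = "character")
  )
}

provenance_header <- function(seed = NA, extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("dsimap")),
                  error = function(e) "dev")
  paste0("# dsimap ", ver, " seed=", seed,
         if (!is.null(extra)) paste0(" ", extra) else "")
}

write_with_header <- function(df, path, seed = NA, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

read_skip_header <- function(path, sep = "\t", ...) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write and read a genotype matrix as TSV
#'
#' One row per marker: `marker`, `locus`, `mother`, `father`, `class`, then
#' one column per individual with calls coded `A`/`H`/`B`/`-`. A provenance
#' comment line (`#`) precedes the header.
#'
#' @param gm A [genotype_matrix()] object.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @return `write_genotype_tsv` returns `path` invisibly;
#'   `read_genotype_tsv` returns a `genotype_matrix`.
#' @export
write_genotype_tsv <- function(gm, path, seed = NA) {
  df <- cbind(gm$markers, as.data.frame(gm$calls, check.names = FALSE,
                                        stringsAsFactors = FALSE))
  write_with_header(df, path, seed)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param thresholds Thresholds attached to the returned object.
#' @export
read_genotype_tsv <- function(path, thresholds = calling_thresholds()) {
  df <- read_skip_header(path, colClasses = "character")
  meta <- c("marker", "locus", "mother", "father", "class")
  calls <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(calls) <- df$marker
  structure(list(calls = calls,
                 markers = df[, meta],
                 excluded = data.frame(marker = character(0),
                                       reason = character(0)),
                 thresholds = thresholds),
            class = "genotype_matrix")
}

#' Write and read read-count matrices as TSV
#'
#' One row per marker, one column per individual, cells coded
#' `"ref,alt"`.
#'
#' @param counts A `read_counts` object.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @export
write_counts_tsv <- function(counts, path, seed = NA) {
  cells <- matrix(paste(counts$ref, counts$alt, sep = ","),
                  nrow(counts$ref), dimnames = dimnames(counts$ref))
  df <- data.frame(marker = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_with_header(df, path, seed)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read_skip_header(path, colClasses = "character")
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df$marker
  sp <- strsplit(cells, ",", fixed = TRUE)
  ref <- matrix(as.integer(vapply(sp, `[`, "", 1)), nrow(cells),
                dimnames = dimnames(cells))
  alt <- matrix(as.integer(vapply(sp, `[`, "", 2)), nrow(cells),
                dimnames = dimnames(cells))
  structure(list(ref = ref, alt = alt,
                 error_log = data.frame(marker = character(0),
                                        individual = character(0),
                                        true = integer(0),
                                        observed_source = integer(0))),
            class = "read_counts")
}

#' Write and read a phenotype table as CSV
#'
#' Two columns: `id`, `group` (`G1`/`G2`/`unknown`).
#'
#' @param phenotypes data.frame with `id` and `group`, or a named vector.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @export
write_phenotype_csv <- function(phenotypes, path, seed = NA) {
  if (!is.data.frame(phenotypes)) {
    phenotypes <- data.frame(id = names(phenotypes),
                             group = unname(phenotypes),
                             stringsAsFactors = FALSE)
  }
  write_with_header(phenotypes, path, seed, sep = ",")
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  read_skip_header(path, sep = ",", colClasses = "character")
}

#' Write a genetic map as TSV
#'
#' Columns: `lg`, `bin`, `pos_cM`, `representative`, `n_markers`,
#' `markers` (semicolon-joined ids).
#'
#' @param map A `genetic_map`.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @export
write_map_tsv <- function(map, path, seed = NA) {
  df <- do.call(rbind, lapply(names(map$lgs), function(nm) {
    tab <- map$lgs[[nm]]$table
    data.frame(lg = nm, bin = tab$bin, pos_cM = tab$pos_cM,
               representative = tab$representative,
               n_markers = tab$n_markers, markers = tab$markers,
               stringsAsFactors = FALSE)
  }))
  write_with_header(df, path, seed)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  read_skip_header(path)
}

#' Write simulation ground truth as JSON
#'
#' Records contaminant flags, the DSI transmission truth, injected
#' genotyping errors and per-meiosis crossover counts, for downstream
#' validation of a simulated analysis.
#'
#' @param sim A [simulate_cross()] result.
#' @param reads Optional [simulate_reads()] result (for the error log).
#' @param path Output file.
#' @export
write_truth_json <- function(sim, reads = NULL, path) {
  xo_counts <- vapply(sim$crossovers, function(z) {
    sum(vapply(z$maternal, function(ch) length(ch$breakpoints), 0L)) +
      sum(vapply(z$paternal, function(ch) length(ch$breakpoints), 0L))
  }, 0L)
  obj <- list(
    seed = sim$config$seed,
    dsi = list(chromosome = sim$config$dsi_chromosome,
               position_cM = sim$config$dsi_position,
               mother_s_hap = sim$mother_s_hap),
    individuals = sim$individuals,
    crossover_counts = xo_counts,
    genotyping_errors = if (is.null(reads)) NULL else reads$error_log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a trait interval report as JSON
#'
#' @param report A [map_trait()] result.
#' @param path Output file.
#' @export
write_trait_report_json <- function(report, path) {
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Render recombinant chromosomes around a trait locus as text
#'
#' A text rendering of the recombinant-chromosome diagram supporting a
#' mapped interval: one row per bin of the trait linkage group, one column
#' per recombinant individual, `S`/`s` marking the phase of the transmitted
#' maternal allele relative to the trait and `.` a missing genotype.
#'
#' @param report A linked [map_trait()] result.
#' @param map The `genetic_map` used for mapping.
#' @param phenotypes Named phenotype vector used for mapping.
#' @return Character vector of lines (also printed invisibly usable with
#'   `writeLines`).
#' @export
render_trait_diagram <- function(report, map, phenotypes) {
  stopifnot(report$linked)
  if (is.data.frame(phenotypes)) {
    phenotypes <- stats::setNames(phenotypes$group, phenotypes$id)
  }
  lg <- map$lgs[[report$lg]]
  rec_ids <- sort(unique(c(
    if (!is.null(report$upper_flank)) report$upper_flank$recombinant_ids,
    if (!is.null(report$lower_flank)) report$lower_flank$recombinant_ids)))
  if (!length(rec_ids)) return("no recombinant individuals at the flanks")
  pat <- lg$patterns[, rec_ids, drop = FALSE]
  trait <- ifelse(phenotypes[rec_ids] == "G1", 1L, 0L)
  lines <- sprintf("%-10s %8s  %s", "bin", "cM", paste(substr(rec_ids, 1, 7),
                                                       collapse = " "))
  for (k in seq_len(nrow(lg$table))) {
    row <- pat[k, ]
    sym <- ifelse(is.na(row), ".", ifelse(row == trait, "S", "s"))
    lines <- c(lines, sprintf("%-10s %8.2f  %s", lg$table$representative[k],
                              lg$table$pos_cM[k],
                              paste(formatC(sym, width = 7), collapse = " ")))
  }
  lines
}

#' Write a DSI classification table as CSV
#'
#' @param classifications A list of [classify_dsi()] results (named by
#'   individual) or a data.frame already in output shape.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @export
write_classification_csv <- function(classifications, path, seed = NA) {
  if (!is.data.frame(classifications)) {
    ids <- names(classifications)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_along(classifications))
    classifications <- do.call(rbind, lapply(seq_along(classifications),
      function(k) {
        cl <- classifications[[k]]
        data.frame(id = ids[k], group = cl$group,
                   pairs = paste(cl$pairs$hap1, cl$pairs$hap2, sep = "/",
                                 collapse = ";"),
                   novel_haplotype = cl$novel_haplotype,
                   homozygous_or_null = cl$homozygous_or_null,
                   stringsAsFactors = FALSE)
      }))
  }
  write_with_header(classifications, path, seed, sep = ",")
  invisible(path)
}
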