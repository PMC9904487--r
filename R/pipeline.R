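## End-to-end pipeline: locate -> assign -> deduce -> (validate), with a
## reproducible run manifest.

.logStage <- function(stage, ..., level = "info", logLevel = "info") {
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[logLevel]])
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full deduction pipeline from files
#'
#' Executes locate, assign, deduce and (when a reported-genotype table is
#' given) validate, writing every artifact plus a manifest with input
#' checksums, parameters and the tool version to the output directory. All
#' stages are deterministic, so re-running with unchanged inputs reproduces
#' identical output files. Undeduced homologs are an ordinary outcome, not
#' an error.
#'
#' @param config either a path to a YAML file or a named list with fields
#'   `map`, `haplotypes`, `pedigree`, `panel` (file paths), `locus_name`,
#'   `locus_chromosome`, `locus_start` and optionally `locus_end`,
#'   `reported` (path), `threshold` (cM; omit for automatic derivation),
#'   `bridge_missing` (default 0), `out_dir`, `log_level`
#'   (debug/info/warn).
#' @param outDir overrides `out_dir` from the config.
#' @return invisibly, a list with the in-memory results (`placement`,
#'   `alleleMap`, `deductions`, `summary`, `threshold`, `validation`) and
#'   the output paths.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  required <- c("map", "haplotypes", "pedigree", "panel", "locus_name",
                "locus_chromosome", "locus_start")
  missing_ <- setdiff(required, names(config))
  if (length(missing_))
    stop("config is missing field(s): ", paste(missing_, collapse = ", "))
  logLevel <- config$log_level %||% "info"
  outDir <- outDir %||% config$out_dir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (f in c("map", "haplotypes", "pedigree", "panel"))
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])

  .logStage("load", "reading inputs", logLevel = logLevel)
  map <- readHaploblockMap(config$map)
  pedigree <- readPedigree(config$pedigree)
  haplotypes <- readPhasedHaplotypes(config$haplotypes, map,
                                     individuals = individuals(pedigree))
  panel <- readReferencePanel(config$panel, config$locus_name)
  locus <- TargetLocus(config$locus_name, config$locus_chromosome,
                       config$locus_start,
                       config$locus_end %||% config$locus_start)

  .logStage("locate", "placing locus ", locus@name, logLevel = logLevel)
  placement <- placeLocus(locus, map)
  .logStage("locate", sprintf("%s %s", placementKind(placement),
                              paste(anchorBlocks(placement), collapse = "..")),
            logLevel = logLevel)

  .logStage("assign", "associating panel alleles with haplotype patterns",
            logLevel = logLevel)
  am <- assignAlleles(panel, haplotypes, pedigree, placement, map)
  .logStage("assign", sprintf("%d entries over %d haploblock(s); %d unresolved",
                              nrow(alleleEntries(am)),
                              length(windowBlocks(finalWindow(am))),
                              nrow(unresolvedAlleles(am))),
            logLevel = logLevel)

  .logStage("deduce", "deducing genotypes", logLevel = logLevel)
  bridge <- as.integer(config$bridge_missing %||% 0L)
  res <- deduceAll(alleleMap = am, haplotypes = haplotypes,
                   pedigree = pedigree, map = map,
                   threshold = config$threshold, panel = panel,
                   bridgeMissing = bridge)
  .logStage("deduce", sprintf("threshold %.2f cM", res$threshold),
            logLevel = logLevel)

  validation <- NULL
  if (!is.null(config$reported)) {
    .logStage("validate", "comparing against reported genotypes",
              logLevel = logLevel)
    reported <- .readTsv(config$reported, c("individual", "allele1", "allele2"))
    validation <- compareGenotypes(res$deductions, reported,
                                   excludePanel = individuals(panel))
  }

  paths <- c(placement = file.path(outDir, "placement.tsv"),
             allele_map = file.path(outDir, "allele_map.tsv"),
             deductions = file.path(outDir, "deductions.tsv"),
             genotypes = file.path(outDir, "genotypes.tsv"),
             inventory = file.path(outDir, "inventory.tsv"),
             manifest = file.path(outDir, "manifest.json"))
  .writeTsv(data.frame(locus = locus@name, chromosome = locus@chromosome,
                       phys_start = locus@start, phys_end = locus@end,
                       kind = placementKind(placement),
                       blocks = paste(anchorBlocks(placement), collapse = ";"),
                       gen_pos_cm = locusGenPos(placement)),
            paths[["placement"]])
  writeAlleleMap(am, paths[["allele_map"]])
  writeDeductions(res$deductions, paths[["deductions"]])
  .writeTsv(genotypeTable(res$deductions), paths[["genotypes"]])
  .writeTsv(res$summary@inventory, paths[["inventory"]])
  if (!is.null(validation)) {
    paths[["validation"]] <- file.path(outDir, "validation.tsv")
    .writeTsv(validationTable(validation), paths[["validation"]])
  }

  inputs <- c("map", "haplotypes", "pedigree", "panel",
              if (!is.null(config$reported)) "reported")
  manifest <- list(
    tool = "haploseer",
    version = as.character(utils::packageVersion("haploseer")),
    parameters = list(
      locus = list(name = locus@name, chromosome = locus@chromosome,
                   start = locus@start, end = locus@end),
      threshold = if (is.null(config$threshold)) "auto" else config$threshold,
      threshold_applied_cm = res$threshold,
      bridge_missing = bridge),
    inputs = lapply(stats::setNames(inputs, inputs), function(f)
      list(path = config[[f]],
           md5 = unname(tools::md5sum(config[[f]])))),
    outputs = lapply(as.list(paths[setdiff(names(paths), "manifest")]),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(placement = placement, alleleMap = am,
                 deductions = res$deductions, summary = res$summary,
                 threshold = res$threshold, validation = validation,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
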