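## Readers and writers. All files are UTF-8, tab-separated, with a header
## row; "NA" and the empty string both denote missing/unknown. This matches
## the export dialect of breeding-database tooling.

.readTsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), encoding = "UTF-8")
  miss <- setdiff(required, colnames(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a haploblock map
#'
#' @param path TSV with columns `chromosome`, `haploblock`, `phys_start`,
#'   `phys_end`, `gen_start`, `gen_end` and optionally `n_snps` and
#'   `snp_ids` (`";"`-joined).
#' @param verbose report per-chromosome haploblock and SNP counts.
#' @return a validated [HaploblockMap-class].
#' @export
readHaploblockMap <- function(path, verbose = FALSE) {
  df <- .readTsv(path, c("chromosome", "haploblock", "phys_start", "phys_end",
                         "gen_start", "gen_end"))
  map <- HaploblockMap(df)
  if (verbose) {
    n <- nHaploblocks(map); s <- snpCounts(map)
    for (chr in names(n))
      message(sprintf("[map] chromosome %s: %d haploblocks, %d SNPs",
                      chr, n[[chr]], s[[chr]]))
  }
  map
}

#' @rdname readHaploblockMap
#' @param map a [HaploblockMap-class] to write.
#' @export
writeHaploblockMap <- function(map, path) .writeTsv(hbTable(map), path)

#' Read phased haplotypes (long format)
#'
#' Unlisted (individual, haploblock, homolog) cells are missing.
#'
#' @param path TSV with columns `individual`, `haploblock`, `homolog`,
#'   `code`.
#' @param map a [HaploblockMap-class]; all haploblock ids must exist in it.
#' @param individuals optional extra individuals to carry as all-missing rows.
#' @return a [HaplotypeSet-class].
#' @export
readPhasedHaplotypes <- function(path, map, individuals = NULL) {
  df <- .readTsv(path, c("individual", "haploblock", "homolog", "code"))
  HaplotypeSet(df, map, individuals = individuals)
}

#' @rdname readPhasedHaplotypes
#' @param haplotypes a [HaplotypeSet-class] to write (only non-missing
#'   cells are listed).
#' @export
writePhasedHaplotypes <- function(haplotypes, path)
  .writeTsv(.haplotypesLong(haplotypes), path)

#' Read a pedigree
#'
#' Parents named but not listed as individuals are auto-created as founders.
#'
#' @param path TSV with columns `individual`, `mother`, `father` (`NA` or
#'   empty = unknown).
#' @return a validated, acyclic [Pedigree-class].
#' @export
readPedigree <- function(path)
  Pedigree(.readTsv(path, c("individual", "mother", "father")))

#' @rdname readPedigree
#' @param pedigree a [Pedigree-class] to write.
#' @export
writePedigree <- function(pedigree, path)
  .writeTsv(pedigreeTable(pedigree), path)

#' Read a reference panel of reported locus genotypes
#'
#' @param path TSV with columns `individual`, `allele1`, `allele2`; a blank
#'   `allele2` means the second allele is unreported, so only one homolog of
#'   that individual can be anchored.
#' @param locus target locus name the genotypes refer to.
#' @return a [ReferencePanel-class].
#' @export
readReferencePanel <- function(path, locus) {
  df <- .readTsv(path, c("individual", "allele1", "allele2"))
  ReferencePanel(locus, df)
}

#' @rdname readReferencePanel
#' @param panel a [ReferencePanel-class] to write.
#' @export
writeReferencePanel <- function(panel, path)
  .writeTsv(panelTable(panel), path)

#' Write an allele map
#'
#' One row per entry: pattern (`";"`-joined codes over the final window),
#' allele, ancestral source and source homolog, followed by the unresolved
#' panel alleles (empty pattern, reason given).
#'
#' @param alleleMap an [AlleleMap-class].
#' @param path output TSV path.
#' @export
writeAlleleMap <- function(alleleMap, path) {
  e <- alleleEntries(alleleMap)
  u <- unresolvedAlleles(alleleMap)
  w <- windowBlocks(finalWindow(alleleMap))
  out <- data.frame(
    locus = locusName(alleleMap),
    pattern = c(e$pattern, rep(NA_character_, nrow(u))),
    window_first_hb = w[1L], window_last_hb = w[length(w)],
    allele = c(e$allele, u$allele),
    source = c(e$source, u$individual),
    source_homolog = c(e$source_homolog, rep(NA_integer_, nrow(u))),
    status = c(rep("assigned", nrow(e)),
               if (nrow(u)) paste0("unresolved:", u$reason) else character()))
  .writeTsv(out, path)
}
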