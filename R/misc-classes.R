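## Constructors, accessors and show methods for the smaller value classes.

#' Construct a TargetLocus
#'
#' @param name locus name.
#' @param chromosome chromosome label matching the haploblock map.
#' @param start,end physical interval in bp (1-based inclusive); omit `end`
#'   for a point locus.
#' @return a [TargetLocus-class].
#' @examples
#' TargetLocus("Ma", "16", 3177899)
#' @export
TargetLocus <- function(name, chromosome, start, end = start) {
  new("TargetLocus", name = as.character(name),
      chromosome = as.character(chromosome),
      start = as.numeric(start), end = as.numeric(end))
}

#' @describeIn TargetLocus locus name
#' @param x a `TargetLocus`.
#' @export
setMethod("locusName", "TargetLocus", function(x) x@name)

setMethod("show", "TargetLocus", function(object) {
  cat(sprintf("TargetLocus %s: chromosome %s, %s bp\n", object@name,
              object@chromosome,
              if (object@start == object@end) format(object@start, big.mark = ",")
              else paste0(format(object@start, big.mark = ","), "-",
                          format(object@end, big.mark = ","))))
})

#' Construct a ReferencePanel
#'
#' @param locus target locus name.
#' @param genotypes data.frame with columns `individual`, `allele1`,
#'   `allele2` (`NA`/`""` allele2 = unreported).
#' @return a [ReferencePanel-class].
#' @export
ReferencePanel <- function(locus, genotypes) {
  df <- data.frame(individual = as.character(genotypes$individual),
                   allele1 = as.character(genotypes$allele1),
                   allele2 = as.character(genotypes$allele2),
                   stringsAsFactors = FALSE)
  df$allele2[!is.na(df$allele2) & df$allele2 == ""] <- NA_character_
  new("ReferencePanel", locus = as.character(locus), genotypes = df)
}

#' @describeIn ReferencePanel the genotype data.frame
#' @param x a `ReferencePanel`.
#' @export
setMethod("panelTable", "ReferencePanel", function(x) x@genotypes)

#' @describeIn ReferencePanel panel individuals
#' @export
setMethod("individuals", "ReferencePanel", function(x) x@genotypes$individual)

#' @describeIn ReferencePanel locus name
#' @export
setMethod("locusName", "ReferencePanel", function(x) x@locus)

setMethod("show", "ReferencePanel", function(object) {
  g <- object@genotypes
  cat(sprintf("ReferencePanel for %s: %d individuals (%d with one reported allele)\n",
              object@locus, nrow(g), sum(is.na(g$allele2))))
})

## ---- Placement / Window ----

#' @describeIn placeLocus `"within"` or `"between"`
#' @export
setMethod("placementKind", "Placement", function(x) x@kind)

#' @describeIn placeLocus anchor haploblock id(s)
#' @export
setMethod("anchorBlocks", "Placement", function(x) x@blocks)

#' @describeIn placeLocus interpolated locus genetic position (cM)
#' @export
setMethod("locusGenPos", "Placement", function(x) x@genPos)

setMethod("show", "Placement", function(object) {
  cat(sprintf("Placement of %s: %s %s (%.2f cM)\n", object@locus@name,
              object@kind, paste(object@blocks, collapse = " and "),
              object@genPos))
})

#' @describeIn baseWindow ordered haploblock ids of the window
#' @export
setMethod("windowBlocks", "Window", function(x) x@blocks)

#' @describeIn baseWindow the anchoring [Placement-class]
#' @export
setMethod("anchor", "Window", function(x) x@anchor)

setMethod("show", "Window", function(object) {
  cat(sprintf("Window on chromosome %s: %d haploblock(s) [%s .. %s]\n",
              object@chromosome, length(object@blocks),
              object@blocks[1L], object@blocks[length(object@blocks)]))
})

## ---- AlleleMap ----

#' @describeIn assignAlleles entries data.frame (pattern, allele, source,
#'   source_homolog)
#' @export
setMethod("alleleEntries", "AlleleMap", function(x) x@entries)

#' @describeIn assignAlleles unresolved panel alleles (individual, allele,
#'   reason)
#' @export
setMethod("unresolvedAlleles", "AlleleMap", function(x) x@unresolved)

#' @describeIn assignAlleles the final shared [Window-class]
#' @export
setMethod("finalWindow", "AlleleMap", function(x) x@window)

#' @describeIn assignAlleles locus name
#' @export
setMethod("locusName", "AlleleMap", function(x) x@locus)

setMethod("show", "AlleleMap", function(object) {
  cat(sprintf("AlleleMap for %s: %d pattern entries (%d alleles, %d sources) over %d haploblock(s)\n",
              object@locus, nrow(object@entries),
              length(unique(object@entries$allele)),
              length(unique(object@entries$source)),
              length(object@window@blocks)))
  if (nrow(object@unresolved))
    cat("  unresolved panel alleles:", nrow(object@unresolved), "\n")
})

## ---- SharedSegment ----

#' @describeIn sharedRun `"shared"`, `"none"` or `"not_evaluable"`
#' @export
setMethod("segmentStatus", "SharedSegment", function(x) x@status)

#' @describeIn sharedRun shared genetic length in cM (`NA` unless shared)
#' @export
setMethod("segmentLength", "SharedSegment", function(x) x@lengthCm)

#' @describeIn sharedRun first and last shared haploblock ids
#' @export
setMethod("segmentBlocks", "SharedSegment", function(x)
  c(first = x@firstBlock, last = x@lastBlock))

setMethod("show", "SharedSegment", function(object) {
  if (object@status == "shared")
    cat(sprintf("SharedSegment: %s/%d ~ %s/%d, %s..%s (%.1f cM)\n",
                object@indA, object@homA, object@indB, object@homB,
                object@firstBlock, object@lastBlock, object@lengthCm))
  else
    cat(sprintf("SharedSegment: %s/%d ~ %s/%d, %s\n",
                object@indA, object@homA, object@indB, object@homB,
                object@status))
})

## ---- ValidationReport ----

#' @describeIn compareGenotypes per-individual comparison table
#' @export
setMethod("validationTable", "ValidationReport", function(x) x@table)

#' @describeIn compareGenotypes matched / validatable deduced alleles
#' @export
setMethod("accuracy", "ValidationReport", function(x) x@accuracy)

setMethod("show", "ValidationReport", function(object) {
  tab <- table(factor(object@table$status,
                      levels = c("MATCH", "PARTIAL", "MISMATCH", "UNTESTABLE")))
  cat(sprintf("ValidationReport for %s: accuracy %.3f\n", object@locus,
              object@accuracy))
  print(tab)
})

## ---- SimulatedDataset ----

#' @describeIn simulateDataset truth table (one row per individual/homolog)
#' @export
setMethod("truthTable", "SimulatedDataset", function(x) x@truth)

#' @describeIn simulateDataset truth-derived reported-genotype table
#' @export
setMethod("reportedGenotypes", "SimulatedDataset", function(x) x@reported)

#' @describeIn simulateDataset list of the core components (map, haplotypes,
#'   pedigree, panel, locus, reported, truth, meioses, config)
#' @export
setMethod("simComponents", "SimulatedDataset", function(x)
  list(map = x@map, haplotypes = x@haplotypes, pedigree = x@pedigree,
       panel = x@panel, locus = x@locus, reported = x@reported,
       truth = x@truth, meioses = x@meioses, config = x@config))

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nrow(object@pedigree@records), "individuals,",
      "locus", object@locus@name, "on chromosome", object@locus@chromosome, "\n")
  cat("  panel:", nrow(object@panel@genotypes), "individuals;",
      "founder mode:", object@config@founderMode, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig (seed %d): %d founders, %d generations x %d matings x %d offspring\n",
    "  map: %d haploblocks / %.0f cM / %.0f bp; founder mode %s\n"),
    object@seed, object@nFounders, object@nGenerations, object@nMatings,
    object@offspringPerMating, object@nHaploblocks, object@chromLengthCm,
    object@chromLengthBp, object@founderMode))
})
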