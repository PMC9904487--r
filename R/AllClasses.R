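## Core S4 classes for the haplotype-sharing genotype deduction toolkit.

#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end
NULL

#' HaploblockMap: the haploblock coordinate system of one or more chromosomes
#'
#' A `HaploblockMap` stores, per chromosome, an ordered sequence of
#' haploblocks: chromosome segments delimited by historic recombination
#' events within which array SNPs are combined into multi-SNP haplotypes.
#' Each haploblock carries a physical interval (base pairs, 1-based
#' inclusive), a genetic interval (centimorgans) and optionally the member
#' SNP identifiers. Physical intervals within a chromosome must be
#' non-overlapping, and genetic positions must be non-decreasing along the
#' physical order.
#'
#' @slot ranges a [GenomicRanges::GRanges] holding the physical intervals;
#'   names are haploblock identifiers and metadata columns `genStart`,
#'   `genEnd` (cM) and `snpIds` (a `CharacterList`).
#'
#' @seealso [HaploblockMap()], [readHaploblockMap()], [hbTable()]
#' @export
setClass("HaploblockMap", representation(ranges = "GRanges"))

setValidity("HaploblockMap", function(object) {
  gr <- object@ranges
  msgs <- character()
  ids <- names(gr)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "every haploblock needs a non-empty identifier")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated haploblock ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  md <- S4Vectors::mcols(gr)
  if (!all(c("genStart", "genEnd", "snpIds") %in% colnames(md)))
    return("metadata columns genStart, genEnd, snpIds are required")
  if (any(md$genStart > md$genEnd))
    msgs <- c(msgs, "genStart must be <= genEnd for every haploblock")
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    o <- order(GenomicRanges::start(sub))
    sub <- sub[o]
    s <- GenomicRanges::start(sub); e <- GenomicRanges::end(sub)
    n <- length(sub)
    if (n > 1L) {
      bad <- which(s[-1L] <= e[-n])
      if (length(bad))
        msgs <- c(msgs, sprintf(
          "chromosome %s: physical overlap between haploblocks %s and %s",
          chr, names(sub)[bad[1L]], names(sub)[bad[1L] + 1L]))
      gs <- S4Vectors::mcols(sub)$genStart
      if (any(diff(gs) < 0))
        msgs <- c(msgs, sprintf(
          "chromosome %s: genetic positions not monotone with physical order (near %s)",
          chr, names(sub)[which(diff(gs) < 0)[1L] + 1L]))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' HaplotypeSet: phased haplotype codes per individual, homolog and haploblock
#'
#' Stores one haplotype code per (individual, homolog, haploblock) cell, with
#' `NA` for missing data. Homolog 1 is, by convention, the maternally
#' inherited chromosome copy and homolog 2 the paternal one (the layout of
#' pedigree-phased array output); for founders and individuals of unknown
#' parentage the order is arbitrary.
#'
#' @slot codes1,codes2 character matrices (individuals x haploblocks) for
#'   homolog 1 and homolog 2; identical dimnames.
#' @seealso [readPhasedHaplotypes()], [homologCodes()]
#' @export
setClass("HaplotypeSet", representation(codes1 = "matrix", codes2 = "matrix"))

setValidity("HaplotypeSet", function(object) {
  if (!identical(dim(object@codes1), dim(object@codes2)) ||
      !identical(dimnames(object@codes1), dimnames(object@codes2)))
    return("codes1 and codes2 must have identical dimensions and dimnames")
  if (is.null(rownames(object@codes1)) || is.null(colnames(object@codes1)))
    return("individual (row) and haploblock (column) names are required")
  TRUE
})

#' Pedigree: acyclic parent links with unknown-parent placeholders
#'
#' Individuals with both parents unknown are founders. Placeholder
#' individuals (e.g. an unnamed parent recorded as `UP_Delicious`) are
#' ordinary individuals and may carry haplotypes.
#'
#' @slot records data.frame with character columns `individual`, `mother`,
#'   `father`; `NA` denotes an unknown parent.
#' @seealso [readPedigree()], [founders()]
#' @export
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
  df <- object@records
  if (!all(c("individual", "mother", "father") %in% colnames(df)))
    return("records must have columns individual, mother, father")
  if (anyDuplicated(df$individual))
    return(sprintf("duplicated individuals: %s",
                   paste(unique(df$individual[duplicated(df$individual)]), collapse = ", ")))
  named <- setdiff(stats::na.omit(c(df$mother, df$father)), df$individual)
  if (length(named))
    return(sprintf("parents not present as individuals: %s",
                   paste(named, collapse = ", ")))
  cyc <- .pedigreeCycle(df)
  if (length(cyc))
    return(sprintf("pedigree contains a cycle: %s", paste(cyc, collapse = " -> ")))
  TRUE
})

# Topological peel; returns members of a cycle (empty if acyclic).
.pedigreeCycle <- function(df) {
  remaining <- df$individual
  parents <- stats::setNames(Map(function(m, f) stats::na.omit(c(m, f)),
                                 df$mother, df$father), df$individual)
  repeat {
    peel <- remaining[vapply(remaining, function(i)
      !any(parents[[i]] %in% remaining), logical(1))]
    if (!length(peel)) break
    remaining <- setdiff(remaining, peel)
    if (!length(remaining)) break
  }
  remaining
}

#' TargetLocus: a locus of interest on the physical map
#'
#' @slot name locus name (e.g. `"Ma"`, `"GD12"`).
#' @slot chromosome chromosome label matching the haploblock map.
#' @slot start,end physical interval in base pairs, 1-based inclusive;
#'   point loci have `start == end`.
#' @export
setClass("TargetLocus",
         representation(name = "character", chromosome = "character",
                        start = "numeric", end = "numeric"))

setValidity("TargetLocus", function(object) {
  if (object@start > object@end) "start must be <= end" else TRUE
})

#' ReferencePanel: historically reported genotypes anchoring allele assignment
#'
#' @slot locus name of the target locus the genotypes refer to.
#' @slot genotypes data.frame with columns `individual`, `allele1`,
#'   `allele2`; `allele2` may be `NA` (unreported second allele, in which
#'   case only one homolog of that individual can be anchored).
#' @seealso [readReferencePanel()], [assignAlleles()]
#' @export
setClass("ReferencePanel",
         representation(locus = "character", genotypes = "data.frame"))

setValidity("ReferencePanel", function(object) {
  df <- object@genotypes
  if (!all(c("individual", "allele1", "allele2") %in% colnames(df)))
    return("genotypes must have columns individual, allele1, allele2")
  if (anyDuplicated(df$individual))
    return(sprintf("duplicated panel individuals: %s",
                   paste(unique(df$individual[duplicated(df$individual)]), collapse = ", ")))
  if (nrow(df) && (anyNA(df$allele1) || any(df$allele1 == "")))
    return("allele1 must be non-empty for every panel individual")
  TRUE
})

#' Placement: a target locus located relative to the haploblock map
#'
#' A locus is either `"within"` a haploblock (its physical interval
#' intersects the haploblock's) or `"between"` two physically adjacent
#' haploblocks. The interpolated genetic position of the locus (cM) is kept
#' for the window-balance rule used during expansion.
#'
#' @slot locus the [TargetLocus-class].
#' @slot kind `"within"` or `"between"`.
#' @slot blocks haploblock id(s): length 1 (within) or 2 (left, right).
#' @slot genPos locus genetic position in cM, linearly interpolated in bp.
#' @export
setClass("Placement",
         representation(locus = "TargetLocus", kind = "character",
                        blocks = "character", genPos = "numeric"))

setValidity("Placement", function(object) {
  if (!object@kind %in% c("within", "between"))
    return("kind must be 'within' or 'between'")
  n <- length(object@blocks)
  if (object@kind == "within" && n != 1L) return("'within' placement needs 1 haploblock")
  if (object@kind == "between" && n != 2L) return("'between' placement needs 2 haploblocks")
  TRUE
})

#' Window: a contiguous run of haploblocks anchored on a placed locus
#'
#' @slot chromosome chromosome label.
#' @slot blocks ordered, map-contiguous haploblock ids; always contains the
#'   anchor haploblock(s).
#' @slot anchor the [Placement-class] the window is centred on.
#' @export
setClass("Window",
         representation(chromosome = "character", blocks = "character",
                        anchor = "Placement"))

#' AlleleMap: the finalized pattern-to-allele dictionary for one locus
#'
#' The product of [assignAlleles()]: each entry associates one extended
#' haplotype pattern over the final window with one locus allele and the
#' ancestral source (individual and homolog) of that pattern. Several
#' patterns may carry the same allele (different ancestral sources), and one
#' pattern may be listed under several sources, but pattern-to-allele is a
#' function. Panel alleles that could not be uniquely associated are kept in
#' `unresolved`, never dropped.
#'
#' @slot locus locus name.
#' @slot window the final [Window-class] shared by all entries.
#' @slot entries data.frame with columns `pattern` (";"-joined codes over
#'   the window), `allele`, `source`, `source_homolog`.
#' @slot unresolved data.frame with columns `individual`, `allele`, `reason`.
#' @export
setClass("AlleleMap",
         representation(locus = "character", window = "Window",
                        entries = "data.frame", unresolved = "data.frame"))

setValidity("AlleleMap", function(object) {
  e <- object@entries
  if (!all(c("pattern", "allele", "source", "source_homolog") %in% colnames(e)))
    return("entries must have columns pattern, allele, source, source_homolog")
  if (nrow(e)) {
    byp <- split(e$allele, e$pattern)
    bad <- names(byp)[vapply(byp, function(a) length(unique(a)) > 1L, logical(1))]
    if (length(bad))
      return(sprintf("pattern mapped to multiple alleles: %s",
                     paste(bad, collapse = "; ")))
  }
  TRUE
})

#' SharedSegment: a maximal run of identical haplotype codes around a locus
#'
#' The result of [sharedRun()]: the maximal contiguous extension, left and
#' right of the anchor window, over which two homologs carry equal,
#' non-missing haplotype codes. `status` is `"shared"` when the anchor
#' matches, `"none"` when any anchor-window code differs, and
#' `"not_evaluable"` when anchor codes are missing on either homolog (a
#' distinct outcome: absence of evidence, not evidence of difference).
#'
#' @slot indA,indB individual identifiers.
#' @slot homA,homB homolog indices (1 or 2).
#' @slot firstBlock,lastBlock haploblock ids delimiting the shared run
#'   (`NA` unless `status == "shared"`).
#' @slot lengthCm shared genetic length: `genEnd(lastBlock) -
#'   genStart(firstBlock)` in cM (`NA` unless shared).
#' @slot status `"shared"`, `"none"` or `"not_evaluable"`.
#' @export
setClass("SharedSegment",
         representation(indA = "character", homA = "integer",
                        indB = "character", homB = "integer",
                        firstBlock = "character", lastBlock = "character",
                        lengthCm = "numeric", status = "character"))

#' ValidationReport: deduced vs independently reported genotypes
#'
#' @slot locus locus name.
#' @slot table per-individual comparison with columns `individual`,
#'   `reported`, `deduced`, `n_deduced`, `n_matched`, `status` (one of
#'   `MATCH`, `PARTIAL`, `MISMATCH`, `UNTESTABLE`).
#' @slot accuracy matched deduced alleles / validatable deduced alleles.
#' @export
setClass("ValidationReport",
         representation(locus = "character", table = "data.frame",
                        accuracy = "numeric"))

#' DeductionSummary: tallies of a deduction run
#'
#' @slot locus locus name.
#' @slot nIndividuals,nHomologs numbers processed (homologs = 2 x
#'   individuals).
#' @slot individualCounts named integer vector: individuals with `two`,
#'   `one` and `zero` deduced alleles.
#' @slot modeCounts named integer vector of homolog counts by outcome
#'   (`PANEL`, `IBD`, `IBS` and the `UNDEDUCED_*` reasons).
#' @slot inventory unassigned-pattern inventory: distinct unmatched
#'   patterns with carrier counts, sorted descending (a prioritization aid
#'   for future DNA testing).
#' @export
setClass("DeductionSummary",
         representation(locus = "character", nIndividuals = "integer",
                        nHomologs = "integer",
                        individualCounts = "integer",
                        modeCounts = "integer",
                        inventory = "data.frame"))

#' SimConfig: study-condition parameters of the pedigree simulator
#'
#' Defaults emulate a pedigree-connected germplasm collection: 50 founders,
#' 4 generations of 28 matings x 4 offspring (~500 individuals), one
#' 100 cM / 40 Mb chromosome tiled by 40 haploblocks, and a hidden biallelic
#' record per founder homolog at a central locus. In `"UNIQUE"` founder mode
#' every founder homolog receives its own haplotype code at every haploblock
#' (so patterns identify founder homologs unambiguously); `"POOLED"` mode
#' draws codes from a small pool per haploblock, creating the
#' identity-by-state ambiguity that exercises window expansion and the
#' shared-length threshold.
#'
#' @slot seed integer RNG seed (base R Mersenne-Twister).
#' @slot nFounders,nGenerations,nMatings,offspringPerMating pedigree shape.
#' @slot nHaploblocks,chromLengthCm,chromLengthBp,chromosome map shape.
#' @slot founderMode `"UNIQUE"` or `"POOLED"`.
#' @slot nCodePool codes per haploblock in POOLED mode.
#' @slot nAllelePool distinct locus alleles in POOLED mode.
#' @slot locusName,locusBp target locus; `locusBp = NA` places the locus at
#'   the genetic midpoint of the central haploblock, where the hidden allele
#'   co-segregates exactly with the block code.
#' @slot missingRate per-cell masking probability applied last.
#' @slot corruptionRate per-individual probability that one reported allele
#'   is replaced by a wrong label.
#' @slot panelGenerations generations (0 = founders) included in the
#'   reference panel.
#' @export
setClass("SimConfig",
         representation(seed = "integer", nFounders = "integer",
                        nGenerations = "integer", nMatings = "integer",
                        offspringPerMating = "integer",
                        nHaploblocks = "integer", chromLengthCm = "numeric",
                        chromLengthBp = "numeric", chromosome = "character",
                        founderMode = "character", nCodePool = "integer",
                        nAllelePool = "integer",
                        locusName = "character", locusBp = "numeric",
                        missingRate = "numeric", corruptionRate = "numeric",
                        panelGenerations = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nFounders < 2L) msgs <- c(msgs, "nFounders must be >= 2")
  for (r in c(missing = object@missingRate, corruption = object@corruptionRate))
    if (r < 0 || r > 1) msgs <- c(msgs, "rates must lie in [0, 1]")
  if (!object@founderMode %in% c("UNIQUE", "POOLED"))
    msgs <- c(msgs, "founderMode must be 'UNIQUE' or 'POOLED'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SimulatedDataset: a ground-truthed synthetic study
#'
#' Everything [simulateDataset()] emits: the core data objects in their
#' native classes plus the hidden truth needed to score every downstream
#' stage. `truth` has one row per (individual, homolog) with the true locus
#' allele, the founder homolog of origin at the locus, and the full
#' transmission chain; `meioses` records the crossover count and positions
#' of every simulated meiosis.
#'
#' @slot map,haplotypes,pedigree,panel the core data objects.
#' @slot locus the simulated [TargetLocus-class].
#' @slot reported truth-derived reported-genotype table (possibly corrupted).
#' @slot truth,meioses truth bookkeeping data.frames.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimulatedDataset",
         representation(map = "HaploblockMap", haplotypes = "HaplotypeSet",
                        pedigree = "Pedigree", panel = "ReferencePanel",
                        locus = "TargetLocus", reported = "data.frame",
                        truth = "data.frame", meioses = "data.frame",
                        config = "SimConfig"))
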