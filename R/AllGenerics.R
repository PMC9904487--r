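## Generics for the accessor surface. Slot access outside the package should
## go through these.

#' @export
setGeneric("hbTable", function(x, ...) standardGeneric("hbTable"))

#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @export
setGeneric("blockIds", function(x, chromosome = NULL) standardGeneric("blockIds"))

#' @export
setGeneric("nHaploblocks", function(x, chromosome = NULL) standardGeneric("nHaploblocks"))

#' @export
setGeneric("snpCounts", function(x) standardGeneric("snpCounts"))

#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @export
setGeneric("homologCodes", function(x, individual, homolog, blocks = NULL)
  standardGeneric("homologCodes"))

#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))

#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @export
setGeneric("parentsOf", function(x, individual) standardGeneric("parentsOf"))

#' @export
setGeneric("childrenOf", function(x, individual) standardGeneric("childrenOf"))

#' @export
setGeneric("sibsOf", function(x, individual) standardGeneric("sibsOf"))

#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))

#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @export
setGeneric("placementKind", function(x) standardGeneric("placementKind"))

#' @export
setGeneric("anchorBlocks", function(x) standardGeneric("anchorBlocks"))

#' @export
setGeneric("locusGenPos", function(x) standardGeneric("locusGenPos"))

#' @export
setGeneric("windowBlocks", function(x) standardGeneric("windowBlocks"))

#' @export
setGeneric("anchor", function(x) standardGeneric("anchor"))

#' @export
setGeneric("alleleEntries", function(x) standardGeneric("alleleEntries"))

#' @export
setGeneric("unresolvedAlleles", function(x) standardGeneric("unresolvedAlleles"))

#' @export
setGeneric("finalWindow", function(x) standardGeneric("finalWindow"))

#' @export
setGeneric("segmentStatus", function(x) standardGeneric("segmentStatus"))

#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @export
setGeneric("segmentBlocks", function(x) standardGeneric("segmentBlocks"))

#' @export
setGeneric("validationTable", function(x) standardGeneric("validationTable"))

#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @export
setGeneric("reportedGenotypes", function(x) standardGeneric("reportedGenotypes"))

#' @export
setGeneric("simComponents", function(x) standardGeneric("simComponents"))
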