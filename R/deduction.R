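## The deduction engine: assign target-locus alleles to every homolog in
## the germplasm from the finalized allele map, via IBD where the pedigree
## allows and thresholded IBS otherwise.

## Core single-homolog deduction. Returns a list with everything needed to
## re-threshold without recomputation.
.deduceOne <- function(individual, homolog, alleleMap, haplotypes, pedigree,
                       map, threshold, panelInds = character(),
                       bridgeMissing = 0L, maxDepth = 10L, oriented = TRUE) {
  w <- finalWindow(alleleMap)
  blocks <- windowBlocks(w)
  out <- list(individual = individual, homolog = as.integer(homolog),
              locus = locusName(alleleMap),
              allele = NA_character_, mode = NA_character_,
              source = NA_character_, shared_cM = NA_real_,
              reason = NA_character_, chain = NA_character_,
              pathLen = NA_integer_)
  key <- .patternKey(.patternCodes(haplotypes, individual, homolog, blocks))
  inPanel <- individual %in% panelInds
  if (is.na(key)) {
    out$mode <- "UNDEDUCED"; out$reason <- "MISSING_DATA"
    return(out)
  }
  e <- alleleEntries(alleleMap)
  hits <- e[!is.na(e$pattern) & e$pattern == key, , drop = FALSE]
  if (!nrow(hits)) {
    out$mode <- "UNDEDUCED"; out$reason <- "UNIQUE_PATTERN"
    return(out)
  }
  allele <- unique(hits$allele)[1L]   # pattern -> allele is a function

  ## candidate sources: prefer IBD reachability, then longest shared run
  cand <- lapply(seq_len(nrow(hits)), function(i) {
    src <- hits$source[i]; sh <- hits$source_homolog[i]
    path <- ibdPath(individual, homolog, src, sh, pedigree, haplotypes, w,
                    map = map, maxDepth = maxDepth, oriented = oriented)
    seg <- sharedRun(individual, homolog, src, sh, w, haplotypes, map,
                     bridgeMissing = bridgeMissing)
    list(source = src, sourceHom = sh, path = path,
         pathLen = if (is.null(path)) NA_integer_ else nrow(path),
         len = if (segmentStatus(seg) == "shared") segmentLength(seg)
               else NA_real_)
  })
  ibd <- Filter(function(x) !is.null(x$path), cand)
  fill <- function(x, mode) {
    out$allele <- allele; out$mode <- mode
    out$source <- x$source; out$shared_cM <- x$len
    if (!is.null(x$path)) {
      out$chain <- paste(x$path$individual, collapse = ";")
      out$pathLen <- x$pathLen
    }
    out
  }
  if (length(ibd)) {
    ## tie-break: shortest pedigree path, then longest shared segment,
    ## then source name
    o <- order(vapply(ibd, `[[`, integer(1), "pathLen"),
               -vapply(ibd, function(x) ifelse(is.na(x$len), -Inf, x$len),
                       numeric(1)),
               vapply(ibd, `[[`, character(1), "source"))
    return(fill(ibd[[o[1L]]], if (inPanel) "PANEL" else "IBD"))
  }
  lens <- vapply(cand, function(x) ifelse(is.na(x$len), -Inf, x$len),
                 numeric(1))
  o <- order(-lens, vapply(cand, `[[`, character(1), "source"))
  best <- cand[[o[1L]]]
  if (inPanel) return(fill(best, "PANEL"))
  if (!is.na(best$len) && best$len >= threshold) return(fill(best, "IBS"))
  out$mode <- "UNDEDUCED"; out$reason <- "BELOW_THRESHOLD"
  out$source <- best$source; out$shared_cM <- best$len
  out
}

.rowFromOne <- function(x, blocks) {
  data.frame(individual = x$individual, locus = x$locus,
             homolog = x$homolog, allele = x$allele, mode = x$mode,
             source = x$source, shared_cM = x$shared_cM,
             window_first_hb = blocks[1L],
             window_last_hb = blocks[length(blocks)],
             reason = x$reason, ibd_chain = x$chain,
             stringsAsFactors = FALSE)
}

#' Deduce the target-locus allele carried by one homolog
#'
#' The homolog's haplotype pattern over the allele map's final window is
#' looked up among the map entries. A missing-contaminated pattern is
#' undeduced (`MISSING_DATA`); an unmatched pattern is undeduced
#' (`UNIQUE_PATTERN`). Among matching entries, a source reachable by an IBD
#' chain ([ibdPath()]) is preferred (ties: shortest pedigree path, then
#' longest shared segment, then source name); otherwise the source with the
#' longest extended shared haplotype is taken and accepted as IBS only when
#' the shared length reaches the threshold — a short match is rejected
#' (`BELOW_THRESHOLD`), never silently guessed. Homologs of reference-panel
#' individuals are labelled mode `PANEL` so accuracy statistics can exclude
#' them.
#'
#' @param individual,homolog the query homolog.
#' @param alleleMap a finalized [AlleleMap-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @param pedigree a [Pedigree-class].
#' @param map the [HaploblockMap-class].
#' @param threshold IBS acceptance threshold in cM (see [ibsThreshold()]).
#' @param panel optional [ReferencePanel-class] used to label panel rows.
#' @param bridgeMissing,maxDepth,oriented passed to [sharedRun()] and
#'   [ibdPath()].
#' @return one-row data.frame with columns `individual`, `locus`,
#'   `homolog`, `allele`, `mode`, `source`, `shared_cM`,
#'   `window_first_hb`, `window_last_hb`, `reason`, `ibd_chain`.
#' @export
deduceHomolog <- function(individual, homolog, alleleMap, haplotypes,
                          pedigree, map, threshold, panel = NULL,
                          bridgeMissing = 0L, maxDepth = 10L,
                          oriented = TRUE) {
  panelInds <- if (is.null(panel)) character() else individuals(panel)
  x <- .deduceOne(individual, homolog, alleleMap, haplotypes, pedigree, map,
                  threshold, panelInds, bridgeMissing, maxDepth, oriented)
  .rowFromOne(x, windowBlocks(finalWindow(alleleMap)))
}

#' Deduce target-locus genotypes for a set of individuals
#'
#' Runs the two-pass protocol: pass 1 accepts IBD matches only and derives
#' the IBS threshold as the shortest IBD-shared length observed
#' ([ibsThreshold()]); pass 2 additionally accepts IBS matches at or above
#' that threshold. Supplying `threshold` skips the derivation and applies
#' the given value directly.
#'
#' @param inds individuals to process (default: everyone in `haplotypes`).
#' @inheritParams deduceHomolog
#' @param threshold `NULL` (derive automatically) or a cM value.
#' @param defaultThreshold fallback when no IBD deduction exists.
#' @return list with elements `deductions` (data.frame, two rows per
#'   individual), `summary` (a [DeductionSummary-class]) and `threshold`
#'   (the cM value applied).
#' @export
deduceAll <- function(inds = NULL, alleleMap, haplotypes, pedigree, map,
                      threshold = NULL, panel = NULL, bridgeMissing = 0L,
                      maxDepth = 10L, oriented = TRUE,
                      defaultThreshold = 9.4) {
  if (is.null(inds)) inds <- individuals(haplotypes)
  panelInds <- if (is.null(panel)) character() else individuals(panel)
  blocks <- windowBlocks(finalWindow(alleleMap))
  ones <- vector("list", 2L * length(inds))
  k <- 0L
  for (ind in inds) for (h in c(1L, 2L)) {
    k <- k + 1L
    ones[[k]] <- .deduceOne(ind, h, alleleMap, haplotypes, pedigree, map,
                            threshold = Inf, panelInds = panelInds,
                            bridgeMissing = bridgeMissing,
                            maxDepth = maxDepth, oriented = oriented)
  }
  thr <- if (!is.null(threshold)) threshold else {
    pass1 <- data.frame(
      mode = vapply(ones, `[[`, character(1), "mode"),
      shared_cM = vapply(ones, `[[`, numeric(1), "shared_cM"))
    ibsThreshold(pass1, default = defaultThreshold)
  }
  ## pass 2: accept IBS at or above the threshold
  ones <- lapply(ones, function(x) {
    if (identical(x$mode, "UNDEDUCED") &&
        identical(x$reason, "BELOW_THRESHOLD") &&
        !is.na(x$shared_cM) && x$shared_cM >= thr) {
      ## recover the allele for this pattern
      e <- alleleEntries(alleleMap)
      key <- .patternKey(.patternCodes(haplotypes, x$individual, x$homolog,
                                       blocks))
      x$allele <- e$allele[match(key, e$pattern)]
      x$mode <- "IBS"; x$reason <- NA_character_
    }
    x
  })
  ded <- do.call(rbind, lapply(ones, .rowFromOne, blocks = blocks))
  list(deductions = ded,
       summary = .summarize(ded, alleleMap, haplotypes),
       threshold = thr)
}

.summarize <- function(ded, alleleMap, haplotypes) {
  perInd <- tapply(!is.na(ded$allele), ded$individual, sum)
  indCounts <- c(two = sum(perInd == 2L), one = sum(perInd == 1L),
                 zero = sum(perInd == 0L))
  modeLab <- ifelse(ded$mode == "UNDEDUCED",
                    paste0("UNDEDUCED_", ded$reason), ded$mode)
  modeCounts <- table(modeLab)
  inv <- unassignedPatternInventory(ded, haplotypes, finalWindow(alleleMap))
  new("DeductionSummary", locus = locusName(alleleMap),
      nIndividuals = length(perInd), nHomologs = nrow(ded),
      individualCounts = stats::setNames(as.integer(indCounts),
                                         names(indCounts)),
      modeCounts = stats::setNames(as.integer(modeCounts),
                                   names(modeCounts)),
      inventory = inv)
}

setMethod("show", "DeductionSummary", function(object) {
  cat(sprintf("DeductionSummary for %s: %d individuals / %d homologs\n",
              object@locus, object@nIndividuals, object@nHomologs))
  ic <- object@individualCounts
  cat(sprintf("  individuals with 2 / 1 / 0 deduced alleles: %d / %d / %d\n",
              ic[["two"]], ic[["one"]], ic[["zero"]]))
  cat("  homolog outcomes:",
      paste(names(object@modeCounts), object@modeCounts,
            sep = "=", collapse = ", "), "\n")
  if (nrow(object@inventory))
    cat("  unassigned patterns:", nrow(object@inventory), "\n")
})

#' Inventory of unmatched haplotype patterns
#'
#' Distinct patterns among homologs undeduced for reason `UNIQUE_PATTERN`,
#' with carrier counts, sorted descending: the patterns whose functional
#' characterization (DNA testing or QTL analysis of representative
#' carriers) would unlock the most additional deductions.
#'
#' @param deductions a deduction table from [deduceAll()].
#' @param haplotypes a [HaplotypeSet-class].
#' @param window the final [Window-class] of the allele map.
#' @return data.frame with columns `pattern`, `carriers`.
#' @export
unassignedPatternInventory <- function(deductions, haplotypes, window) {
  blocks <- windowBlocks(window)
  un <- deductions[deductions$mode == "UNDEDUCED" &
                   !is.na(deductions$reason) &
                   deductions$reason == "UNIQUE_PATTERN", , drop = FALSE]
  if (!nrow(un))
    return(data.frame(pattern = character(), carriers = integer()))
  keys <- .keysFor(haplotypes, un$individual, un$homolog, blocks)
  tab <- sort(table(keys), decreasing = TRUE)
  data.frame(pattern = names(tab), carriers = as.integer(tab),
             row.names = NULL)
}

#' Cultivar-level genotype view of a deduction table
#'
#' Convenience pivot merging the two homolog rows of each individual into an
#' unordered allele pair; single-allele results are shown as `"allele / -"`.
#'
#' @param deductions a deduction table from [deduceAll()].
#' @return data.frame with columns `individual`, `allele1`, `allele2`,
#'   `genotype`, `n_deduced`.
#' @export
genotypeTable <- function(deductions) {
  split_ <- split(deductions, deductions$individual)
  out <- lapply(names(split_), function(ind) {
    al <- sort(stats::na.omit(split_[[ind]]$allele))
    data.frame(individual = ind,
               allele1 = if (length(al) >= 1L) al[1L] else NA_character_,
               allele2 = if (length(al) >= 2L) al[2L] else NA_character_,
               genotype = if (!length(al)) "- / -"
                          else if (length(al) == 1L) paste(al, "/ -")
                          else paste(al, collapse = " / "),
               n_deduced = length(al))
  })
  do.call(rbind, out)
}

#' Write a deduction table
#'
#' @param deductions a deduction table from [deduceAll()].
#' @param path output TSV path.
#' @export
writeDeductions <- function(deductions, path) .writeTsv(deductions, path)
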