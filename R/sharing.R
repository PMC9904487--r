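## Extended shared-haplotype segments, IBD tracing through the pedigree,
## and the IBS shared-length threshold.

#' Maximal extended shared haplotype around an anchor window
#'
#' Two homologs share a segment when all their haplotype codes over the
#' anchor window are equal and non-missing; the segment is then the maximal
#' contiguous extension left and right of the anchor over which codes remain
#' equal and non-missing. Its length is the genetic distance from
#' `gen_start` of the first shared haploblock to `gen_end` of the last, so
#' that full-chromosome sharing reproduces one constant length per
#' chromosome. Missing data terminate the extension conservatively (no
#' bridging of unobserved regions) unless `bridgeMissing > 0`, which allows
#' skipping up to that many consecutive missing haploblocks per gap.
#'
#' @param a,b individual identifiers.
#' @param homA,homB homolog indices (1 or 2).
#' @param anchorWindow the anchor [Window-class] (must stay inside the run).
#' @param haplotypes a [HaplotypeSet-class].
#' @param map the [HaploblockMap-class].
#' @param bridgeMissing maximum consecutive missing haploblocks to skip when
#'   extending (default 0).
#' @return a [SharedSegment-class]. `status` is `"shared"`, `"none"` (codes
#'   differ inside the anchor window) or `"not_evaluable"` (anchor codes
#'   missing on either homolog — absence of evidence).
#' @export
sharedRun <- function(a, homA, b, homB, anchorWindow, haplotypes, map,
                      bridgeMissing = 0L) {
  cf <- .chromFrame(map, anchorWindow@chromosome)
  blocks <- cf$haploblock
  ca <- .patternCodes(haplotypes, a, homA, blocks)
  cb <- .patternCodes(haplotypes, b, homB, blocks)
  aIdx <- .blockIndex(cf, windowBlocks(anchorWindow))
  res <- function(status, first = NA_character_, last = NA_character_,
                  len = NA_real_)
    new("SharedSegment", indA = a, homA = as.integer(homA), indB = b,
        homB = as.integer(homB), firstBlock = first, lastBlock = last,
        lengthCm = len, status = status)
  anc_a <- ca[aIdx]; anc_b <- cb[aIdx]
  if (anyNA(anc_a) || anyNA(anc_b)) return(res("not_evaluable"))
  if (any(anc_a != anc_b)) return(res("none"))
  ok <- !is.na(ca) & !is.na(cb) & ca == cb
  miss <- is.na(ca) | is.na(cb)
  extend <- function(from, step) {
    last <- from
    i <- from
    budget <- bridgeMissing
    repeat {
      i <- i + step
      if (i < 1L || i > length(blocks)) break
      if (ok[i]) {
        last <- i
        budget <- bridgeMissing
      } else if (miss[i] && budget > 0L) {
        budget <- budget - 1L
      } else break
    }
    last
  }
  first <- extend(aIdx[1L], -1L)
  last <- extend(aIdx[length(aIdx)], 1L)
  res("shared", blocks[first], blocks[last],
      cf$gen_end[last] - cf$gen_start[first])
}

#' Trace an IBD chain from an individual's homolog to an ancestral source
#'
#' Searches ancestor chains in which every member carries the query
#' homolog's anchor-window haplotype pattern and every link is a
#' parent-child relation, returning the shortest qualifying chain to the
#' source (or `NULL`). Only the anchor-window pattern — not the full
#' extended segment — must be preserved along the chain, mirroring
#' pattern-level inheritance rather than whole-chromosome identity.
#'
#' With `oriented = TRUE` (the default, matching the convention that
#' homolog 1 is maternal and homolog 2 paternal) each step follows the
#' parent the carrying homolog was actually inherited from, so every link of
#' the returned chain is transmission-consistent; `oriented = FALSE` relaxes
#' this to any parent carrying the pattern.
#'
#' When an ancestor carries the anchor pattern on both homologs (homozygous
#' by descent at the window) either continuation is a valid carrier chain;
#' if `map` is supplied, the homolog with the longer extended shared
#' haplotype with the descendant homolog is preferred (the transmitted copy
#' normally shares well beyond the anchor), ties going to homolog 1.
#'
#' @param individual,homolog the query homolog.
#' @param source,sourceHomolog the ancestral source homolog to reach;
#'   `sourceHomolog = NA` accepts either source homolog.
#' @param pedigree a [Pedigree-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @param anchorWindow the anchor [Window-class].
#' @param map optional [HaploblockMap-class] enabling the extended-sharing
#'   preference between a carrier's two homologs (see Details).
#' @param maxDepth generation cap on the search (default 10).
#' @param oriented follow homolog orientation (see Details).
#' @return data.frame with columns `individual`, `homolog` — the chain from
#'   the query (first row) to the source (last row) — or `NULL` when no
#'   qualifying chain exists.
#' @export
ibdPath <- function(individual, homolog, source, sourceHomolog,
                    pedigree, haplotypes, anchorWindow, map = NULL,
                    maxDepth = 10L, oriented = TRUE) {
  blocks <- windowBlocks(anchorWindow)
  key <- .patternKey(.patternCodes(haplotypes, individual, homolog, blocks))
  if (is.na(key)) return(NULL)
  carries <- function(ind, hom)
    identical(.patternKey(.patternCodes(haplotypes, ind, hom, blocks)), key)
  ped <- pedigreeTable(pedigree)
  atGoal <- function(ind, hom)
    ind == source && (is.na(sourceHomolog) || hom == sourceHomolog)
  ## BFS over (individual, homolog) carrier states
  start <- list(list(ind = individual, hom = as.integer(homolog),
                     chain = data.frame(individual = individual,
                                        homolog = as.integer(homolog))))
  queue <- start
  seen <- paste(individual, homolog)
  depth <- 0L
  while (length(queue) && depth <= maxDepth) {
    nextQueue <- list()
    for (node in queue) {
      if (atGoal(node$ind, node$hom)) return(node$chain)
      i <- match(node$ind, ped$individual)
      if (is.na(i)) next
      parents <- if (oriented) {
        if (node$hom == 1L) ped$mother[i] else ped$father[i]
      } else c(ped$mother[i], ped$father[i])
      for (p in stats::na.omit(parents)) {
        hps <- c(1L, 2L)
        if (!is.null(map) && carries(p, 1L) && carries(p, 2L)) {
          ## homozygous-by-descent carrier: prefer the homolog sharing the
          ## longer extended haplotype with the descendant homolog
          lens <- vapply(hps, function(hp) {
            seg <- sharedRun(node$ind, node$hom, p, hp, anchorWindow,
                             haplotypes, map)
            if (segmentStatus(seg) == "shared") segmentLength(seg) else -Inf
          }, numeric(1))
          if (lens[2L] > lens[1L]) hps <- c(2L, 1L)
        }
        for (hp in hps) {
          tag <- paste(p, hp)
          if (tag %in% seen || !carries(p, hp)) next
          seen <- c(seen, tag)
          nextQueue[[length(nextQueue) + 1L]] <- list(
            ind = p, hom = hp,
            chain = rbind(node$chain,
                          data.frame(individual = p, homolog = hp)))
        }
      }
    }
    queue <- nextQueue
    depth <- depth + 1L
  }
  NULL
}

#' Derive the IBS acceptance threshold from observed IBD segment lengths
#'
#' Identity-by-state matches carry less certainty than pedigree-traceable
#' identity-by-descent, especially for short segments. The acceptance
#' threshold is therefore the shortest extended shared haplotype observed
#' among the IBD-mode deductions, taken globally across all loci analysed
#' together; IBS matches shorter than this are rejected.
#'
#' @param deductions a deduction table (as returned by [deduceAll()]) with
#'   columns `mode` and `shared_cM`.
#' @param default threshold returned (with a warning) when the table
#'   contains no IBD-mode rows; 9.4 cM, a value typical of dense pedigreed
#'   germplasm, is the shipped default.
#' @return threshold in cM.
#' @export
ibsThreshold <- function(deductions, default = 9.4) {
  len <- deductions$shared_cM[deductions$mode == "IBD" &
                              !is.na(deductions$shared_cM)]
  if (!length(len)) {
    warning("no IBD-mode deductions; using the configured default threshold of ",
            default, " cM")
    return(default)
  }
  min(len)
}
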