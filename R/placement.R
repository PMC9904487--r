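## Locus placement and the expanding haplotype-pattern window.

#' Place a target locus relative to the haploblock map
#'
#' The locus is `"within"` a haploblock if its physical interval intersects
#' that haploblock's interval (partial overlap counts as within), otherwise
#' `"between"` the two physically adjacent haploblocks flanking it. Loci
#' before the first or after the last haploblock of the chromosome are out
#' of coverage: the method needs flanking haplotypes on both sides.
#'
#' The locus's own genetic position, needed by the window-balance rule, is
#' interpolated linearly in bp: within a haploblock between its `gen_start`
#' and `gen_end`, between haploblocks across the physical gap between the
#' left block's `gen_end` and the right block's `gen_start`.
#'
#' @param locus a [TargetLocus-class].
#' @param map a [HaploblockMap-class] containing the locus chromosome.
#' @return a [Placement-class].
#' @examples
#' map <- HaploblockMap(data.frame(
#'   chromosome = "16",
#'   haploblock = c("HB-16-5", "HB-16-6"),
#'   phys_start = c(3003499, 3304530), phys_end = c(3132772, 3349986),
#'   gen_start = c(10.0, 11.5), gen_end = c(11.0, 12.0)))
#' placeLocus(TargetLocus("Ma", "16", 3177899), map)
#' @export
placeLocus <- function(locus, map) {
  cf <- .chromFrame(map, locus@chromosome)
  s <- locus@start; e <- locus@end
  hit <- which(cf$phys_start <= e & cf$phys_end >= s)
  if (length(hit)) {
    i <- hit[1L]
    mid <- (max(s, cf$phys_start[i]) + min(e, cf$phys_end[i])) / 2
    frac <- if (cf$phys_end[i] > cf$phys_start[i])
      (mid - cf$phys_start[i]) / (cf$phys_end[i] - cf$phys_start[i]) else 0.5
    gpos <- cf$gen_start[i] + frac * (cf$gen_end[i] - cf$gen_start[i])
    return(new("Placement", locus = locus, kind = "within",
               blocks = cf$haploblock[i], genPos = gpos))
  }
  if (e < cf$phys_start[1L] || s > cf$phys_end[nrow(cf)])
    stop("locus ", locus@name, " lies outside haploblock coverage of chromosome ",
         locus@chromosome, "; flanking haploblocks are required on both sides")
  left <- max(which(cf$phys_end < s))
  right <- left + 1L
  gap <- cf$phys_start[right] - cf$phys_end[left]
  frac <- if (gap > 0) ((s + e) / 2 - cf$phys_end[left]) / gap else 0.5
  gpos <- cf$gen_end[left] + frac * (cf$gen_start[right] - cf$gen_end[left])
  new("Placement", locus = locus, kind = "between",
      blocks = cf$haploblock[c(left, right)], genPos = gpos)
}

#' Base window of a placed locus
#'
#' One haploblock for a within-placement, the two flanking haploblocks for a
#' between-placement: the smallest haplotype-pattern context a locus allele
#' can be associated with.
#'
#' @param placement a [Placement-class].
#' @param map the [HaploblockMap-class] used for placement.
#' @return a [Window-class] of 1 or 2 haploblocks.
#' @export
baseWindow <- function(placement, map) {
  new("Window", chromosome = placement@locus@chromosome,
      blocks = placement@blocks, anchor = placement)
}

#' Grow a window by one haploblock, keeping the locus centred genetically
#'
#' The window grows by exactly one map-adjacent haploblock per call, choosing
#' the side so that the genetic lengths flanking the locus (cM upstream vs
#' downstream of its interpolated position) are as near-equal as possible
#' after the expansion; this keeps the target locus at the centre of the
#' multi-haploblock cluster, taking the nearest new haploblock first. Ties
#' on imbalance go to the side whose candidate haploblock is physically
#' nearer the locus, then to the left. At a chromosome end growth continues
#' on the open side only.
#'
#' @param window a [Window-class].
#' @param map the [HaploblockMap-class].
#' @return the grown [Window-class].
#' @export
expandWindow <- function(window, map) {
  cf <- .chromFrame(map, window@chromosome)
  idx <- .blockIndex(cf, window@blocks)
  iL <- idx[1L] - 1L
  iR <- idx[length(idx)] + 1L
  canL <- iL >= 1L
  canR <- iR <= nrow(cf)
  if (!canL && !canR)
    stop("window already spans the whole chromosome; cannot expand")
  side <- if (!canL) "right" else if (!canR) "left"
          else .balanceSide(cf, iL, iR, window@anchor@genPos,
                            window@anchor@locus)
  blocks <- if (side == "left") c(cf$haploblock[iL], window@blocks)
            else c(window@blocks, cf$haploblock[iR])
  new("Window", chromosome = window@chromosome, blocks = blocks,
      anchor = window@anchor)
}

## Choose the expansion side: minimal post-expansion |upstream - downstream|
## genetic length around the locus; tie -> physically nearer candidate;
## tie -> left.
.balanceSide <- function(cf, iL, iR, genPos, locus) {
  upL <- genPos - cf$gen_start[iL]        # if expanding left
  downL <- cf$gen_end[iR - 1L] - genPos
  upR <- genPos - cf$gen_start[iL + 1L]   # if expanding right
  downR <- cf$gen_end[iR] - genPos
  imbL <- abs(upL - downL)
  imbR <- abs(upR - downR)
  if (imbL < imbR) return("left")
  if (imbR < imbL) return("right")
  dL <- locus@start - cf$phys_end[iL]
  dR <- cf$phys_start[iR] - locus@end
  if (dR < dL) "right" else "left"
}

#' Genetic span of a window
#'
#' @param window a [Window-class].
#' @param map the [HaploblockMap-class].
#' @return `gen_end` of the last haploblock minus `gen_start` of the first,
#'   in cM.
#' @export
windowSpan <- function(window, map) {
  cf <- .chromFrame(map, window@chromosome)
  idx <- .blockIndex(cf, window@blocks)
  cf$gen_end[idx[length(idx)]] - cf$gen_start[idx[1L]]
}
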