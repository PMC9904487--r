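## Shared fixtures and independent oracles, all built in code.

## A small map with a physical gap between every pair of haploblocks, so
## loci can fall between blocks. Genetic spacing optionally symmetric.
toyMap <- function(n = 7, chrom = "1", cmPerBlock = 2, gapCm = 1,
                   bpPerBlock = 1e6, gapBp = 5e5) {
  i <- seq_len(n)
  s <- (i - 1) * (bpPerBlock + gapBp) + 1
  gs <- (i - 1) * (cmPerBlock + gapCm)
  HaploblockMap(data.frame(
    chromosome = chrom,
    haploblock = sprintf("HB-%s-%d", chrom, i),
    phys_start = s, phys_end = s + bpPerBlock - 1,
    gen_start = gs, gen_end = gs + cmPerBlock))
}

## HaplotypeSet directly from a named list: codes[[ind]] = list(h1, h2),
## each a vector over the map's blocks (NA allowed)
toyHaplotypes <- function(codes, map) {
  rows <- do.call(rbind, lapply(names(codes), function(ind) {
    do.call(rbind, lapply(1:2, function(h) {
      v <- codes[[ind]][[h]]
      ids <- blockIds(map)
      keep <- !is.na(v)
      if (!any(keep)) return(NULL)
      data.frame(individual = ind, haploblock = ids[keep], homolog = h,
                 code = as.character(v[keep]))
    }))
  }))
  HaplotypeSet(rows, map, individuals = names(codes))
}

trioPedigree <- function() {
  Pedigree(data.frame(individual = c("child", "mom", "dad"),
                      mother = c("mom", NA, NA),
                      father = c("dad", NA, NA)))
}

## --- independent oracles -------------------------------------------------

## brute-force maximal contiguous equal run containing the anchor indices
bruteSharedRun <- function(codesA, codesB, anchorIdx) {
  ok <- !is.na(codesA) & !is.na(codesB) & codesA == codesB
  if (!all(ok[anchorIdx])) return(NULL)
  best <- NULL
  n <- length(ok)
  for (i in seq_len(min(anchorIdx))) {
    for (j in seq(max(anchorIdx), n)) {
      if (all(ok[i:j])) {
        if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
      }
    }
  }
  best
}

## brute-force re-derivation of the balanced expansion side, written
## directly from the definition (independent code path)
bruteExpansionSide <- function(df, winIdx, genPos, locusStart, locusEnd) {
  iL <- min(winIdx) - 1; iR <- max(winIdx) + 1
  canL <- iL >= 1; canR <- iR <= nrow(df)
  if (!canL && !canR) return(NULL)
  if (!canL) return("right")
  if (!canR) return("left")
  imb <- function(first, last)
    abs((genPos - df$gen_start[first]) - (df$gen_end[last] - genPos))
  iL_imb <- imb(iL, max(winIdx))
  iR_imb <- imb(min(winIdx), iR)
  if (iL_imb < iR_imb) "left"
  else if (iR_imb < iL_imb) "right"
  else {
    dL <- locusStart - df$phys_end[iL]
    dR <- df$phys_start[iR] - locusEnd
    if (dR < dL) "right" else "left"
  }
}

## small simulation used by several files (fast: ~90 individuals)
smallSim <- function(seed = 42, ...) {
  simulateDataset(SimConfig(seed = seed, nFounders = 10L, nGenerations = 3L,
                            nMatings = 6L, offspringPerMating = 3L,
                            nHaploblocks = 20L, missingRate = 0, ...))
}

## run assignment + deduction on a simulated dataset
runDeduction <- function(sim, threshold = NULL) {
  cmp <- simComponents(sim)
  pl <- placeLocus(cmp$locus, cmp$map)
  am <- suppressWarnings(
    assignAlleles(cmp$panel, cmp$haplotypes, cmp$pedigree, pl, cmp$map))
  res <- suppressWarnings(
    deduceAll(alleleMap = am, haplotypes = cmp$haplotypes,
              pedigree = cmp$pedigree, map = cmp$map,
              threshold = threshold, panel = cmp$panel))
  c(res, list(alleleMap = am, placement = pl, cmp = cmp))
}

truthAlleleOf <- function(sim, inds, homs) {
  tr <- truthTable(sim)
  tr$allele[match(paste(inds, homs), paste(tr$individual, tr$homolog))]
}
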