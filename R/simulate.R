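## Pedigree meiosis simulator: generates phased, haploblocked datasets with
## hidden locus alleles riding on founder homologs, plus the complete
## transmission truth, so every downstream stage can be scored without any
## external data.

#' Construct a simulator configuration
#'
#' See [SimConfig-class] for the meaning and rationale of every parameter.
#' The defaults describe the reference study conditions: 50 founders, 4
#' generations of 28 matings x 4 offspring (~500 individuals), a 100 cM /
#' 40 Mb chromosome tiled by 40 haploblocks, UNIQUE founder codes, a locus
#' at the genetic midpoint of the central haploblock, 2% missing cells and
#' no reported-genotype corruption.
#'
#' @param seed integer RNG seed.
#' @param nFounders,nGenerations,nMatings,offspringPerMating pedigree shape.
#' @param nHaploblocks,chromLengthCm,chromLengthBp,chromosome map shape.
#' @param founderMode `"UNIQUE"` or `"POOLED"`.
#' @param nCodePool,nAllelePool pool sizes for POOLED mode.
#' @param locusName,locusBp target locus (`NA` bp = central midpoint).
#' @param missingRate,corruptionRate data-degradation rates in \[0, 1\].
#' @param panelGenerations generations included in the reference panel
#'   (0 = founders only; default 1 = founders plus first generation, so
#'   pedigree links inside the panel can phase founder homologs).
#' @return a validated [SimConfig-class].
#' @export
SimConfig <- function(seed = 1L, nFounders = 50L, nGenerations = 4L,
                      nMatings = 28L, offspringPerMating = 4L,
                      nHaploblocks = 40L, chromLengthCm = 100,
                      chromLengthBp = 4e7, chromosome = "1",
                      founderMode = c("UNIQUE", "POOLED"),
                      nCodePool = 8L, nAllelePool = 6L,
                      locusName = "SimLocus", locusBp = NA_real_,
                      missingRate = 0.02, corruptionRate = 0,
                      panelGenerations = 1L) {
  new("SimConfig", seed = as.integer(seed), nFounders = as.integer(nFounders),
      nGenerations = as.integer(nGenerations), nMatings = as.integer(nMatings),
      offspringPerMating = as.integer(offspringPerMating),
      nHaploblocks = as.integer(nHaploblocks),
      chromLengthCm = as.numeric(chromLengthCm),
      chromLengthBp = as.numeric(chromLengthBp),
      chromosome = as.character(chromosome),
      founderMode = match.arg(founderMode),
      nCodePool = as.integer(nCodePool), nAllelePool = as.integer(nAllelePool),
      locusName = as.character(locusName), locusBp = as.numeric(locusBp),
      missingRate = as.numeric(missingRate),
      corruptionRate = as.numeric(corruptionRate),
      panelGenerations = as.integer(panelGenerations))
}

#' Simulate a haploblock map
#'
#' `nHaploblocks` contiguous, non-overlapping haploblocks tile the
#' chromosome uniformly in both bp and cM, so genetic positions are
#' monotone with physical positions and the total genetic span equals the
#' configured chromosome length.
#'
#' @param config a [SimConfig-class].
#' @return a [HaploblockMap-class].
#' @export
simulateMap <- function(config) {
  n <- config@nHaploblocks
  bp <- config@chromLengthBp
  cm <- config@chromLengthCm
  i <- seq_len(n)
  HaploblockMap(data.frame(
    chromosome = config@chromosome,
    haploblock = sprintf("HB-%s-%d", config@chromosome, i),
    phys_start = floor((i - 1) * bp / n) + 1,
    phys_end = floor(i * bp / n),
    gen_start = (i - 1) * cm / n,
    gen_end = i * cm / n))
}

## active parental homolog (1/2) at genetic position g, for a meiosis that
## started on `start` with crossovers at `pos`
.activeHomolog <- function(g, start, pos) {
  flips <- vapply(g, function(x) sum(pos <= x), numeric(1))
  as.integer((start - 1 + flips) %% 2 + 1)
}

#' Simulate one meiosis over the haploblock map
#'
#' Crossover count is Poisson with mean equal to the map length in Morgans;
#' crossover positions are uniform on the cM axis (no interference); the
#' starting homolog is a fair coin. Each haploblock of the gamete inherits
#' the code of the parental homolog active at the block's genetic midpoint
#' (haploblocks are historic-recombination units, so a within-block
#' crossover is resolved to one side). Uses the current RNG state.
#'
#' @param parentHomologs 2-row character matrix of haploblock codes (rows =
#'   parental homologs 1 and 2, columns = haploblocks in map order).
#' @param map the [HaploblockMap-class] (single chromosome).
#' @return list with elements `codes` (gamete haploblock codes),
#'   `crossovers` (cM positions), `startHomolog` and `originPerBlock` (the
#'   parental homolog each block came from).
#' @export
simulateMeiosis <- function(parentHomologs, map) {
  cf <- .chromFrame(map, chromosomes(map)[1L])
  g0 <- cf$gen_start[1L]
  g1 <- cf$gen_end[nrow(cf)]
  nCx <- stats::rpois(1L, (g1 - g0) / 100)
  pos <- sort(stats::runif(nCx, g0, g1))
  start <- sample(c(1L, 2L), 1L)
  mids <- (cf$gen_start + cf$gen_end) / 2
  origin <- .activeHomolog(mids, start, pos)
  list(codes = parentHomologs[cbind(origin, seq_along(mids))],
       crossovers = pos, startHomolog = start, originPerBlock = origin)
}

#' Simulate a complete pedigreed, phased, ground-truthed dataset
#'
#' Founders receive haplotype codes (unique per founder homolog in UNIQUE
#' mode, drawn from per-block pools in POOLED mode) and one hidden locus
#' allele per homolog. Generation 1 mates all founders round-robin (so
#' every founder has panel offspring and its homologs can be phased from
#' pedigree links); later generations mate random pairs of the previous
#' generation. Every gamete is produced by [simulateMeiosis()]; homolog 1
#' of each offspring is the maternal gamete. The hidden allele always
#' travels with the founder segment covering the locus genetic position.
#' The reference panel (with truth genotypes) covers founders and the
#' configured early generations; the reported-genotype table is derived
#' from truth with the configured corruption rate; missing-data masking is
#' applied last.
#'
#' @param config a [SimConfig-class].
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(config) {
  set.seed(config@seed)
  map <- simulateMap(config)
  cf <- .chromFrame(map, config@chromosome)
  nB <- nrow(cf)

  locusBp <- config@locusBp
  if (is.na(locusBp)) {
    mid <- ceiling(nB / 2)
    locusBp <- round((cf$phys_start[mid] + cf$phys_end[mid]) / 2)
  }
  locus <- TargetLocus(config@locusName, config@chromosome, locusBp)
  locusGen <- locusGenPos(placeLocus(locus, map))

  founderNames <- sprintf("F%03d", seq_len(config@nFounders))
  ## per-individual state: codes[[ind]] = 2 x nB matrix; allele/chain/origin
  codes <- list(); allele <- list(); chain <- list(); origin <- list()
  for (f in founderNames) {
    if (config@founderMode == "UNIQUE") {
      m <- rbind(rep(paste0(f, ".1"), nB), rep(paste0(f, ".2"), nB))
      al <- c(paste0("a-", f, ".1"), paste0("a-", f, ".2"))
    } else {
      m <- rbind(as.character(sample.int(config@nCodePool, nB, replace = TRUE)),
                 as.character(sample.int(config@nCodePool, nB, replace = TRUE)))
      al <- paste0("A", sample.int(config@nAllelePool, 2L, replace = TRUE))
    }
    codes[[f]] <- m
    allele[[f]] <- al
    chain[[f]] <- list(f, f)
    origin[[f]] <- c(paste0(f, ".1"), paste0(f, ".2"))
  }
  ped <- data.frame(individual = founderNames, mother = NA_character_,
                    father = NA_character_)
  generation <- stats::setNames(rep(0L, length(founderNames)), founderNames)
  meioses <- list()

  prev <- founderNames
  for (g in seq_len(config@nGenerations)) {
    pairs <- if (g == 1L) {
      perm <- sample(founderNames)
      base <- lapply(seq_len(floor(length(perm) / 2)),
                     function(i) perm[c(2L * i - 1L, 2L * i)])
      extra <- max(0L, config@nMatings - length(base))
      c(base[seq_len(min(length(base), config@nMatings))],
        lapply(seq_len(extra), function(i) sample(founderNames, 2L)))
    } else {
      lapply(seq_len(config@nMatings), function(i) sample(prev, 2L))
    }
    newNames <- character()
    for (m in seq_along(pairs)) {
      mo <- pairs[[m]][1L]; fa <- pairs[[m]][2L]
      for (j in seq_len(config@offspringPerMating)) {
        ind <- sprintf("G%d-%02d-%d", g, m, j)
        newNames <- c(newNames, ind)
        gam <- list(simulateMeiosis(codes[[mo]], map),
                    simulateMeiosis(codes[[fa]], map))
        par <- c(mo, fa)
        codes[[ind]] <- rbind(gam[[1L]]$codes, gam[[2L]]$codes)
        allele[[ind]] <- character(2L)
        chain[[ind]] <- list(NULL, NULL)
        origin[[ind]] <- character(2L)
        for (h in c(1L, 2L)) {
          src <- .activeHomolog(locusGen, gam[[h]]$startHomolog,
                                gam[[h]]$crossovers)
          allele[[ind]][h] <- allele[[par[h]]][src]
          chain[[ind]][[h]] <- c(ind, chain[[par[h]]][[src]])
          origin[[ind]][h] <- origin[[par[h]]][src]
          meioses[[length(meioses) + 1L]] <- data.frame(
            child = ind, homolog = h, parent = par[h],
            n_crossovers = length(gam[[h]]$crossovers),
            positions_cm = paste(sprintf("%.4f", gam[[h]]$crossovers),
                                 collapse = ";"))
        }
        ped <- rbind(ped, data.frame(individual = ind, mother = mo,
                                     father = fa))
        generation[ind] <- g
      }
    }
    prev <- newNames
  }

  inds <- ped$individual
  m1 <- t(vapply(inds, function(i) codes[[i]][1L, ], character(nB)))
  m2 <- t(vapply(inds, function(i) codes[[i]][2L, ], character(nB)))
  dimnames(m1) <- dimnames(m2) <- list(inds, cf$haploblock)

  truth <- data.frame(
    individual = rep(inds, each = 2L),
    homolog = rep(c(1L, 2L), length(inds)),
    allele = unlist(lapply(inds, function(i) allele[[i]])),
    founder_homolog = unlist(lapply(inds, function(i) origin[[i]])),
    chain = unlist(lapply(inds, function(i)
      c(paste(chain[[i]][[1L]], collapse = ";"),
        paste(chain[[i]][[2L]], collapse = ";")))),
    generation = rep(unname(generation[inds]), each = 2L))

  panelInds <- inds[generation[inds] <= config@panelGenerations]
  panel <- ReferencePanel(config@locusName, data.frame(
    individual = panelInds,
    allele1 = vapply(panelInds, function(i) allele[[i]][1L], character(1)),
    allele2 = vapply(panelInds, function(i) allele[[i]][2L], character(1))))

  reported <- data.frame(
    individual = inds,
    allele1 = vapply(inds, function(i) allele[[i]][1L], character(1)),
    allele2 = vapply(inds, function(i) allele[[i]][2L], character(1)),
    row.names = NULL)
  if (config@corruptionRate > 0) {
    hitInd <- stats::runif(nrow(reported)) < config@corruptionRate
    for (i in which(hitInd)) {
      slot_ <- sample(c("allele1", "allele2"), 1L)
      reported[i, slot_] <- paste0(reported[i, slot_], "*err")
    }
  }

  if (config@missingRate > 0) {
    m1[stats::runif(length(m1)) < config@missingRate] <- NA_character_
    m2[stats::runif(length(m2)) < config@missingRate] <- NA_character_
  }

  new("SimulatedDataset", map = map,
      haplotypes = new("HaplotypeSet", codes1 = m1, codes2 = m2),
      pedigree = Pedigree(ped), panel = panel, locus = locus,
      reported = reported, truth = truth,
      meioses = do.call(rbind, meioses), config = config)
}

#' Write all components of a simulated dataset as TSV files
#'
#' Emits `map.tsv`, `haplotypes.tsv`, `pedigree.tsv`, `panel.tsv`,
#' `reported.tsv`, `truth.tsv` and `meioses.tsv` in the loader formats, so
#' a full file-based pipeline run can start from them.
#'
#' @param sim a [SimulatedDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cmp <- simComponents(sim)
  paths <- c(map = file.path(dir, "map.tsv"),
             haplotypes = file.path(dir, "haplotypes.tsv"),
             pedigree = file.path(dir, "pedigree.tsv"),
             panel = file.path(dir, "panel.tsv"),
             reported = file.path(dir, "reported.tsv"),
             truth = file.path(dir, "truth.tsv"),
             meioses = file.path(dir, "meioses.tsv"))
  writeHaploblockMap(cmp$map, paths[["map"]])
  writePhasedHaplotypes(cmp$haplotypes, paths[["haplotypes"]])
  writePedigree(cmp$pedigree, paths[["pedigree"]])
  writeReferencePanel(cmp$panel, paths[["panel"]])
  .writeTsv(cmp$reported, paths[["reported"]])
  .writeTsv(cmp$truth, paths[["truth"]])
  .writeTsv(cmp$meioses, paths[["meioses"]])
  invisible(paths)
}
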