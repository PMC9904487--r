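## The pedigree meiosis simulator.

test_that("simulated maps tile the chromosome and satisfy loader invariants", {
  set.seed(88)
  for (rep in 1:100) {
    cfg <- SimConfig(seed = rep, nHaploblocks = sample(5:60, 1),
                     chromLengthCm = runif(1, 40, 200),
                     chromLengthBp = runif(1, 1e7, 8e7))
    map <- simulateMap(cfg)
    df <- hbTable(map)
    expect_identical(nrow(df), cfg@nHaploblocks)
    ## contiguous, non-overlapping bp tiling
    expect_true(all(df$phys_start[-1] == df$phys_end[-nrow(df)] + 1))
    ## total genetic span equals the configured length
    expect_equal(df$gen_end[nrow(df)] - df$gen_start[1], cfg@chromLengthCm)
    ## monotone cM with bp
    expect_true(all(diff(df$gen_start) > 0))
  }
  ## write/read round trip passes validation
  map <- simulateMap(SimConfig())
  p <- withr::local_tempfile(fileext = ".tsv")
  writeHaploblockMap(map, p)
  expect_identical(hbTable(readHaploblockMap(p)), hbTable(map))
})

test_that("a zero-crossover meiosis copies one parental homolog", {
  map <- simulateMap(SimConfig(nHaploblocks = 12))
  parent <- rbind(rep("m", 12), rep("p", 12))
  set.seed(3)
  found <- FALSE
  for (i in 1:50) {
    gam <- simulateMeiosis(parent, map)
    if (length(gam$crossovers) == 0L) {
      found <- TRUE
      expect_identical(unique(gam$codes),
                       if (gam$startHomolog == 1L) "m" else "p")
      expect_identical(unique(gam$originPerBlock), gam$startHomolog)
    } else {
      ## crossovers partition blocks between the two parental homologs
      expect_identical(gam$codes, c("m", "p")[gam$originPerBlock])
    }
  }
  expect_true(found)
})

test_that("crossover counts are Poisson with mean = map length in Morgans", {
  map <- simulateMap(SimConfig(nHaploblocks = 10, chromLengthCm = 100))
  parent <- rbind(rep("m", 10), rep("p", 10))
  set.seed(2024)
  n <- 2000L
  counts <- vapply(seq_len(n),
                   function(i) length(simulateMeiosis(parent, map)$crossovers),
                   numeric(1))
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - 1), 3 * se)
})

test_that("simulated data are Mendelian-consistent and truth-complete", {
  sim <- smallSim(seed = 17)
  cmp <- simComponents(sim)
  hs <- cmp$haplotypes
  ped <- pedigreeTable(cmp$pedigree)
  tr <- truthTable(sim)
  nonF <- ped[!is.na(ped$mother), ]
  for (i in sample(nrow(nonF), 20)) {
    ind <- nonF$individual[i]
    ## homolog 1 cells come from the mother, homolog 2 from the father
    for (h in 1:2) {
      p <- if (h == 1) nonF$mother[i] else nonF$father[i]
      mine <- homologCodes(hs, ind, h)
      pc <- rbind(homologCodes(hs, p, 1), homologCodes(hs, p, 2))
      ok <- is.na(mine) | mine == pc[1, ] | mine == pc[2, ]
      expect_true(all(ok))
      ## the hidden allele is one of that parent's two alleles
      myAl <- tr$allele[tr$individual == ind & tr$homolog == h]
      pAl <- tr$allele[tr$individual == p]
      expect_true(myAl %in% pAl)
      ## the transmission chain walks child -> parent -> ... -> founder
      ch <- strsplit(tr$chain[tr$individual == ind & tr$homolog == h],
                     ";")[[1]]
      expect_identical(ch[1], ind)
      expect_identical(ch[2], p)
      expect_true(ch[length(ch)] %in% founders(cmp$pedigree))
    }
  }
})

test_that("the hidden allele travels with the founder segment covering the locus", {
  sim <- smallSim(seed = 23)
  cmp <- simComponents(sim)
  tr <- truthTable(sim)
  ## in UNIQUE mode the code at the locus block names the founder homolog,
  ## which must agree with the truth's founder-of-origin bookkeeping
  pl <- placeLocus(cmp$locus, cmp$map)
  blk <- anchorBlocks(pl)
  for (i in seq_len(nrow(tr))) {
    code <- homologCodes(cmp$haplotypes, tr$individual[i], tr$homolog[i],
                         blk)[[1]]
    expect_identical(code, tr$founder_homolog[i])
    expect_identical(paste0("a-", code), tr$allele[i])
  }
})

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- SimConfig(seed = 99, nFounders = 8L, nGenerations = 2L,
                   nMatings = 4L, offspringPerMating = 2L,
                   nHaploblocks = 10L, missingRate = 0.05,
                   corruptionRate = 0.2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulatedDataset(simulateDataset(cfg), d1)
  writeSimulatedDataset(simulateDataset(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## and a different seed differs
  d3 <- withr::local_tempdir()
  cfg2 <- SimConfig(seed = 100, nFounders = 8L, nGenerations = 2L,
                    nMatings = 4L, offspringPerMating = 2L,
                    nHaploblocks = 10L, missingRate = 0.05,
                    corruptionRate = 0.2)
  writeSimulatedDataset(simulateDataset(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "haplotypes.tsv")),
                         readLines(file.path(d3, "haplotypes.tsv"))))
})

test_that("reported-genotype corruption hits close to its configured rate", {
  cfg <- SimConfig(seed = 55, nFounders = 20L, nGenerations = 3L,
                   nMatings = 10L, offspringPerMating = 4L,
                   nHaploblocks = 15L, missingRate = 0,
                   corruptionRate = 0.3)
  sim <- simulateDataset(cfg)
  rep_ <- reportedGenotypes(sim)
  tr <- truthTable(sim)
  truthGeno <- cbind(tr$allele[tr$homolog == 1], tr$allele[tr$homolog == 2])
  corrupted <- rep_$allele1 != truthGeno[, 1] | rep_$allele2 != truthGeno[, 2]
  m <- nrow(rep_)
  ## binomial expectation within 4 sd
  expect_lt(abs(sum(corrupted) - 0.3 * m), 4 * sqrt(m * 0.3 * 0.7) + 1)
  ## a corrupted genotype has exactly one wrong-label allele, an intact one
  ## has none
  nErr <- grepl("\\*err$", rep_$allele1) + grepl("\\*err$", rep_$allele2)
  expect_true(all(nErr[corrupted] == 1L))
  expect_true(all(nErr[!corrupted] == 0L))
})

test_that("POOLED founder mode produces code collisions (IBS ambiguity exists)", {
  sim <- simulateDataset(SimConfig(seed = 77, nFounders = 12L,
                                   nGenerations = 2L, nMatings = 6L,
                                   offspringPerMating = 2L,
                                   nHaploblocks = 12L,
                                   founderMode = "POOLED", nCodePool = 4L,
                                   nAllelePool = 3L, missingRate = 0))
  cmp <- simComponents(sim)
  pl <- placeLocus(cmp$locus, cmp$map)
  blk <- anchorBlocks(pl)
  f <- founders(cmp$pedigree)
  codes <- c(vapply(f, function(i) homologCodes(cmp$haplotypes, i, 1, blk)[[1]],
                    character(1)),
             vapply(f, function(i) homologCodes(cmp$haplotypes, i, 2, blk)[[1]],
                    character(1)))
  expect_gt(max(table(codes)), 1)   # at least one collision among founders
})
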