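## The deduction engine: IBD preference, the IBS threshold contract,
## panel self-consistency, inventories and determinism.

## hand-built fixture: one homozygous panel source S, a pedigree-connected
## descendant D, and unrelated individuals sharing runs of graded lengths
thresholdFixture <- function() {
  map <- toyMap(n = 9, cmPerBlock = 2, gapCm = 1)   # blocks at 3 cM pitch
  src <- as.character(1:9)
  ## anchor will be blocks 5 (within-block locus)
  mkShare <- function(from, to) {
    v <- rep("z", 9); v[from:to] <- src[from:to]; v
  }
  hs <- toyHaplotypes(list(
    S = list(src, src),
    D = list(src, rep("y", 9)),                  # child of S, intact homolog
    X1 = list(mkShare(4, 6), rep("x", 9)),       # 3 blocks: 8 cM
    X2 = list(mkShare(3, 7), rep("w", 9)),       # 5 blocks: 14 cM
    X3 = list(mkShare(5, 5), rep("v", 9))),      # 1 block: 2 cM
    map)
  ped <- Pedigree(data.frame(
    individual = c("S", "UP", "D", "X1", "X2", "X3"),
    mother = c(NA, NA, "S", NA, NA, NA),
    father = c(NA, NA, "UP", NA, NA, NA)))
  panel <- ReferencePanel("T", data.frame(individual = "S", allele1 = "A",
                                          allele2 = "A"))
  df <- hbTable(map)
  pl <- placeLocus(TargetLocus("T", "1",
                               round((df$phys_start[5] + df$phys_end[5]) / 2)),
                   map)
  list(map = map, hs = hs, ped = ped, panel = panel, pl = pl)
}

test_that("IBS matches below the derived threshold are rejected, above accepted", {
  f <- thresholdFixture()
  am <- assignAlleles(f$panel, f$hs, f$ped, f$pl, f$map)
  res <- deduceAll(alleleMap = am, haplotypes = f$hs, pedigree = f$ped,
                   map = f$map, panel = f$panel)
  d <- res$deductions
  ## D shares the whole chromosome via IBD; that run (26 cM) sets the
  ## threshold
  dd <- d[d$individual == "D" & d$homolog == 1, ]
  expect_identical(dd$mode, "IBD")
  expect_identical(res$threshold, dd$shared_cM)
  ## every planted IBS match is shorter than the threshold: all rejected,
  ## with the reason recorded, never a silent guess
  for (x in c("X1", "X2", "X3")) {
    r <- d[d$individual == x & d$homolog == 1, ]
    expect_identical(r$mode, "UNDEDUCED")
    expect_identical(r$reason, "BELOW_THRESHOLD")
    expect_true(is.na(r$allele))
  }
  ## with an explicit threshold of 9.4 cM, exactly the matches straddling
  ## it flip: X2 (14 cM) accepted, X1 (8 cM) and X3 (2 cM) rejected
  res2 <- deduceAll(alleleMap = am, haplotypes = f$hs, pedigree = f$ped,
                    map = f$map, panel = f$panel, threshold = 9.4)
  d2 <- res2$deductions
  expect_identical(d2$mode[d2$individual == "X2" & d2$homolog == 1], "IBS")
  expect_identical(d2$allele[d2$individual == "X2" & d2$homolog == 1], "A")
  expect_identical(d2$reason[d2$individual == "X1" & d2$homolog == 1],
                   "BELOW_THRESHOLD")
  expect_identical(d2$reason[d2$individual == "X3" & d2$homolog == 1],
                   "BELOW_THRESHOLD")
  ## invariant: every IBS row satisfies length >= threshold
  ibs <- d2[d2$mode == "IBS", ]
  expect_true(all(ibs$shared_cM >= 9.4))
})

test_that("panel individuals recover their own panel genotypes", {
  sim <- smallSim(seed = 9)
  res <- runDeduction(sim)
  d <- res$deductions
  g <- panelTable(simComponents(sim)$panel)
  u <- unresolvedAlleles(res$alleleMap)
  for (i in seq_len(nrow(g))) {
    mine <- d[d$individual == g$individual[i], ]
    expect_true(all(mine$mode[!is.na(mine$allele)] == "PANEL"))
    ded <- sort(na.omit(mine$allele))
    rep_ <- sort(c(g$allele1[i], g$allele2[i]))
    if (length(ded) == 2L) {
      expect_identical(ded, rep_)
    } else {
      ## partially recovered: the deduced part agrees and every missing
      ## allele is accounted for in the unresolved list
      expect_true(all(ded %in% rep_))
      missing_ <- setdiff(rep_, ded)
      expect_true(all(missing_ %in%
                        u$allele[u$individual == g$individual[i]]))
    }
  }
})

test_that("deduction recovers simulated truth with exact precision", {
  sim <- smallSim(seed = 13)
  res <- runDeduction(sim)
  d <- res$deductions
  tall <- truthAlleleOf(sim, d$individual, d$homolog)
  called <- !is.na(d$allele)
  expect_identical(d$allele[called], tall[called])
  expect_gt(mean(called), 0.8)
  ## fully pedigree-connected germplasm: no IBS calls needed
  expect_identical(sort(unique(d$mode[called])), c("IBD", "PANEL"))
})

test_that("summary tallies conserve counts and the inventory adds up", {
  sim <- smallSim(seed = 13)
  res <- runDeduction(sim)
  d <- res$deductions
  s <- res$summary
  expect_identical(s@nHomologs, nrow(d))
  expect_identical(s@nHomologs, 2L * s@nIndividuals)
  expect_identical(sum(s@individualCounts), s@nIndividuals)
  expect_identical(sum(s@modeCounts), s@nHomologs)
  ## inventory counts sum to the UNIQUE_PATTERN homologs
  nUnique <- sum(d$mode == "UNDEDUCED" & d$reason == "UNIQUE_PATTERN",
                 na.rm = TRUE)
  expect_identical(sum(s@inventory$carriers), nUnique)
})

test_that("planted novel patterns appear in the inventory with their multiplicities", {
  map <- toyMap(n = 5)
  src <- as.character(1:5)
  novel <- function(tag) { v <- src; v[2:4] <- paste0(tag, 2:4); v }
  codes <- list(S = list(src, src))
  ## plant three novel patterns with multiplicities 4 / 2 / 1 on hom 1;
  ## hom 2 carries the panel pattern so only the novelties are unmatched
  k <- 0
  for (m in c(4, 2, 1)) {
    k <- k + 1
    for (j in seq_len(m))
      codes[[paste0("N", k, "_", j)]] <- list(novel(paste0("t", k)), src)
  }
  hs <- toyHaplotypes(codes, map)
  ped <- Pedigree(data.frame(individual = names(codes),
                             mother = NA_character_, father = NA_character_))
  panel <- ReferencePanel("T", data.frame(individual = "S", allele1 = "A",
                                          allele2 = "A"))
  df <- hbTable(map)
  pl <- placeLocus(TargetLocus("T", "1",
                               round((df$phys_start[3] + df$phys_end[3]) / 2)),
                   map)
  am <- assignAlleles(panel, hs, ped, pl, map)
  res <- deduceAll(alleleMap = am, haplotypes = hs, pedigree = ped,
                   map = map, panel = panel, threshold = 9.4)
  inv <- res$summary@inventory
  expect_identical(inv$carriers, c(4L, 2L, 1L))
  ## all homologs deduced -> empty inventory
  res2 <- deduceAll(inds = "S", alleleMap = am, haplotypes = hs,
                    pedigree = ped, map = map, panel = panel,
                    threshold = 9.4)
  expect_identical(nrow(res2$summary@inventory), 0L)
})

test_that("deduction output is deterministic", {
  sim <- smallSim(seed = 21)
  r1 <- runDeduction(sim)
  r2 <- runDeduction(smallSim(seed = 21))
  expect_identical(r1$deductions, r2$deductions)
  expect_identical(r1$threshold, r2$threshold)
  expect_identical(alleleEntries(r1$alleleMap), alleleEntries(r2$alleleMap))
})

test_that("missing window data yields UNDEDUCED(MISSING_DATA)", {
  f <- thresholdFixture()
  am <- assignAlleles(f$panel, f$hs, f$ped, f$pl, f$map)
  ## an individual with no data over the window
  hs2 <- toyHaplotypes(list(S = list(as.character(1:9), as.character(1:9)),
                            Q = list(rep(NA_character_, 9),
                                     rep(NA_character_, 9))), f$map)
  row <- deduceHomolog("Q", 1, am, hs2, f$ped, f$map, threshold = 5)
  expect_identical(row$mode, "UNDEDUCED")
  expect_identical(row$reason, "MISSING_DATA")
})
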