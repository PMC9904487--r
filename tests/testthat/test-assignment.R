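## Allele assignment: homozygote anchoring, heterozygote propagation,
## pedigree phase resolution, conflict-driven window expansion, ancestral
## sources and minimal discriminating windows.

## map with gaps so a locus can sit between blocks 3 and 4
assignMap <- function(n = 7) toyMap(n = n)

placeBetween <- function(map, leftIdx = 3) {
  df <- hbTable(map)
  placeLocus(TargetLocus("T", df$chromosome[1], df$phys_end[leftIdx] + 100),
             map)
}

test_that("a homozygote forces the assignment and propagates to a heterozygote", {
  map <- assignMap()
  ## patterns over blocks 3 and 4 (flanking the locus)
  hap <- function(p, q) c("1", "2", p, q, "5", "6", "7")
  hs <- toyHaplotypes(list(
    AA = list(hap("p", "p"), hap("p", "p")),
    AB = list(hap("p", "p"), hap("q", "q"))), map)
  panel <- ReferencePanel("T", data.frame(
    individual = c("AA", "AB"), allele1 = c("A", "A"), allele2 = c("A", "B")))
  ped <- Pedigree(data.frame(individual = c("AA", "AB"),
                             mother = NA_character_, father = NA_character_))
  am <- assignAlleles(panel, hs, ped, placeBetween(map), map)
  e <- alleleEntries(am)
  expect_identical(sort(unique(e$allele)), c("A", "B"))
  expect_identical(unique(e$allele[e$pattern == "p;p"]), "A")
  expect_identical(unique(e$allele[e$pattern == "q;q"]), "B")
  expect_identical(nrow(unresolvedAlleles(am)), 0L)
  expect_length(windowBlocks(finalWindow(am)), 2L)
})

test_that("identical base patterns with different alleles force window expansion", {
  ## two homozygous sources share the immediate flanking haplotypes and
  ## separate after one extra haploblock per side
  map <- assignMap()
  s1 <- c("1", "2", "p", "q", "5", "6", "7")
  s2 <- c("1", "2", "p", "q", "8", "6", "7")   # differs only at block 5
  hs <- toyHaplotypes(list(S1 = list(s1, s1), S2 = list(s2, s2)), map)
  panel <- ReferencePanel("T", data.frame(
    individual = c("S1", "S2"), allele1 = c("A", "B"), allele2 = c("A", "B")))
  ped <- Pedigree(data.frame(individual = c("S1", "S2"),
                             mother = NA_character_, father = NA_character_))
  am <- assignAlleles(panel, hs, ped, placeBetween(map), map)
  e <- alleleEntries(am)
  ## one extra haploblock per side was needed: window blocks 2..5
  expect_identical(windowBlocks(finalWindow(am)),
                   sprintf("HB-1-%d", 2:5))
  expect_identical(unique(e$allele[e$pattern == "2;p;q;5"]), "A")
  expect_identical(unique(e$allele[e$pattern == "2;p;q;8"]), "B")
  expect_identical(nrow(unresolvedAlleles(am)), 0L)
})

test_that("pedigree links phase a heterozygous panel individual", {
  map <- assignMap()
  hp <- function(p, q) c("1", "2", p, q, "5", "6", "7")
  momH1 <- hp("p", "p"); momH2 <- hp("q", "q")
  dadH1 <- hp("r", "r"); dadH2 <- hp("s", "s")
  ## child is het A/C: maternal homolog matches mom's first pattern
  hs <- toyHaplotypes(list(
    mom = list(momH1, momH2), dad = list(dadH1, dadH2),
    child = list(momH1, dadH2)), map)
  ## mom A/B het, dad C/D het, child A/C: without the pedigree no homozygote
  ## anchors anything; with it, the shared alleles ride the shared patterns
  panel <- ReferencePanel("T", data.frame(
    individual = c("mom", "dad", "child"),
    allele1 = c("A", "C", "A"), allele2 = c("B", "D", "C")))
  ped <- trioPedigree()
  am <- assignAlleles(panel, hs, ped, placeBetween(map), map)
  e <- alleleEntries(am)
  expect_identical(unique(e$allele[e$pattern == "p;p"]), "A")
  expect_identical(unique(e$allele[e$pattern == "q;q"]), "B")
  expect_identical(unique(e$allele[e$pattern == "s;s"]), "C")
  expect_identical(unique(e$allele[e$pattern == "r;r"]), "D")
  expect_identical(nrow(unresolvedAlleles(am)), 0L)
})

test_that("unresolvable alleles are reported, never silently dropped", {
  map <- assignMap()
  hp <- function(p, q) c("1", "2", p, q, "5", "6", "7")
  ## lone heterozygote with no homozygote, no relative: phase is ambiguous
  hs <- toyHaplotypes(list(X = list(hp("p", "p"), hp("q", "q"))), map)
  panel <- ReferencePanel("T", data.frame(individual = "X", allele1 = "A",
                                          allele2 = "B"))
  ped <- Pedigree(data.frame(individual = "X", mother = NA_character_,
                             father = NA_character_))
  am <- assignAlleles(panel, hs, ped, placeBetween(map), map)
  expect_identical(nrow(alleleEntries(am)), 0L)
  u <- unresolvedAlleles(am)
  expect_setequal(u$allele, c("A", "B"))
  expect_true(all(u$reason == "ambiguous_phase"))

  ## empty panel: nothing assignable, nothing fatal
  empty <- ReferencePanel("T", data.frame(individual = character(),
                                          allele1 = character(),
                                          allele2 = character()))
  am0 <- assignAlleles(empty, hs, ped, placeBetween(map), map)
  expect_identical(nrow(alleleEntries(am0)), 0L)
  expect_identical(nrow(unresolvedAlleles(am0)), 0L)
})

test_that("assignment recovers the simulator's allele-on-homolog truth", {
  sim <- smallSim(seed = 3)
  cmp <- simComponents(sim)
  pl <- placeLocus(cmp$locus, cmp$map)
  am <- suppressWarnings(
    assignAlleles(cmp$panel, cmp$haplotypes, cmp$pedigree, pl, cmp$map))
  e <- alleleEntries(am)
  tr <- truthTable(sim)
  blocks <- windowBlocks(finalWindow(am))
  ## every entry's allele equals the truth allele of any panel carrier of
  ## that pattern
  for (i in seq_len(nrow(e))) {
    carriers <- haploseer:::.carriersOf(cmp$haplotypes, e$pattern[i], blocks)
    carriers <- carriers[carriers$individual %in% individuals(cmp$panel), ]
    truthAl <- tr$allele[match(paste(carriers$individual, carriers$homolog),
                               paste(tr$individual, tr$homolog))]
    expect_true(all(truthAl == e$allele[i]))
  }
  ## idempotence: re-assigning from the sources' own genotypes reproduces
  ## the same pattern->allele function
  srcGeno <- do.call(rbind, lapply(split(e, e$source), function(s) {
    al <- sort(tapply(s$allele, s$source_homolog, unique))
    data.frame(individual = s$source[1],
               allele1 = al[1], allele2 = if (length(al) > 1) al[2] else al[1])
  }))
  panel2 <- ReferencePanel("SimLocus", srcGeno)
  am2 <- suppressWarnings(
    assignAlleles(panel2, cmp$haplotypes, cmp$pedigree, pl, cmp$map))
  e2 <- alleleEntries(am2)
  common <- intersect(e$pattern, e2$pattern)
  expect_identical(e2$allele[match(common, e2$pattern)],
                   e$allele[match(common, e$pattern)])
})

test_that("ancestral sources are the earliest carriers up unbroken chains", {
  sim <- smallSim(seed = 3)
  res <- runDeduction(sim)
  e <- alleleEntries(res$alleleMap)
  tr <- truthTable(sim)
  ## with UNIQUE founder codes and no masking every source is the founder
  ## homolog that owns the pattern
  expect_true(all(grepl("^F", e$source)))
  expect_identical(paste0(e$source, ".", e$source_homolog),
                   tr$founder_homolog[match(paste(e$source, e$source_homolog),
                                            paste(tr$individual, tr$homolog))])
  ## a founder carrying a unique pattern is its own source
  cmp <- simComponents(sim)
  w <- finalWindow(res$alleleMap)
  f <- e$source[1]
  src <- findAncestralSource(e$pattern[1], w, cmp$pedigree, cmp$haplotypes)
  expect_identical(src$individual, f)
})

test_that("minimal discriminating windows match exhaustive enumeration", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(7:11, 1)
    map <- toyMap(n = n)
    df <- hbTable(map)
    k <- sample(2:(n - 2), 1)
    pl <- placeLocus(TargetLocus("T", "1", df$phys_end[k] + 100), map)
    ## three homologs equal on the base window, diverging randomly outside
    base <- as.character(sample(1:3, n, replace = TRUE))
    mk <- function() {
      v <- base
      out <- sample(setdiff(seq_len(n), c(k, k + 1)), sample(1:3, 1))
      v[out] <- as.character(sample(4:9, length(out), replace = TRUE))
      v
    }
    hs <- toyHaplotypes(list(S1 = list(mk(), rep("z", n)),
                             S2 = list(mk(), rep("z", n)),
                             S3 = list(mk(), rep("z", n))), map)
    sources <- data.frame(individual = c("S1", "S2", "S3"), homolog = 1L)
    got <- minimalDiscriminatingWindow(sources, map, cmp <- hs,
                                       placement = pl)
    ## oracle: walk the expansion sequence independently and find the first
    ## window where the source differs from all others
    for (i in 1:3) {
      w <- baseWindow(pl, map)
      found <- NULL
      repeat {
        blocks <- windowBlocks(w)
        pats <- sapply(c("S1", "S2", "S3"), function(s)
          paste(homologCodes(hs, s, 1, blocks), collapse = ";"))
        if (!any(pats[-i] == pats[i])) { found <- blocks; break }
        w <- tryCatch(expandWindow(w, map), error = function(e) NULL)
        if (is.null(w)) break
      }
      if (is.null(found)) {
        expect_false(got$distinguishable[i])
      } else {
        expect_true(got$distinguishable[i])
        expect_identical(got$n_blocks[i], length(found))
        expect_identical(got$first_hb[i], found[1])
        expect_identical(got$last_hb[i], found[length(found)])
      }
    }
  }
})

test_that("sources differing already at the base window keep the base window", {
  map <- toyMap(n = 5)
  hs <- toyHaplotypes(list(S1 = list(as.character(1:5), rep("z", 5)),
                           S2 = list(as.character(6:10), rep("z", 5))), map)
  df <- hbTable(map)
  pl <- placeLocus(TargetLocus("T", "1", df$phys_end[2] + 100), map)
  got <- minimalDiscriminatingWindow(
    data.frame(individual = c("S1", "S2"), homolog = 1L), map, hs, pl)
  expect_true(all(got$distinguishable))
  expect_true(all(got$n_blocks == 2L))
})
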