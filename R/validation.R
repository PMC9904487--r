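## Validation: compare deduced genotypes with independently reported
## genotypes and triage mismatches with pedigree evidence.

.alleleMultiset <- function(x) {
  x <- as.character(unlist(x, use.names = FALSE))
  sort(x[!is.na(x)])
}

.matchedCount <- function(d, r) {
  m <- 0L
  for (al in d) {
    i <- match(al, r)
    if (!is.na(i)) { r <- r[-i]; m <- m + 1L }
  }
  m
}

#' Compare deduced genotypes against independently reported genotypes
#'
#' Genotypes are compared as unordered allele multisets. An individual is a
#' `MATCH` when both sides report two alleles and they agree exactly;
#' `PARTIAL` when the smaller multiset (e.g. a single deduced allele) is
#' contained in the larger; `MISMATCH` when any deduced allele cannot be
#' matched; `UNTESTABLE` when either side is empty. Aggregate accuracy is
#' the proportion of matched deduced alleles among validatable deduced
#' alleles (those of individuals with a report).
#'
#' @param deductions a deduction table from [deduceAll()].
#' @param reported data.frame with columns `individual`, `allele1`,
#'   `allele2` (`allele2` may be `NA`).
#' @param excludePanel optional character vector of individuals (e.g. the
#'   reference panel, whose genotypes anchored the allele map) to mark
#'   `UNTESTABLE` rather than let them inflate accuracy.
#' @return a [ValidationReport-class].
#' @export
compareGenotypes <- function(deductions, reported, excludePanel = character()) {
  locus <- unique(deductions$locus)[1L]
  geno <- genotypeTable(deductions)
  inds <- sort(union(geno$individual, reported$individual))
  rows <- lapply(inds, function(ind) {
    d <- .alleleMultiset(geno[geno$individual == ind, c("allele1", "allele2")])
    ri <- match(ind, reported$individual)
    r <- if (is.na(ri)) character()
         else .alleleMultiset(reported[ri, c("allele1", "allele2")])
    m <- .matchedCount(d, r)
    status <- if (ind %in% excludePanel) "UNTESTABLE"
      else if (!length(d) || !length(r)) "UNTESTABLE"
      else if (length(d) == 2L && length(r) == 2L && m == 2L) "MATCH"
      else if (m == min(length(d), length(r))) "PARTIAL"
      else "MISMATCH"
    data.frame(individual = ind,
               reported = if (length(r)) paste(r, collapse = " / ") else NA,
               deduced = if (length(d)) paste(d, collapse = " / ") else NA,
               n_deduced = length(d), n_matched = m, status = status)
  })
  tab <- do.call(rbind, rows)
  testable <- tab$status != "UNTESTABLE"
  denom <- sum(tab$n_deduced[testable])
  acc <- if (denom > 0) sum(tab$n_matched[testable]) / denom else NA_real_
  new("ValidationReport", locus = locus, table = tab, accuracy = acc)
}

#' Pedigree evidence for a mismatching individual
#'
#' For an individual whose deduced genotype mismatches its reported
#' genotype, lists its parents, siblings (sharing at least one named
#' parent) and offspring, and for every homolog pair whether a haplotype is
#' shared across the locus ([sharedRun()]), over what genetic length, and
#' which allele the relative carries on the shared homolog according to the
#' deduction table, together with the relative's reported genotype. A
#' relative sharing a long homolog whose validated allele agrees with the
#' deduction — and not with the report — is the evidence pattern pointing
#' to a reporting error. The function emits evidence, not verdicts.
#'
#' @param individual the mismatching individual.
#' @param deductions a deduction table from [deduceAll()].
#' @param pedigree a [Pedigree-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @param map the [HaploblockMap-class].
#' @param anchorWindow the anchor [Window-class] (the allele map's final
#'   window).
#' @param reported the reported-genotype table used for validation.
#' @param report optional precomputed [ValidationReport-class]; recomputed
#'   otherwise. The individual must have status `MISMATCH`.
#' @return data.frame with columns `relative`, `relation`, `ind_homolog`,
#'   `rel_homolog`, `shared`, `shared_cM`, `relative_allele`,
#'   `relative_reported`.
#' @export
triageMismatch <- function(individual, deductions, pedigree, haplotypes,
                           map, anchorWindow, reported, report = NULL) {
  if (is.null(report)) report <- compareGenotypes(deductions, reported)
  tab <- validationTable(report)
  st <- tab$status[match(individual, tab$individual)]
  if (is.na(st) || st != "MISMATCH")
    stop("individual '", individual, "' does not have status MISMATCH (",
         if (is.na(st)) "not in report" else st, ")")
  mk <- function(v, relation)
    if (length(v)) data.frame(relative = v, relation = relation) else NULL
  rel <- do.call(rbind, c(list(
    mk(as.character(stats::na.omit(unname(parentsOf(pedigree, individual)))),
       "parent"),
    mk(sibsOf(pedigree, individual), "sibling"),
    mk(childrenOf(pedigree, individual), "offspring"))))
  if (is.null(rel))
    rel <- data.frame(relative = character(), relation = character())
  rel <- rel[rel$relative %in% individuals(haplotypes), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rel))) {
    r <- rel$relative[i]
    ri <- match(r, reported$individual)
    rep_ <- if (is.na(ri)) NA_character_
            else paste(.alleleMultiset(reported[ri, c("allele1", "allele2")]),
                       collapse = " / ")
    any_shared <- FALSE
    for (hi in c(1L, 2L)) for (hr in c(1L, 2L)) {
      seg <- sharedRun(individual, hi, r, hr, anchorWindow, haplotypes, map)
      if (segmentStatus(seg) != "shared") next
      any_shared <- TRUE
      da <- deductions$allele[deductions$individual == r &
                              deductions$homolog == hr]
      out[[length(out) + 1L]] <- data.frame(
        relative = r, relation = rel$relation[i], ind_homolog = hi,
        rel_homolog = hr, shared = TRUE, shared_cM = segmentLength(seg),
        relative_allele = if (length(da)) da[1L] else NA_character_,
        relative_reported = rep_)
    }
    if (!any_shared)
      out[[length(out) + 1L]] <- data.frame(
        relative = r, relation = rel$relation[i], ind_homolog = NA_integer_,
        rel_homolog = NA_integer_, shared = FALSE, shared_cM = NA_real_,
        relative_allele = NA_character_, relative_reported = rep_)
  }
  if (!length(out))
    return(data.frame(relative = character(), relation = character(),
                      ind_homolog = integer(), rel_homolog = integer(),
                      shared = logical(), shared_cM = numeric(),
                      relative_allele = character(),
                      relative_reported = character()))
  do.call(rbind, out)
}
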