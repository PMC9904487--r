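## Allele assignment: associate each reference-panel locus allele with a
## unique extended haplotype pattern, then identify the ancestral source of
## each pattern through the pedigree.

#' Assign reference-panel locus alleles to extended haplotype patterns
#'
#' Implements the assignment workflow for one target locus. Starting at the
#' base window (the haploblock containing the locus, or the two flanking
#' it):
#'
#' 1. alleles of homozygous panel individuals are assigned first — both of
#'    their homolog patterns must carry the same allele;
#' 2. heterozygous individuals are resolved by comparison: when an
#'    individual shares an allele and one flanking pattern with an
#'    already-assigned case, that allele goes to the shared pattern and the
#'    individual's other allele to its other pattern;
#' 3. pedigree links among panel individuals break remaining phase
#'    ambiguity: a homolog is matched to its (oriented) parent's homolog
#'    when their patterns agree over the current window, and the single
#'    allele the two reported genotypes share rides that homolog;
#' 4. whenever one pattern ends up associated with more than one distinct
#'    allele, the window is grown by one haploblock (nearest first, locus
#'    kept genetically centred — see [expandWindow()]) and matching restarts
#'    on the larger patterns.
#'
#' The loop terminates when pattern-to-allele is a function or the window
#' cannot expand further; an irreducible conflict at the maximal window is
#' reported through the `unresolved` slot, never silently dropped and never
#' fatal. Patterns containing missing codes match nothing and are never
#' used to merge or split allele classes. Individuals are processed in
#' sorted name order so the result is reproducible.
#'
#' Afterwards each assigned pattern is traced to its ancestral source(s):
#' the earliest known ancestor(s) whose homolog carries the pattern via an
#' unbroken chain of parent-child transmissions from a panel carrier. A
#' pattern reachable from several distinct ultimate ancestors yields one
#' entry per source.
#'
#' @param panel a [ReferencePanel-class] of reported genotypes.
#' @param haplotypes a [HaplotypeSet-class].
#' @param pedigree a [Pedigree-class].
#' @param placement the locus [Placement-class].
#' @param map the [HaploblockMap-class].
#' @param maxBlocks optional cap on the window size in haploblocks.
#' @return an [AlleleMap-class].
#' @export
assignAlleles <- function(panel, haplotypes, pedigree, placement, map,
                          maxBlocks = NULL) {
  window <- baseWindow(placement, map)
  repeat {
    trial <- .tryAssign(panel, haplotypes, pedigree, window)
    if (!trial$conflict) break
    grown <- tryCatch(expandWindow(window, map), error = function(e) NULL)
    if (is.null(grown) ||
        (!is.null(maxBlocks) && length(windowBlocks(grown)) > maxBlocks))
      break
    window <- grown
  }
  .finalizeAlleleMap(panel, haplotypes, pedigree, window, trial)
}

## One matching round at a fixed window. Returns the pattern->alleles
## proposal table, the skipped individuals and whether any pattern drew two
## distinct alleles (a conflict, triggering expansion).
.tryAssign <- function(panel, haplotypes, pedigree, window) {
  blocks <- windowBlocks(window)
  g <- panelTable(panel)
  g <- g[order(g$individual), , drop = FALSE]
  key <- list()
  for (h in c(1L, 2L))
    key[[h]] <- vapply(g$individual, function(i)
      .patternKey(.patternCodes(haplotypes, i, h, blocks)), character(1))
  skipped <- g$individual[is.na(key[[1L]]) & is.na(key[[2L]])]
  if (length(skipped))
    warning("panel individual(s) without usable haplotype data over the window: ",
            paste(skipped, collapse = ", "))

  prop <- new.env(parent = emptyenv())
  propose <- function(k, allele) {
    if (is.na(k) || is.na(allele)) return(invisible(FALSE))
    cur <- prop[[k]]
    if (is.null(cur)) { prop[[k]] <- allele; return(invisible(TRUE)) }
    if (!allele %in% cur) { prop[[k]] <- c(cur, allele); return(invisible(TRUE)) }
    invisible(FALSE)
  }
  assigned <- function(k) {     # unique allele of k, else NA
    if (is.na(k)) return(NA_character_)
    cur <- prop[[k]]
    if (is.null(cur) || length(cur) != 1L) NA_character_ else cur
  }

  ## step 1: homozygotes anchor both homolog patterns
  for (i in seq_len(nrow(g))) {
    if (is.na(g$allele2[i]) || g$allele1[i] != g$allele2[i]) next
    propose(key[[1L]][i], g$allele1[i])
    propose(key[[2L]][i], g$allele1[i])
  }

  ## steps 2 + 3 to fixpoint
  ped <- pedigreeTable(pedigree)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(g))) {
      a <- g$allele1[i]; b <- g$allele2[i]
      k1 <- key[[1L]][i]; k2 <- key[[2L]][i]
      if (!is.na(b) && a == b) next                   # homozygote, done
      if (!is.na(b)) {
        ## heterozygote with both alleles reported
        if (!is.na(k1) && !is.na(k2) && k1 == k2) {
          ## one pattern cannot carry two alleles -> force the conflict
          changed <- propose(k1, a) | changed
          changed <- propose(k1, b) | changed
          next
        }
        for (ord in list(c(k1, k2), c(k2, k1))) {
          known <- assigned(ord[1L])
          if (is.na(known)) next
          if (known %in% c(a, b)) {
            changed <- propose(ord[2L], setdiff(c(a, b), known)[1L]) | changed
          } else {
            ## pattern already carries a third allele: genuine collision
            changed <- propose(ord[1L], a) | changed
          }
        }
        ## step 3: oriented parent with fully reported genotype
        for (h in c(1L, 2L)) {
          kh <- if (h == 1L) k1 else k2
          if (is.na(kh) || !is.na(assigned(kh))) next
          p <- if (h == 1L) ped$mother[match(g$individual[i], ped$individual)]
               else ped$father[match(g$individual[i], ped$individual)]
          if (is.na(p)) next
          j <- match(p, g$individual)
          if (is.na(j) || is.na(g$allele2[j])) next
          shared <- intersect(c(a, b), c(g$allele1[j], g$allele2[j]))
          if (length(shared) != 1L) next
          pk <- c(key[[1L]][j], key[[2L]][j])
          if (!kh %in% pk[!is.na(pk)]) next           # patterns must agree
          changed <- propose(kh, shared) | changed
          other <- if (h == 1L) k2 else k1
          changed <- propose(other, setdiff(c(a, b), shared)[1L]) | changed
        }
      } else {
        ## only one reported allele: it can be placed once the other
        ## homolog's pattern is known to carry something else
        for (ord in list(c(k1, k2), c(k2, k1))) {
          known <- assigned(ord[1L])
          if (!is.na(known) && known != a)
            changed <- propose(ord[2L], a) | changed
        }
      }
    }
    if (!changed) break
  }

  keys <- ls(prop)
  alleles <- lapply(keys, function(k) prop[[k]])
  list(proposals = stats::setNames(alleles, keys),
       conflict = any(lengths(alleles) > 1L),
       skipped = skipped, keys = key, genotypes = g)
}

.finalizeAlleleMap <- function(panel, haplotypes, pedigree, window, trial) {
  props <- trial$proposals
  good <- names(props)[lengths(props) == 1L]
  g <- trial$genotypes
  key <- trial$keys

  entries <- do.call(rbind, c(list(
    data.frame(pattern = character(), allele = character(),
               source = character(), source_homolog = integer())),
    lapply(good, function(k) {
      carriers <- .panelCarriers(g, key, k)
      src <- .ancestralSources(k, windowBlocks(window), pedigree, haplotypes,
                               carriers)
      data.frame(pattern = k, allele = props[[k]],
                 source = src$individual, source_homolog = src$homolog)
    })))
  entries <- unique(entries)
  entries <- entries[order(entries$allele, entries$pattern, entries$source), ,
                     drop = FALSE]
  rownames(entries) <- NULL

  ## every panel allele is either mapped or listed unresolved
  unresolved <- data.frame(individual = character(), allele = character(),
                           reason = character())
  for (i in seq_len(nrow(g))) {
    ind <- g$individual[i]
    myKeys <- c(key[[1L]][i], key[[2L]][i])
    myAssigned <- entries$allele[match(myKeys[!is.na(myKeys)], entries$pattern)]
    for (al in unique(stats::na.omit(c(g$allele1[i], g$allele2[i])))) {
      if (al %in% myAssigned) next
      reason <- if (ind %in% trial$skipped) "missing_window_data"
                else if (any(vapply(myKeys[!is.na(myKeys)],
                                    function(k) length(props[[k]]) > 1L &&
                                      al %in% props[[k]], logical(1))))
                  "irreducible_conflict"
                else "ambiguous_phase"
      unresolved <- rbind(unresolved,
                          data.frame(individual = ind, allele = al,
                                     reason = reason))
    }
  }
  new("AlleleMap", locus = locusName(panel), window = window,
      entries = entries, unresolved = unresolved)
}

.panelCarriers <- function(g, key, k) {
  out <- data.frame(individual = character(), homolog = integer())
  for (h in c(1L, 2L)) {
    hit <- !is.na(key[[h]]) & key[[h]] == k
    if (any(hit))
      out <- rbind(out, data.frame(individual = g$individual[hit], homolog = h))
  }
  out
}

## Climb parent links from the given carriers; each distinct ultimate
## carrier (one with no carrying oriented parent) is an ancestral source.
.ancestralSources <- function(key, blocks, pedigree, haplotypes, carriers) {
  ped <- pedigreeTable(pedigree)
  carries <- function(ind, hom)
    identical(.patternKey(.patternCodes(haplotypes, ind, hom, blocks)), key)
  climb <- function(ind, hom, depth = 0L) {
    if (depth > 50L) return(list(ind = ind, hom = hom, len = 0L))
    i <- match(ind, ped$individual)
    p <- if (is.na(i)) NA_character_
         else if (hom == 1L) ped$mother[i] else ped$father[i]
    if (is.na(p)) return(list(ind = ind, hom = hom, len = 0L))
    best <- NULL
    for (hp in c(1L, 2L)) {
      if (!carries(p, hp)) next
      up <- climb(p, hp, depth + 1L)
      up$len <- up$len + 1L
      if (is.null(best) || up$len > best$len) best <- up
    }
    if (is.null(best)) list(ind = ind, hom = hom, len = 0L) else best
  }
  ups <- lapply(seq_len(nrow(carriers)), function(i)
    climb(carriers$individual[i], carriers$homolog[i]))
  if (!length(ups))
    stop("pattern carried by nobody: ", key)
  src <- unique(data.frame(
    individual = vapply(ups, `[[`, character(1), "ind"),
    homolog = vapply(ups, function(u) as.integer(u$hom), integer(1))))
  src[order(src$individual, src$homolog), , drop = FALSE]
}

#' Ancestral source of a haplotype pattern
#'
#' Walks parent links upward from the pattern's carriers; the source is the
#' most ancestral individual whose homolog carries the pattern and is
#' connected to a carrier by an unbroken chain of parent-child
#' transmissions of that pattern. When several distinct ultimate ancestors
#' exist (identity-by-state among sources), the one at the end of the
#' longest transmission chain is returned, ties broken by name.
#'
#' @param pattern a pattern key (`";"`-joined codes) or code vector.
#' @param window the [Window-class] the pattern is defined over.
#' @param pedigree a [Pedigree-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @return list with elements `individual` and `homolog`.
#' @export
findAncestralSource <- function(pattern, window, pedigree, haplotypes) {
  key <- if (length(pattern) > 1L) .patternKey(pattern) else pattern
  blocks <- windowBlocks(window)
  carriers <- .carriersOf(haplotypes, key, blocks)
  if (!nrow(carriers))
    stop("pattern carried by nobody: ", key)
  ## rank ultimate ancestors by chain length from any carrier
  ped <- pedigreeTable(pedigree)
  carries <- function(ind, hom)
    identical(.patternKey(.patternCodes(haplotypes, ind, hom, blocks)), key)
  climb <- function(ind, hom, depth = 0L) {
    i <- match(ind, ped$individual)
    p <- if (is.na(i) || depth > 50L) NA_character_
         else if (hom == 1L) ped$mother[i] else ped$father[i]
    if (is.na(p)) return(list(ind = ind, hom = hom, len = 0L))
    best <- NULL
    for (hp in c(1L, 2L)) {
      if (!carries(p, hp)) next
      up <- climb(p, hp, depth + 1L)
      up$len <- up$len + 1L
      if (is.null(best) || up$len > best$len) best <- up
    }
    if (is.null(best)) list(ind = ind, hom = hom, len = 0L) else best
  }
  ups <- lapply(seq_len(nrow(carriers)), function(i)
    climb(carriers$individual[i], carriers$homolog[i]))
  lens <- vapply(ups, `[[`, integer(1), "len")
  nms <- vapply(ups, `[[`, character(1), "ind")
  pick <- order(-lens, nms)[1L]
  list(individual = ups[[pick]]$ind, homolog = as.integer(ups[[pick]]$hom))
}

#' Smallest discriminating window for each of several identical sources
#'
#' For ancestral-source homologs whose patterns coincide at the base
#' window, grows the window by the same balanced-expansion rule as
#' [expandWindow()] until each source's pattern differs from all the
#' others', and reports the window reached and its genetic span. Sources
#' identical over the whole chromosome are reported as indistinguishable.
#'
#' @param sources data.frame with columns `individual`, `homolog`.
#' @param map the [HaploblockMap-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @param placement the locus [Placement-class].
#' @return data.frame with one row per source: `individual`, `homolog`,
#'   `distinguishable`, `n_blocks`, `first_hb`, `last_hb`, `span_cm`.
#' @export
minimalDiscriminatingWindow <- function(sources, map, haplotypes, placement) {
  if (nrow(sources) < 2L)
    stop("at least two source homologs are required")
  out <- lapply(seq_len(nrow(sources)), function(i) {
    me <- sources[i, ]
    others <- sources[-i, , drop = FALSE]
    w <- baseWindow(placement, map)
    repeat {
      blocks <- windowBlocks(w)
      myKey <- .patternKey(.patternCodes(haplotypes, me$individual,
                                         me$homolog, blocks))
      otherKeys <- .keysFor(haplotypes, others$individual, others$homolog,
                            blocks)
      clash <- !is.na(myKey) & !is.na(otherKeys) & otherKeys == myKey
      if (!any(clash))
        return(data.frame(individual = me$individual, homolog = me$homolog,
                          distinguishable = TRUE,
                          n_blocks = length(blocks),
                          first_hb = blocks[1L],
                          last_hb = blocks[length(blocks)],
                          span_cm = windowSpan(w, map)))
      grown <- tryCatch(expandWindow(w, map), error = function(e) NULL)
      if (is.null(grown))
        return(data.frame(individual = me$individual, homolog = me$homolog,
                          distinguishable = FALSE,
                          n_blocks = NA_integer_, first_hb = NA_character_,
                          last_hb = NA_character_, span_cm = NA_real_))
      w <- grown
    }
  })
  do.call(rbind, out)
}
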