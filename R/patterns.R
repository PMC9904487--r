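## Haplotype patterns: the ordered tuple of haplotype codes carried by one
## homolog over a window of haploblocks. Patterns are matched by exact code
## equality; a pattern containing any missing code matches nothing (missing
## never equals anything, including missing). The canonical key is the
## ";"-joined code string, which is also the file representation; codes may
## therefore not contain ";" themselves.

.patternCodes <- function(haplotypes, individual, homolog, blocks)
  homologCodes(haplotypes, individual, homolog, blocks)

.patternKey <- function(codes) {
  if (anyNA(codes)) NA_character_ else paste(codes, collapse = ";")
}

#' Haplotype pattern of one homolog over a window
#'
#' @param individual individual identifier.
#' @param homolog 1 or 2.
#' @param window a [Window-class].
#' @param haplotypes a [HaplotypeSet-class].
#' @return named character vector of codes over the window haploblocks
#'   (`NA` where data are missing). An all-missing or partially missing
#'   pattern is unusable for matching.
#' @export
patternOf <- function(individual, homolog, window, haplotypes)
  .patternCodes(haplotypes, individual, homolog, windowBlocks(window))

## keys for many (individual, homolog) pairs at once
.keysFor <- function(haplotypes, inds, homs, blocks) {
  vapply(seq_along(inds), function(i)
    .patternKey(.patternCodes(haplotypes, inds[i], homs[i], blocks)),
    character(1))
}

## all (individual, homolog) carriers of a pattern key over blocks
.carriersOf <- function(haplotypes, key, blocks) {
  inds <- individuals(haplotypes)
  out <- lapply(c(1L, 2L), function(h) {
    keys <- vapply(inds, function(i)
      .patternKey(.patternCodes(haplotypes, i, h, blocks)), character(1))
    hit <- !is.na(keys) & keys == key
    data.frame(individual = unname(inds[hit]),
               homolog = rep(h, sum(hit)))
  })
  rbind(out[[1L]], out[[2L]])
}
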