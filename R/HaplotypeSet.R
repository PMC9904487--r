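## HaplotypeSet construction and accessors.

#' Construct a HaplotypeSet from a long-format table
#'
#' @param table data.frame with columns `individual`, `haploblock`,
#'   `homolog` (1 or 2), `code`. Cells not listed are missing.
#' @param map a [HaploblockMap-class]; every `haploblock` must exist in it,
#'   and the matrix columns follow map order.
#' @param individuals optional character vector forcing the row universe
#'   (e.g. pedigree members with no haplotype data); defaults to the
#'   individuals present in `table`.
#' @return a [HaplotypeSet-class].
#' @export
HaplotypeSet <- function(table, map, individuals = NULL) {
  needed <- c("individual", "haploblock", "homolog", "code")
  miss <- setdiff(needed, colnames(table))
  if (length(miss))
    stop("haplotype table is missing column(s): ", paste(miss, collapse = ", "))
  hom <- suppressWarnings(as.integer(table$homolog))
  if (anyNA(hom) || !all(hom %in% c(1L, 2L)))
    stop("homolog must be 1 or 2 for every row")
  ids <- blockIds(map)
  unknown <- setdiff(unique(as.character(table$haploblock)), ids)
  if (length(unknown))
    stop("haploblock id(s) not in the map: ", paste(unknown, collapse = ", "))
  inds <- if (is.null(individuals)) sort(unique(as.character(table$individual)))
          else unique(c(individuals, as.character(table$individual)))
  empty <- matrix(NA_character_, nrow = length(inds), ncol = length(ids),
                  dimnames = list(inds, ids))
  m1 <- empty; m2 <- empty
  ri <- match(as.character(table$individual), inds)
  ci <- match(as.character(table$haploblock), ids)
  code <- as.character(table$code)
  code[!is.na(code) & code == ""] <- NA_character_
  sel1 <- hom == 1L
  m1[cbind(ri[sel1], ci[sel1])] <- code[sel1]
  m2[cbind(ri[!sel1], ci[!sel1])] <- code[!sel1]
  new("HaplotypeSet", codes1 = m1, codes2 = m2)
}

#' @describeIn HaplotypeSet individuals carried by the set
#' @param x a `HaplotypeSet`.
#' @export
setMethod("individuals", "HaplotypeSet", function(x) rownames(x@codes1))

#' Haplotype codes of one homolog
#'
#' @param x a [HaplotypeSet-class].
#' @param individual individual identifier.
#' @param homolog 1 (maternal by convention) or 2 (paternal).
#' @param blocks haploblock ids to extract (default: all, in map order).
#' @return named character vector of codes; `NA` where missing. Individuals
#'   absent from the set yield all-`NA` vectors.
#' @export
setMethod("homologCodes", "HaplotypeSet",
          function(x, individual, homolog, blocks = NULL) {
  m <- if (homolog == 1L) x@codes1 else if (homolog == 2L) x@codes2
       else stop("homolog must be 1 or 2")
  if (is.null(blocks)) blocks <- colnames(m)
  if (individual %in% rownames(m))
    stats::setNames(m[individual, blocks], blocks)
  else
    stats::setNames(rep(NA_character_, length(blocks)), blocks)
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", nrow(object@codes1), "individuals x",
      ncol(object@codes1), "haploblocks x 2 homologs\n")
  miss <- mean(is.na(object@codes1)) / 2 + mean(is.na(object@codes2)) / 2
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
})

## internal: long-format view of all non-missing cells (writer + round trips)
.haplotypesLong <- function(hs) {
  out <- lapply(c(1L, 2L), function(h) {
    m <- if (h == 1L) hs@codes1 else hs@codes2
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(individual = rownames(m)[idx[, 1L]],
               haploblock = colnames(m)[idx[, 2L]],
               homolog = h, code = m[idx], row.names = NULL)
  })
  out <- rbind(out[[1L]], out[[2L]])
  out[order(out$individual, out$haploblock, out$homolog), , drop = FALSE]
}
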