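## HaploblockMap construction and accessors.

#' Construct a HaploblockMap from a haploblock table
#'
#' Rows may arrive in any order; they are sorted by chromosome and physical
#' start. True physical overlaps, or genetic positions that decrease along
#' the physical order, are structural errors (they are never silently
#' reordered away).
#'
#' @param table data.frame with columns `chromosome`, `haploblock`,
#'   `phys_start`, `phys_end`, `gen_start`, `gen_end` and optionally
#'   `snp_ids` (`";"`-joined SNP labels).
#' @return a validated [HaploblockMap-class].
#' @examples
#' map <- HaploblockMap(data.frame(
#'   chromosome = "3", haploblock = c("HB-3-1", "HB-3-2"),
#'   phys_start = c(1, 2e6), phys_end = c(1e6, 3e6),
#'   gen_start = c(0, 5), gen_end = c(4, 9)))
#' nHaploblocks(map)
#' @export
HaploblockMap <- function(table) {
  needed <- c("chromosome", "haploblock", "phys_start", "phys_end",
              "gen_start", "gen_end")
  miss <- setdiff(needed, colnames(table))
  if (length(miss))
    stop("haploblock table is missing column(s): ", paste(miss, collapse = ", "))
  table <- table[order(table$chromosome, table$phys_start), , drop = FALSE]
  snp <- if ("snp_ids" %in% colnames(table)) {
    lapply(table$snp_ids, function(s)
      if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1L]])
  } else rep(list(character()), nrow(table))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(table$chromosome),
    ranges = IRanges::IRanges(start = as.numeric(table$phys_start),
                              end = as.numeric(table$phys_end)))
  names(gr) <- as.character(table$haploblock)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    genStart = as.numeric(table$gen_start),
    genEnd = as.numeric(table$gen_end),
    snpIds = IRanges::CharacterList(snp))
  new("HaploblockMap", ranges = gr)
}

#' Haploblock map as a plain data.frame
#'
#' @param x a [HaploblockMap-class].
#' @param ... unused.
#' @return data.frame with one row per haploblock in map order, columns
#'   `chromosome`, `haploblock`, `phys_start`, `phys_end`, `gen_start`,
#'   `gen_end`, `n_snps`, `snp_ids`.
#' @export
setMethod("hbTable", "HaploblockMap", function(x, ...) {
  gr <- x@ranges
  md <- S4Vectors::mcols(gr)
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    haploblock = names(gr),
    phys_start = GenomicRanges::start(gr),
    phys_end = GenomicRanges::end(gr),
    gen_start = md$genStart,
    gen_end = md$genEnd,
    n_snps = lengths(md$snpIds),
    snp_ids = vapply(md$snpIds, paste, character(1), collapse = ";"),
    row.names = NULL)
})

#' @describeIn hbTable chromosome labels present in the map
#' @export
setMethod("chromosomes", "HaploblockMap", function(x)
  unique(as.character(GenomicRanges::seqnames(x@ranges))))

#' @describeIn hbTable ordered haploblock ids, optionally for one chromosome
#' @export
setMethod("blockIds", "HaploblockMap", function(x, chromosome = NULL) {
  gr <- x@ranges
  if (!is.null(chromosome))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chromosome]
  names(gr)
})

#' @describeIn hbTable haploblock counts (named by chromosome, or one count)
#' @export
setMethod("nHaploblocks", "HaploblockMap", function(x, chromosome = NULL) {
  if (!is.null(chromosome)) return(length(blockIds(x, chromosome)))
  tab <- table(as.character(GenomicRanges::seqnames(x@ranges)))
  stats::setNames(as.integer(tab), names(tab))
})

#' @describeIn hbTable member-SNP counts per chromosome
#' @export
setMethod("snpCounts", "HaploblockMap", function(x) {
  df <- hbTable(x)
  tapply(df$n_snps, df$chromosome, sum)
})

setMethod("show", "HaploblockMap", function(object) {
  n <- nHaploblocks(object)
  cat("HaploblockMap with", sum(n), "haploblocks on",
      length(n), "chromosome(s)\n")
  for (chr in names(n)) {
    df <- hbTable(object)
    df <- df[df$chromosome == chr, ]
    cat(sprintf("  %s: %d haploblocks, %d SNPs, %.1f-%.1f cM\n",
                chr, n[[chr]], sum(df$n_snps),
                min(df$gen_start), max(df$gen_end)))
  }
})

## internal: per-chromosome lookup used throughout placement / sharing
.chromFrame <- function(map, chromosome) {
  df <- hbTable(map)
  df <- df[df$chromosome == chromosome, , drop = FALSE]
  if (!nrow(df)) stop("chromosome '", chromosome, "' not present in the map")
  rownames(df) <- df$haploblock
  df
}

.blockIndex <- function(chromFrame, blocks) {
  i <- match(blocks, chromFrame$haploblock)
  if (anyNA(i))
    stop("haploblock(s) not on this chromosome: ",
         paste(blocks[is.na(i)], collapse = ", "))
  i
}
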