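## Pedigree construction and kinship accessors.

#' Construct a Pedigree
#'
#' Parents that are named but not listed as individuals are auto-created as
#' founder records, so a bare trio table is sufficient. Unknown parents are
#' `NA`. Placeholder individuals (e.g. `"UP_Delicious"` for an unnamed
#' parent) are ordinary individuals and may carry haplotypes.
#'
#' @param table data.frame with columns `individual`, `mother`, `father`
#'   (`NA` or `""` = unknown).
#' @return a validated, acyclic [Pedigree-class].
#' @export
Pedigree <- function(table) {
  needed <- c("individual", "mother", "father")
  miss <- setdiff(needed, colnames(table))
  if (length(miss))
    stop("pedigree table is missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(individual = as.character(table$individual),
                   mother = as.character(table$mother),
                   father = as.character(table$father),
                   stringsAsFactors = FALSE)
  df$mother[!is.na(df$mother) & df$mother == ""] <- NA_character_
  df$father[!is.na(df$father) & df$father == ""] <- NA_character_
  extra <- setdiff(stats::na.omit(c(df$mother, df$father)), df$individual)
  if (length(extra))
    df <- rbind(df, data.frame(individual = extra, mother = NA_character_,
                               father = NA_character_))
  rownames(df) <- NULL
  new("Pedigree", records = df)
}

#' @describeIn Pedigree the records data.frame
#' @param x a `Pedigree`.
#' @export
setMethod("pedigreeTable", "Pedigree", function(x) x@records)

#' @describeIn Pedigree all individuals
#' @export
setMethod("individuals", "Pedigree", function(x) x@records$individual)

#' @describeIn Pedigree individuals with both parents unknown
#' @export
setMethod("founders", "Pedigree", function(x) {
  df <- x@records
  df$individual[is.na(df$mother) & is.na(df$father)]
})

#' @describeIn Pedigree named vector `c(mother = ..., father = ...)` (`NA`
#'   for unknown); errors if the individual is not in the pedigree
#' @param individual individual identifier.
#' @export
setMethod("parentsOf", "Pedigree", function(x, individual) {
  df <- x@records
  i <- match(individual, df$individual)
  if (is.na(i)) stop("individual '", individual, "' not in the pedigree")
  c(mother = df$mother[i], father = df$father[i])
})

#' @describeIn Pedigree individuals having `individual` as a parent
#' @export
setMethod("childrenOf", "Pedigree", function(x, individual) {
  df <- x@records
  df$individual[(!is.na(df$mother) & df$mother == individual) |
                (!is.na(df$father) & df$father == individual)]
})

#' @describeIn Pedigree individuals sharing at least one named parent
#'   (half-sibs included)
#' @export
setMethod("sibsOf", "Pedigree", function(x, individual) {
  p <- stats::na.omit(parentsOf(x, individual))
  if (!length(p)) return(character())
  sibs <- unique(unlist(lapply(p, childrenOf, x = x)))
  setdiff(sibs, individual)
})

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree:", nrow(object@records), "individuals,",
      length(founders(object)), "founders\n")
})

## internal: a topological order (founders first); the validity method
## guarantees one exists
.topoOrder <- function(ped) {
  df <- ped@records
  placed <- character()
  remaining <- df$individual
  while (length(remaining)) {
    i <- match(remaining, df$individual)
    ready <- remaining[
      (is.na(df$mother[i]) | df$mother[i] %in% placed | !(df$mother[i] %in% remaining)) &
      (is.na(df$father[i]) | df$father[i] %in% placed | !(df$father[i] %in% remaining))]
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}
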