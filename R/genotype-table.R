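#' Marker genotype table for an F2 population
#'
#' A `genotype_table` holds per-plant calls at an ordered set of marker
#' loci.  Codominant loci distinguish all three F2 genotypes and carry
#' calls in `{AA, AB, BB, NA}`; dominant loci collapse the heterozygote and
#' the dominant homozygote and carry calls in `{A-, BB, NA}`.  Allele `A`
#' is by convention the allele of the tall parent and `B` that of the
#' dwarf parent, but nothing downstream depends on the labels.
#'
#' @param calls character matrix, plants x loci, entries in
#'   `{"AA","AB","BB","A-",NA}`.  Row names (or `plant_id`) identify plants.
#' @param modes character vector, one of `"codominant"`/`"dominant"` per
#'   locus (recycled if length 1).
#' @param plant_id optional plant identifiers (default: rownames or 1..n).
#' @param pos_cM optional numeric vector of map positions for the loci.
#' @return an object of class `genotype_table`: a list with elements
#'   `calls` (matrix), `loci` (data.frame: locus, mode, pos_cM),
#'   `plant_id`.
#' @export
genotype_table <- function(calls, modes, plant_id = NULL, pos_cM = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  if (is.null(plant_id)) {
    plant_id <- rownames(calls)
    if (is.null(plant_id)) plant_id <- as.character(seq_len(nrow(calls)))
  }
  plant_id <- as.character(plant_id)
  if (anyDuplicated(plant_id))
    stop("duplicate plant ids: ",
         paste(unique(plant_id[duplicated(plant_id)]), collapse = ", "))
  rownames(calls) <- plant_id
  modes <- rep_len(match.arg(modes, c("codominant", "dominant"),
                             several.ok = TRUE), ncol(calls))
  if (is.null(pos_cM)) pos_cM <- rep(NA_real_, ncol(calls))

  ok_cod <- c("AA", "AB", "BB")
  ok_dom <- c("A-", "BB")
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j]
    ok <- if (modes[j] == "dominant") ok_dom else ok_cod
    bad <- which(!is.na(v) & !(v %in% ok))
    if (length(bad))
      stop(sprintf("invalid call '%s' at locus %s (%s), plant %s",
                   v[bad[1]], colnames(calls)[j], modes[j],
                   plant_id[bad[1]]))
  }
  structure(list(calls = calls,
                 loci = data.frame(locus = colnames(calls), mode = modes,
                                   pos_cM = pos_cM,
                                   stringsAsFactors = FALSE),
                 plant_id = plant_id),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d plants x %d loci (%d dominant)\n",
              nrow(x$calls), ncol(x$calls), sum(x$loci$mode == "dominant")))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

locus_index <- function(table, locus) {
  i <- match(locus, table$loci$locus)
  if (is.na(i)) stop("locus not present in table: ", locus)
  i
}

#' Restrict a genotype table to a subset of plants
#'
#' @param table a [genotype_table()].
#' @param plants plant ids or logical/integer index.
#' @return a `genotype_table` with the selected plants.
#' @export
subset_plants <- function(table, plants) {
  if (is.character(plants)) {
    idx <- match(plants, table$plant_id)
    if (anyNA(idx)) stop("unknown plant id(s): ",
                         paste(plants[is.na(idx)], collapse = ", "))
  } else idx <- plants
  genotype_table(table$calls[idx, , drop = FALSE], table$loci$mode,
                 plant_id = table$plant_id[idx], pos_cM = table$loci$pos_cM)
}
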