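#' Allele matrix of tall and dwarf inbred panels
#'
#' @param alleles character matrix, lines x loci; arbitrary allele labels,
#'   `"ND"` (or NA) for missing data.  Loci must be ordered consistently
#'   with the linkage map (distal to proximal).
#' @param class character vector over lines, `"tall"` or `"dwarf"`
#'   (>= 1 line per class).
#' @param line_id optional line names (default rownames).
#' @return object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, class, line_id = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "character"
  alleles[alleles == "ND"] <- NA_character_
  class <- match.arg(class, c("tall", "dwarf"), several.ok = TRUE)
  stopifnot(length(class) == nrow(alleles))
  if (!all(c("tall", "dwarf") %in% class))
    stop("need at least one line per class")
  if (is.null(line_id)) {
    line_id <- rownames(alleles)
    if (is.null(line_id)) line_id <- paste0("L", seq_len(nrow(alleles)))
  }
  rownames(alleles) <- line_id
  if (is.null(colnames(alleles)))
    colnames(alleles) <- paste0("locus", seq_len(ncol(alleles)))
  structure(list(alleles = alleles, class = class, line_id = line_id),
            class = "haplotype_matrix")
}

#' Assess whether one locus discriminates the dwarf from the tall class
#'
#' The dwarf class defines the target allele: the locus is
#' \describe{
#'  \item{discriminating}{all non-missing dwarf alleles identical and no
#'    non-missing tall line carries that allele;}
#'  \item{exception}{dwarfs uniform, at most `max_exceptions` tall lines
#'    carry the dwarf allele (the others differ);}
#'  \item{broken}{dwarfs non-uniform, or more than `max_exceptions` tall
#'    lines share the dwarf allele;}
#'  \item{uninformative}{all calls missing in one class.}
#' }
#' Missing calls are ignored, never imputed.
#'
#' @param tall,dwarf character vectors of allele calls (NA / "ND" missing).
#' @param max_exceptions tolerated tall lines sharing the dwarf allele.
#' @param locus locus name carried through to the verdict.
#' @return list (`locus_verdict`): `locus`, `status`, `dwarf_allele`,
#'   `exception_lines` (indices or names of tall lines sharing the allele).
#' @export
assess_locus <- function(tall, dwarf, max_exceptions = 1, locus = NA) {
  tall[tall %in% "ND"] <- NA
  dwarf[dwarf %in% "ND"] <- NA
  if (!length(tall) || !length(dwarf)) stop("column must be nonempty")
  verdict <- function(status, allele = NA_character_, exc = character())
    structure(list(locus = locus, status = status, dwarf_allele = allele,
                   exception_lines = exc), class = "locus_verdict")
  t_ok <- !is.na(tall); d_ok <- !is.na(dwarf)
  if (!any(t_ok) || !any(d_ok)) return(verdict("uninformative"))
  d_alleles <- unique(dwarf[d_ok])
  if (length(d_alleles) > 1) return(verdict("broken"))
  a <- d_alleles
  sharers <- which(t_ok & tall == a)
  nm <- if (!is.null(names(tall))) names(tall)[sharers] else
    as.character(sharers)
  if (length(sharers) == 0) return(verdict("discriminating", a))
  if (length(sharers) <= max_exceptions) return(verdict("exception", a, nm))
  verdict("broken", a, nm)
}

#' Scan all loci of a haplotype matrix
#'
#' @param matrix a [haplotype_matrix()].
#' @inheritParams assess_locus
#' @return data.frame with one row per locus: `locus`, `status`,
#'   `dwarf_allele`, `exception_lines` (comma-separated).
#' @export
scan_loci <- function(matrix, max_exceptions = 1) {
  stopifnot(inherits(matrix, "haplotype_matrix"))
  tall <- matrix$alleles[matrix$class == "tall", , drop = FALSE]
  dwarf <- matrix$alleles[matrix$class == "dwarf", , drop = FALSE]
  rows <- lapply(colnames(matrix$alleles), function(lc) {
    v <- assess_locus(stats::setNames(tall[, lc], rownames(tall)),
                      dwarf[, lc], max_exceptions, locus = lc)
    data.frame(locus = lc, status = v$status,
               dwarf_allele = v$dwarf_allele,
               exception_lines = paste(v$exception_lines, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Delineate the maximal haplotype block discriminating dwarf from tall
#'
#' Scans loci in map order and grows the maximal contiguous run of
#' discriminating / exception loci (uninformative loci neither extend nor
#' break a run).  Two rules terminate a run: a stretch of `break_run`
#' consecutive broken loci, or an exception that would exceed a tall
#' line's exception budget --- within one block each tall line may carry
#' the dwarf allele at no more than `max_exceptions` loci, so a line
#' sharing the dwarf allele repeatedly (a real introgressed or ancestral
#' haplotype rather than allele-size homoplasy) closes the block.  The
#' boundary on each side is the first locus beyond the block that broke
#' it, reported by name; when the block reaches the end of the map the
#' boundary is `NA` (open end).
#'
#' @param matrix a [haplotype_matrix()].
#' @param max_exceptions per tall line, tolerated loci sharing the dwarf
#'   allele (both per locus and within the block).
#' @param break_run consecutive broken loci required to terminate a run.
#' @return list: `block_loci`, `distal_boundary`, `proximal_boundary`
#'   (locus names or NA), `verdicts` (the [scan_loci()] table),
#'   `open_distal`, `open_proximal`.
#' @export
delineate_block <- function(matrix, max_exceptions = 1, break_run = 1) {
  stopifnot(inherits(matrix, "haplotype_matrix"))
  if (ncol(matrix$alleles) < 2) stop("need at least two loci")
  verdicts <- scan_loci(matrix, max_exceptions)
  loci <- verdicts$locus
  tall_lines <- matrix$line_id[matrix$class == "tall"]
  talls <- matrix$alleles[matrix$class == "tall", , drop = FALSE]

  if (!any(verdicts$status %in% c("discriminating", "exception"))) {
    warning("no discriminating locus; empty block")
    return(list(block_loci = character(), distal_boundary = NA_character_,
                proximal_boundary = NA_character_, verdicts = verdicts,
                open_distal = FALSE, open_proximal = FALSE))
  }

  # segment the scan into runs
  n <- length(loci)
  runs <- list(); cur <- integer(); broken_streak <- 0L
  budget <- stats::setNames(integer(length(tall_lines)), tall_lines)
  terminator <- NA_integer_
  close_run <- function(cur, term) {
    if (length(cur)) runs[[length(runs) + 1L]] <<-
        list(idx = cur, term = term)
  }
  i <- 1L
  while (i <= n) {
    st <- verdicts$status[i]
    if (st == "broken") {
      broken_streak <- broken_streak + 1L
      if (broken_streak >= break_run) {
        close_run(cur, i)
        cur <- integer(); budget[] <- 0L; broken_streak <- 0L
      }
    } else if (st == "uninformative") {
      broken_streak <- 0L
    } else {  # discriminating or exception
      broken_streak <- 0L
      if (st == "exception") {
        a <- verdicts$dwarf_allele[i]
        sharers <- tall_lines[!is.na(talls[, i]) & talls[, i] == a]
        if (any(budget[sharers] + 1L > max_exceptions)) {
          close_run(cur, i)
          cur <- integer(); budget[] <- 0L
          # the offending locus seeds a new run and spends its budget
          budget[sharers] <- 1L
          cur <- i
          i <- i + 1L
          next
        }
        budget[sharers] <- budget[sharers] + 1L
      }
      cur <- c(cur, i)
    }
    i <- i + 1L
  }
  close_run(cur, NA_integer_)

  score <- vapply(runs, function(r)
    sum(verdicts$status[r$idx] %in% c("discriminating", "exception")),
    numeric(1))
  has_disc <- vapply(runs, function(r)
    any(verdicts$status[r$idx] == "discriminating"), logical(1))
  eligible <- which(has_disc)
  if (!length(eligible)) eligible <- seq_along(runs)
  best <- eligible[which.max(score[eligible])]
  idx <- runs[[best]]$idx
  block <- loci[min(idx):max(idx)]
  block <- block[verdicts$status[match(block, loci)] != "broken"]

  distal <- if (min(idx) > 1) loci[min(idx) - 1L] else NA_character_
  prox_i <- if (!is.na(runs[[best]]$term)) runs[[best]]$term else
    if (max(idx) < n) max(idx) + 1L else NA_integer_
  proximal <- if (!is.na(prox_i)) loci[prox_i] else NA_character_

  list(block_loci = block,
       distal_boundary = distal,
       proximal_boundary = proximal,
       verdicts = verdicts,
       open_distal = is.na(distal),
       open_proximal = is.na(proximal))
}

#' Pairwise allele sharing of lines within the haplotype block
#'
#' @param matrix a [haplotype_matrix()].
#' @param block_loci loci to compare over (default: the delineated block).
#' @return data.frame of line pairs with the fraction of shared alleles
#'   over loci where both lines have calls, plus the pair's class
#'   combination (`dwarf-dwarf`, `tall-tall`, `tall-dwarf`).
#' @export
haplotype_concordance <- function(matrix,
                                  block_loci = delineate_block(matrix)$block_loci) {
  stopifnot(inherits(matrix, "haplotype_matrix"))
  a <- matrix$alleles[, block_loci, drop = FALSE]
  ids <- matrix$line_id
  out <- NULL
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ok <- !is.na(a[i, ]) & !is.na(a[j, ])
    frac <- if (any(ok)) mean(a[i, ok] == a[j, ok]) else NA_real_
    cls <- paste(sort(c(matrix$class[i], matrix$class[j])), collapse = "-")
    out <- rbind(out, data.frame(line1 = ids[i], line2 = ids[j],
                                 class_pair = cls, n_loci = sum(ok),
                                 sharing = frac, stringsAsFactors = FALSE))
  }
  out
}
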