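#' Filter raw homologous gene-pair anchors
#'
#' Keeps pairs with E-value below `emax` and, per query gene (`gene_a`),
#' at most the `max_hits` best pairs by E-value (ties broken by the
#' `gene_b` identifier), mirroring a top-hits BLASTP protocol.
#'
#' @param anchors data.frame with columns `gene_a`, `chr_a`, `pos_a`,
#'   `gene_b`, `chr_b`, `pos_b`, `evalue`.
#' @param emax E-value threshold (pairs with `evalue >= emax` removed).
#' @param max_hits maximum retained pairs per `gene_a`.
#' @return the filtered data.frame.
#' @export
filter_anchors <- function(anchors, emax = 1e-5, max_hits = 4) {
  req <- c("gene_a", "chr_a", "pos_a", "gene_b", "chr_b", "pos_b", "evalue")
  miss <- setdiff(req, names(anchors))
  if (length(miss)) stop("anchor table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(anchors$evalue) | anchors$evalue < 0 |
                 !is.finite(anchors$pos_a) | !is.finite(anchors$pos_b))
  if (length(bad))
    stop("malformed anchor record(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (anyDuplicated(anchors[c("gene_a", "gene_b")]))
    stop("anchor pairs must be unique per (gene_a, gene_b)")
  out <- anchors[anchors$evalue < emax, , drop = FALSE]
  if (!nrow(out)) return(out)
  o <- order(out$gene_a, out$evalue, out$gene_b)
  out <- out[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(out)), out$gene_a,
                     FUN = seq_along) <= max_hits
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score of a single anchor pair
#'
#' `min(-log10(E), 50)`; an E-value of 0 maps to the cap 50.
#'
#' @param evalue E-value(s), >= 0.
#' @return numeric score(s).
#' @export
pair_score <- function(evalue) {
  if (any(evalue < 0)) stop("negative evalue")
  ifelse(evalue == 0, 50, pmin(-log10(evalue), 50))
}

gap_penalty <- function(dpa, dpb, gap_unit_bp, aggregate = "max") {
  d <- switch(aggregate,
              max = pmax(abs(dpa), abs(dpb)),
              mean = (abs(dpa) + abs(dpb)) / 2,
              sum = abs(dpa) + abs(dpb),
              stop("unknown gap aggregate: ", aggregate))
  d / gap_unit_bp
}

# best monotone chain by dynamic programming over anchors of one
# chr_a x chr_b pair; dir = +1 (pos_b ascending) or -1 (descending)
best_chain <- function(a, dir, gap_unit_bp, aggregate) {
  n <- nrow(a)
  s <- pair_score(a$evalue)
  o <- order(a$pos_a, dir * a$pos_b)
  f <- s[o]; prev <- rep(NA_integer_, n)
  pa <- a$pos_a[o]; pb <- a$pos_b[o]
  if (n > 1) {
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (pa[j] >= pa[i]) next              # strictly monotone in pos_a
        if (dir * (pb[i] - pb[j]) < 0) next   # monotone in pos_b
        cand <- f[j] + s[o[i]] -
          gap_penalty(pa[i] - pa[j], pb[i] - pb[j], gap_unit_bp, aggregate)
        if (cand > f[i]) { f[i] <- cand; prev[i] <- j }
      }
    }
  }
  end <- which.max(f)
  chain <- integer()
  i <- end
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  list(rows = o[chain], score = f[end])
}

#' Chain anchors into scored collinear synteny blocks
#'
#' Dynamic-programming chaining maximising the sum of [pair_score()] over
#' anchors minus a gap penalty of 1 per `gap_unit_bp` between consecutive
#' anchors (gap distance = `gap_aggregate` of the two genomic distances;
#' default the maximum).  Ascending and descending chains (in `pos_b`) are
#' computed independently per `(chr_a, chr_b)` pair and compete during
#' greedy non-overlap extraction: the best-scoring chain is extracted, its
#' anchors removed, and the search repeated until no chain exceeds
#' `score_min`.
#'
#' @param anchors filtered anchor data.frame (see [filter_anchors()]).
#' @param gap_unit_bp bp of gap incurring one penalty unit (default 10 kb).
#' @param score_min blocks with score <= `score_min` are discarded
#'   (default 300).
#' @param gap_aggregate `"max"` (default), `"mean"` or `"sum"` of the two
#'   genomic gap distances.
#' @return object of class `synteny_blocks`: list with `blocks`
#'   (data.frame: block_id, chr_a, chr_b, orientation, score, n_anchors,
#'   spans) and `anchors` (the input rows plus `block_id`, NA when
#'   unassigned), ordered by descending score.
#' @export
chain_blocks <- function(anchors, gap_unit_bp = 10000, score_min = 300,
                         gap_aggregate = c("max", "mean", "sum")) {
  gap_aggregate <- match.arg(gap_aggregate)
  anchors <- as.data.frame(anchors)
  anchors$block_id <- NA_integer_
  blocks <- NULL
  bid <- 0L
  for (grp in split(seq_len(nrow(anchors)),
                    paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    avail <- grp
    repeat {
      if (!length(avail)) break
      sub <- anchors[avail, , drop = FALSE]
      up <- best_chain(sub, +1, gap_unit_bp, gap_aggregate)
      dn <- best_chain(sub, -1, gap_unit_bp, gap_aggregate)
      ch <- if (up$score >= dn$score) up else dn
      orient <- if (up$score >= dn$score) "+" else "-"
      if (ch$score <= score_min) break
      rows <- avail[ch$rows]
      bid <- bid + 1L
      anchors$block_id[rows] <- bid
      blocks <- rbind(blocks, data.frame(
        block_id = bid,
        chr_a = anchors$chr_a[rows[1]], chr_b = anchors$chr_b[rows[1]],
        orientation = orient, score = ch$score,
        n_anchors = length(rows),
        span_a_start = min(anchors$pos_a[rows]),
        span_a_end = max(anchors$pos_a[rows]),
        span_b_start = min(anchors$pos_b[rows]),
        span_b_end = max(anchors$pos_b[rows]),
        stringsAsFactors = FALSE))
      avail <- setdiff(avail, rows)
    }
  }
  if (!is.null(blocks)) {
    blocks <- blocks[order(-blocks$score), , drop = FALSE]
    rownames(blocks) <- NULL
  } else {
    blocks <- data.frame(block_id = integer(), chr_a = character(),
                         chr_b = character(), orientation = character(),
                         score = numeric(), n_anchors = integer(),
                         span_a_start = numeric(), span_a_end = numeric(),
                         span_b_start = numeric(), span_b_end = numeric(),
                         stringsAsFactors = FALSE)
  }
  structure(list(blocks = blocks, anchors = anchors),
            class = "synteny_blocks")
}

#' Recompute a block's chain score anchor-by-anchor
#'
#' @param blocks a [chain_blocks()] result.
#' @param block_id block to rescore.
#' @param gap_unit_bp,gap_aggregate scoring parameters (must match those
#'   used for chaining).
#' @return the recomputed score.
#' @export
rescore_block <- function(blocks, block_id, gap_unit_bp = 10000,
                          gap_aggregate = "max") {
  a <- blocks$anchors[which(blocks$anchors$block_id == block_id), ,
                      drop = FALSE]
  if (!nrow(a)) stop("unknown block_id: ", block_id)
  a <- a[order(a$pos_a), , drop = FALSE]
  s <- sum(pair_score(a$evalue))
  if (nrow(a) > 1)
    s <- s - sum(gap_penalty(diff(a$pos_a), diff(a$pos_b), gap_unit_bp,
                             gap_aggregate))
  s
}

#' Dot-plot table of anchors with block membership
#'
#' @param blocks a [chain_blocks()] result (or NULL for unchained anchors).
#' @param anchors optionally, the raw anchor table when `blocks` is NULL.
#' @return data.frame with one row per anchor: positions on both genomes,
#'   `block_id` (NA outside any block) and `orientation`.
#' @export
dotplot_data <- function(blocks = NULL, anchors = NULL) {
  if (is.null(blocks)) {
    a <- as.data.frame(anchors)
    a$block_id <- NA_integer_
  } else a <- blocks$anchors
  ori <- rep(NA_character_, nrow(a))
  if (!is.null(blocks) && nrow(blocks$blocks))
    ori <- blocks$blocks$orientation[match(a$block_id,
                                           blocks$blocks$block_id)]
  data.frame(gene_a = a$gene_a, gene_b = a$gene_b,
             chr_a = a$chr_a, chr_b = a$chr_b,
             pos_a = a$pos_a, pos_b = a$pos_b,
             block_id = a$block_id, orientation = ori,
             stringsAsFactors = FALSE)
}

#' Call inversions and translocation boundaries from chained blocks
#'
#' Blocks are ordered along genome A.  A `-` block flanked by `+` blocks
#' (or by a chromosome end) is called an inversion; its breakpoint
#' intervals are the gaps between the block's outermost anchors and the
#' nearest anchors of other blocks, on each genome.  Adjacent blocks whose
#' `chr_b` differs mark translocation boundaries.
#'
#' Before the gaps are measured, the inverted segment is refined: a long
#' ascending chain bridging an inversion can profitably absorb one anchor
#' from inside it (the anchor's score exceeds the marginal gap penalty),
#' so the descending run is extended over neighbouring anchors that
#' continue its descending `pos_b` order.  This automates the otherwise
#' manual determination of precise breakpoints.
#'
#' @param blocks a [chain_blocks()] result with >= 1 block.
#' @return data.frame of calls: `type` (`inversion` /
#'   `translocation-boundary`), `block_id`, breakpoint interval columns
#'   `bp_a_left_start/end`, `bp_a_right_start/end`, and the same for
#'   genome B (NA at chromosome ends and for translocation boundaries,
#'   which report the single inter-block gap on A).
#' @export
detect_rearrangements <- function(blocks) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  b <- blocks$blocks
  if (!nrow(b)) stop("need at least one block")
  a <- blocks$anchors
  out <- NULL
  for (chr in unique(b$chr_a)) {
    bc <- b[b$chr_a == chr, , drop = FALSE]
    bc <- bc[order(bc$span_a_start), , drop = FALSE]
    for (i in seq_len(nrow(bc))) {
      if (bc$orientation[i] != "-") next
      id <- bc$block_id[i]
      own <- a$block_id == id & !is.na(a$block_id)
      # refine the inverted segment: extend over neighbouring anchors of
      # the same chr pair that continue the descending pos_b run
      cand <- which(a$chr_a == chr & a$chr_b == bc$chr_b[i])
      cand <- cand[order(a$pos_a[cand])]
      seg <- which(own[cand])
      if (length(seg)) {
        lo <- min(seg); hi <- max(seg)
        while (lo > 1 &&
               a$pos_b[cand[lo - 1]] > max(a$pos_b[cand[seg]])) {
          lo <- lo - 1; seg <- c(lo, seg)
        }
        while (hi < length(cand) &&
               a$pos_b[cand[hi + 1]] < min(a$pos_b[cand[seg]])) {
          hi <- hi + 1; seg <- c(seg, hi)
        }
        own[] <- FALSE
        own[cand[seg]] <- TRUE
      }
      other <- !is.na(a$block_id) & !own & a$chr_a == chr
      # flanks along genome A must belong to + blocks (or be absent):
      # nearest other-block anchors on each side determine the neighbours
      flank_ori <- function(side) {
        cand2 <- if (side == "left")
          which(other & a$pos_a < min(a$pos_a[own]))
        else which(other & a$pos_a > max(a$pos_a[own]))
        if (!length(cand2)) return("+")   # chromosome end
        j <- if (side == "left") cand2[which.max(a$pos_a[cand2])]
             else cand2[which.min(a$pos_a[cand2])]
        b$orientation[match(a$block_id[j], b$block_id)]
      }
      if (flank_ori("left") == "-" || flank_ori("right") == "-") next
      gap <- function(pos_own, pos_other, side) {
        if (side == "left") {
          lo <- suppressWarnings(max(pos_other[pos_other < min(pos_own)]))
          c(if (is.finite(lo)) lo else NA_real_, min(pos_own))
        } else {
          hi <- suppressWarnings(min(pos_other[pos_other > max(pos_own)]))
          c(max(pos_own), if (is.finite(hi)) hi else NA_real_)
        }
      }
      ga_l <- gap(a$pos_a[own], a$pos_a[other], "left")
      ga_r <- gap(a$pos_a[own], a$pos_a[other], "right")
      same_b <- other & a$chr_b == bc$chr_b[i]
      gb_l <- gap(a$pos_b[own], a$pos_b[same_b], "left")
      gb_r <- gap(a$pos_b[own], a$pos_b[same_b], "right")
      out <- rbind(out, data.frame(
        type = "inversion", block_id = id, chr_a = chr,
        bp_a_left_start = ga_l[1], bp_a_left_end = ga_l[2],
        bp_a_right_start = ga_r[1], bp_a_right_end = ga_r[2],
        bp_b_left_start = gb_l[1], bp_b_left_end = gb_l[2],
        bp_b_right_start = gb_r[1], bp_b_right_end = gb_r[2],
        stringsAsFactors = FALSE))
    }
    # translocation boundaries: chr_b switches between A-adjacent blocks
    if (nrow(bc) > 1) {
      for (i in seq_len(nrow(bc) - 1)) {
        if (bc$chr_b[i] != bc$chr_b[i + 1]) {
          out <- rbind(out, data.frame(
            type = "translocation-boundary", block_id = bc$block_id[i],
            chr_a = chr,
            bp_a_left_start = bc$span_a_end[i],
            bp_a_left_end = bc$span_a_start[i + 1],
            bp_a_right_start = NA_real_, bp_a_right_end = NA_real_,
            bp_b_left_start = NA_real_, bp_b_left_end = NA_real_,
            bp_b_right_start = NA_real_, bp_b_right_end = NA_real_,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out))
    out <- data.frame(type = character(), block_id = integer(),
                      chr_a = character(),
                      bp_a_left_start = numeric(), bp_a_left_end = numeric(),
                      bp_a_right_start = numeric(),
                      bp_a_right_end = numeric(),
                      bp_b_left_start = numeric(), bp_b_left_end = numeric(),
                      bp_b_right_start = numeric(),
                      bp_b_right_end = numeric(), stringsAsFactors = FALSE)
  # order along genome A
  if (nrow(out))
    out <- out[order(out$chr_a, out$bp_a_left_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a marker-bounded candidate interval onto a reference genome
#'
#' @param marker_distal,marker_proximal lists with `name`, `chr`, `pos`
#'   (reference ortholog position, bp) for the two boundary markers.
#' @param annotation optional gene table (data.frame with `gene`, `chr`,
#'   `pos` -- representative coordinate, e.g. gene start) or a GFF3 path
#'   accepted by [read_gene_annotation()].
#' @return object of class `candidate_interval`: `chr`, `start_bp`,
#'   `end_bp`, `length_bp`, `markers`, and `genes` (data.frame of genes
#'   whose representative coordinate lies within the closed interval;
#'   NULL without annotation).
#' @examples
#' project_interval(list(name = "M_distal", chr = "chr7", pos = 58.78e6),
#'                  list(name = "M_proximal", chr = "chr7", pos = 58.37e6))
#' @export
project_interval <- function(marker_distal, marker_proximal,
                             annotation = NULL) {
  for (m in list(marker_distal, marker_proximal))
    stopifnot(all(c("name", "chr", "pos") %in% names(m)))
  if (marker_distal$chr != marker_proximal$chr)
    stop(sprintf("markers map to different chromosomes: %s on %s, %s on %s",
                 marker_distal$name, marker_distal$chr,
                 marker_proximal$name, marker_proximal$chr))
  pos <- sort(c(marker_distal$pos, marker_proximal$pos))
  if (pos[1] == pos[2])
    warning("boundary markers share one position; zero-length interval")
  genes <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_gene_annotation(annotation)
           else annotation
    stopifnot(all(c("gene", "chr", "pos") %in% names(ann)))
    genes <- ann[ann$chr == marker_distal$chr &
                   ann$pos >= pos[1] & ann$pos <= pos[2], , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(chr = marker_distal$chr, start_bp = pos[1],
                 end_bp = pos[2], length_bp = pos[2] - pos[1],
                 markers = c(marker_distal$name, marker_proximal$name),
                 genes = genes),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf("candidate interval %s:%s-%s (%.0f kb), bounded by %s\n",
              x$chr, format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","), x$length_bp / 1000,
              paste(x$markers, collapse = " / ")))
  if (!is.null(x$genes))
    cat(sprintf("  %d annotated gene(s) within the closed interval\n",
                nrow(x$genes)))
  invisible(x)
}
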