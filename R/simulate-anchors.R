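#' Simulate dual-genome gene-order anchor tables with planted inversions
#'
#' Generates a table of homologous gene-pair anchors between a genome A
#' (gene order = identity) and a genome B whose order carries the requested
#' inverted segments, plus optional unpaired gene insertions (B-only genes
#' that stretch the gaps) and deletions (A genes absent from B, so no
#' anchor).  Gene positions are spaced by draws from `gap_bp_model`;
#' anchor E-values are `10^-x` with `x` drawn from `evalue_model`.
#'
#' Ground truth (which genes lie in which planted inversion, and the true
#' breakpoint gaps on genome A) is returned alongside so that downstream
#' rearrangement calls can be scored exactly.
#'
#' @param n_genes number of genes on genome A.
#' @param inversions list of integer pairs `c(start, end)` (gene indices on
#'   genome A, inclusive) to reverse in genome B; must be non-overlapping
#'   and within range.
#' @param n_insertions number of B-only genes inserted at random positions.
#' @param n_deletions number of A genes absent from genome B.
#' @param evalue_model function(n) returning n draws of -log10(E-value).
#' @param gap_bp_model function(n) returning n positive inter-gene gaps, bp.
#' @param seed integer seed.
#' @return list with `anchors` (data.frame: gene_a, chr_a, pos_a, gene_b,
#'   chr_b, pos_b, evalue) and `truth` (list: `inversion_id` per anchor row,
#'   0 = collinear background; `inversions`: per planted inversion the gene
#'   range and the true flanking gap intervals on both genomes).
#' @examples
#' tab <- simulate_anchor_tables(50, inversions = list(c(20, 29)), seed = 1)
#' table(tab$truth$inversion_id)
#' @export
simulate_anchor_tables <- function(n_genes,
                                   inversions = list(),
                                   n_insertions = 0, n_deletions = 0,
                                   evalue_model = function(n)
                                     stats::runif(n, 15, 60),
                                   gap_bp_model = function(n)
                                     stats::rexp(n, 1 / 30000) + 500,
                                   seed = 1L) {
  stopifnot(n_genes >= 1, n_insertions >= 0, n_deletions >= 0)
  if (length(inversions)) {
    rng <- do.call(rbind, lapply(inversions, function(x) sort(as.integer(x))))
    if (any(rng < 1) || any(rng > n_genes))
      stop("inversion ranges must lie within the gene count")
    o <- order(rng[, 1])
    rng <- rng[o, , drop = FALSE]
    if (nrow(rng) > 1 && any(rng[-1, 1] <= rng[-nrow(rng), 2]))
      stop("overlapping inversions")
  } else rng <- matrix(integer(), 0, 2)
  set.seed(seed)

  pos_a <- cumsum(gap_bp_model(n_genes))
  inv_id <- integer(n_genes)
  for (k in seq_len(nrow(rng))) inv_id[rng[k, 1]:rng[k, 2]] <- k

  deleted <- if (n_deletions > 0)
    sort(sample(n_genes, min(n_deletions, n_genes))) else integer()

  # genome B order: identity, then reverse each planted segment
  order_b <- seq_len(n_genes)
  for (k in seq_len(nrow(rng)))
    order_b[rng[k, 1]:rng[k, 2]] <- rev(order_b[rng[k, 1]:rng[k, 2]])
  keep <- !(order_b %in% deleted)
  order_b <- order_b[keep]
  # B-only insertions occupy slots (gene id 0)
  if (n_insertions > 0) {
    slots <- sort(sample(length(order_b) + 1, n_insertions, replace = TRUE))
    full <- integer(length(order_b) + n_insertions)
    ins_at <- slots + seq_len(n_insertions) - 1L
    full[ins_at] <- 0L
    full[-ins_at] <- order_b
    order_b <- full
  }
  pos_b_all <- cumsum(gap_bp_model(length(order_b)))
  shared <- order_b != 0L
  gene_b_order <- order_b[shared]
  pos_b <- pos_b_all[shared]

  # anchors, one per shared gene, in genome A order
  a_idx <- sort(gene_b_order)
  pos_b_of <- pos_b[match(a_idx, gene_b_order)]
  anchors <- data.frame(
    gene_a = sprintf("gA%04d", a_idx),
    chr_a = "A1",
    pos_a = pos_a[a_idx],
    gene_b = sprintf("gB%04d", a_idx),
    chr_b = "B1",
    pos_b = pos_b_of,
    evalue = 10^(-evalue_model(length(a_idx))),
    stringsAsFactors = FALSE)

  # true breakpoint gaps on genome A, measured between anchored genes
  # (a deleted flank gene leaves no anchor, so the recoverable gap runs
  # to the nearest anchored neighbour)
  inv_truth <- lapply(seq_len(nrow(rng)), function(k) {
    g <- rng[k, 1]:rng[k, 2]
    g_in <- intersect(g, a_idx)
    left_out <- a_idx[a_idx < rng[k, 1]]
    right_out <- a_idx[a_idx > rng[k, 2]]
    left_a <- c(if (length(left_out)) pos_a[max(left_out)] else 0,
                if (length(g_in)) pos_a[min(g_in)] else NA_real_)
    right_a <- c(if (length(g_in)) pos_a[max(g_in)] else NA_real_,
                 if (length(right_out)) pos_a[min(right_out)] else Inf)
    list(genes = g, anchored_genes = g_in,
         gap_a_left = left_a, gap_a_right = right_a)
  })

  list(anchors = anchors,
       truth = list(inversion_id = inv_id[a_idx],
                    inversions = inv_truth,
                    deleted = deleted))
}
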