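# Minimum recombinant gametes forced by a two-locus F2 genotype: the
# smallest number of recombinant F1 gametes consistent with the observed
# unordered genotype (AA/AB forces one, AA/BB two; AB/AB is
# parental-compatible and forces none).
MINREC <- matrix(c(0L, 1L, 2L,
                   1L, 0L, 1L,
                   2L, 1L, 0L), 3, 3, byrow = TRUE,
                 dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))

expand_call <- function(x) {
  if (is.na(x)) return(c("AA", "AB", "BB"))
  if (x == "A-") return(c("AA", "AB"))
  x
}

# min/max recombination events between two calls, allowing dominant
# collapse; NA counts 0 (uninformative)
rec_range_pair <- function(a, b) {
  if (is.na(a) || is.na(b)) return(c(0L, 0L))
  vals <- outer(expand_call(a), expand_call(b),
                Vectorize(function(x, y) MINREC[x, y]))
  c(min(vals), max(vals))
}

rec_range_vec <- function(va, vb) {
  r <- vapply(seq_along(va), function(i) rec_range_pair(va[i], vb[i]),
              integer(2))
  c(min = sum(r[1, ]), max = sum(r[2, ]))
}

#' Identify informative (recombinant) plants between two flanking markers
#'
#' A plant is informative iff its two-locus genotype requires at least one
#' recombinant gamete from the F1: AA/AB-type combinations force one
#' recombinant chromosome, AA/BB-type combinations force two, while
#' AA/AA, AB/AB and BB/BB are compatible with two parental gametes.
#' Plants missing a call at either locus are excluded and reported.
#'
#' @param table a [genotype_table()].
#' @param locus_a,locus_b names of two codominant loci in the table.
#' @return data.frame of informative plants (`plant_id`, `call_a`,
#'   `call_b`, `n_rec_chromosomes` in {1, 2}), with attributes
#'   `excluded_na` (plant ids missing either call) and `n_scored`
#'   (plants with both calls).
#' @examples
#' cfg <- sim_config(n_f2 = 500, seed = 7)
#' pop <- simulate_f2(cfg)
#' inf <- find_recombinants(pop$geno, "FLANK_L", "FLANK_R")
#' nrow(inf)
#' @export
find_recombinants <- function(table, locus_a, locus_b) {
  stopifnot(inherits(table, "genotype_table"))
  ia <- locus_index(table, locus_a); ib <- locus_index(table, locus_b)
  for (i in c(ia, ib))
    if (table$loci$mode[i] != "codominant")
      stop("locus ", table$loci$locus[i],
           " is dominant; recombinant screening needs codominant calls")
  a <- table$calls[, ia]; b <- table$calls[, ib]
  has_na <- is.na(a) | is.na(b)
  nrec <- rep(NA_integer_, length(a))
  nrec[!has_na] <- MINREC[cbind(a[!has_na], b[!has_na])]
  keep <- !has_na & nrec >= 1L
  out <- data.frame(plant_id = table$plant_id[keep],
                    call_a = a[keep], call_b = b[keep],
                    n_rec_chromosomes = nrec[keep],
                    stringsAsFactors = FALSE)
  attr(out, "excluded_na") <- table$plant_id[has_na]
  attr(out, "n_scored") <- sum(!has_na)
  out
}

#' Genetic distance from a recombinant-chromosome count
#'
#' Distance (cM) is estimated as `100 * R / (2N)`: recombinant chromosomes
#' over gametes scored, the estimator under which 29 recombinants among
#' 915 plants give 1.6 cM.  The standard error comes from the binomial
#' variance on `2N` chromosomes.  `method = "haldane"` additionally inverts
#' the Haldane map function (delta-method SE), appropriate for larger
#' distances.
#'
#' @param recombinant_chromosomes count of recombinant chromosomes
#'   (informative plants contribute 1, double recombinants 2).
#' @param n_plants number of plants scored at both loci.
#' @param method `"morgan"` (plain recombinant fraction, default) or
#'   `"haldane"`.
#' @return list with `d_cM`, `se_cM` and the recombination fraction `r`.
#' @examples
#' map_distance(29, 915)$d_cM    # 1.5847
#' @export
map_distance <- function(recombinant_chromosomes, n_plants,
                         method = c("morgan", "haldane")) {
  method <- match.arg(method)
  if (n_plants < 1) stop("n_plants must be >= 1")
  if (recombinant_chromosomes < 0) stop("counts must be non-negative")
  n_chrom <- 2 * n_plants
  if (recombinant_chromosomes > n_chrom)
    stop("recombinant_chromosomes exceeds 2 * n_plants")
  p <- recombinant_chromosomes / n_chrom
  se_p <- sqrt(p * (1 - p) / n_chrom)
  if (p >= 0.5) {
    warning("recombination fraction at or above 0.5; ",
            "distance capped at 100 cM (loci effectively unlinked)")
    return(list(d_cM = 100, se_cM = NA_real_, r = p))
  }
  if (method == "morgan") {
    list(d_cM = 100 * p, se_cM = 100 * se_p, r = p)
  } else {
    list(d_cM = haldane_d(p), se_cM = 100 * se_p / (1 - 2 * p), r = p)
  }
}

combine_vectors <- function(mat) {
  # element-wise first non-NA across rows of a character matrix
  apply(mat, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v)) v[1] else NA_character_
  })
}

#' Cluster cosegregating markers over the informative plants
#'
#' Codominant loci with identical genotype vectors (over the supplied
#' plants, treating NA as matching nothing) merge into one cluster.
#' Dominant loci attach to the unique cluster whose vector is compatible
#' with their collapsed calls; ambiguous attachments (several compatible
#' clusters) and unplaceable loci are reported separately.  Clusters are
#' then ordered to minimise the total recombination events between
#' adjacent clusters, with the clusters containing the first and last
#' loci of the table anchored at the ends when they differ.
#'
#' @param table a [genotype_table()] restricted to the informative plants.
#' @param anchor_flanks logical; keep the clusters of the outermost loci
#'   at the ends of the order (default `TRUE`).
#' @return object of class `marker_clusters`: list with `clusters` (list
#'   of `loci`, `vector`, `dominant_members`), `order` (cluster indices in
#'   map order), `adjacency` (data.frame of min/max recombination events
#'   between adjacent clusters), `ambiguous`, `unplaced`, `plant_id`.
#' @export
cluster_markers <- function(table, anchor_flanks = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  if (nrow(table$calls) < 1) stop("need at least one informative plant")
  cod <- which(table$loci$mode == "codominant")
  dom <- which(table$loci$mode == "dominant")
  if (!length(cod)) stop("need at least one codominant locus to seed clusters")

  keys <- apply(table$calls[, cod, drop = FALSE], 2, function(v)
    paste(ifelse(is.na(v), ".", v), collapse = "|"))
  groups <- split(cod, keys)
  # deterministic cluster order: by first column index of each group
  groups <- unname(groups[order(vapply(groups, min, integer(1)))])
  clusters <- lapply(groups, function(idx) {
    vec <- combine_vectors(t(table$calls[, idx, drop = FALSE]))
    list(loci = table$loci$locus[idx], vector = vec,
         dominant_members = character())
  })

  ambiguous <- list(); unplaced <- character()
  for (j in dom) {
    v <- table$calls[, j]
    compat <- which(vapply(clusters, function(cl) {
      all(vapply(seq_along(v), function(i) {
        if (is.na(v[i]) || is.na(cl$vector[i])) return(TRUE)
        if (v[i] == "BB") cl$vector[i] == "BB"
        else cl$vector[i] %in% c("AA", "AB")
      }, logical(1)))
    }, logical(1)))
    nm <- table$loci$locus[j]
    if (length(compat) == 1) {
      clusters[[compat]]$dominant_members <-
        c(clusters[[compat]]$dominant_members, nm)
      clusters[[compat]]$loci <- c(clusters[[compat]]$loci, nm)
    } else if (length(compat) > 1) {
      ambiguous[[nm]] <- compat
    } else {
      unplaced <- c(unplaced, nm)
    }
  }

  k <- length(clusters)
  ord <- seq_len(k)
  if (k > 1) {
    if (k > 8) stop("too many clusters for exhaustive ordering (> 8)")
    first_cl <- which(vapply(clusters, function(cl)
      table$loci$locus[min(cod)] %in% cl$loci, logical(1)))
    last_cl <- which(vapply(clusters, function(cl)
      table$loci$locus[max(cod)] %in% cl$loci, logical(1)))
    perms <- permutations_of(k)
    if (anchor_flanks && first_cl != last_cl) {
      keep <- vapply(perms, function(p)
        (p[1] == first_cl && p[k] == last_cl) ||
        (p[1] == last_cl && p[k] == first_cl), logical(1))
      perms <- perms[keep]
    }
    cost <- vapply(perms, function(p) {
      sum(vapply(seq_len(k - 1), function(i)
        rec_range_vec(clusters[[p[i]]]$vector,
                      clusters[[p[i + 1]]]$vector)[["min"]], numeric(1)))
    }, numeric(1))
    best <- which(cost == min(cost))
    # deterministic tie-break: lexicographic on the permutation
    keyfun <- function(p) paste(sprintf("%02d", p), collapse = "")
    ord <- perms[best][[order(vapply(perms[best], keyfun, character(1)))[1]]]
    if (ord[1] > ord[k]) ord <- rev(ord)
  }

  adjacency <- if (k > 1) {
    do.call(rbind, lapply(seq_len(k - 1), function(i) {
      rr <- rec_range_vec(clusters[[ord[i]]]$vector,
                          clusters[[ord[i + 1]]]$vector)
      data.frame(from = ord[i], to = ord[i + 1],
                 rec_min = rr[["min"]], rec_max = rr[["max"]])
    }))
  } else NULL

  structure(list(clusters = clusters, order = ord, adjacency = adjacency,
                 ambiguous = ambiguous, unplaced = unplaced,
                 plant_id = table$plant_id),
            class = "marker_clusters")
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

#' @export
print.marker_clusters <- function(x, ...) {
  cat(sprintf("marker_clusters: %d cluster(s) over %d plants\n",
              length(x$clusters), length(x$plant_id)))
  for (i in x$order)
    cat(sprintf("  [%d] %s\n", i, paste(x$clusters[[i]]$loci,
                                        collapse = ", ")))
  if (length(x$unplaced))
    cat("  unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  invisible(x)
}

trait_to_marker <- function(call) {
  switch(call, dd = "BB", Dd = "AB", DD = "AA", NA_character_)
}

#' Place the trait locus among the marker clusters
#'
#' The trait is assigned the position (cosegregation with one cluster)
#' minimising the total recombination events between the trait genotype
#' vector and all cluster vectors; ties are reported as an interval.
#' Plants called `tall_unresolved` or `no_data` are excluded.
#'
#' @param clusters a [cluster_markers()] result.
#' @param trait_calls data.frame of trait calls (as produced by
#'   [classify_population()]`$calls`) with `f2_id` matching the cluster
#'   table's plant ids.
#' @return list with `best_cluster` (indices of minimising cluster(s)),
#'   `distances` (recombination events trait vs each cluster, in map
#'   order), `trait_vector`, `plants_used`, and `cosegregating`
#'   (TRUE when the minimum distance is zero).
#' @export
place_trait <- function(clusters, trait_calls) {
  stopifnot(inherits(clusters, "marker_clusters"))
  idx <- match(clusters$plant_id, trait_calls$f2_id)
  call <- trait_calls$call[idx]
  usable <- !is.na(call) & call %in% c("dd", "Dd", "DD")
  if (!any(usable)) stop("all trait calls unresolved; cannot place trait")
  tv <- rep(NA_character_, length(call))
  tv[usable] <- vapply(call[usable], trait_to_marker, character(1))

  d <- vapply(clusters$clusters, function(cl)
    rec_range_vec(tv, cl$vector)[["min"]], numeric(1))
  best <- which(d == min(d))
  list(best_cluster = best, distances = d, trait_vector = tv,
       plants_used = clusters$plant_id[usable],
       cosegregating = min(d) == 0)
}

#' Flag plants whose trait call implies a double recombination event
#'
#' A plant is flagged when its trait call disagrees with the genotype of
#' the marker clusters flanking the trait position although those flanking
#' clusters show no recombination at that plant (identical calls): the
#' trait call then requires a recombination on both sides of the trait in
#' an interval where no marker recombination occurred.  The suggested
#' re-call is the flanking genotype, annotated with the family's 3:1
#' segregation p-value when available.
#'
#' @param clusters a [cluster_markers()] result.
#' @param trait_calls trait-call data.frame (see [place_trait()]).
#' @return data.frame of flagged plants (possibly empty): `plant_id`,
#'   `trait_call`, `flanking_genotype`, `suggested_call`,
#'   `p_value_3to1`.
#' @export
flag_double_recombinants <- function(clusters, trait_calls) {
  placement <- place_trait(clusters, trait_calls)
  ord <- clusters$order
  k <- length(ord)
  pos <- match(placement$best_cluster[1], ord)
  tv <- placement$trait_vector

  empty <- data.frame(plant_id = character(), trait_call = character(),
                      flanking_genotype = character(),
                      suggested_call = character(),
                      p_value_3to1 = numeric(), stringsAsFactors = FALSE)
  if (k < 2) return(empty)
  left <- if (pos > 1) clusters$clusters[[ord[pos - 1]]]$vector else NULL
  right <- if (pos < k) clusters$clusters[[ord[pos + 1]]]$vector else NULL
  home <- clusters$clusters[[ord[pos]]]$vector
  if (is.null(left)) left <- home
  if (is.null(right)) right <- home

  flags <- empty
  back_call <- c(AA = "DD", AB = "Dd", BB = "dd")
  for (i in seq_along(tv)) {
    if (is.na(tv[i]) || is.na(left[i]) || is.na(right[i])) next
    if (left[i] == right[i] && tv[i] != left[i]) {
      pid <- clusters$plant_id[i]
      row <- trait_calls[trait_calls$f2_id == pid, , drop = FALSE]
      pval <- if (nrow(row) && "p_value_3to1" %in% names(row))
        row$p_value_3to1[1] else NA_real_
      flags <- rbind(flags, data.frame(
        plant_id = pid,
        trait_call = back_call[[tv[i]]],
        flanking_genotype = left[i],
        suggested_call = back_call[[left[i]]],
        p_value_3to1 = pval, stringsAsFactors = FALSE))
    }
  }
  rownames(flags) <- NULL
  flags
}
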