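#' Simulate gametes of a fully heterozygous F1
#'
#' Each gamete is a 0/1 haplotype over the ordered loci (0 = tall-parent
#' allele A, 1 = dwarf-parent allele B).  The allele at the first locus is
#' fair Bernoulli; a crossover occurs independently in each inter-locus
#' interval with the recombination fraction implied by the map function.
#'
#' @param n number of gametes.
#' @param pos_cM ordered locus positions (cM); `Inf` spacing gives r = 0.5.
#' @param map_function `"haldane"` or `"morgan"`.
#' @return integer matrix, `n` x `length(pos_cM)`.
#' @export
simulate_gametes <- function(n, pos_cM, map_function = "haldane") {
  L <- length(pos_cM)
  g <- matrix(0L, n, L)
  g[, 1] <- stats::rbinom(n, 1, 0.5)
  if (L > 1) {
    d <- diff(pos_cM)
    r <- vapply(d, function(x)
      if (is.infinite(x)) 0.5 else map_r(x, map_function), numeric(1))
    for (j in 2:L) {
      xo <- stats::rbinom(n, 1, r[j - 1])
      g[, j] <- (g[, j - 1] + xo) %% 2L
    }
  }
  g
}

#' Simulate an F2 mapping population segregating for a recessive locus
#'
#' Forms each F2 plant from two independent F1 gametes simulated under the
#' configured map.  The recessive trait locus is placed at its cM position
#' among the markers (`Inf` = unlinked, segregating independently).
#' Dominant loci are reported with the heterozygote and the dominant
#' homozygote collapsed to `A-`; missing calls are injected uniformly at
#' random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return list with elements `geno` (a [genotype_table()] over the marker
#'   loci only), `trait` (character vector of per-plant truth genotypes at
#'   the trait locus: `dd`, `Dd` or `DD`) and `config`.
#' @examples
#' cfg <- sim_config(n_f2 = 200, seed = 42)
#' pop <- simulate_f2(cfg)
#' table(pop$trait)
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mm <- config$marker_map
  tp <- config$trait_locus_position

  if (is.finite(tp)) {
    pos <- c(mm$pos_cM, tp)
    names <- c(mm$locus, ".trait")
    o <- order(pos, seq_along(pos))   # stable: trait after coincident marker
    pos <- pos[o]; names <- names[o]
  } else {
    pos <- c(mm$pos_cM, Inf)
    names <- c(mm$locus, ".trait")
  }
  ti <- which(names == ".trait")

  g1 <- simulate_gametes(config$n_f2, pos, config$map_function)
  g2 <- simulate_gametes(config$n_f2, pos, config$map_function)
  dosage <- g1 + g2                     # copies of dwarf-parent allele B

  trait <- c("DD", "Dd", "dd")[dosage[, ti] + 1L]

  calls <- matrix(c("AA", "AB", "BB")[dosage[, -ti, drop = FALSE] + 1L],
                  nrow = config$n_f2,
                  dimnames = list(NULL, names[-ti]))
  calls <- calls[, mm$locus, drop = FALSE]   # original marker order
  modes <- ifelse(mm$locus %in% config$dominant_loci, "dominant",
                  "codominant")
  dom <- which(modes == "dominant")
  for (j in dom) calls[calls[, j] %in% c("AA", "AB"), j] <- "A-"

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow = nrow(calls))
    calls[miss] <- NA_character_
  }

  geno <- genotype_table(calls, modes,
                         plant_id = sprintf("P%04d", seq_len(config$n_f2)),
                         pos_cM = mm$pos_cM)
  list(geno = geno, trait = trait, config = config)
}
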