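# Independent brute-force oracles used to validate the implementation.

# All 4 F1 gamete haplotypes over two loci; 0 = allele A, 1 = allele B.
# A gamete is recombinant iff its two alleles derive from different
# parental haplotypes (0,1 or 1,0).
oracle_min_rec <- function(call_a, call_b) {
  gametes <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  rec <- c(0L, 1L, 1L, 0L)
  code <- c("AA", "AB", "BB")
  best <- Inf
  for (i in seq_along(gametes)) for (j in seq_along(gametes)) {
    g <- gametes[[i]] + gametes[[j]]
    if (code[g[1] + 1] == call_a && code[g[2] + 1] == call_b)
      best <- min(best, rec[i] + rec[j])
  }
  best
}

# Exhaustive best monotone chain over <= ~12 anchors: enumerate all
# subsets, keep those monotone in pos_a (strict) and pos_b (either
# direction), score as pair scores minus gap penalties.
oracle_best_chain <- function(anchors, gap_unit_bp = 10000) {
  n <- nrow(anchors)
  o <- order(anchors$pos_a)
  a <- anchors[o, , drop = FALSE]
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    pa <- a$pos_a[idx]; pb <- a$pos_b[idx]
    if (any(diff(pa) <= 0)) next
    dpb <- diff(pb)
    if (length(dpb) && !(all(dpb >= 0) || all(dpb <= 0))) next
    s <- sum(pmin(-log10(a$evalue[idx]), 50))
    if (length(idx) > 1)
      s <- s - sum(pmax(abs(diff(pa)), abs(dpb)) / gap_unit_bp)
    if (s > best) best <- s
  }
  best
}

# Random small anchor instance for DP-vs-oracle property tests
random_anchor_instance <- function(seed, n_max = 10) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  data.frame(gene_a = paste0("a", seq_len(n)), chr_a = "A",
             pos_a = sort(sample.int(1e6, n)),
             gene_b = paste0("b", seq_len(n)), chr_b = "B",
             pos_b = sample.int(1e6, n),
             evalue = 10^-stats::runif(n, 2, 60),
             stringsAsFactors = FALSE)
}

# A small two-cluster genotype table over informative plants, emulating
# the structure of a fine-mapping marker panel (synthetic data).
two_cluster_table <- function() {
  # 16 plants; cluster 1 loci share vector v1, cluster 2 loci share v2
  v1 <- c("AA", "AA", "AB", "AB", "BB", "AB", "AA", "BB",
          "AB", "AA", "AB", "BB", "AA", "AB", "AA", "AB")
  v2 <- c("AA", "AB", "AB", "AB", "BB", "AB", "AA", "BB",
          "AB", "AB", "AB", "BB", "AA", "AB", "AB", "AB")
  calls <- cbind(RGR1963 = v1, Ca_Sb07g023910 = v1, Ca_Sb07g024020 = v1,
                 Ca_Sb07g023810 = v1,
                 Ca_Sb07g023630 = v2, Ca_Sb07g023520 = v2,
                 Ca_Sb07g023430 = v2)
  genotype_table(calls, "codominant",
                 plant_id = sprintf("R%02d", 1:16))
}

table1_path <- function()
  system.file("extdata", "table1_f3_families.tsv", package = "pmfinemap")

table2_path <- function()
  system.file("extdata", "table2_haplotypes.tsv", package = "pmfinemap")
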