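test_that("informative-plant detection equals gamete enumeration on all
           nine two-locus genotypes", {
  combos <- expand.grid(a = c("AA", "AB", "BB"), b = c("AA", "AB", "BB"),
                        stringsAsFactors = FALSE)
  calls <- cbind(L1 = combos$a, L2 = combos$b)
  tab <- genotype_table(calls, "codominant",
                        plant_id = paste0("p", 1:9))
  inf <- find_recombinants(tab, "L1", "L2")
  for (i in 1:9) {
    oracle <- oracle_min_rec(combos$a[i], combos$b[i])
    row <- inf[inf$plant_id == paste0("p", i), ]
    if (oracle == 0) expect_equal(nrow(row), 0)
    else expect_equal(row$n_rec_chromosomes, oracle)
  }
})

test_that("plants with missing flanking calls are excluded and reported", {
  calls <- cbind(L1 = c("AA", NA, "AB"), L2 = c("AB", "BB", NA))
  tab <- genotype_table(calls, "codominant")
  inf <- find_recombinants(tab, "L1", "L2")
  expect_equal(inf$plant_id, "1")
  expect_setequal(attr(inf, "excluded_na"), c("2", "3"))
  expect_equal(attr(inf, "n_scored"), 1)
})

test_that("recombinant screening rejects dominant or absent loci", {
  calls <- cbind(L1 = c("AA", "AB"), D1 = c("A-", "BB"))
  tab <- genotype_table(calls, c("codominant", "dominant"))
  expect_error(find_recombinants(tab, "L1", "D1"), "dominant")
  expect_error(find_recombinants(tab, "L1", "nope"), "not present")
})

test_that("map distance: 29 recombinant chromosomes in 915 plants give
           1.6 cM", {
  md <- map_distance(29, 915)
  expect_equal(md$d_cM, 100 * 29 / (2 * 915))
  expect_equal(round(md$d_cM, 3), 1.585)
  expect_equal(sprintf("%.1f", md$d_cM), "1.6")
  expect_equal(map_distance(0, 100)$d_cM, 0)
  expect_warning(md2 <- map_distance(200, 100), "100 cM")
  expect_equal(md2$d_cM, 100)
  expect_error(map_distance(-1, 10), "non-negative")
  expect_error(map_distance(30, 10), "exceeds")
})

test_that("recombination fraction is recovered from simulated populations", {
  # quick two-distance version; the full grid runs in the acceptance suite
  for (spec in list(list(d = 1.6, seed = 61), list(d = 5, seed = 62))) {
    cfg <- sim_config(n_f2 = 5000,
                      marker_map = data.frame(locus = c("A", "B"),
                                              pos_cM = c(0, spec$d)),
                      trait_locus_position = spec$d / 2, seed = spec$seed)
    pop <- simulate_f2(cfg)
    inf <- find_recombinants(pop$geno, "A", "B")
    md <- map_distance(sum(inf$n_rec_chromosomes), 5000)
    r <- haldane_r(spec$d)
    se <- sqrt(r * (1 - r) / 10000)
    expect_lt(abs(md$r - r), 3 * se)
  }
})

test_that("cosegregating markers cluster by genotype vector", {
  tab <- two_cluster_table()
  cl <- cluster_markers(tab)
  expect_length(cl$clusters, 2)
  expect_setequal(cl$clusters[[1]]$loci,
                  c("RGR1963", "Ca_Sb07g023910", "Ca_Sb07g024020",
                    "Ca_Sb07g023810"))
  expect_setequal(cl$clusters[[2]]$loci,
                  c("Ca_Sb07g023630", "Ca_Sb07g023520", "Ca_Sb07g023430"))

  # all identical vectors -> one cluster
  one <- genotype_table(cbind(L1 = c("AA", "AB"), L2 = c("AA", "AB")),
                        "codominant")
  expect_length(cluster_markers(one)$clusters, 1)
})

test_that("cluster count equals the number of distinct genotype vectors", {
  set.seed(19)
  for (rep in 1:5) {
    calls <- matrix(sample(c("AA", "AB", "BB"), 16 * 6, replace = TRUE),
                    16, 6, dimnames = list(NULL, paste0("L", 1:6)))
    tab <- genotype_table(calls, "codominant")
    expected <- length(unique(apply(calls, 2, paste, collapse = "|")))
    expect_length(cluster_markers(tab, anchor_flanks = FALSE)$clusters,
                  expected)
  }
})

test_that("dominant loci attach uniquely when a BB call discriminates,
           and are reported as ambiguous otherwise", {
  vA <- c("AA", "AB", "BB", "AA")
  vB <- c("AA", "AB", "AB", "BB")
  dom_b <- ifelse(vB == "BB", "BB", "A-")   # incompatible with vA's AA
  tab <- genotype_table(cbind(X1 = vA, X2 = vB, DOM = dom_b),
                        c("codominant", "codominant", "dominant"))
  cl <- cluster_markers(tab, anchor_flanks = FALSE)
  in_b <- vapply(cl$clusters, function(x)
    all(c("X2", "DOM") %in% x$loci), logical(1))
  expect_true(any(in_b))

  # clusters differing only at AA/AB plants cannot be separated by a
  # dominant locus: its attachment is reported as ambiguous
  vC <- c("AA", "AB", "BB", "AA")
  vD <- c("AB", "AA", "BB", "AA")
  dom_amb <- ifelse(vC == "BB", "BB", "A-")
  tab2 <- genotype_table(cbind(X1 = vC, X2 = vD, DOM = dom_amb),
                         c("codominant", "codominant", "dominant"))
  cl2 <- cluster_markers(tab2, anchor_flanks = FALSE)
  expect_length(cl2$clusters, 2)
  expect_true("DOM" %in% names(cl2$ambiguous))
  expect_length(cl2$ambiguous$DOM, 2)
})

test_that("cluster structure is invariant to global allele relabeling and
           plant order", {
  tab <- two_cluster_table()
  swap <- c(AA = "BB", AB = "AB", BB = "AA")
  calls2 <- matrix(swap[tab$calls], nrow = nrow(tab$calls),
                   dimnames = dimnames(tab$calls))
  cl1 <- cluster_markers(tab)
  cl2 <- cluster_markers(genotype_table(calls2, "codominant",
                                        plant_id = tab$plant_id))
  loci1 <- lapply(cl1$clusters[cl1$order], `[[`, "loci")
  loci2 <- lapply(cl2$clusters[cl2$order], `[[`, "loci")
  expect_identical(loci1, loci2)

  perm <- sample(nrow(tab$calls))
  cl3 <- cluster_markers(genotype_table(tab$calls[perm, ], "codominant",
                                        plant_id = tab$plant_id[perm]))
  expect_identical(lapply(cl3$clusters[cl3$order], `[[`, "loci"), loci1)
})

test_that("trait placement minimises recombination events (brute force)", {
  tab <- two_cluster_table()
  cl <- cluster_markers(tab)
  # trait identical to cluster 1's vector -> distance 0, cosegregating
  back <- c(AA = "DD", AB = "Dd", BB = "dd")
  calls <- data.frame(f2_id = tab$plant_id,
                      call = unname(back[cl$clusters[[1]]$vector]),
                      p_value_3to1 = NA_real_, stringsAsFactors = FALSE)
  pl <- place_trait(cl, calls)
  expect_true(pl$cosegregating)
  expect_equal(pl$best_cluster, 1)
  expect_equal(pl$distances[1], 0)

  # randomized instances: reported distances equal brute-force counts
  set.seed(23)
  for (rep in 1:10) {
    tv <- sample(c("dd", "Dd", "DD"), 16, replace = TRUE)
    calls$call <- tv
    pl <- place_trait(cl, calls)
    mk <- c(dd = "BB", Dd = "AB", DD = "AA")[tv]
    brute <- vapply(cl$clusters, function(x)
      sum(vapply(seq_along(mk), function(i)
        oracle_min_rec(mk[i], x$vector[i]), numeric(1))), numeric(1))
    expect_equal(pl$distances, brute)
    expect_equal(pl$best_cluster, which(brute == min(brute)))
  }

  calls$call <- "tall_unresolved"
  expect_error(place_trait(cl, calls), "unresolved")
})

test_that("a trait call inside a non-recombinant stretch is flagged as a
           double recombinant with the re-call suggestion", {
  # three clusters; plant p2's trait call disagrees with identical
  # flanking genotypes (the published plant-612 configuration)
  v_left <- c("AA", "AA", "AB", "BB", "AB")
  v_mid <- c("AA", "AA", "AB", "BB", "BB")   # trait cosegregates here
  v_right <- c("AB", "AA", "AB", "BB", "BB")
  tab <- genotype_table(cbind(L = v_left, M = v_mid, R = v_right),
                        "codominant", plant_id = paste0("p", 1:5))
  cl <- cluster_markers(tab)
  trait <- c("DD", "Dd", "Dd", "dd", "dd")   # p2 should be DD
  calls <- data.frame(f2_id = paste0("p", 1:5), call = trait,
                      p_value_3to1 = c(NA, 0.071, NA, NA, NA),
                      stringsAsFactors = FALSE)
  flags <- flag_double_recombinants(cl, calls)
  expect_equal(flags$plant_id, "p2")
  expect_equal(flags$suggested_call, "DD")
  expect_equal(flags$p_value_3to1, 0.071)

  # fully cosegregating data -> no flags
  calls$call <- c("DD", "DD", "Dd", "dd", "dd")
  expect_equal(nrow(flag_double_recombinants(cl, calls)), 0)
})

test_that("end-to-end placement puts the trait in the correct interval", {
  cfg <- sim_config(n_f2 = 3000,
                    marker_map = data.frame(
                      locus = c("M1", "M2", "M3"),
                      pos_cM = c(0, 2, 6)),
                    trait_locus_position = 1, seed = 17)
  pop <- simulate_f2(cfg)
  inf <- find_recombinants(pop$geno, "M1", "M3")
  tab <- subset_plants(pop$geno, inf$plant_id)
  cl <- cluster_markers(tab)
  truth <- pop$trait[match(inf$plant_id, pop$geno$plant_id)]
  calls <- data.frame(f2_id = inf$plant_id, call = truth,
                      p_value_3to1 = NA_real_, stringsAsFactors = FALSE)
  pl <- place_trait(cl, calls)
  # the trait (at 1 cM) must sit closer to the M1/M2 clusters than to M3
  m3_cluster <- which(vapply(cl$clusters, function(x) "M3" %in% x$loci,
                             logical(1)))
  expect_false(m3_cluster %in% pl$best_cluster)
})
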