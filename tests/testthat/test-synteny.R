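make_anchors <- function(pos_a, pos_b, evalue = 1e-60, chr_b = "B") {
  n <- length(pos_a)
  data.frame(gene_a = paste0("a", seq_len(n)), chr_a = "A", pos_a = pos_a,
             gene_b = paste0("b", seq_len(n)), chr_b = chr_b, pos_b = pos_b,
             evalue = rep_len(evalue, n), stringsAsFactors = FALSE)
}

test_that("anchor filtering applies the E-value threshold and per-gene
           hit cap", {
  a <- make_anchors(1:3 * 1000, 1:3 * 1000, evalue = c(1e-4, 1e-5, 1e-6))
  out <- filter_anchors(a)
  expect_equal(out$gene_a, "a3")        # 1e-4 and 1e-5 are not < 1e-5

  # six hits for one query: the best four are kept, ties broken by gene_b
  b <- data.frame(gene_a = "q", chr_a = "A", pos_a = 1,
                  gene_b = paste0("h", 1:6), chr_b = "B", pos_b = 1:6,
                  evalue = c(1e-50, 1e-40, 1e-30, 1e-20, 1e-10, 1e-8))
  out2 <- filter_anchors(b)
  expect_equal(nrow(out2), 4)
  expect_setequal(out2$gene_b, c("h1", "h2", "h3", "h4"))

  expect_equal(nrow(filter_anchors(a[0, ])), 0)
  bad <- a; bad$evalue[2] <- NA
  expect_error(filter_anchors(bad), "malformed")
})

test_that("pair scores follow min(-log10 E, 50)", {
  expect_equal(pair_score(1e-60), 50)
  expect_equal(pair_score(1e-40), 40)
  expect_equal(pair_score(1), 0)
  expect_equal(pair_score(0), 50)
  expect_error(pair_score(-1), "negative")
})

test_that("chain scores match the stated scoring scheme arithmetic", {
  # two anchors 25 kb apart on both genomes: 50 + 40 - 2.5
  a <- make_anchors(c(0, 25000), c(0, 25000), evalue = c(1e-60, 1e-40))
  bl <- chain_blocks(a, score_min = 0)
  expect_equal(bl$blocks$score, 87.5)

  # ten anchors scoring 50 with 5-kb gaps: 500 - 9 * 0.5 = 495.5 > 300
  b <- make_anchors(seq(0, by = 5000, length.out = 10),
                    seq(0, by = 5000, length.out = 10))
  bl2 <- chain_blocks(b)            # default score_min = 300
  expect_equal(nrow(bl2$blocks), 1)
  expect_equal(bl2$blocks$score, 495.5)
  expect_equal(bl2$blocks$n_anchors, 10)
  expect_equal(bl2$blocks$orientation, "+")
})

test_that("dynamic-programming chaining equals the exhaustive oracle on
           random small instances", {
  for (seed in 1:60) {
    a <- random_anchor_instance(seed, n_max = 9)
    bl <- chain_blocks(a, score_min = 0)
    expect_equal(bl$blocks$score[1], oracle_best_chain(a),
                 tolerance = 1e-9)
  }
})

test_that("reported block scores equal their anchor-by-anchor recomputation", {
  tab <- simulate_anchor_tables(150, inversions = list(c(60, 75)), seed = 21)
  bl <- chain_blocks(filter_anchors(tab$anchors), score_min = 50)
  for (id in bl$blocks$block_id)
    expect_equal(rescore_block(bl, id),
                 bl$blocks$score[bl$blocks$block_id == id],
                 tolerance = 1e-9)
})

test_that("reversing genome B's axis flips orientations and preserves
           scores", {
  tab <- simulate_anchor_tables(120, inversions = list(c(50, 64)), seed = 9)
  a <- filter_anchors(tab$anchors)
  bl1 <- chain_blocks(a, score_min = 50)
  flipped <- a
  flipped$pos_b <- max(a$pos_b) + min(a$pos_b) - a$pos_b
  bl2 <- chain_blocks(flipped, score_min = 50)
  o1 <- bl1$blocks[order(bl1$blocks$span_a_start), ]
  o2 <- bl2$blocks[order(bl2$blocks$span_a_start), ]
  expect_equal(o1$score, o2$score, tolerance = 1e-9)
  expect_equal(o1$n_anchors, o2$n_anchors)
  expect_equal(o1$orientation, chartr("+-", "-+", o2$orientation))
})

test_that("dot-plot tables carry block membership and orientation", {
  tab <- simulate_anchor_tables(100, seed = 12)
  bl <- chain_blocks(tab$anchors, score_min = 50)
  dp <- dotplot_data(bl)
  expect_equal(nrow(dp), nrow(tab$anchors))
  expect_true(all(dp$orientation[!is.na(dp$block_id)] == "+"))

  inv <- simulate_anchor_tables(100, inversions = list(c(40, 59)), seed = 12)
  bli <- chain_blocks(inv$anchors, score_min = 50)
  dpi <- dotplot_data(bli)
  minus <- dpi$block_id %in% bli$blocks$block_id[bli$blocks$orientation == "-"]
  expect_gt(sum(minus), 0)

  dp0 <- dotplot_data(anchors = tab$anchors)
  expect_true(all(is.na(dp0$block_id)))
})

test_that("collinear data yield no rearrangement calls; planted inversions
           are called with breakpoints in the true gaps", {
  tab <- simulate_anchor_tables(100, seed = 2)
  bl <- chain_blocks(tab$anchors, score_min = 50)
  rr <- detect_rearrangements(bl)
  expect_equal(nrow(rr), 0)

  one <- simulate_anchor_tables(200, inversions = list(c(80, 99)), seed = 4)
  blo <- chain_blocks(filter_anchors(one$anchors), score_min = 50)
  ro <- detect_rearrangements(blo)
  ro <- ro[ro$type == "inversion", ]
  expect_equal(nrow(ro), 1)
  tr <- one$truth$inversions[[1]]
  expect_gte(ro$bp_a_left_start, tr$gap_a_left[1])
  expect_lte(ro$bp_a_left_end, tr$gap_a_left[2])
  expect_gte(ro$bp_a_right_start, tr$gap_a_right[1])
  expect_lte(ro$bp_a_right_end, tr$gap_a_right[2])

  two <- simulate_anchor_tables(300, inversions = list(c(60, 79),
                                                       c(180, 199)),
                                seed = 6)
  blt <- chain_blocks(filter_anchors(two$anchors), score_min = 50)
  rt <- detect_rearrangements(blt)
  rt <- rt[rt$type == "inversion", ]
  expect_equal(nrow(rt), 2)
  expect_lt(rt$bp_a_left_end[1], rt$bp_a_left_start[2])  # ordered along A
})

test_that("blocks on different target chromosomes mark translocation
           boundaries", {
  a1 <- make_anchors(seq(0, by = 5000, length.out = 10),
                     seq(0, by = 5000, length.out = 10), chr_b = "B1")
  a2 <- make_anchors(seq(1e6, by = 5000, length.out = 10),
                     seq(0, by = 5000, length.out = 10), chr_b = "B2")
  a2$gene_a <- paste0("c", 1:10); a2$gene_b <- paste0("d", 1:10)
  bl <- chain_blocks(rbind(a1, a2))
  rr <- detect_rearrangements(bl)
  expect_true("translocation-boundary" %in% rr$type)
})

test_that("interval projection reproduces the 410-kb candidate region and
           its gene content", {
  ci <- project_interval(
    list(name = "Ca_Sb07g023810", chr = "chr7", pos = 58.78e6),
    list(name = "Ca_Sb07g023430", chr = "chr7", pos = 58.37e6))
  expect_equal(ci$length_bp, 410000)
  expect_equal(ci$start_bp, 58.37e6)

  # genes planted inside the closed interval are all recovered
  set.seed(14)
  inside <- sort(sample(seq(58.37e6, 58.78e6, by = 1), 40))
  outside <- c(58.36e6, 58.79e6, 60e6)
  ann <- data.frame(gene = paste0("g", seq_len(43)), chr = "chr7",
                    pos = c(inside, outside))
  ci2 <- project_interval(
    list(name = "d", chr = "chr7", pos = 58.78e6),
    list(name = "p", chr = "chr7", pos = 58.37e6), annotation = ann)
  expect_equal(nrow(ci2$genes), 40)

  expect_warning(project_interval(list(name = "m1", chr = "c", pos = 5),
                                  list(name = "m2", chr = "c", pos = 5)),
                 "zero-length")
  expect_error(project_interval(list(name = "m1", chr = "c1", pos = 5),
                                list(name = "m2", chr = "c2", pos = 9)),
               "different chromosomes")
})
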