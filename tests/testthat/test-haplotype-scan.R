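tall3 <- function(x) stats::setNames(x, c("T1", "T2", "T3"))

test_that("per-locus verdicts follow the dwarf-allele discrimination rule", {
  # all talls differ from the uniform dwarf allele
  expect_equal(assess_locus(tall3(c("b", "b", "b")), c("a", "a", "a"))$status,
               "discriminating")
  # one tall line shares the dwarf allele -> exception, line named
  v <- assess_locus(tall3(c("b", "b", "a")), c("a", "a", "a"))
  expect_equal(v$status, "exception")
  expect_equal(v$exception_lines, "T3")
  # dwarfs non-uniform -> broken
  expect_equal(assess_locus(tall3(c("b", "b", "a")), c("a", "b", "a"))$status,
               "broken")
  # missing calls ignored: still discriminating on the available calls
  expect_equal(assess_locus(tall3(c(NA, "b", "b")), c(NA, NA, "a"))$status,
               "discriminating")
  # a whole class missing -> uninformative
  expect_equal(assess_locus(tall3(c(NA, NA, NA)), c("a", "a", "a"))$status,
               "uninformative")
  # more sharers than the budget -> broken
  expect_equal(assess_locus(tall3(c("a", "a", "b")), c("a", "a", "a"))$status,
               "broken")
  expect_equal(assess_locus(tall3(c("a", "a", "b")), c("a", "a", "a"),
                            max_exceptions = 2)$status, "exception")
})

test_that("verdicts are invariant to allele relabeling", {
  relabel <- c(a = "q", b = "r", c = "s")
  t1 <- tall3(c("b", "c", "a")); d1 <- c("a", "a", "a")
  v1 <- assess_locus(t1, d1)
  v2 <- assess_locus(tall3(unname(relabel[t1])), unname(relabel[d1]))
  expect_equal(v1$status, v2$status)
  expect_equal(v1$exception_lines, v2$exception_lines)
})

test_that("the published allele matrix yields the 9-locus dwarf block with
           proximal boundary Ca_Sb07g023430", {
  hm <- read_haplotype_matrix(table2_path())
  bl <- delineate_block(hm)
  expect_equal(bl$block_loci,
               c("B224C4P2", "Ca_Sb07g023840", "RGR1963", "Ca_Sb07g023910",
                 "Ca_Sb07g024020", "Ca_Sb07g023810", "Ca_Sb07g023630",
                 "Ca_Sb07g023520", "Ca_Sb07g023440"))
  expect_equal(bl$proximal_boundary, "Ca_Sb07g023430")
  expect_true(bl$open_distal)
  # the three most proximal loci do not discriminate: the dwarf/tall
  # differentiation is lost there (two broken, one closed by the same
  # tall line's repeated sharing of the dwarf allele)
  v <- bl$verdicts
  expect_setequal(v$locus[v$status == "broken"], c("PSMP344", "PSMP305"))
  expect_equal(v$status[v$locus == "Ca_Sb07g023910"], "exception")
  expect_equal(v$status[v$locus == "Ca_Sb07g024020"], "discriminating")
})

test_that("all-discriminating matrices give an open-ended block", {
  m <- haplotype_matrix(rbind(c("b", "b", "b"), c("c", "c", "c"),
                              c("a", "a", "a")),
                        class = c("tall", "tall", "dwarf"))
  bl <- delineate_block(m)
  expect_length(bl$block_loci, 3)
  expect_true(bl$open_distal && bl$open_proximal)
})

test_that("a matrix without discriminating loci warns and returns an
           empty block", {
  m <- haplotype_matrix(rbind(c("a", "a"), c("a", "b"), c("b", "a")),
                        class = c("tall", "dwarf", "dwarf"))
  expect_warning(bl <- delineate_block(m), "no discriminating locus")
  expect_length(bl$block_loci, 0)
})

test_that("a simulated introgression breakpoint is recovered exactly", {
  set.seed(303)
  for (rep in 1:10) {
    n_loci <- 20
    brk <- sample(5:15, 1)   # last locus of the shared dwarf block
    loci <- sprintf("L%02d", 1:n_loci)
    mk <- function(alleles) alleles
    dwarfs <- t(sapply(1:3, function(i) {
      within_block <- rep("a", brk)
      outside <- sample(c("a", "b", "c"), n_loci - brk, replace = TRUE)
      c(within_block, outside)
    }))
    # force loss of dwarf uniformity right after the block
    dwarfs[1, brk + 1] <- "b"; dwarfs[2, brk + 1] <- "c"
    talls <- t(sapply(1:3, function(i)
      sample(c("b", "c", "d"), n_loci, replace = TRUE)))
    m <- haplotype_matrix(rbind(talls, dwarfs),
                          class = rep(c("tall", "dwarf"), each = 3))
    colnames(m$alleles) <- loci
    bl <- delineate_block(m)
    expect_equal(bl$proximal_boundary %in% loci[(brk + 1):n_loci], TRUE)
    expect_equal(utils::tail(bl$block_loci, 1), loci[brk])
  }
})

test_that("adding an all-missing line does not change the block", {
  hm <- read_haplotype_matrix(table2_path())
  ref <- delineate_block(hm)
  aug <- haplotype_matrix(rbind(hm$alleles,
                                ND = rep(NA_character_, ncol(hm$alleles))),
                          class = c(hm$class, "tall"),
                          line_id = c(hm$line_id, "blank"))
  bl <- delineate_block(aug)
  expect_identical(bl$block_loci, ref$block_loci)
  expect_identical(bl$proximal_boundary, ref$proximal_boundary)
})

test_that("dwarf lines share the full haplotype within the block", {
  hm <- read_haplotype_matrix(table2_path())
  conc <- haplotype_concordance(hm)
  dd <- conc[conc$class_pair == "dwarf-dwarf", ]
  expect_equal(nrow(dd), 3)
  expect_true(all(dd$sharing == 1))
  tt <- conc[conc$class_pair == "tall-tall", ]
  expect_true(all(tt$sharing < 1))

  # two identical lines share everything
  m <- haplotype_matrix(rbind(c("a", "a"), c("a", "a"), c("b", "c")),
                        class = c("dwarf", "dwarf", "tall"))
  cc <- haplotype_concordance(m, block_loci = colnames(m$alleles))
  expect_equal(cc$sharing[cc$line1 == "L1" & cc$line2 == "L2"], 1)
})

test_that("random binary alleles share about half their calls", {
  set.seed(77)
  k <- 2000
  m <- haplotype_matrix(rbind(sample(c("a", "b"), k, replace = TRUE),
                              sample(c("a", "b"), k, replace = TRUE),
                              rep("a", k)),
                        class = c("tall", "tall", "dwarf"))
  cc <- haplotype_concordance(m, block_loci = colnames(m$alleles))
  sh <- cc$sharing[cc$line1 == "L1" & cc$line2 == "L2"]
  expect_lt(abs(sh - 0.5), 3 * sqrt(0.25 / k))
})
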