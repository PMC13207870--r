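# Exon-based annotation: strand grouping, gap splitting, order validation,
# pseudogene classification.

test_that("the five-exon strand pattern (+,-,-,-,+) yields three transcripts", {
  p <- make_placements("nad1", 1:5,
                       starts = c(100, 1000, 2000, 3000, 4000),
                       ends = c(480, 1060, 2190, 3220, 4110),
                       strands = c("+", "-", "-", "-", "+"))
  g <- groupByStrand(p)
  expect_length(g, 3)
  expect_identical(lapply(g, function(x) x@placements$exon),
                   list(1L, 2:4, 5L))
  expect_identical(vapply(g, function(x) x@label, character(1)),
                   c("1", "2", "3"))
})

test_that("uniform strand gives a single transcript", {
  p <- make_placements("nad2", 1:5, starts = (1:5) * 1000,
                       ends = (1:5) * 1000 + 100, strands = rep("+", 5))
  expect_length(groupByStrand(p), 1)
})

test_that("group counts match the run-length oracle on random strand vectors", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(1:8, 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    p <- make_placements("g", 1:n, starts = (1:n) * 500,
                         ends = (1:n) * 500 + 99, strands = strands)
    expect_identical(length(groupByStrand(p)), rle_group_count(strands))
  }
})

test_that("a chromosome change splits a group like a strand flip", {
  p <- make_placements("nad5", 1:3, starts = c(100, 700, 1300),
                       ends = c(300, 900, 1500), strands = rep("+", 3),
                       subjects = c("chr1", "chr1", "chr2"))
  g <- groupByStrand(p)
  expect_length(g, 2)
  expect_identical(g[[2]]@subjectId, "chr2")
})

test_that("gap splitting produces the documented sublabels", {
  p <- make_placements("nad1", 2:4, starts = c(1000, 2000, 40000),
                       ends = c(1100, 2100, 40100), strands = rep("-", 3))
  grp <- mitoPCG:::.newGroup("2", p)
  out <- splitByGap(grp, threshold = 5000)
  expect_length(out, 2)
  expect_identical(vapply(out, function(x) x@label, character(1)),
                   c("2-1", "2-2"))
  expect_identical(lapply(out, function(x) x@placements$exon), list(2:3, 4L))
  # threshold larger than any gap: the group comes back unchanged
  expect_identical(splitByGap(grp, threshold = 1e6), list(grp))
  # both gaps above threshold: three singletons
  out3 <- splitByGap(grp, threshold = 500)
  expect_length(out3, 3)
  # overlapping exons are flagged and treated as gap 0
  po <- make_placements("g", 1:2, starts = c(100, 150), ends = c(300, 350),
                        strands = rep("+", 2))
  expect_warning(res <- splitByGap(mitoPCG:::.newGroup("1", po), 50),
                 "overlap")
  expect_length(res, 1)
})

test_that("two-pass composition equals the brute-force segmentation oracle", {
  # exhaustive over all strand vectors and gap configurations for <= 6 exons
  thr <- 1000
  for (n in 2:6) {
    strandGrid <- expand.grid(rep(list(c("+", "-")), n),
                              stringsAsFactors = FALSE)
    gapGrid <- expand.grid(rep(list(c(200, 5000)), n - 1))
    for (si in seq_len(nrow(strandGrid))) {
      strands <- unlist(strandGrid[si, ])
      for (gi in seq_len(nrow(gapGrid))) {
        gaps <- unlist(gapGrid[gi, ])
        starts <- cumsum(c(1, head(rep(100, n), -1) + gaps + 1))
        ends <- starts + 99
        p <- make_placements("g", 1:n, starts, ends, strands)
        groups <- groupByStrand(p)
        final <- do.call(c, lapply(groups, splitByGap, threshold = thr))
        got <- lapply(final, function(x) x@placements$exon)
        truth <- brute_force_segments(strands, starts, ends, thr)
        expect_identical(got, lapply(truth, as.integer))
        # conservation: no exon lost or duplicated across both passes
        expect_identical(sort(unlist(got)), 1:n)
      }
    }
  }
})

test_that("splitting with an effectively infinite threshold is a no-op", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    starts <- cumsum(sample(500:8000, n))
    p <- make_placements("g", 1:n, starts = starts, ends = starts + 99,
                         strands = sample(c("+", "-"), n, TRUE))
    g1 <- groupByStrand(p)
    g2 <- do.call(c, lapply(g1, splitByGap, threshold = .Machine$integer.max))
    expect_identical(lapply(g2, function(x) x@placements$exon),
                     lapply(g1, function(x) x@placements$exon))
  }
})

test_that("exon-order validation follows the strand-mirrored rule, opt-in", {
  # plus strand, exon2 before exon1 on the axis -> one violation
  p <- make_placements("g", 1:2, starts = c(500, 100), ends = c(600, 200),
                       strands = rep("+", 2))
  grp <- mitoPCG:::.newGroup("1", p)
  v <- validateExonOrder(grp, enabled = TRUE)
  expect_identical(nrow(v), 1L)
  expect_identical(c(v$exon_from, v$exon_to), c(1L, 2L))
  # minus strand, exon1 downstream of exon2 on the axis -> no violation
  pm <- make_placements("g", 1:2, starts = c(500, 100), ends = c(600, 200),
                        strands = rep("-", 2))
  expect_identical(nrow(validateExonOrder(mitoPCG:::.newGroup("1", pm),
                                          enabled = TRUE)), 0L)
  # disabled (the default) returns an empty list even on violating input
  expect_identical(nrow(validateExonOrder(grp)), 0L)
})

test_that("classification flags pseudogenes and trans-splicing correctly", {
  lib <- paper_library()
  mkGroups <- function(gene, n, splitAt = integer(0)) {
    p <- make_placements(gene, 1:n, starts = (1:n) * 1000,
                         ends = (1:n) * 1000 + 99,
                         strands = rep("+", n))
    gid <- cumsum(seq_len(n) %in% splitAt)
    lapply(split(seq_len(n), gid), function(ix)
      mitoPCG:::.newGroup("x", p[ix, , drop = FALSE]))
  }
  # nad1 with all 5 exons in 3 groups: trans-spliced, not pseudogene
  a <- classifyGene("nad1", mkGroups("nad1", 5, splitAt = c(2, 5)), lib)
  expect_true(isTransSpliced(a)); expect_false(isPseudogene(a))
  # nad4 with 3 of 4 exons: pseudogene by exon count
  b <- classifyGene("nad4", mkGroups("nad4", 3), lib)
  expect_true(isPseudogene(b))
  expect_identical(pseudogeneReasons(b), "EXON_COUNT_MISMATCH")
  # cox1 placed once: one group, no flags
  c1 <- classifyGene("cox1", mkGroups("cox1", 1), lib)
  expect_false(isTransSpliced(c1)); expect_false(isPseudogene(c1))
  # nothing placed: missing gene
  d <- classifyGene("cox1", list(), lib)
  expect_identical(pseudogeneReasons(d), "MISSING_GENE")
  expect_false(isTransSpliced(d))
  # order violation only counts when the check is enabled
  pv <- make_placements("cox2", c(1, 2, 3), starts = c(5000, 100, 9000),
                        ends = c(5100, 200, 9100), strands = rep("+", 3))
  gv <- list(mitoPCG:::.newGroup("1", pv))
  expect_false(isPseudogene(classifyGene("cox2", gv, lib)))
  e <- classifyGene("cox2", gv, lib, orderCheck = TRUE)
  expect_true("EXON_ORDER_VIOLATION" %in% pseudogeneReasons(e))
  expect_error(classifyGene("nope", list(), lib), "unknown gene")
})
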