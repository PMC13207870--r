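# Supermatrix construction: shared genes, concatenation, conserved-region
# fills, gene exclusion, PHYLIP handoff.

rand_alignment <- function(taxa, width) {
  stats::setNames(replicate(length(taxa), rand_dna(width)), taxa)
}

test_that("shared genes are the sorted intersection across all sets", {
  expect_identical(sharedGenes(list(c("a", "b", "c"), c("a", "b")),
                               c("a", "b", "d")), c("a", "b"))
  expect_identical(sharedGenes(list(c("x", "y")), c("y", "x")), c("x", "y"))
  expect_error(sharedGenes(list(c("a"), c("b")), c("a", "b")), "no gene")
  set.seed(81)
  pool <- paste0("g", 1:15)
  for (i in 1:20) {
    sets <- replicate(4, sample(pool, sample(5:15, 1)), simplify = FALSE)
    og <- sample(pool, sample(5:15, 1))
    truth <- sort(Reduce(intersect, c(sets, list(og))))
    if (length(truth) == 0) {
      expect_error(sharedGenes(sets, og))
    } else {
      expect_identical(sharedGenes(sets, og), truth)
    }
  }
})

test_that("concatenation records tiling partitions", {
  set.seed(82)
  taxa <- c("t1", "t2", "t3")
  pg <- list(atp1 = rand_alignment(taxa, 300), cob = rand_alignment(taxa, 150))
  sm <- concatenateAlignments(pg)
  expect_identical(partitions(sm),
                   data.frame(gene = c("atp1", "cob"), start = c(1L, 301L),
                              end = c(300L, 450L), stringsAsFactors = FALSE))
  expect_identical(unique(BiocGenerics::width(alignmentRows(sm))), 450L)
  row <- as.character(alignmentRows(sm)[["t2"]])
  expect_identical(substr(row, 1, 300), pg$atp1[["t2"]])
  expect_identical(substr(row, 301, 450), pg$cob[["t2"]])
  # single gene: the matrix equals that alignment
  sm1 <- concatenateAlignments(pg["atp1"])
  expect_identical(stats::setNames(as.character(alignmentRows(sm1)), taxa(sm1)),
                   pg$atp1[sort(taxa)])
  # permuting the gene order permutes the partitions consistently
  sm2 <- concatenateAlignments(pg, geneOrder = c("cob", "atp1"))
  expect_identical(partitions(sm2)$gene, c("cob", "atp1"))
  expect_identical(partitions(sm2)$end, c(150L, 450L))
  expect_identical(substr(as.character(alignmentRows(sm2)[["t2"]]), 1, 150),
                   pg$cob[["t2"]])
  # a taxon missing from one gene is an error naming taxon and gene
  pg$cob <- pg$cob[c("t1", "t2")]
  expect_error(concatenateAlignments(pg), "cob.*t3")
})

test_that("conserved-region fills are permitted only when cohort-identical", {
  rows <- c(sp1_a = "ACGTACGTAC", sp1_b = "ACGTACGTAC", sp2_a = "ACGTACGTAC")
  sp <- c(sp1_a = "sp1", sp1_b = "sp1", sp2_a = "sp2")
  gap <- rows
  substr(gap["sp1_a"], 4, 6) <- "---"
  r <- fillMissing(gap, "sp1_a", c(4, 6), sp, gene = "nad5")
  expect_true(r$filled)
  expect_identical(as.character(r$alignment[["sp1_a"]]), rows[["sp1_a"]])
  expect_identical(r$log$action, "filled")
  expect_identical(r$log$donor, "sp1_b")
  # one cohort row differing at one column -> refusal, alignment untouched
  div <- gap
  substr(div["sp2_a"], 5, 5) <- "T"
  r2 <- fillMissing(div, "sp1_a", c(4, 6), sp)
  expect_false(r2$filled)
  expect_match(r2$log$reason, "not completely conserved")
  expect_identical(r2$alignment, div)
  # no conspecific donor -> refusal
  sp2 <- c(sp1_a = "sp1", sp1_b = "spX", sp2_a = "sp2")
  r3 <- fillMissing(gap, "sp1_a", c(4, 6), sp2)
  expect_false(r3$filled)
  expect_match(r3$log$reason, "no conspecific donor")
  # fills never change columns outside the region
  expect_identical(substr(as.character(r$alignment[["sp1_a"]]), 7, 10),
                   substr(gap[["sp1_a"]], 7, 10))
})

test_that("taxa with extensive missing data are recommended for exclusion", {
  set.seed(83)
  taxa <- c("sp1_a", "sp1_b", "sp2_a")
  pg <- list(g1 = rand_alignment(taxa, 200), g2 = rand_alignment(taxa, 200))
  pg$g2[["sp1_a"]] <- strrep("-", 200)   # fully missing gene
  sm <- concatenateAlignments(pg)
  expect_identical(recommendExclusion(sm, maxMissing = 0.2), "sp1_a")
  expect_identical(recommendExclusion(sm, maxMissing = 0.6), character(0))
})

test_that("gene exclusion reduces the matrix inputs exactly", {
  lib <- paper_library()
  set.seed(84)
  pg <- stats::setNames(lapply(geneNames(lib), function(g)
    rand_alignment(c("t1", "t2"), 30)), geneNames(lib))
  reduced <- excludeGenes(pg, c("atp9", "rpl10", "nad3", "nad4L"))
  expect_length(reduced, 26)
  expect_false(any(c("atp9", "rpl10", "nad3", "nad4L") %in% names(reduced)))
  expect_identical(excludeGenes(pg, character(0)), pg)
  expect_error(excludeGenes(pg, "made_up"), "unknown gene")
  expect_error(excludeGenes(pg, names(pg)), "empty matrix")
})

test_that("relaxed PHYLIP round-trips exactly and matches ape's reader", {
  set.seed(85)
  taxa <- c("R_rosea_HB_1", "R_crenulata_XZ_1", "Sedum_outgroup")
  sm <- concatenateAlignments(list(g1 = rand_alignment(taxa, 120),
                                   g2 = rand_alignment(taxa, 60)))
  f <- withr::local_tempfile(fileext = ".phy")
  writePhylip(sm, f)
  rt <- readPhylip(f)
  expect_identical(rt, stats::setNames(as.character(alignmentRows(sm)),
                                       taxa(sm)))
  hdr <- strsplit(readLines(f, n = 1), "\\s+")[[1]]
  expect_identical(as.integer(hdr), c(3L, 180L))
  skip_if_not_installed("ape")
  apeRows <- ape::read.dna(f, format = "sequential")
  expect_identical(rownames(apeRows), taxa(sm))
  expect_identical(toupper(paste(as.character(apeRows[1, ]), collapse = "")),
                   rt[[1]])
})

test_that("the phylo handoff embeds the model and replicate count", {
  set.seed(86)
  sm <- concatenateAlignments(list(g1 = rand_alignment(c("a", "b"), 90),
                                   g2 = rand_alignment(c("a", "b"), 30)))
  d <- withr::local_tempdir()
  h <- emitPhyloHandoff(sm, d)
  expect_match(h$command, "GTR+GAMMA+I", fixed = TRUE)
  expect_match(h$command, "1000", fixed = TRUE)
  expect_true(all(file.exists(h$files)))
  parts <- readLines(h$files["partitions"])
  expect_identical(parts, c("DNA, g1 = 1-90", "DNA, g2 = 91-120"))
  # custom model strings pass through verbatim
  h2 <- emitPhyloHandoff(sm, d, model = "GTRCAT", bootstraps = 250)
  expect_match(h2$command, "GTRCAT", fixed = TRUE)
  expect_match(h2$command, "250", fixed = TRUE)
})
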