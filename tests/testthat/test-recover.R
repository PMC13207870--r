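# Short-read PCG recovery: read-pair extraction, CDS reconstruction, error
# logging, output organization, SNP counting.

test_that("the union rule keeps a pair when either mate matches", {
  lib <- paper_library()
  nad4 <- splicedCDS(geneModel(lib, "nad4"))
  set.seed(61)
  m1 <- c(p1 = substr(nad4, 501, 650),   # inside nad4 exon 2
          p2 = rand_dna(150))
  m2 <- c(p1 = rand_dna(150),            # mate matches nothing
          p2 = rand_dna(150))
  res <- extractReadPairs(m1, m2, lib, genes = "nad4")
  expect_identical(res$nad4$names, "p1")
  expect_identical(unname(res$nad4$mate1), unname(m1["p1"]))
  expect_identical(unname(res$nad4$mate2), unname(m2["p1"]))
  # neither mate matches -> pair in no set
  res2 <- extractReadPairs(c(q = rand_dna(150)), c(q = rand_dna(150)), lib,
                           genes = "nad4")
  expect_length(res2, 0)
  # orphan mates are logged and dropped
  expect_warning(
    extractReadPairs(c(a = substr(nad4, 1, 150), b = rand_dna(150)),
                     c(a = substr(nad4, 200, 349)), lib, genes = "nad4"),
    "orphan")
})

test_that("simulated reads from a planted locus are captured with recall 1", {
  lib <- paper_library()
  sim <- makeGenome(lib, list(geneLayout("cox1")), seed = 62)
  reads <- simulateReads(sim$genome, coverage = 50, seed = 62)
  res <- extractReadPairs(reads$mate1, reads$mate2, lib, genes = "cox1")
  # truth manifest: pairs where either mate overlaps the locus by >= 50 bp
  m <- sim$manifest[sim$manifest$gene == "cox1", ]
  info <- do.call(rbind, strsplit(names(reads$mate1), ":"))
  fs <- as.integer(info[, 3]); fe <- as.integer(info[, 4])
  ov <- function(s, e) pmax(0, pmin(e, m$end) - pmax(s, m$start) + 1)
  truth <- names(reads$mate1)[ov(fs, fs + 149) >= 50 | ov(fe - 149, fe) >= 50]
  expect_true(all(truth %in% res$cox1$names))
  expect_identical(sort(res$cox1$names), sort(truth))
})

test_that("read-pair extraction is independent of input read order", {
  lib <- paper_library()
  cob <- splicedCDS(geneModel(lib, "cob"))
  set.seed(63)
  nm <- sprintf("r%02d", 1:20)
  m1 <- stats::setNames(c(substring(cob, seq(1, 751, 150),
                                    seq(150, 900, 150)),
                          replicate(14, rand_dna(150))), nm)
  m2 <- stats::setNames(replicate(20, rand_dna(150)), nm)
  a <- extractReadPairs(m1, m2, lib, genes = "cob")
  o <- sample(20)
  b <- extractReadPairs(m1[o], m2[o], lib, genes = "cob")
  expect_identical(a$cob, b$cob)
})

test_that("single-exon reconstruction picks the longest alignment", {
  lib <- paper_library()
  cox1 <- geneModel(lib, "cox1")
  cds <- splicedCDS(cox1)
  set.seed(64)
  # full-length 100% hit -> complete CDS equal to the planted gene
  contigs <- c(ctgA = paste0(rand_dna(80), cds, rand_dna(80)))
  res <- reconstructSingleExon(cox1, contigs)
  expect_true(isComplete(res$cds))
  expect_identical(cdsSequence(res$cds), cds)
  expect_identical(nrow(res$errors), 0L)
  # minus-strand contig is strand-resolved
  res2 <- reconstructSingleExon(cox1, c(ctgB = rc(contigs[["ctgA"]])))
  expect_identical(cdsSequence(res2$cds), cds)
  # alignment-length rule: hits of 500 vs 480 -> the 500 bp hit is chosen
  contigs3 <- c(long = substr(cds, 1, 500), short = substr(cds, 21, 500))
  res3 <- reconstructSingleExon(cox1, contigs3)
  expect_identical(res3$cds@sourceContigs, "long")
  # coverage arithmetic: contig covering 1..290 of a 300 bp gene
  set.seed(65)
  toy <- newGeneModel("toy", mitoPCG:::randomCDS(300))
  res4 <- reconstructSingleExon(toy, c(c1 = substr(splicedCDS(toy), 1, 290)))
  expect_false(isComplete(res4$cds))
  expect_identical(cdsGaps(res4$cds),
                   data.frame(cds_start = 291L, cds_end = 300L,
                              stringsAsFactors = FALSE))
  # no hit at all -> absent CDS plus a MISSING_EXON entry
  res5 <- reconstructSingleExon(toy, c(c1 = rand_dna(400)))
  expect_null(res5$cds)
  expect_identical(res5$errors$reason, "MISSING_EXON")
})

test_that("multi-exon reconstruction splices exons and flags split exons", {
  lib <- paper_library()
  nad4 <- geneModel(lib, "nad4")
  sim <- makeGenome(lib, list(geneLayout("nad4")), seed = 66)
  # one contig per exon
  m <- sim$manifest
  contigs <- stats::setNames(lapply(seq_len(nrow(m)), function(i)
    substr(sim$genome[[m$chrom[i]]], m$start[i] - 50, m$end[i] + 50)),
    paste0("ctg", seq_len(nrow(m))))
  res <- reconstructMultiExon(nad4, unlist(contigs))
  expect_true(isComplete(res$cds))
  expect_identical(cdsSequence(res$cds), splicedCDS(nad4))
  expect_identical(nrow(res$errors), 0L)

  # cox2 exon2 split 60/40 across two contigs
  cox2 <- geneModel(lib, "cox2")
  ex <- as.character(exonSequences(cox2))
  cut <- round(nchar(ex[2]) * 0.6)
  set.seed(67)
  contigs2 <- c(c1 = paste0(rand_dna(60), ex[1], rand_dna(60)),
                c2 = paste0(rand_dna(60), substr(ex[2], 1, cut)),
                c3 = paste0(substr(ex[2], cut + 1, nchar(ex[2])), rand_dna(60)),
                c4 = paste0(rand_dna(60), ex[3], rand_dna(60)))
  res2 <- reconstructMultiExon(cox2, contigs2)
  split <- res2$errors[res2$errors$reason == "EXON_SPLIT_ACROSS_CONTIGS", ]
  expect_identical(nrow(split), 1L)
  expect_identical(split$exon, 2L)
  expect_false(isComplete(res2$cds))

  # a deleted exon surfaces as MISSING_EXON with the exon's CDS interval
  contigs3 <- contigs2[c("c1", "c4")]
  res3 <- reconstructMultiExon(cox2, contigs3)
  expect_true(2L %in% res3$errors$exon[res3$errors$reason == "MISSING_EXON"])
  lens <- exonLengths(cox2)
  expect_true(any(res3$cds@gaps$cds_start == lens[1] + 1 &
                    res3$cds@gaps$cds_end == lens[1] + lens[2]))
})

test_that("the 22 bp nad5 exon is recovered via the flank-padded reference", {
  lib <- paper_library()
  sim <- makeGenome(lib, list(geneLayout("nad5")), seed = 68)
  genome <- sim$genome[[1]]
  nad5 <- geneModel(lib, "nad5")
  m3 <- sim$manifest[sim$manifest$exon == 3, ]
  ctx <- substr(genome, m3$start - 200, m3$end + 200)
  aug <- augmentWithFlanks(nad5, ctx, flankLen = 150)
  expect_identical(nchar(as.character(exonSequences(aug)[[3]])), 322L)
  res <- reconstructMultiExon(aug, c(chr1 = genome))
  expect_true(isComplete(res$cds))
  # the final CDS contains exactly the 22 bp exon, flanks stripped
  expect_identical(cdsSequence(res$cds), splicedCDS(nad5))
})

test_that("outputs are organized gene-wise and sample-wise, deterministically", {
  set.seed(69)
  mk <- function() stats::setNames(lapply(1:3, function(i) rand_dna(90)),
                                   c("atp1", "cob", "nad3"))
  samples <- list(s2 = mk(), s1 = mk())
  samples$s1$nad3 <- NULL   # gene missing in one sample
  d <- withr::local_tempdir()
  out <- organizeOutputs(samples, d)
  expect_identical(sort(list.files(file.path(d, "by_gene"))),
                   c("atp1.fasta", "cob.fasta", "nad3.fasta"))
  expect_identical(sort(list.files(file.path(d, "by_sample"))),
                   c("s1.fasta", "s2.fasta"))
  g <- Biostrings::readDNAStringSet(file.path(d, "by_gene", "atp1.fasta"))
  expect_identical(names(g), c("s1", "s2"))
  n3 <- Biostrings::readDNAStringSet(file.path(d, "by_gene", "nad3.fasta"))
  expect_identical(names(n3), "s2")
  miss <- attr(out, "missing")
  expect_identical(miss$sample, "s1")
  expect_identical(miss$gene, "nad3")
  s1 <- Biostrings::readDNAStringSet(file.path(d, "by_sample", "s1.fasta"))
  expect_identical(names(s1), c("atp1", "cob"))
  # idempotence: re-running overwrites to identical bytes
  before <- readLines(file.path(d, "by_gene", "atp1.fasta"))
  organizeOutputs(samples, d)
  expect_identical(readLines(file.path(d, "by_gene", "atp1.fasta")), before)
})

test_that("variable-site counting matches a per-column scan", {
  expect_identical(countVariableSites(c(a = "ACGT", b = "ACGT")), 0L)
  expect_identical(countVariableSites(c(a = "ACGTAA", b = "TCGTCC")), 3L)
  # gaps and N are not states
  expect_identical(countVariableSites(c(a = "A-GN", b = "ACG-", c = "ACGA")), 0L)
  expect_error(countVariableSites(c(a = "ACG", b = "ACGT")), "equal length")
  set.seed(70)
  for (i in 1:10) {
    n <- sample(3:6, 1); w <- 120
    rows <- replicate(n, paste(sample(c("A", "C", "G", "T", "-", "N"), w,
                                      replace = TRUE,
                                      prob = c(rep(0.22, 4), 0.06, 0.06)),
                               collapse = ""))
    names(rows) <- paste0("t", 1:n)
    mat <- do.call(rbind, strsplit(rows, ""))
    truth <- sum(apply(mat, 2, function(col)
      length(unique(setdiff(col, c("-", "N")))) >= 2))
    expect_identical(countVariableSites(rows), as.integer(truth))
  }
})

test_that("error logs serialize as TSV", {
  e <- mitoPCG:::.errorEntry("cox2", 2L, "EXON_SPLIT_ACROSS_CONTIGS", "d")
  f <- withr::local_tempfile()
  writeErrorLog(e, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_identical(back$reason, "EXON_SPLIT_ACROSS_CONTIGS")
})
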