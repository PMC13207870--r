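# Codon rules: translation, RNA-editing qualifiers, non-canonical notes,
# missing-stop boundary resolution, internal-stop scanning.

test_that("translation follows the standard code with exceptions", {
  expect_identical(as.character(translateCDS("ATGGCTTAA")), "MA")
  expect_identical(
    as.character(translateCDS("ACGGCTTAA",
                              data.frame(codon_index = 1, amino_acid = "M"))),
    "MA")
  # TERM exception terminates translation at that codon
  expect_identical(
    as.character(translateCDS("ATGGCTCAAGCT",
                              data.frame(codon_index = 3, amino_acid = "TERM"))),
    "MA")
  # trailing incomplete codon dropped with a flag
  tr <- translateCDS("ATGGCTTA")
  expect_identical(as.character(tr), "MA")
  expect_true(attr(tr, "incomplete_tail"))
  expect_error(translateCDS("ATGQQQ"), "non-ACGTN")
  expect_error(translateCDS("ATGGCT",
                            data.frame(codon_index = 9, amino_acid = "M")),
               "out of range")
})

test_that("translation agrees with an independent codon table on random CDSs", {
  set.seed(31)
  for (i in 1:10) {
    cds <- rand_dna(3 * 300)
    expect_identical(as.character(translateCDS(cds)), oracle_translate(cds))
  }
})

test_that("start-gain editing emits the transl_except qualifier and renders M", {
  lib <- paper_library()
  model <- geneModel(lib, "nad4L")
  cds <- splicedCDS(model)
  expect_identical(substr(cds, 1, 3), "ACG")
  asm <- codingAssembly("nad4L", cds,
                        genomicPositions = seq(2001, 2000 + nchar(cds)))
  asm <- applyEditingExceptions(asm, editingSites(model))
  expect_identical(qualifiers(asm), "/transl_except=(pos:2001..2003,aa:Met)")
  expect_identical(substr(proteinSequence(asm), 1, 1), "M")
  # the stored CDS nucleotides are never changed
  expect_identical(cdsSequence(asm), cds)
})

test_that("stop-gain editing emits aa:TERM and truncates the 3' extension", {
  lib <- paper_library()
  model <- geneModel(lib, "atp6")
  cds <- splicedCDS(model)
  expect_identical(substr(cds, nchar(cds) - 2, nchar(cds)), "CAA")
  asm <- codingAssembly("atp6", cds,
                        genomicPositions = seq_len(nchar(cds)))
  asm <- applyEditingExceptions(asm, editingSites(model))
  expect_match(qualifiers(asm), "aa:TERM", fixed = TRUE)
  expect_identical(nchar(proteinSequence(asm)), as.integer(nchar(cds) / 3 - 1))
})

test_that("an unedited ATG gene passes through unchanged", {
  lib <- paper_library()
  model <- geneModel(lib, "cox1")
  cds <- splicedCDS(model)
  asm <- codingAssembly("cox1", cds)
  out <- applyEditingExceptions(asm, editingSites(model))
  out <- annotateNonCanonical(out, model)
  expect_identical(qualifiers(out), character(0))
  expect_identical(proteinSequence(out), proteinSequence(asm))
})

test_that("non-canonical codon notes are byte-exact and generic", {
  lib <- paper_library()
  cob <- geneModel(lib, "cob")
  asm <- annotateNonCanonical(codingAssembly("cob", splicedCDS(cob)), cob)
  expect_identical(
    qualifiers(asm),
    "/note=Translation initiates from a non-canonical ATT start codon.")
  expect_identical(substr(proteinSequence(asm), 1, 1), "M")
  # GTG start (species variant of atp8)
  set.seed(32)
  gtg <- newGeneModel("atp8", mitoPCG:::randomCDS(480, start = "GTG"),
                      startCodon = "GTG")
  a2 <- annotateNonCanonical(codingAssembly("atp8", splicedCDS(gtg)), gtg)
  expect_match(qualifiers(a2), "non-canonical GTG start codon", fixed = TRUE)
  # GGA stop (species variant of cox1)
  gga <- newGeneModel("cox1", mitoPCG:::randomCDS(300, stop = "NONE"),
                      stopCodon = "GGA")
  cds <- paste0(substr(splicedCDS(gga), 1, 297), "GGA")
  gga <- newGeneModel("cox1", cds, stopCodon = "GGA")
  a3 <- annotateNonCanonical(codingAssembly("cox1", cds), gga)
  expect_identical(
    qualifiers(a3),
    "/note=Translation terminates at a non-canonical GGA stop codon.")
  # declared codon disagreeing with the CDS yields a warning qualifier + flag
  off <- newGeneModel("cob", paste0("ATG", substr(splicedCDS(cob), 4, 1182)),
                      startCodon = "ATT")
  a4 <- annotateNonCanonical(codingAssembly("cob", splicedCDS(off)), off)
  expect_match(qualifiers(a4), "disagrees")
  expect_true(isTRUE(boundaryNote(a4)$codon_mismatch))
})

test_that("missing-stop boundary resolution selects by score, then ORF", {
  lib <- paper_library()
  nad6 <- geneModel(lib, "nad6")
  cds <- splicedCDS(nad6)
  set.seed(33)
  region <- paste0(rand_dna(300), cds, rand_dna(300))
  res <- resolveMissingStop(nad6, region)
  expect_identical(res$form, "reference")
  expect_identical(res$boundary, 300L + nchar(cds))
  # argmax rule: a longer-aligning variant wins
  longer <- paste0(cds, substr(region, 301 + nchar(cds), 360 + nchar(cds)))
  lib2 <- addVariantForm(lib, "nad6", "extended", longer)
  res2 <- resolveMissingStop(geneModel(lib2, "nad6"), region)
  expect_identical(res2$form, "extended")
  expect_identical(res2$boundary, 360L + nchar(cds))
  # no variant aligns -> MISSING_GENE error
  expect_error(resolveMissingStop(nad6, rand_dna(1000)), "MISSING_GENE")
  expect_error(resolveMissingStop(geneModel(lib, "cox1"), region),
               "neither missing_stop")
})

test_that("equal scores are broken by the longest identifiable ORF", {
  # two stop-free variants of equal length planted at different loci: equal
  # alignment scores; the tie goes to the variant with the longer ORF
  set.seed(34)
  v1 <- mitoPCG:::randomCDS(600, stop = "NONE")           # ORF spans all 600
  v2 <- paste0(substr(mitoPCG:::randomCDS(570, stop = "NONE"), 1, 567),
               "TAA", rand_dna(30))                       # ORF ends at 570
  expect_identical(nchar(v1), nchar(v2))
  region <- paste0(rand_dna(100), v2, rand_dna(400), v1, rand_dna(100))
  model <- newGeneModel("nad6x", v1, stopCodon = "NONE", missingStop = TRUE,
                        variantForms = c(longer = v1, shorter = v2))
  # both variants align somewhere at full length and 100% identity
  res <- resolveMissingStop(model, region)
  expect_identical(res$scores$score[1], res$scores$score[2])
  expect_identical(res$form, "longer")
  # permutation invariance in the variant list
  model2 <- newGeneModel("nad6x", v1, stopCodon = "NONE", missingStop = TRUE,
                         variantForms = c(shorter = v2, longer = v1))
  expect_identical(resolveMissingStop(model2, region)$form, "longer")
})

test_that("a planted frameshift moves the boundary to the longest-ORF end", {
  lib <- paper_library()
  nad6 <- geneModel(lib, "nad6")
  cds <- splicedCDS(nad6)
  set.seed(35)
  # single-nucleotide deletion after 619 bp
  mutated <- paste0(substr(cds, 1, 619), substr(cds, 621, nchar(cds)),
                    rand_dna(120))
  region <- paste0(rand_dna(250), mutated, rand_dna(250))
  # exhaustive ORF scan of the mutated gene (the oracle)
  ncod <- nchar(mutated) %/% 3
  codons <- substring(mutated, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  stopAt <- which(codons %in% c("TAA", "TAG", "TGA"))
  orfEnd <- if (length(stopAt)) 3 * stopAt[1] else 3 * ncod
  observed <- substr(mutated, 1, orfEnd)
  lib2 <- addVariantForm(lib, "nad6", "observed", observed)
  res <- resolveMissingStop(geneModel(lib2, "nad6"), region)
  expect_identical(res$form, "observed")
  expect_identical(res$boundary, as.integer(250 + orfEnd))
})

test_that("internal stop codons are reported with 1-based codon indices", {
  # rpl16-style CDS with a TAA created at codon 73
  set.seed(36)
  cds <- mitoPCG:::randomCDS(540)
  substr(cds, 217, 219) <- "TAA"  # codon 73
  hits <- scanInternalStops(cds)
  expect_identical(hits$codon_index, 73L)
  expect_identical(hits$codon, "TAA")
  # terminal stop only -> empty
  expect_identical(nrow(scanInternalStops(mitoPCG:::randomCDS(300))), 0L)
  # random CDSs agree with a naive triplet scan
  for (i in 1:10) {
    cds <- rand_dna(3 * 120)
    got <- scanInternalStops(cds)
    ncod <- 120
    codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    truth <- which(codons[-ncod] %in% c("TAA", "TAG", "TGA"))
    expect_identical(got$codon_index, as.integer(truth))
  }
})
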