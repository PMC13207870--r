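#' @import methods
NULL

EDITING_EFFECTS <- c("start_gain", "stop_gain", "missense", "synonymous")
PSEUDO_REASONS <- c("EXON_COUNT_MISMATCH", "EXON_ORDER_VIOLATION", "MISSING_GENE")
RECOVERY_REASONS <- c("EXON_SPLIT_ACROSS_CONTIGS", "MISSING_EXON", "AMBIGUOUS_HIT")

# Empty editing-site table (the canonical column layout).
emptyEditingSites <- function() {
  data.frame(cds_position = integer(0), genomic_codon = character(0),
             edited_codon = character(0), effect = character(0),
             amino_acid = character(0), stringsAsFactors = FALSE)
}

validateEditingSites <- function(df) {
  need <- names(emptyEditingSites())
  if (!is.data.frame(df) || !all(need %in% names(df)))
    return("editingSites must be a data.frame with columns cds_position, genomic_codon, edited_codon, effect, amino_acid")
  if (nrow(df) == 0) return(character(0))
  msg <- character(0)
  if (any(nchar(df$genomic_codon) != 3) || any(nchar(df$edited_codon) != 3))
    msg <- c(msg, "editing-site codons must be 3 nt")
  if (!all(df$effect %in% EDITING_EFFECTS))
    msg <- c(msg, sprintf("editing-site effect must be one of %s",
                          paste(EDITING_EFFECTS, collapse = ", ")))
  # C-to-U type: edited codon differs from genomic only where C becomes T
  for (i in seq_len(nrow(df))) {
    g <- strsplit(df$genomic_codon[i], "")[[1]]
    e <- strsplit(df$edited_codon[i], "")[[1]]
    diff <- which(g != e)
    if (length(diff) == 0 || !all(g[diff] == "C" & e[diff] == "T"))
      msg <- c(msg, sprintf("editing site %d is not of C-to-U type (%s -> %s)",
                            i, df$genomic_codon[i], df$edited_codon[i]))
  }
  if (any(df$effect == "start_gain" & df$edited_codon != "ATG"))
    msg <- c(msg, "start_gain sites must edit to ATG")
  if (any(df$effect == "stop_gain" & !(df$edited_codon %in% STOP_CODONS)))
    msg <- c(msg, "stop_gain sites must edit to a stop codon")
  msg
}

#' GeneModel: one curated reference protein-coding gene
#'
#' A reference PCG model: ordered exon sequences, declared start/stop codons,
#' C-to-U RNA-editing sites expressed in spliced-CDS coordinates, optional
#' alternate full-CDS forms, and bookkeeping for conserved-flank padding of
#' very short exons.
#'
#' @slot name gene symbol.
#' @slot exons \code{DNAStringSet} of exon sequences in ordinal order
#'   (flank padding, when applied, is part of the stored sequence).
#' @slot startCodon,stopCodon declared codons; \code{stopCodon} may be the
#'   token \code{"NONE"} for stop-less genes.
#' @slot editingSites data.frame of C-to-U editing sites
#'   (\code{cds_position}, \code{genomic_codon}, \code{edited_codon},
#'   \code{effect}, \code{amino_acid}).
#' @slot missingStop logical; gene lacks a genomic stop codon (nad6-style).
#' @slot transSplicingAllowed logical; gene is known to trans-splice.
#' @slot variantForms \code{DNAStringSet} of labelled alternate CDS forms.
#' @slot flankPad integer; bp of conserved flank prepended/appended to each
#'   flanked exon (0 when none).
#' @slot flankedExons integer ordinals of exons carrying the flank padding.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(name = "character", exons = "DNAStringSet",
                 startCodon = "character", stopCodon = "character",
                 editingSites = "data.frame", missingStop = "logical",
                 transSplicingAllowed = "logical",
                 variantForms = "DNAStringSet",
                 flankPad = "integer", flankedExons = "integer"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@exons) < 1) msg <- c(msg, "at least one exon is required")
  if (any(BiocGenerics::width(object@exons) < 1))
    msg <- c(msg, "exon length must be >= 1")
  if (nchar(object@startCodon) != 3) msg <- c(msg, "startCodon must be 3 nt")
  if (object@stopCodon != "NONE" && nchar(object@stopCodon) != 3)
    msg <- c(msg, "stopCodon must be 3 nt or the token NONE")
  msg <- c(msg, validateEditingSites(object@editingSites))
  if (object@flankPad < 0) msg <- c(msg, "flankPad must be >= 0")
  if (length(object@flankedExons) &&
      !all(object@flankedExons %in% seq_along(object@exons)))
    msg <- c(msg, "flankedExons must reference existing exon ordinals")
  if (object@flankPad > 0 && length(object@flankedExons) == 0)
    msg <- c(msg, "flankPad > 0 requires flankedExons")
  cds <- splicedCDSChar(object)
  if (!object@missingStop && nchar(cds) %% 3 != 0)
    msg <- c(msg, sprintf("spliced CDS length (%d) of %s is not a multiple of 3",
                          nchar(cds), object@name))
  if (length(msg)) msg else TRUE
})

#' ReferenceLibrary: the curated reference gene library
#'
#' Holds the full set of reference \linkS4class{GeneModel}s, the loci treated
#' as pseudogenes genus-wide, and the intron-length thresholds used by the
#' gap-based transcript splitting pass.
#'
#' @slot genes named list of \linkS4class{GeneModel}.
#' @slot pseudogeneLoci character vector of pseudogene locus names.
#' @slot intronThresholds named numeric vector of per-gene overrides (bp).
#' @slot defaultIntronThreshold numeric; default gap threshold (bp).
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
  representation(genes = "list", pseudogeneLoci = "character",
                 intronThresholds = "numeric",
                 defaultIntronThreshold = "numeric"))

setValidity("ReferenceLibrary", function(object) {
  msg <- character(0)
  nm <- names(object@genes)
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "gene names must be unique")
  ok <- vapply(object@genes, function(g) methods::is(g, "GeneModel"), logical(1))
  if (!all(ok)) msg <- c(msg, "genes must be GeneModel objects")
  if (length(intersect(object@pseudogeneLoci, nm)))
    msg <- c(msg, "pseudogene loci must be disjoint from gene names")
  if (length(object@defaultIntronThreshold) != 1 ||
      object@defaultIntronThreshold <= 0)
    msg <- c(msg, "defaultIntronThreshold must be a single positive number")
  if (length(object@intronThresholds) &&
      (is.null(names(object@intronThresholds)) ||
       !all(names(object@intronThresholds) %in% nm)))
    msg <- c(msg, "intronThresholds must be named by known genes")
  if (length(msg)) msg else TRUE
})

#' TranscriptGroup: one transcript of a (possibly trans-spliced) gene
#'
#' A maximal run of consecutively numbered exon placements sharing strand and
#' subject sequence, optionally re-split by the intron-gap pass.
#'
#' @slot label transcript label: "1", "2", ... after the strand pass;
#'   "2-1", "2-2", ... after the gap pass.
#' @slot placements data.frame of exon placements sorted by exon ordinal
#'   (columns gene, exon, subject_id, start, end, strand, identity,
#'   aln_length, score, is_duplicate_copy).
#' @slot strand "+" or "-".
#' @slot subjectId genome sequence id the group lies on.
#' @exportClass TranscriptGroup
setClass("TranscriptGroup",
  representation(label = "character", placements = "data.frame",
                 strand = "character", subjectId = "character"))

setValidity("TranscriptGroup", function(object) {
  msg <- character(0)
  p <- object@placements
  if (nrow(p) == 0) msg <- c(msg, "a transcript group needs >= 1 placement")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  if (nrow(p)) {
    if (!all(p$strand == object@strand) || !all(p$subject_id == object@subjectId))
      msg <- c(msg, "all placements must share the group's strand and subject")
    if (is.unsorted(p$exon, strictly = TRUE))
      msg <- c(msg, "placements must be sorted by exon ordinal")
  }
  if (length(msg)) msg else TRUE
})

#' GeneAnnotation: annotation outcome for one gene
#'
#' @slot gene gene symbol.
#' @slot groups list of \linkS4class{TranscriptGroup}.
#' @slot transSpliced logical.
#' @slot pseudogene logical.
#' @slot reasons pseudogene reason codes (EXON_COUNT_MISMATCH,
#'   EXON_ORDER_VIOLATION, MISSING_GENE).
#' @slot placedExonCount number of distinct placed exon ordinals.
#' @slot duplicates data.frame of extra non-overlapping placements
#'   (multi-copy exons), same columns as group placements.
#' @slot assembly a \linkS4class{CodingAssembly} or NULL for pseudogenes.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
  representation(gene = "character", groups = "list", transSpliced = "logical",
                 pseudogene = "logical", reasons = "character",
                 placedExonCount = "integer", duplicates = "data.frame",
                 assembly = "ANY"))

setValidity("GeneAnnotation", function(object) {
  msg <- character(0)
  if (!all(object@reasons %in% PSEUDO_REASONS))
    msg <- c(msg, "unknown pseudogene reason code")
  if (object@pseudogene != (length(object@reasons) > 0))
    msg <- c(msg, "reasons must be non-empty iff pseudogene")
  if (object@transSpliced !=
      (length(object@groups) >= 2 && !("MISSING_GENE" %in% object@reasons)))
    msg <- c(msg, "transSpliced must hold iff >=2 groups and gene not missing")
  if (length(msg)) msg else TRUE
})

#' CodingAssembly: a spliced, strand-resolved coding sequence
#'
#' @slot gene gene symbol.
#' @slot cds spliced strand-resolved nucleotide string (pre-edited genomic
#'   sequence; RNA-editing never alters the stored CDS).
#' @slot protein translated amino-acid string.
#' @slot qualifiers ordered verbatim GenBank qualifier strings.
#' @slot genomicPositions integer vector: genomic coordinate of every CDS base.
#' @slot boundaryNote list; records of 3' boundary choice and editing events.
#' @exportClass CodingAssembly
setClass("CodingAssembly",
  representation(gene = "character", cds = "character", protein = "character",
                 qualifiers = "character", genomicPositions = "integer",
                 boundaryNote = "list"))

setValidity("CodingAssembly", function(object) {
  msg <- character(0)
  if (nchar(object@cds) < 3) msg <- c(msg, "cds must be >= 3 nt")
  if (length(object@genomicPositions) &&
      length(object@genomicPositions) != nchar(object@cds))
    msg <- c(msg, "genomicPositions must map every CDS base")
  if (length(msg)) msg else TRUE
})

#' RecoveredCDS: a coding sequence rebuilt from contigs
#'
#' @slot gene gene symbol.
#' @slot sequence recovered nucleotide string (concatenated recovered spans).
#' @slot complete logical; TRUE iff no reference position is uncovered.
#' @slot gaps data.frame of missing spliced-CDS intervals
#'   (\code{cds_start}, \code{cds_end}).
#' @slot sourceContigs contig names contributing sequence.
#' @slot provenance data.frame of per-exon origin
#'   (exon, contig, identity, ref_start, ref_end).
#' @exportClass RecoveredCDS
setClass("RecoveredCDS",
  representation(gene = "character", sequence = "character",
                 complete = "logical", gaps = "data.frame",
                 sourceContigs = "character", provenance = "data.frame"))

setValidity("RecoveredCDS", function(object) {
  if (object@complete != (nrow(object@gaps) == 0))
    "complete must hold iff gaps is empty" else TRUE
})

#' Supermatrix: concatenated per-gene alignments with a partition map
#'
#' @slot taxa ordered taxon names.
#' @slot alignment \code{DNAStringSet}; one aligned row per taxon
#'   (gaps/missing as "-", ambiguity as "N").
#' @slot partitions data.frame (gene, start, end), 1-based inclusive,
#'   tiling 1..L in concatenation order.
#' @slot fillLog data.frame of conserved-region fills and refusals.
#' @exportClass Supermatrix
setClass("Supermatrix",
  representation(taxa = "character", alignment = "DNAStringSet",
                 partitions = "data.frame", fillLog = "data.frame"))

setValidity("Supermatrix", function(object) {
  msg <- character(0)
  w <- BiocGenerics::width(object@alignment)
  if (length(unique(w)) > 1) msg <- c(msg, "all rows must have equal length")
  if (!identical(object@taxa, names(object@alignment)))
    msg <- c(msg, "taxa must equal alignment row names")
  p <- object@partitions
  if (nrow(p)) {
    if (p$start[1] != 1 || p$end[nrow(p)] != w[1] ||
        (nrow(p) > 1 && !all(p$start[-1] == p$end[-nrow(p)] + 1)))
      msg <- c(msg, "partitions must tile 1..L without overlap")
  }
  if (length(msg)) msg else TRUE
})
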