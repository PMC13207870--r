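# Exon-based annotation: strand/subject grouping, intron-gap splitting,
# optional exon-order validation, pseudogene classification, and the
# top-level genome annotator.

.newGroup <- function(label, placements) {
  methods::new("TranscriptGroup", label = label, placements = placements,
               strand = placements$strand[1],
               subjectId = placements$subject_id[1])
}

#' Group placed exons into transcripts by strand and subject
#'
#' Maximal runs of consecutively numbered exons sharing strand and subject
#' sequence become one transcript group each; a strand flip, a chromosome
#' change, or a jump in exon ordinal starts a new group. Groups are labelled
#' "1", "2", ... in ordinal order.
#'
#' @param placements primary (non-duplicate) placements of one gene, one row
#'   per placed exon (see \code{\link{placeExons}}).
#' @return list of \linkS4class{TranscriptGroup}.
#' @export
groupByStrand <- function(placements) {
  if (nrow(placements) == 0) return(list())
  if (any(placements$is_duplicate_copy))
    stop("groupByStrand expects primary placements only")
  p <- placements[order(placements$exon), , drop = FALSE]
  brk <- c(TRUE, p$strand[-1] != p$strand[-nrow(p)] |
             p$subject_id[-1] != p$subject_id[-nrow(p)] |
             p$exon[-1] != p$exon[-nrow(p)] + 1L)
  gid <- cumsum(brk)
  lapply(unique(gid), function(g)
    .newGroup(as.character(g), p[gid == g, , drop = FALSE]))
}

# Forward-axis distance between two placement intervals; overlapping
# intervals are flagged and treated as gap 0.
.intervalGap <- function(a, b) {
  g <- max(a$start, b$start) - min(a$end, b$end) - 1L
  max(0L, g)
}

#' Split a transcript group at oversized introns
#'
#' Between each pair of ordinally adjacent placements the forward-axis gap is
#' measured; where it exceeds the intron-length threshold the group is split.
#' Sublabels "k-1", "k-2", ... are appended to the parent label in order.
#' Overlapping placements (negative gap) are flagged and treated as gap 0.
#'
#' @param group a \linkS4class{TranscriptGroup}.
#' @param threshold intron length threshold in bp (> 0).
#' @return list of \linkS4class{TranscriptGroup} (the input group, unchanged,
#'   when no gap exceeds the threshold).
#' @export
splitByGap <- function(group, threshold) {
  stopifnot(methods::is(group, "TranscriptGroup"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  p <- group@placements
  if (nrow(p) < 2) return(list(group))
  gaps <- vapply(seq_len(nrow(p) - 1), function(i) {
    raw <- max(p$start[i], p$start[i + 1]) - min(p$end[i], p$end[i + 1]) - 1
    if (raw < 0)
      warning(sprintf("gene %s: exons %d and %d overlap; gap treated as 0",
                      p$gene[1], p$exon[i], p$exon[i + 1]))
    max(0, raw)
  }, numeric(1))
  brk <- cumsum(c(0L, as.integer(gaps > threshold)))
  if (max(brk) == 0L) return(list(group))
  lapply(unique(brk), function(b)
    .newGroup(sprintf("%s-%d", group@label, b + 1L),
              p[brk == b, , drop = FALSE]))
}

#' Validate canonical exon order within a transcript group
#'
#' On the plus strand, consecutively numbered exons are expected in
#' increasing genomic start order; on the minus strand in decreasing order.
#' Disabled by default (it is an optional user-specified check); when
#' disabled an empty violation table is returned.
#'
#' @param group a \linkS4class{TranscriptGroup}.
#' @param enabled logical (default FALSE).
#' @return data.frame of violations (gene, exon_from, exon_to).
#' @export
validateExonOrder <- function(group, enabled = FALSE) {
  empty <- data.frame(gene = character(0), exon_from = integer(0),
                      exon_to = integer(0), stringsAsFactors = FALSE)
  if (!enabled) return(empty)
  p <- group@placements
  if (nrow(p) < 2) return(empty)
  bad <- vapply(seq_len(nrow(p) - 1), function(i) {
    if (group@strand == "+") p$start[i] >= p$start[i + 1]
    else p$start[i] <= p$start[i + 1]
  }, logical(1))
  if (!any(bad)) return(empty)
  data.frame(gene = p$gene[1], exon_from = p$exon[which(bad)],
             exon_to = p$exon[which(bad) + 1], stringsAsFactors = FALSE)
}

#' Classify a gene from its transcript groups
#'
#' A gene is a pseudogene when the number of distinct placed exon ordinals
#' deviates from the reference exon count (EXON_COUNT_MISMATCH), when the
#' optional exon-order check is enabled and violated (EXON_ORDER_VIOLATION),
#' or when no exon is placed at all (MISSING_GENE). A gene split over two or
#' more transcript groups and not missing is marked trans-spliced.
#'
#' @param geneName gene symbol (must exist in \code{library}).
#' @param groups list of \linkS4class{TranscriptGroup} from the two splitting
#'   passes.
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param orderCheck enable the exon-order validation (default FALSE).
#' @param duplicates optional data.frame of duplicate-copy placements.
#' @return a \linkS4class{GeneAnnotation} (assembly slot NULL).
#' @export
classifyGene <- function(geneName, groups, library, orderCheck = FALSE,
                         duplicates = emptyPlacements()) {
  if (!geneName %in% names(library@genes))
    stop(sprintf("unknown gene '%s'", geneName))
  model <- library@genes[[geneName]]
  ordinals <- unique(unlist(lapply(groups, function(g) g@placements$exon)))
  reasons <- character(0)
  if (length(ordinals) == 0) {
    reasons <- "MISSING_GENE"
  } else if (length(ordinals) != length(model@exons)) {
    reasons <- "EXON_COUNT_MISMATCH"
  }
  if (orderCheck && length(groups)) {
    viol <- do.call(rbind, lapply(groups, validateExonOrder, enabled = TRUE))
    if (nrow(viol)) reasons <- c(reasons, "EXON_ORDER_VIOLATION")
  }
  methods::new("GeneAnnotation", gene = geneName, groups = groups,
               transSpliced = length(groups) >= 2 && !("MISSING_GENE" %in% reasons),
               pseudogene = length(reasons) > 0, reasons = reasons,
               placedExonCount = length(ordinals), duplicates = duplicates,
               assembly = NULL)
}

# Extract the spliced, strand-resolved CDS and the genomic position of every
# CDS base from a gene's primary placements.
.assembleFromPlacements <- function(groups, genome) {
  p <- do.call(rbind, lapply(groups, function(g) g@placements))
  p <- p[order(p$exon), , drop = FALSE]
  pieces <- character(nrow(p))
  positions <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    seg <- substr(genome[[p$subject_id[i]]], p$start[i], p$end[i])
    if (p$strand[i] == "+") {
      pieces[i] <- seg
      positions[[i]] <- seq.int(p$start[i], p$end[i])
    } else {
      pieces[i] <- revComp(seg)
      positions[[i]] <- seq.int(p$end[i], p$start[i])
    }
  }
  list(cds = paste(pieces, collapse = ""),
       positions = as.integer(unlist(positions)))
}

#' Annotate a genome against the reference library
#'
#' The full annotation pass: hits are computed with the internal seeded
#' aligner (or supplied as a tabular hit table), turned into exon placements,
#' grouped by strand/subject, re-split at oversized introns, classified, and
#' -- for non-pseudogenes -- assembled into a spliced CDS with RNA-editing
#' \code{transl_except} qualifiers and non-canonical codon notes applied.
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param genome genome sequences (named character, \code{DNAStringSet} or
#'   FASTA path).
#' @param hits optional precomputed hit table (see
#'   \code{\link{parseHitsTabular}}); computed internally when NULL.
#' @param minIdentity,minCoverage placement thresholds (see
#'   \code{\link{placeExons}}).
#' @param orderCheck enable exon-order validation (default FALSE).
#' @param intronThreshold optional single override of the library thresholds.
#' @param genes optional subset of genes to annotate.
#' @return named list of \linkS4class{GeneAnnotation}, one per reference gene
#'   (assembly slot filled for non-pseudogenes).
#' @export
annotateGenome <- function(library, genome, hits = NULL, minIdentity = 90,
                           minCoverage = 0.8, orderCheck = FALSE,
                           intronThreshold = NULL, genes = NULL) {
  stopifnot(methods::is(library, "ReferenceLibrary"))
  gseq <- asSequenceSet(genome)
  if (is.null(hits))
    hits <- alignLibraryToGenome(library, gseq, minIdentity = minIdentity,
                                 genes = genes)
  pl <- placeExons(library, hits, minIdentity = minIdentity,
                   minCoverage = minCoverage)
  if (is.null(genes)) genes <- names(library@genes)
  out <- lapply(genes, function(nm) {
    sub <- pl[pl$gene == nm, , drop = FALSE]
    prim <- sub[!sub$is_duplicate_copy, , drop = FALSE]
    dup <- sub[sub$is_duplicate_copy, , drop = FALSE]
    thr <- if (is.null(intronThreshold)) intronThreshold(library, nm)
           else intronThreshold
    groups <- groupByStrand(prim)
    groups <- do.call(c, c(lapply(groups, splitByGap, threshold = thr),
                           list(list())))
    ann <- classifyGene(nm, groups, library, orderCheck = orderCheck,
                        duplicates = dup)
    if (!ann@pseudogene && length(groups)) {
      asm <- .assembleFromPlacements(groups, gseq)
      model <- library@genes[[nm]]
      ca <- codingAssembly(nm, asm$cds, genomicPositions = asm$positions)
      ca <- applyEditingExceptions(ca, model@editingSites)
      ca <- annotateNonCanonical(ca, model)
      ann@assembly <- ca
    }
    ann
  })
  names(out) <- genes
  out
}

#' Write a JSON report of gene annotations
#'
#' @param annotations named list of \linkS4class{GeneAnnotation} from
#'   \code{\link{annotateGenome}}.
#' @param file output path.
#' @return invisibly, the report list.
#' @export
writeAnnotationReport <- function(annotations, file) {
  rep <- lapply(annotations, function(a) {
    list(gene = a@gene,
         placed_exons = a@placedExonCount,
         trans_spliced = a@transSpliced,
         pseudogene = a@pseudogene,
         reasons = as.list(a@reasons),
         groups = lapply(a@groups, function(g)
           list(label = g@label, strand = g@strand, subject = g@subjectId,
                exons = g@placements$exon,
                start = g@placements$start, end = g@placements$end)),
         qualifiers = if (!is.null(a@assembly)) as.list(a@assembly@qualifiers)
                      else list())
  })
  jsonlite::write_json(rep, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(rep)
}
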