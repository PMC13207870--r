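# Generics, accessors and show methods.

#' Accessors for reference-library and annotation objects
#'
#' @param x,object a \linkS4class{ReferenceLibrary}, \linkS4class{GeneModel},
#'   \linkS4class{GeneAnnotation}, \linkS4class{CodingAssembly},
#'   \linkS4class{RecoveredCDS} or \linkS4class{Supermatrix}, as documented
#'   per method.
#' @param gene gene symbol (for library lookups).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("geneModel", function(x, gene) standardGeneric("geneModel"))
#' @rdname accessors
#' @export
setGeneric("pseudogeneLoci", function(x) standardGeneric("pseudogeneLoci"))
#' @rdname accessors
#' @export
setGeneric("intronThreshold", function(x, gene) standardGeneric("intronThreshold"))
#' @rdname accessors
#' @export
setGeneric("exonCount", function(x) standardGeneric("exonCount"))
#' @rdname accessors
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))
#' @rdname accessors
#' @export
setGeneric("exonSequences", function(x) standardGeneric("exonSequences"))
#' @rdname accessors
#' @export
setGeneric("splicedCDS", function(x) standardGeneric("splicedCDS"))
#' @rdname accessors
#' @export
setGeneric("editingSites", function(x) standardGeneric("editingSites"))
#' @rdname accessors
#' @export
setGeneric("variantForms", function(x) standardGeneric("variantForms"))
#' @rdname accessors
#' @export
setGeneric("startCodon", function(x) standardGeneric("startCodon"))
#' @rdname accessors
#' @export
setGeneric("stopCodon", function(x) standardGeneric("stopCodon"))
#' @rdname accessors
#' @export
setGeneric("isMissingStop", function(x) standardGeneric("isMissingStop"))
#' @rdname accessors
#' @export
setGeneric("transcriptGroups", function(x) standardGeneric("transcriptGroups"))
#' @rdname accessors
#' @export
setGeneric("isTransSpliced", function(x) standardGeneric("isTransSpliced"))
#' @rdname accessors
#' @export
setGeneric("isPseudogene", function(x) standardGeneric("isPseudogene"))
#' @rdname accessors
#' @export
setGeneric("pseudogeneReasons", function(x) standardGeneric("pseudogeneReasons"))
#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setGeneric("assembly", function(x) standardGeneric("assembly"))
#' @rdname accessors
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))
#' @rdname accessors
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))
#' @rdname accessors
#' @export
setGeneric("qualifiers", function(x) standardGeneric("qualifiers"))
#' @rdname accessors
#' @export
setGeneric("boundaryNote", function(x) standardGeneric("boundaryNote"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setGeneric("cdsGaps", function(x) standardGeneric("cdsGaps"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))
#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @rdname accessors
#' @export
setGeneric("fillLog", function(x) standardGeneric("fillLog"))

## ---- ReferenceLibrary ----

#' @rdname accessors
#' @export
setMethod("geneNames", "ReferenceLibrary", function(x) names(x@genes))

#' @rdname accessors
#' @export
setMethod("geneModel", "ReferenceLibrary", function(x, gene) {
  if (!gene %in% names(x@genes)) stop(sprintf("unknown gene '%s'", gene))
  x@genes[[gene]]
})

#' @rdname accessors
#' @export
setMethod("pseudogeneLoci", "ReferenceLibrary", function(x) x@pseudogeneLoci)

#' @rdname accessors
#' @export
setMethod("intronThreshold", "ReferenceLibrary", function(x, gene) {
  if (gene %in% names(x@intronThresholds)) unname(x@intronThresholds[[gene]])
  else x@defaultIntronThreshold
})

setMethod("show", "ReferenceLibrary", function(object) {
  multi <- sum(vapply(object@genes, function(g) length(g@exons) > 1, logical(1)))
  cat(sprintf("ReferenceLibrary with %d protein-coding genes (%d multi-exon)\n",
              length(object@genes), multi))
  cat(sprintf("  pseudogene loci: %s\n",
              paste(object@pseudogeneLoci, collapse = ", ")))
  cat(sprintf("  default intron threshold: %g bp (%d per-gene overrides)\n",
              object@defaultIntronThreshold, length(object@intronThresholds)))
})

## ---- GeneModel ----

# spliced CDS with flank padding stripped (plain character; internal).
splicedCDSChar <- function(model) {
  seqs <- as.character(model@exons)
  if (model@flankPad > 0) {
    for (i in model@flankedExons) {
      seqs[i] <- substr(seqs[i], model@flankPad + 1,
                        nchar(seqs[i]) - model@flankPad)
    }
  }
  paste(seqs, collapse = "")
}

# unpadded exon lengths (internal).
coreExonLengths <- function(model) {
  w <- BiocGenerics::width(model@exons)
  if (model@flankPad > 0) w[model@flankedExons] <- w[model@flankedExons] - 2L * model@flankPad
  w
}

#' @rdname accessors
#' @export
setMethod("exonCount", "GeneModel", function(x) length(x@exons))
#' @rdname accessors
#' @export
setMethod("exonLengths", "GeneModel", function(x) coreExonLengths(x))
#' @rdname accessors
#' @export
setMethod("exonSequences", "GeneModel", function(x) x@exons)
#' @rdname accessors
#' @export
setMethod("splicedCDS", "GeneModel", function(x) splicedCDSChar(x))
#' @rdname accessors
#' @export
setMethod("editingSites", "GeneModel", function(x) x@editingSites)
#' @rdname accessors
#' @export
setMethod("variantForms", "GeneModel", function(x) x@variantForms)
#' @rdname accessors
#' @export
setMethod("startCodon", "GeneModel", function(x) x@startCodon)
#' @rdname accessors
#' @export
setMethod("stopCodon", "GeneModel", function(x) x@stopCodon)
#' @rdname accessors
#' @export
setMethod("isMissingStop", "GeneModel", function(x) x@missingStop)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s: %d exon(s), spliced CDS %d bp, start %s, stop %s%s\n",
              object@name, length(object@exons), nchar(splicedCDSChar(object)),
              object@startCodon, object@stopCodon,
              if (object@missingStop) " (missing stop)" else ""))
  if (nrow(object@editingSites))
    cat(sprintf("  %d C-to-U editing site(s)\n", nrow(object@editingSites)))
  if (length(object@variantForms))
    cat(sprintf("  variant forms: %s\n",
                paste(names(object@variantForms), collapse = ", ")))
  if (object@flankPad > 0)
    cat(sprintf("  flank pad %d bp on exon(s) %s\n", object@flankPad,
                paste(object@flankedExons, collapse = ",")))
})

## ---- TranscriptGroup / GeneAnnotation ----

#' @rdname accessors
#' @export
setMethod("placements", "TranscriptGroup", function(x) x@placements)

setMethod("show", "TranscriptGroup", function(object) {
  cat(sprintf("TranscriptGroup %s [%s on %s]: exons %s\n", object@label,
              object@strand, object@subjectId,
              paste(object@placements$exon, collapse = ",")))
})

#' @rdname accessors
#' @export
setMethod("transcriptGroups", "GeneAnnotation", function(x) x@groups)
#' @rdname accessors
#' @export
setMethod("isTransSpliced", "GeneAnnotation", function(x) x@transSpliced)
#' @rdname accessors
#' @export
setMethod("isPseudogene", "GeneAnnotation", function(x) x@pseudogene)
#' @rdname accessors
#' @export
setMethod("pseudogeneReasons", "GeneAnnotation", function(x) x@reasons)
#' @rdname accessors
#' @export
setMethod("assembly", "GeneAnnotation", function(x) x@assembly)
#' @rdname accessors
#' @export
setMethod("placements", "GeneAnnotation", function(x) {
  do.call(rbind, c(lapply(x@groups, function(g) g@placements),
                   list(x@duplicates)))
})

setMethod("show", "GeneAnnotation", function(object) {
  flag <- c(if (object@transSpliced) "trans-spliced",
            if (object@pseudogene) paste0("pseudogene[",
                                          paste(object@reasons, collapse = ","), "]"))
  cat(sprintf("GeneAnnotation %s: %d exon(s) placed in %d group(s)%s\n",
              object@gene, object@placedExonCount, length(object@groups),
              if (length(flag)) paste0(" - ", paste(flag, collapse = ", ")) else ""))
})

## ---- CodingAssembly ----

#' @rdname accessors
#' @export
setMethod("cdsSequence", "CodingAssembly", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("proteinSequence", "CodingAssembly", function(x) x@protein)
#' @rdname accessors
#' @export
setMethod("qualifiers", "CodingAssembly", function(x) x@qualifiers)
#' @rdname accessors
#' @export
setMethod("boundaryNote", "CodingAssembly", function(x) x@boundaryNote)

setMethod("show", "CodingAssembly", function(object) {
  cat(sprintf("CodingAssembly %s: CDS %d bp, protein %d aa, %d qualifier(s)\n",
              object@gene, nchar(object@cds), nchar(object@protein),
              length(object@qualifiers)))
})

## ---- RecoveredCDS ----

#' @rdname accessors
#' @export
setMethod("cdsSequence", "RecoveredCDS", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("isComplete", "RecoveredCDS", function(x) x@complete)
#' @rdname accessors
#' @export
setMethod("cdsGaps", "RecoveredCDS", function(x) x@gaps)

setMethod("show", "RecoveredCDS", function(object) {
  cat(sprintf("RecoveredCDS %s: %d bp, %s, %d contig(s)\n", object@gene,
              nchar(object@sequence),
              if (object@complete) "complete" else
                sprintf("%d gap(s)", nrow(object@gaps)),
              length(object@sourceContigs)))
})

## ---- Supermatrix ----

#' @rdname accessors
#' @export
setMethod("taxa", "Supermatrix", function(x) x@taxa)
#' @rdname accessors
#' @export
setMethod("partitions", "Supermatrix", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("alignmentRows", "Supermatrix", function(x) x@alignment)
#' @rdname accessors
#' @export
setMethod("fillLog", "Supermatrix", function(x) x@fillLog)

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partition(s)\n",
              length(object@taxa),
              if (length(object@alignment)) BiocGenerics::width(object@alignment)[1] else 0L,
              nrow(object@partitions)))
})
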