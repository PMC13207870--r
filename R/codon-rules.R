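# Codon rules: RNA-editing transl_except qualifiers, non-canonical codon
# notes, missing-stop 3' boundary resolution, translation, internal-stop scan.

#' Construct a CodingAssembly
#'
#' @param gene gene symbol.
#' @param cds spliced, strand-resolved nucleotide string.
#' @param genomicPositions integer vector giving the genomic coordinate of
#'   every CDS base (optional; required for transl_except emission).
#' @param missingStop logical; a trailing incomplete codon is tolerated.
#' @return a \linkS4class{CodingAssembly} with the translation filled in.
#' @export
codingAssembly <- function(gene, cds, genomicPositions = integer(0),
                           missingStop = FALSE) {
  cds <- toupper(cds)
  checkDNA(cds, "cds")
  methods::new("CodingAssembly", gene = gene, cds = cds,
               protein = translateCDS(cds),
               qualifiers = character(0),
               genomicPositions = as.integer(genomicPositions),
               boundaryNote = list())
}

#' Translate a CDS under the standard genetic code
#'
#' Codon-wise translation (translation table 1, as used for land-plant
#' mitochondria); positional exceptions override the code, a trailing
#' incomplete codon is dropped with a flag, a terminal stop is removed from
#' the protein, and codons containing N translate to X.
#'
#' @param cds nucleotide string over ACGTN, length >= 3.
#' @param exceptions optional data.frame with columns \code{codon_index} and
#'   \code{amino_acid} (one-letter code, or the token \code{TERM} to
#'   terminate translation at that codon).
#' @return the protein string; attribute \code{incomplete_tail} flags a
#'   dropped trailing partial codon.
#' @export
translateCDS <- function(cds, exceptions = NULL) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) stop("cds must be at least 3 nt")
  checkDNA(cds, "cds")
  ncod <- nchar(cds) %/% 3L
  tail <- nchar(cds) %% 3L
  codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (!is.null(exceptions) && nrow(exceptions)) {
    if (any(exceptions$codon_index < 1 | exceptions$codon_index > ncod))
      stop("exception codon_index out of range")
    termAt <- ncod + 1L
    for (i in seq_len(nrow(exceptions))) {
      j <- exceptions$codon_index[i]
      if (exceptions$amino_acid[i] %in% c("TERM", "*")) {
        aa[j] <- "*"
        termAt <- min(termAt, j)
      } else {
        aa[j] <- exceptions$amino_acid[i]
      }
    }
    if (termAt <= ncod) aa <- aa[seq_len(termAt)]
  }
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  out <- paste(aa, collapse = "")
  attr(out, "incomplete_tail") <- tail > 0L
  out
}

#' Apply RNA-editing codon exceptions to a coding assembly
#'
#' For each C-to-U editing site whose genomic codon is observed in the CDS, a
#' start gain emits a verbatim
#' \code{/transl_except=(pos:P..P+2,aa:Met)} qualifier (P being the genomic
#' position of the codon's first base) and renders the first residue as M;
#' a stop gain emits \code{aa:TERM} and terminates the translation at that
#' codon. Missense/synonymous sites are recorded in the boundary note but do
#' not emit qualifiers. The stored CDS nucleotides are never changed: the
#' pre-edited genomic sequence is what gets annotated.
#'
#' @param assembly a \linkS4class{CodingAssembly}.
#' @param editingSites editing-site data.frame (see \linkS4class{GeneModel}).
#' @param genomicPositions optional override of the assembly's per-base
#'   genomic coordinates.
#' @return the updated assembly.
#' @export
applyEditingExceptions <- function(assembly, editingSites,
                                   genomicPositions = NULL) {
  stopifnot(methods::is(assembly, "CodingAssembly"))
  if (is.null(genomicPositions)) genomicPositions <- assembly@genomicPositions
  cds <- assembly@cds
  if (is.null(editingSites) || nrow(editingSites) == 0) return(assembly)
  exceptions <- data.frame(codon_index = integer(0), amino_acid = character(0),
                           stringsAsFactors = FALSE)
  quals <- character(0)
  records <- list()
  for (i in seq_len(nrow(editingSites))) {
    p <- editingSites$cds_position[i]
    if (p < 1 || p + 2 > nchar(cds))
      stop(sprintf("editing site cds_position %d out of range for a %d nt CDS",
                   p, nchar(cds)))
    observed <- substr(cds, p, p + 2)
    if (observed == editingSites$edited_codon[i]) next  # already canonical
    if (observed != editingSites$genomic_codon[i]) {
      warning(sprintf(
        "%s: codon at CDS position %d is %s, not the declared genomic codon %s; site skipped",
        assembly@gene, p, observed, editingSites$genomic_codon[i]))
      next
    }
    codonIdx <- (p + 2L) %/% 3L
    eff <- editingSites$effect[i]
    gp <- if (length(genomicPositions)) genomicPositions[p:(p + 2)] else integer(0)
    posTxt <- if (length(gp)) sprintf("%d..%d", min(gp), max(gp))
              else sprintf("%d..%d", p, p + 2L)
    if (eff == "start_gain") {
      quals <- c(quals, sprintf("/transl_except=(pos:%s,aa:Met)", posTxt))
      exceptions <- rbind(exceptions,
                          data.frame(codon_index = codonIdx, amino_acid = "M",
                                     stringsAsFactors = FALSE))
    } else if (eff == "stop_gain") {
      quals <- c(quals, sprintf("/transl_except=(pos:%s,aa:TERM)", posTxt))
      exceptions <- rbind(exceptions,
                          data.frame(codon_index = codonIdx, amino_acid = "TERM",
                                     stringsAsFactors = FALSE))
    }
    records[[length(records) + 1L]] <- list(
      cds_position = p, effect = eff,
      genomic_codon = editingSites$genomic_codon[i],
      edited_codon = editingSites$edited_codon[i],
      amino_acid = editingSites$amino_acid[i])
  }
  assembly@qualifiers <- c(assembly@qualifiers, quals)
  if (nrow(exceptions))
    assembly@protein <- as.character(translateCDS(cds, exceptions))
  if (length(records)) {
    bn <- assembly@boundaryNote
    bn$editing_records <- c(bn$editing_records, records)
    assembly@boundaryNote <- bn
  }
  assembly
}

#' Annotate non-canonical start/stop codons
#'
#' When the reference model declares a non-canonical start (not ATG) or stop
#' (not TAA/TAG/TGA) codon that is not explained by an RNA-editing site, a
#' verbatim note qualifier is emitted -- for a cob-style ATT start it is
#' byte-identical to
#' \code{/note=Translation initiates from a non-canonical ATT start codon.} --
#' and translation still begins with M. A declared codon that disagrees with
#' the observed CDS adds a warning qualifier and sets a flag in the boundary
#' note.
#'
#' @param assembly a \linkS4class{CodingAssembly}.
#' @param model the gene's \linkS4class{GeneModel}.
#' @return the updated assembly.
#' @export
annotateNonCanonical <- function(assembly, model) {
  stopifnot(methods::is(assembly, "CodingAssembly"),
            methods::is(model, "GeneModel"))
  cds <- assembly@cds
  es <- model@editingSites
  hasStartEdit <- nrow(es) > 0 && any(es$effect == "start_gain" & es$cds_position == 1L)
  lastCodonPos <- nchar(cds) - 2L
  hasStopEdit <- nrow(es) > 0 && any(es$effect == "stop_gain" &
                                       es$cds_position >= lastCodonPos - 2L)
  if (model@startCodon != "ATG" && !hasStartEdit) {
    observed <- substr(cds, 1, 3)
    if (observed != model@startCodon) {
      assembly@qualifiers <- c(assembly@qualifiers, sprintf(
        "/note=Declared start codon %s disagrees with observed %s.",
        model@startCodon, observed))
      bn <- assembly@boundaryNote; bn$codon_mismatch <- TRUE
      assembly@boundaryNote <- bn
    } else {
      assembly@qualifiers <- c(assembly@qualifiers, sprintf(
        "/note=Translation initiates from a non-canonical %s start codon.",
        model@startCodon))
      assembly@protein <- as.character(translateCDS(
        cds, data.frame(codon_index = 1L, amino_acid = "M",
                        stringsAsFactors = FALSE)))
    }
  }
  if (!model@missingStop && model@stopCodon != "NONE" &&
      !(model@stopCodon %in% STOP_CODONS) && !hasStopEdit) {
    observed <- substr(cds, lastCodonPos, nchar(cds))
    if (observed != model@stopCodon) {
      assembly@qualifiers <- c(assembly@qualifiers, sprintf(
        "/note=Declared stop codon %s disagrees with observed %s.",
        model@stopCodon, observed))
      bn <- assembly@boundaryNote; bn$codon_mismatch <- TRUE
      assembly@boundaryNote <- bn
    } else {
      assembly@qualifiers <- c(assembly@qualifiers, sprintf(
        "/note=Translation terminates at a non-canonical %s stop codon.",
        model@stopCodon))
    }
  }
  assembly
}

# Longest ORF (in nt, from position 1 in frame) of a candidate form: length
# up to and including the first in-frame stop, or the full in-frame length.
.orfLength <- function(seq) {
  ncod <- nchar(seq) %/% 3L
  if (ncod == 0) return(0L)
  codons <- substring(seq, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  stopAt <- which(codons %in% STOP_CODONS)
  if (length(stopAt)) 3L * stopAt[1] else 3L * ncod
}

#' Resolve the 3' boundary of a stop-less gene
#'
#' For genes lacking a genomic stop codon (nad6-style) or with poorly
#' conserved 3' ends, each registered reference form (the primary spliced CDS
#' plus every variant form) is aligned to the genomic region; the boundary is
#' taken from the form with the highest alignment score
#' (\code{aln_length * identity / 100}), ties broken by the longest
#' identifiable ORF.
#'
#' @param model a \linkS4class{GeneModel} with \code{missingStop} or
#'   registered variant forms.
#' @param genomeRegion the genomic region (character or \code{DNAString}).
#' @param minIdentity alignment acceptance threshold (default 90).
#' @param k seed length (default 15).
#' @return list with \code{boundary} (subject coordinate of the chosen form's
#'   3' end), \code{form} (winning label) and \code{scores} (per-form table);
#'   also usable as the \code{boundary_note}.
#' @export
resolveMissingStop <- function(model, genomeRegion, minIdentity = 90, k = 15L) {
  stopifnot(methods::is(model, "GeneModel"))
  if (!model@missingStop && length(model@variantForms) < 2)
    stop(sprintf("gene %s has neither missing_stop nor >= 2 variant forms",
                 model@name))
  forms <- c(stats::setNames(splicedCDSChar(model), "reference"),
             stats::setNames(as.character(model@variantForms),
                             names(model@variantForms)))
  region <- toupper(if (methods::is(genomeRegion, "XString"))
    as.character(genomeRegion) else genomeRegion)
  rows <- lapply(names(forms), function(lab) {
    hits <- seededAlign(forms[[lab]], region, k = k, minIdentity = minIdentity,
                        queryId = lab)
    if (nrow(hits) == 0)
      return(data.frame(form = lab, score = 0, boundary = NA_integer_,
                        orf = .orfLength(forms[[lab]]), stringsAsFactors = FALSE))
    best <- hits[which.max(hits$bitscore), , drop = FALSE]
    # subject coordinate corresponding to the query 3' end
    boundary <- if (best$sstart <= best$send) best$send else best$send
    data.frame(form = lab, score = best$bitscore, boundary = boundary,
               orf = .orfLength(forms[[lab]]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, -tab$orf, tab$form), , drop = FALSE]
  if (all(is.na(tab$boundary)) || tab$score[1] <= 0)
    stop(sprintf("MISSING_GENE: no reference form of %s aligns above %g%% identity",
                 model@name, minIdentity))
  list(boundary = tab$boundary[1], form = tab$form[1], scores = tab)
}

#' Scan a CDS for internal stop codons
#'
#' Reports every stop codon strictly before the final codon of an in-frame
#' CDS, as 1-based codon indices (the site naming convention "rpl16-73"
#' refers to codon 73 of the spliced CDS).
#'
#' @param cds in-frame nucleotide string.
#' @return data.frame (codon_index, codon); empty when the only stop is
#'   terminal.
#' @export
scanInternalStops <- function(cds) {
  cds <- toupper(cds)
  checkDNA(cds, "cds")
  ncod <- nchar(cds) %/% 3L
  if (ncod < 2) return(data.frame(codon_index = integer(0), codon = character(0),
                                  stringsAsFactors = FALSE))
  codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  idx <- which(codons[-ncod] %in% STOP_CODONS)
  data.frame(codon_index = idx, codon = codons[idx], stringsAsFactors = FALSE)
}
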