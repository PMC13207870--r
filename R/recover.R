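# Short-read PCG recovery: homology-based read-pair extraction, contig-based
# CDS reconstruction with error logging, output organization, SNP counting.

emptyErrorLog <- function() {
  data.frame(gene = character(0), exon = integer(0), reason = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

.errorEntry <- function(gene, exon, reason, detail) {
  stopifnot(reason %in% RECOVERY_REASONS)
  data.frame(gene = gene, exon = as.integer(exon), reason = reason,
             detail = detail, stringsAsFactors = FALSE)
}

# k-mer dictionary (both strands) mapping k-mers -> gene names.
.buildKmerIndex <- function(searchSeqs, genes, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(searchSeqs)) {
    for (sq in c(searchSeqs[[i]], revComp(searchSeqs[[i]]))) {
      L <- nchar(sq)
      if (L < k) next
      kms <- unique(substring(sq, 1:(L - k + 1L), k:L))
      kms <- kms[!grepl("N", kms, fixed = TRUE)]
      for (km in kms) {
        cur <- if (exists(km, envir = env, inherits = FALSE))
          get(km, envir = env) else character(0)
        if (!genes[i] %in% cur) assign(km, c(cur, genes[i]), envir = env)
      }
    }
  }
  env
}

.stripMateSuffix <- function(x) sub("\\s.*$", "", sub("/[12]$", "", x))

#' Extract read pairs matching reference genes
#'
#' A read pair is assigned to a gene when EITHER mate matches that gene's
#' reference sequences (union rule), so no mate is left unpaired; both mates
#' are always emitted together and a pair may serve several genes. Matching
#' uses the internal seeded aligner (default k = 21, >= 95\% identity over
#' >= 50 bp), with a k-mer prefilter. Orphan mates are logged and dropped.
#'
#' @param mate1,mate2 named \code{DNAStringSet}/character vectors, or FASTQ
#'   file paths. Mates are paired by name (trailing \code{/1}, \code{/2} and
#'   comments stripped).
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param k seed/k-mer length (default 21).
#' @param minIdentity minimum percent identity (default 95).
#' @param minLength minimum matched length (default 50 bp).
#' @param genes optional subset of genes.
#' @return named list: gene -> list(names, mate1, mate2) with mates as named
#'   character vectors in name order.
#' @export
extractReadPairs <- function(mate1, mate2, library, k = 21L, minIdentity = 95,
                             minLength = 50L, genes = NULL) {
  readFq <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      x <- Biostrings::readDNAStringSet(x, format = "fastq")
    asSequenceSet(x)
  }
  m1 <- readFq(mate1); m2 <- readFq(mate2)
  names(m1) <- .stripMateSuffix(names(m1))
  names(m2) <- .stripMateSuffix(names(m2))
  common <- intersect(names(m1), names(m2))
  orphan <- c(setdiff(names(m1), common), setdiff(names(m2), common))
  if (length(orphan))
    warning(sprintf("%d orphan mate(s) dropped (e.g. %s)", length(orphan),
                    orphan[1]))
  common <- sort(common)
  m1 <- m1[common]; m2 <- m2[common]

  searchSeqs <- librarySearchSequences(library, genes)
  geneOf <- sub("\\.exon\\d+$", "", names(searchSeqs))
  idx <- .buildKmerIndex(searchSeqs, geneOf, k)
  byGene <- split(seq_along(searchSeqs), geneOf)
  seqIdx <- lapply(searchSeqs, .subjectKmerIndex, k = k)

  matchGenes <- function(read) {
    L <- nchar(read)
    if (L < k) return(character(0))
    starts <- unique(c(seq(1L, L - k + 1L, by = 10L), L - k + 1L))
    kms <- substring(read, starts, starts + k - 1L)
    cand <- unique(unlist(lapply(kms, function(km)
      if (exists(km, envir = idx, inherits = FALSE)) get(km, envir = idx)
      else character(0))))
    if (!length(cand)) return(character(0))
    ok <- vapply(cand, function(g) {
      any(vapply(byGene[[g]], function(j) {
        h <- seededAlign(read, searchSeqs[[j]], k = k,
                         minIdentity = minIdentity, minLength = minLength,
                         subjectIndex = seqIdx[[j]])
        nrow(h) > 0
      }, logical(1)))
    }, logical(1))
    cand[ok]
  }

  assign1 <- lapply(m1, matchGenes)
  assign2 <- lapply(m2, matchGenes)
  allGenes <- if (is.null(genes)) names(library@genes) else genes
  out <- list()
  for (g in allGenes) {
    keep <- vapply(common, function(nm)
      g %in% assign1[[nm]] || g %in% assign2[[nm]], logical(1))
    if (!any(keep)) next
    nm <- common[keep]
    out[[g]] <- list(names = nm, mate1 = m1[nm], mate2 = m2[nm])
  }
  out
}

#' Write an extracted read-pair set as paired FASTQ
#'
#' @param pairSet one element of the \code{\link{extractReadPairs}} result.
#' @param file1,file2 output FASTQ paths.
#' @return invisibly, the two paths.
#' @export
writeReadPairSet <- function(pairSet, file1, file2) {
  wr <- function(sq, path) {
    x <- Biostrings::DNAStringSet(sq)
    q <- Biostrings::BStringSet(vapply(nchar(sq), function(n)
      strrep("I", n), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(pairSet$mate1, file1)
  wr(pairSet$mate2, file2)
  invisible(c(file1, file2))
}

# Reference-position coverage bookkeeping: merge recovered query intervals,
# return gaps against 1..refLen.
.coverageGaps <- function(intervals, refLen, offset = 0L) {
  if (!nrow(intervals))
    return(data.frame(cds_start = offset + 1L, cds_end = offset + refLen,
                      stringsAsFactors = FALSE))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  merged <- list(c(iv$start[1], iv$end[1]))
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$start[i] <= last[2] + 1L)
      merged[[length(merged)]] <- c(last[1], max(last[2], iv$end[i]))
    else merged[[length(merged) + 1L]] <- c(iv$start[i], iv$end[i])
  }
  gaps <- list()
  prev <- 0L
  for (mg in merged) {
    if (mg[1] > prev + 1L)
      gaps[[length(gaps) + 1L]] <- c(prev + 1L, mg[1] - 1L)
    prev <- mg[2]
  }
  if (prev < refLen) gaps[[length(gaps) + 1L]] <- c(prev + 1L, refLen)
  if (!length(gaps))
    return(data.frame(cds_start = integer(0), cds_end = integer(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, gaps)
  data.frame(cds_start = offset + m[, 1], cds_end = offset + m[, 2],
             stringsAsFactors = FALSE)
}

# Strand-resolve a hit's subject span and return the recovered query-oriented
# sequence together with the covered (unpadded) query interval.
.recoverSpan <- function(hit, contigs, pad = 0L, coreLen = NULL) {
  sq <- substr(contigs[[hit$sseqid]], min(hit$sstart, hit$send),
               max(hit$sstart, hit$send))
  if (hit$sstart > hit$send) sq <- revComp(sq)
  qs <- hit$qstart; qe <- hit$qend
  if (pad > 0) {
    lo <- pad + 1L; hi <- pad + coreLen
    nqs <- max(qs, lo); nqe <- min(qe, hi)
    if (nqs > nqe) return(NULL)
    sq <- substr(sq, nqs - qs + 1L, nchar(sq) - (qe - nqe))
    qs <- nqs - pad; qe <- nqe - pad
  }
  list(seq = sq, start = qs, end = qe)
}

#' Reconstruct a single-exon CDS from contig alignments
#'
#' The optimal alignment is selected by alignment length (ties broken by
#' identity, then contig name); the contig region is strand-resolved and
#' trimmed to the reference-aligned span, and uncovered reference positions
#' are recorded as gaps.
#'
#' @param model the gene's \linkS4class{GeneModel} (single exon).
#' @param contigs contig sequences (named character, \code{DNAStringSet} or
#'   FASTA path).
#' @param hits optional precomputed hit table (query = the gene CDS); computed
#'   with \code{\link{seededAlign}} when NULL.
#' @param minIdentity acceptance threshold (default 90).
#' @return list(cds = \linkS4class{RecoveredCDS} or NULL,
#'   errors = error-log data.frame).
#' @export
reconstructSingleExon <- function(model, contigs, hits = NULL,
                                  minIdentity = 90) {
  stopifnot(methods::is(model, "GeneModel"), length(model@exons) == 1)
  contigs <- asSequenceSet(contigs)
  ref <- splicedCDSChar(model)
  if (is.null(hits))
    hits <- alignSeqsToSubjects(stats::setNames(list(ref), model@name),
                                contigs, minIdentity = minIdentity)
  hits <- hits[hits$pident >= minIdentity, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(cds = NULL,
                errors = .errorEntry(model@name, 1L, "MISSING_EXON",
                                     "no contig alignment for the gene")))
  }
  hits <- hits[order(-hits$length, -hits$pident, hits$sseqid), , drop = FALSE]
  best <- hits[1, , drop = FALSE]
  span <- .recoverSpan(best, contigs)
  gaps <- .coverageGaps(data.frame(start = span$start, end = span$end),
                        nchar(ref))
  cds <- methods::new("RecoveredCDS", gene = model@name, sequence = span$seq,
                      complete = nrow(gaps) == 0, gaps = gaps,
                      sourceContigs = best$sseqid,
                      provenance = data.frame(exon = 1L, contig = best$sseqid,
                                              identity = best$pident,
                                              ref_start = span$start,
                                              ref_end = span$end,
                                              stringsAsFactors = FALSE))
  list(cds = cds, errors = emptyErrorLog())
}

#' Reconstruct a multi-exon CDS from contig alignments
#'
#' The best alignment per exon (by exon-aligned length) is chosen and exon
#' sequences are concatenated in ordinal order; flank-padded exons are
#' trimmed back to the core exon. When one exon yields two partial
#' alignments on different contigs the exon is NOT auto-merged: the best
#' partial is used, a gap is recorded, and an EXON_SPLIT_ACROSS_CONTIGS
#' error-log entry is emitted. Unhit exons yield MISSING_EXON and an
#' incomplete CDS.
#'
#' @param model the gene's \linkS4class{GeneModel}.
#' @param contigs contig sequences.
#' @param hits optional precomputed hit table with \code{qseqid} =
#'   \code{gene.exonN}.
#' @param minIdentity acceptance threshold (default 90).
#' @return list(cds = \linkS4class{RecoveredCDS} or NULL,
#'   errors = error-log data.frame).
#' @export
reconstructMultiExon <- function(model, contigs, hits = NULL,
                                 minIdentity = 90) {
  stopifnot(methods::is(model, "GeneModel"), length(model@exons) > 1)
  contigs <- asSequenceSet(contigs)
  exonSeqs <- as.character(model@exons)
  coreLens <- coreExonLengths(model)
  labels <- paste0(model@name, ".exon", seq_along(exonSeqs))
  if (is.null(hits))
    hits <- alignSeqsToSubjects(stats::setNames(as.list(exonSeqs), labels),
                                contigs, minIdentity = minIdentity)
  hits <- hits[hits$pident >= minIdentity, , drop = FALSE]

  offsets <- c(0L, cumsum(coreLens))
  pieces <- character(0)
  gaps <- list()
  errors <- emptyErrorLog()
  prov <- list()
  srcContigs <- character(0)
  for (i in seq_along(exonSeqs)) {
    sub <- hits[hits$qseqid == labels[i], , drop = FALSE]
    pad <- if (i %in% model@flankedExons) model@flankPad else 0L
    if (nrow(sub) == 0) {
      errors <- rbind(errors, .errorEntry(model@name, i, "MISSING_EXON",
                                          "exon has no contig alignment"))
      gaps[[length(gaps) + 1L]] <- data.frame(
        cds_start = offsets[i] + 1L, cds_end = offsets[i] + coreLens[i],
        stringsAsFactors = FALSE)
      next
    }
    sub <- sub[order(-sub$length, -sub$pident, sub$sseqid), , drop = FALSE]
    best <- sub[1, , drop = FALSE]
    span <- .recoverSpan(best, contigs, pad, coreLens[i])
    if (is.null(span)) {
      errors <- rbind(errors, .errorEntry(model@name, i, "MISSING_EXON",
                                          "alignments cover only the flank pad"))
      gaps[[length(gaps) + 1L]] <- data.frame(
        cds_start = offsets[i] + 1L, cds_end = offsets[i] + coreLens[i],
        stringsAsFactors = FALSE)
      next
    }
    fullCover <- span$start == 1L && span$end == coreLens[i]
    if (!fullCover) {
      others <- sub[-1, , drop = FALSE]
      others <- others[others$sseqid != best$sseqid, , drop = FALSE]
      complementary <- FALSE
      for (j in seq_len(nrow(others))) {
        osp <- .recoverSpan(others[j, , drop = FALSE], contigs, pad, coreLens[i])
        if (is.null(osp)) next
        if (osp$start < span$start || osp$end > span$end) {
          complementary <- TRUE
          break
        }
      }
      if (complementary)
        errors <- rbind(errors, .errorEntry(
          model@name, i, "EXON_SPLIT_ACROSS_CONTIGS",
          sprintf("exon %d fragmented across contigs %s", i,
                  paste(unique(sub$sseqid), collapse = ","))))
    }
    pieces <- c(pieces, span$seq)
    srcContigs <- unique(c(srcContigs, best$sseqid))
    prov[[length(prov) + 1L]] <- data.frame(
      exon = i, contig = best$sseqid, identity = best$pident,
      ref_start = span$start, ref_end = span$end, stringsAsFactors = FALSE)
    g <- .coverageGaps(data.frame(start = span$start, end = span$end),
                       coreLens[i], offset = offsets[i])
    if (nrow(g)) gaps[[length(gaps) + 1L]] <- g
  }
  gapDf <- if (length(gaps)) do.call(rbind, gaps)
  else data.frame(cds_start = integer(0), cds_end = integer(0),
                  stringsAsFactors = FALSE)
  if (!length(pieces))
    return(list(cds = NULL, errors = errors))
  cds <- methods::new("RecoveredCDS", gene = model@name,
                      sequence = paste(pieces, collapse = ""),
                      complete = nrow(gapDf) == 0, gaps = gapDf,
                      sourceContigs = srcContigs,
                      provenance = do.call(rbind, prov))
  list(cds = cds, errors = errors)
}

#' Recover every reference gene from a contig set
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param contigs contig sequences.
#' @param genes optional subset.
#' @param minIdentity acceptance threshold (default 90).
#' @return list(cds = named list of \linkS4class{RecoveredCDS},
#'   errors = combined error log).
#' @export
recoverFromContigs <- function(library, contigs, genes = NULL,
                               minIdentity = 90) {
  stopifnot(methods::is(library, "ReferenceLibrary"))
  contigs <- asSequenceSet(contigs)
  if (is.null(genes)) genes <- names(library@genes)
  searchSeqs <- librarySearchSequences(library, genes)
  allHits <- alignSeqsToSubjects(as.list(searchSeqs), contigs,
                                 minIdentity = minIdentity)
  geneOf <- sub("\\.exon\\d+$", "", allHits$qseqid)
  cdss <- list()
  errors <- emptyErrorLog()
  for (nm in genes) {
    model <- library@genes[[nm]]
    sub <- allHits[geneOf == nm, , drop = FALSE]
    res <- if (length(model@exons) == 1)
      reconstructSingleExon(model, contigs, hits = sub,
                            minIdentity = minIdentity)
    else reconstructMultiExon(model, contigs, hits = sub,
                              minIdentity = minIdentity)
    if (!is.null(res$cds)) cdss[[nm]] <- res$cds
    errors <- rbind(errors, res$errors)
  }
  list(cds = cdss, errors = errors)
}

#' Organize recovered CDSs into gene-wise and sample-wise FASTA trees
#'
#' Writes \code{by_gene/<gene>.fasta} (records named by sample) and
#' \code{by_sample/<sample>.fasta} (records named by gene), in deterministic
#' lexicographic order; re-running overwrites to identical bytes. Gene-wise
#' files suit SNP analysis; sample-wise files suit phylogenetic
#' reconstruction.
#'
#' @param samples named list: sample -> (named list of
#'   \linkS4class{RecoveredCDS} or named character of sequences).
#' @param outDir output directory (created if needed).
#' @return invisibly, a data.frame of written files; genes absent from a
#'   sample are logged as an attribute \code{missing}.
#' @export
organizeOutputs <- function(samples, outDir) {
  stopifnot(length(samples) >= 1)
  seqOf <- function(x) if (methods::is(x, "RecoveredCDS")) x@sequence
                       else as.character(x)
  dirG <- file.path(outDir, "by_gene")
  dirS <- file.path(outDir, "by_sample")
  dir.create(dirG, recursive = TRUE, showWarnings = FALSE)
  dir.create(dirS, recursive = TRUE, showWarnings = FALSE)
  sampleNames <- sort(names(samples))
  geneNames <- sort(unique(unlist(lapply(samples, names))))
  missing <- list()
  files <- list()
  for (g in geneNames) {
    recs <- character(0)
    for (s in sampleNames) {
      if (g %in% names(samples[[s]])) recs[s] <- seqOf(samples[[s]][[g]])
      else missing[[length(missing) + 1L]] <- data.frame(
        sample = s, gene = g, stringsAsFactors = FALSE)
    }
    path <- file.path(dirG, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), path, width = 70L)
    files[[length(files) + 1L]] <- data.frame(kind = "gene", name = g,
                                              path = path,
                                              stringsAsFactors = FALSE)
  }
  for (s in sampleNames) {
    recs <- vapply(samples[[s]], seqOf, character(1))[order(names(samples[[s]]))]
    path <- file.path(dirS, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), path, width = 70L)
    files[[length(files) + 1L]] <- data.frame(kind = "sample", name = s,
                                              path = path,
                                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, files)
  attr(out, "missing") <- if (length(missing)) do.call(rbind, missing)
  else data.frame(sample = character(0), gene = character(0),
                  stringsAsFactors = FALSE)
  invisible(out)
}

#' Count variable alignment columns
#'
#' Number of columns of an equal-length alignment with at least two distinct
#' non-gap, non-N states.
#'
#' @param alignment \code{DNAStringSet} or character vector of equal-length
#'   aligned sequences.
#' @return integer SNP count.
#' @export
countVariableSites <- function(alignment) {
  sq <- if (methods::is(alignment, "XStringSet")) as.character(alignment)
        else toupper(as.character(alignment))
  if (length(unique(nchar(sq))) != 1)
    stop("alignment rows must have equal length")
  xs <- Biostrings::DNAStringSet(sq)
  cm <- Biostrings::consensusMatrix(xs)
  keep <- setdiff(rownames(cm), c("-", "N", "+", "."))
  sum(colSums(cm[keep, , drop = FALSE] > 0) >= 2)
}

#' Write a recovery error log as TSV
#'
#' @param errors error-log data.frame.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeErrorLog <- function(errors, file) {
  utils::write.table(errors, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
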