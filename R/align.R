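# Homology mapping: internal seeded aligner, tabular-hit import, and
# strand-aware exon placement.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

emptyHits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

# Maximal-scoring contiguous segment (Kadane); returns c(from, to) or NULL.
.maxSegment <- function(x) {
  best <- 0; bi <- 0L; bj <- -1L
  cur <- 0; ci <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) { cur <- x[i]; ci <- i } else cur <- cur + x[i]
    if (cur > best) { best <- cur; bi <- ci; bj <- i }
  }
  if (bj < bi) NULL else c(bi, bj)
}

# Hash index of all k-mer start positions in a subject (N-containing k-mers
# excluded: N never seeds).
.subjectKmerIndex <- function(s, k) {
  m <- nchar(s)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (m < k) return(env)
  pos <- seq_len(m - k + 1L)
  kms <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", kms, fixed = TRUE)
  list2env(split(pos[keep], kms[keep]), envir = env)
}

# Exact k-mer seed diagonals of query vs subject (plus orientation only).
.seedDiagonals <- function(query, index, k, step) {
  n <- nchar(query)
  if (n < k) return(integer(0))
  starts <- unique(c(seq(1L, n - k + 1L, by = step), n - k + 1L))
  seeds <- substring(query, starts, starts + k - 1L)
  diags <- unlist(lapply(seq_along(starts), function(i) {
    hit <- get0(seeds[i], envir = index, ifnotfound = NULL, inherits = FALSE)
    if (is.null(hit)) integer(0) else hit - starts[i]
  }))
  unique(diags)
}

# Ungapped extension along each diagonal; N counts as a mismatch.
.extendDiagonals <- function(qc, sc, diags, minIdentity, minLength,
                             mismatchPenalty = 3) {
  n <- length(qc); m <- length(sc)
  out <- vector("list", length(diags)); nout <- 0L
  for (d in diags) {
    i1 <- max(1L, 1L - d); i2 <- min(n, m - d)
    if (i2 - i1 + 1L < minLength) next
    qseg <- qc[i1:i2]; sseg <- sc[(i1 + d):(i2 + d)]
    hit <- (qseg == sseg) & qseg != "N" & sseg != "N"
    seg <- .maxSegment(ifelse(hit, 1, -mismatchPenalty))
    if (is.null(seg)) next
    len <- seg[2] - seg[1] + 1L
    mm <- sum(!hit[seg[1]:seg[2]])
    pid <- 100 * (len - mm) / len
    if (len >= minLength && pid >= minIdentity) {
      nout <- nout + 1L
      out[[nout]] <- c(qs = i1 + seg[1] - 1L, qe = i1 + seg[2] - 1L,
                       d = d, len = len, mm = mm, pid = pid)
    }
  }
  out[seq_len(nout)]
}

#' Seeded ungapped pairwise alignment
#'
#' A self-contained homology search used throughout the package in place of
#' an external aligner: exact k-mer seeds on both strands, merged by ungapped
#' extension along the seed diagonal (maximal-scoring segment; N never seeds
#' and counts as a mismatch in extension). Coordinates follow the 12-column
#' tabular convention: query coordinates are always forward;
#' \code{sstart > send} encodes a minus-strand hit.
#'
#' @param query,subject sequences (character or \code{DNAString}).
#' @param k seed length (>= 8; default 15).
#' @param minIdentity minimum percent identity of a reported hit (default 90).
#' @param minLength minimum alignment length of a reported hit (default
#'   \code{k}).
#' @param queryId,subjectId labels copied into the hit table.
#' @param subjectIndex optional precomputed subject k-mer index (internal
#'   reuse across queries; must match \code{subject} and \code{k}).
#' @return a hit data.frame with the 12 standard columns; scores are
#'   \code{length * identity / 100}. No hit yields an empty table.
#' @export
seededAlign <- function(query, subject, k = 15L, minIdentity = 90,
                        minLength = NULL, queryId = "query",
                        subjectId = "subject", subjectIndex = NULL) {
  k <- as.integer(k)
  if (k < 8L) stop("seed length k must be >= 8")
  if (is.null(minLength)) minLength <- k
  q <- toupper(if (methods::is(query, "XString")) as.character(query) else query)
  s <- toupper(if (methods::is(subject, "XString")) as.character(subject) else subject)
  checkDNA(q, "query"); checkDNA(s, "subject")
  step <- max(1L, k %/% 2L)
  if (is.null(subjectIndex)) subjectIndex <- .subjectKmerIndex(s, k)
  sc <- strsplit(s, "")[[1]]
  n <- nchar(q)

  collect <- function(qq, minus) {
    diags <- .seedDiagonals(qq, subjectIndex, k, step)
    if (!length(diags)) return(NULL)
    qc <- strsplit(qq, "")[[1]]
    hits <- .extendDiagonals(qc, sc, diags, minIdentity, minLength)
    if (!length(hits)) return(NULL)
    do.call(rbind, lapply(hits, function(h) {
      ss <- as.integer(h[["qs"]] + h[["d"]])
      se <- as.integer(h[["qe"]] + h[["d"]])
      qs <- as.integer(h[["qs"]]); qe <- as.integer(h[["qe"]])
      data.frame(qseqid = queryId, sseqid = subjectId, pident = h[["pid"]],
                 length = as.integer(h[["len"]]),
                 mismatch = as.integer(h[["mm"]]), gapopen = 0L,
                 qstart = if (minus) n - qe + 1L else qs,
                 qend = if (minus) n - qs + 1L else qe,
                 sstart = if (minus) se else ss,
                 send = if (minus) ss else se, evalue = 0,
                 bitscore = h[["len"]] * h[["pid"]] / 100,
                 stringsAsFactors = FALSE)
    }))
  }
  res <- rbind(collect(q, FALSE), collect(revComp(q), TRUE))
  if (is.null(res)) return(emptyHits())
  res <- res[order(-res$bitscore, res$sstart), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Parse 12-column tabular alignment hits
#'
#' Reads the standard 12-column tabular pairwise-alignment dialect (BLAST
#' outfmt 6). Subject coordinates are preserved as printed; orientation is
#' decoded later by \code{\link{placeExons}}.
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @return a hit data.frame (see \code{\link{seededAlign}} for columns).
#' @export
parseHitsTabular <- function(input) {
  lines <- if (is.character(input) && length(input) == 1 && file.exists(input))
    readLines(input) else if (inherits(input, "connection"))
      readLines(input) else as.character(input)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyHits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 bad[1], lengths(fields)[bad[1]]))
  m <- do.call(rbind, fields)
  data.frame(qseqid = m[, 1], sseqid = m[, 2], pident = as.numeric(m[, 3]),
             length = as.integer(m[, 4]), mismatch = as.integer(m[, 5]),
             gapopen = as.integer(m[, 6]), qstart = as.integer(m[, 7]),
             qend = as.integer(m[, 8]), sstart = as.integer(m[, 9]),
             send = as.integer(m[, 10]), evalue = as.numeric(m[, 11]),
             bitscore = as.numeric(m[, 12]), stringsAsFactors = FALSE)
}

# Reference search sequences: one record per single-exon gene ("gene") or
# per exon ("gene.exonN"); flank-padded sequences are used as stored.
librarySearchSequences <- function(library, genes = NULL) {
  if (is.null(genes)) genes <- names(library@genes)
  out <- character(0)
  for (nm in genes) {
    g <- library@genes[[nm]]
    sq <- as.character(g@exons)
    names(sq) <- if (length(sq) == 1) nm else paste0(nm, ".exon", seq_along(sq))
    out <- c(out, sq)
  }
  out
}

#' Align every reference gene/exon against a genome
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param genome genome sequences (named character, \code{DNAStringSet} or
#'   FASTA path).
#' @param k,minIdentity passed to \code{\link{seededAlign}}.
#' @param genes optional subset of genes to search.
#' @return combined hit table with \code{qseqid} = \code{gene} or
#'   \code{gene.exonN} and \code{sseqid} = genome sequence name.
#' @export
alignLibraryToGenome <- function(library, genome, k = 15L, minIdentity = 90,
                                 genes = NULL) {
  gseq <- asSequenceSet(genome)
  queries <- librarySearchSequences(library, genes)
  alignSeqsToSubjects(queries, gseq, k = k, minIdentity = minIdentity)
}

# Align a set of named queries against a set of named subjects, reusing one
# k-mer index per subject (internal work-horse).
alignSeqsToSubjects <- function(queries, subjects, k = 15L, minIdentity = 90,
                                minLength = NULL) {
  res <- lapply(names(subjects), function(sid) {
    s <- toupper(subjects[[sid]])
    idx <- .subjectKmerIndex(s, as.integer(k))
    hits <- lapply(names(queries), function(qid)
      seededAlign(queries[[qid]], s, k = k, minIdentity = minIdentity,
                  minLength = minLength, queryId = qid, subjectId = sid,
                  subjectIndex = idx))
    do.call(rbind, hits)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) emptyHits() else out
}

# split "gene.exonN" labels -> (gene, exon)
.parseQueryId <- function(qid) {
  exon <- rep(1L, length(qid))
  isExon <- grepl("\\.exon\\d+$", qid)
  exon[isExon] <- as.integer(sub("^.*\\.exon(\\d+)$", "\\1", qid[isExon]))
  gene <- sub("\\.exon\\d+$", "", qid)
  data.frame(gene = gene, exon = exon, stringsAsFactors = FALSE)
}

emptyPlacements <- function() {
  data.frame(gene = character(0), exon = integer(0), subject_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             identity = numeric(0), aln_length = integer(0), score = numeric(0),
             is_duplicate_copy = logical(0), stringsAsFactors = FALSE)
}

# Trim flank padding out of a placement interval, mapping padded-query
# coordinates onto the subject axis. Returns NULL when the hit covers no
# core-exon base.
.trimFlankPlacement <- function(row, pad, coreLen) {
  lo <- pad + 1L; hi <- pad + coreLen
  qs <- row$qstart; qe <- row$qend
  nqs <- max(qs, lo); nqe <- min(qe, hi)
  if (nqs > nqe) return(NULL)
  if (row$strand == "+") {
    row$start <- row$start + (nqs - qs)
    row$end <- row$end - (qe - nqe)
  } else {
    row$start <- row$start + (qe - nqe)
    row$end <- row$end - (nqs - qs)
  }
  row$qstart <- nqs; row$qend <- nqe
  row$aln_length <- nqe - nqs + 1L
  row
}

#' Select exon placements from alignment hits
#'
#' Per exon, hits passing the identity and coverage thresholds are ranked by
#' (1) greatest alignment length, (2) greatest identity, (3) greatest score,
#' (4) smallest subject start; the best hit becomes the primary placement and
#' additional passing hits that do not overlap an already retained placement
#' (>= 1 bp shared on the same subject, either strand) are kept as duplicate
#' copies. Flank-padded exons have their pad trimmed from the interval.
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param hits hit table from \code{\link{seededAlign}},
#'   \code{\link{alignLibraryToGenome}} or \code{\link{parseHitsTabular}}.
#' @param minIdentity minimum percent identity (default 90).
#' @param minCoverage minimum alignment length as a fraction of the (padded)
#'   reference exon length (default 0.8).
#' @return placement data.frame: gene, exon, subject_id, start, end, strand,
#'   identity, aln_length, score, is_duplicate_copy. Unplaced exons are
#'   simply absent.
#' @export
placeExons <- function(library, hits, minIdentity = 90, minCoverage = 0.8) {
  if (nrow(hits) == 0) return(emptyPlacements())
  qlens <- nchar(librarySearchSequences(library))
  unknown <- setdiff(unique(hits$qseqid), names(qlens))
  if (length(unknown))
    stop(sprintf("hits reference unknown gene/exon label(s): %s",
                 paste(unknown, collapse = ", ")))
  ge <- .parseQueryId(hits$qseqid)
  df <- data.frame(gene = ge$gene, exon = ge$exon, subject_id = hits$sseqid,
                   start = as.integer(pmin(hits$sstart, hits$send)),
                   end = as.integer(pmax(hits$sstart, hits$send)),
                   strand = ifelse(hits$sstart <= hits$send, "+", "-"),
                   identity = hits$pident, aln_length = hits$length,
                   score = hits$bitscore, qstart = hits$qstart,
                   qend = hits$qend, stringsAsFactors = FALSE)
  df <- df[df$identity >= minIdentity &
             df$aln_length / qlens[hits$qseqid] >= minCoverage, , drop = FALSE]
  if (nrow(df) == 0) return(emptyPlacements())

  out <- list()
  for (key in sort(unique(paste(df$gene, df$exon)))) {
    sub <- df[paste(df$gene, df$exon) == key, , drop = FALSE]
    sub <- sub[order(-sub$aln_length, -sub$identity, -sub$score, sub$start,
                     sub$subject_id), , drop = FALSE]
    model <- library@genes[[sub$gene[1]]]
    pad <- if (sub$exon[1] %in% model@flankedExons) model@flankPad else 0L
    coreLen <- coreExonLengths(model)[sub$exon[1]]
    kept <- list()
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, , drop = FALSE]
      overlaps <- any(vapply(kept, function(kk)
        kk$subject_id == row$subject_id &&
          kk$start <= row$end && row$start <= kk$end, logical(1)))
      if (overlaps) next
      if (pad > 0) {
        row <- .trimFlankPlacement(row, pad, coreLen)
        if (is.null(row)) next
      }
      row$is_duplicate_copy <- length(kept) > 0
      kept[[length(kept) + 1L]] <- row
    }
    out <- c(out, kept)
  }
  res <- do.call(rbind, out)
  res$qstart <- NULL; res$qend <- NULL
  res <- res[order(res$gene, res$exon, res$is_duplicate_copy, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
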