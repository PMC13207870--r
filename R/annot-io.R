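# GenBank flat-file and GFF3 serialization of annotations, plus extraction
# of outgroup CDSs from GenBank files.

#' Build a feature record
#'
#' @param kind "gene" or "CDS".
#' @param segments data.frame (subject_id, start, end, strand), 1-based
#'   inclusive, in translation (exon-ordinal) order.
#' @param gene gene symbol.
#' @param qualifiers verbatim qualifier strings (each starting with "/").
#' @param pseudo,transSpliced flags.
#' @return a feature record list consumed by \code{\link{writeGenBank}}.
#' @export
featureRecord <- function(kind, segments, gene, qualifiers = character(0),
                          pseudo = FALSE, transSpliced = FALSE) {
  stopifnot(kind %in% c("gene", "CDS"), nrow(segments) >= 1,
            all(segments$start <= segments$end))
  list(kind = kind, segments = segments, gene = gene, qualifiers = qualifiers,
       pseudo = pseudo, transSpliced = transSpliced)
}

# Feature records for one annotated gene (gene + CDS; gene-only for
# pseudogenes). Trans-spliced location segments are ordered by exon ordinal
# (translation order).
.annotationFeatures <- function(ann) {
  segsOf <- function(groups) {
    p <- do.call(rbind, lapply(groups, function(g) g@placements))
    p <- p[order(p$exon), , drop = FALSE]
    data.frame(subject_id = p$subject_id, start = p$start, end = p$end,
               strand = p$strand, exon = p$exon, stringsAsFactors = FALSE)
  }
  if (length(ann@groups) == 0) return(list())
  segs <- segsOf(ann@groups)
  feats <- list()
  for (chrom in unique(segs$subject_id)) {
    s <- segs[segs$subject_id == chrom, , drop = FALSE]
    gseg <- data.frame(subject_id = chrom, start = min(s$start),
                       end = max(s$end),
                       strand = if (all(s$strand == "-")) "-" else "+",
                       stringsAsFactors = FALSE)
    gq <- sprintf("/gene=\"%s\"", ann@gene)
    if (ann@pseudogene) {
      feats[[length(feats) + 1L]] <- featureRecord(
        "gene", gseg, ann@gene, qualifiers = c(gq, "/pseudo"), pseudo = TRUE)
      next
    }
    feats[[length(feats) + 1L]] <- featureRecord("gene", gseg, ann@gene,
                                                 qualifiers = gq)
    cq <- gq
    if (ann@transSpliced) cq <- c(cq, "/trans_splicing")
    if (length(unique(segs$subject_id)) > 1)
      cq <- c(cq, "/note=\"trans-splicing partner\"")
    if (!is.null(ann@assembly)) {
      cq <- c(cq, ann@assembly@qualifiers,
              sprintf("/translation=\"%s\"", ann@assembly@protein))
    }
    feats[[length(feats) + 1L]] <- featureRecord(
      "CDS", s[, c("subject_id", "start", "end", "strand")], ann@gene,
      qualifiers = cq, transSpliced = ann@transSpliced)
  }
  feats
}

# GenBank location string for the segments lying on one record, given in
# translation order. Uniform minus-strand multi-segment features use
# complement(join(...)) with segments listed in ascending genomic order;
# mixed strands fall back to per-segment complement() inside join().
.locationString <- function(segments) {
  one <- function(s, e) sprintf("%d..%d", s, e)
  if (nrow(segments) == 1) {
    loc <- one(segments$start, segments$end)
    if (segments$strand == "-") loc <- sprintf("complement(%s)", loc)
    return(loc)
  }
  if (all(segments$strand == "-") &&
      !is.unsorted(rev(segments$start), strictly = TRUE)) {
    # canonical minus-strand gene: translation order descends the axis, so
    # complement(join(ascending)) reads the segments in translation order
    o <- order(segments$start)
    inner <- paste(one(segments$start[o], segments$end[o]), collapse = ",")
    return(sprintf("complement(join(%s))", inner))
  }
  if (all(segments$strand == "+")) {
    return(sprintf("join(%s)", paste(one(segments$start, segments$end),
                                     collapse = ",")))
  }
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    loc <- one(segments$start[i], segments$end[i])
    if (segments$strand[i] == "-") sprintf("complement(%s)", loc) else loc
  }, character(1))
  sprintf("join(%s)", paste(parts, collapse = ","))
}

.wrapFeatureText <- function(text, indent = 21L, width = 79L) {
  avail <- width - indent
  out <- character(0)
  while (nchar(text) > avail) {
    cut <- avail
    # prefer breaking after a comma (locations) or at a space (notes)
    chunk <- substr(text, 1, avail)
    pos <- max(gregexpr("[, ]", chunk)[[1]])
    if (pos > 1) cut <- pos
    out <- c(out, substr(text, 1, cut))
    text <- substr(text, cut + 1L, nchar(text))
  }
  c(out, text)
}

.featureLines <- function(key, location, qualifiers) {
  pad <- strrep(" ", 21L)
  loc <- .wrapFeatureText(location)
  lines <- c(sprintf("     %-16s%s", key, loc[1]),
             if (length(loc) > 1) paste0(pad, loc[-1]))
  for (q in qualifiers) {
    w <- .wrapFeatureText(q)
    lines <- c(lines, paste0(pad, w))
  }
  lines
}

#' Write annotations as a GenBank flat file
#'
#' One LOCUS record per genome sequence. Cis multi-exon CDSs use
#' \code{join(...)}; minus-strand features are wrapped in
#' \code{complement(...)}; trans-spliced genes carry a
#' \code{/trans_splicing} qualifier with location segments in exon-ordinal
#' (translation) order; pseudogenes are written as gene features with
#' \code{/pseudo} and no CDS; transl_except and note qualifiers are emitted
#' verbatim. Genes spanning several sequences are written as one CDS per
#' record sharing the \code{/gene} qualifier.
#'
#' @param genome genome sequences (named character, \code{DNAStringSet} or
#'   FASTA path).
#' @param annotations named list of \linkS4class{GeneAnnotation}, or a list of
#'   \code{\link{featureRecord}}s.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeGenBank <- function(genome, annotations, file) {
  gseq <- asSequenceSet(genome)
  feats <- if (length(annotations) &&
               methods::is(annotations[[1]], "GeneAnnotation"))
    do.call(c, c(lapply(annotations, .annotationFeatures), list(list())))
  else annotations
  for (f in feats) {
    bad <- !(f$segments$subject_id %in% names(gseq)) |
      f$segments$end > nchar(gseq)[f$segments$subject_id]
    if (any(bad))
      stop(sprintf("feature for gene %s extends beyond sequence bounds", f$gene))
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (chrom in names(gseq)) {
    sq <- gseq[[chrom]]
    writeLines(sprintf("LOCUS       %-17s%d bp    DNA     linear   PLN 01-JAN-2026",
                       chrom, nchar(sq)), con)
    writeLines("DEFINITION  synthetic plant mitochondrial sequence.", con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(.featureLines("source", sprintf("1..%d", nchar(sq)),
                             "/organelle=\"mitochondrion\""), con)
    for (f in feats) {
      segs <- f$segments[f$segments$subject_id == chrom, , drop = FALSE]
      if (nrow(segs) == 0) next
      writeLines(.featureLines(f$kind, .locationString(segs), f$qualifiers), con)
    }
    writeLines("ORIGIN", con)
    lower <- tolower(sq)
    pos <- seq(1, nchar(sq), by = 60)
    for (p in pos) {
      chunk <- substr(lower, p, min(p + 59, nchar(sq)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(file)
}

# ---- GenBank parsing --------------------------------------------------------

# Evaluate a GenBank location expression against a sequence.
.evalLocation <- function(txt, seqchar) {
  txt <- gsub("\\s", "", txt)
  if (grepl("^complement\\(", txt)) {
    inner <- substr(txt, nchar("complement(") + 1L, nchar(txt) - 1L)
    return(revComp(.evalLocation(inner, seqchar)))
  }
  if (grepl("^join\\(", txt)) {
    inner <- substr(txt, nchar("join(") + 1L, nchar(txt) - 1L)
    # split on top-level commas
    depth <- 0L; parts <- character(0); cur <- ""
    for (ch in strsplit(inner, "")[[1]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (ch == "," && depth == 0L) { parts <- c(parts, cur); cur <- "" }
      else cur <- paste0(cur, ch)
    }
    parts <- c(parts, cur)
    return(paste(vapply(parts, .evalLocation, character(1),
                        seqchar = seqchar), collapse = ""))
  }
  m <- regexec("^<?(\\d+)\\.\\.>?(\\d+)$", txt)[[1]]
  if (m[1] != -1) {
    g <- regmatches(txt, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", txt))[[1]]
    return(substr(seqchar, as.integer(g[2]), as.integer(g[3])))
  }
  if (grepl("^\\d+$", txt)) {
    p <- as.integer(txt)
    return(substr(seqchar, p, p))
  }
  stop(sprintf("malformed location '%s'", txt))
}

# Split one GenBank record's lines into LOCUS name, feature list and sequence.
.parseGenBankRecord <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  name <- strsplit(trimws(locus[1]), "\\s+")[[1]][2]
  fStart <- grep("^FEATURES", lines)
  oStart <- grep("^ORIGIN", lines)
  if (!length(fStart) || !length(oStart))
    stop("GenBank record lacks FEATURES or ORIGIN section")
  seqLines <- lines[seq(oStart + 1L, length(lines))]
  seqchar <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  featLines <- lines[seq(fStart + 1L, oStart - 1L)]
  feats <- list()
  cur <- NULL
  mode <- "loc"
  for (ln in featLines) {
    key <- trimws(substr(ln, 1, 20))
    rest <- trimws(substr(ln, 21, nchar(ln)))
    if (nzchar(key)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- list(key = key, location = rest, qualifiers = character(0))
      mode <- "loc"
    } else if (startsWith(rest, "/")) {
      cur$qualifiers <- c(cur$qualifiers, rest)
      mode <- "qual"
    } else if (mode == "loc") {
      cur$location <- paste0(cur$location, rest)
    } else {
      n <- length(cur$qualifiers)
      sep <- if (grepl("^/translation=", cur$qualifiers[n]) ||
                 grepl("^[^ ]*[,)]$", rest)) "" else " "
      cur$qualifiers[n] <- paste0(cur$qualifiers[n], sep, rest)
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  list(name = name, features = feats, sequence = seqchar)
}

#' Extract CDS sequences from a GenBank flat file
#'
#' Returns the spliced, strand-resolved CDS of every CDS feature carrying a
#' \code{/gene} qualifier (join/complement location grammar handled; features
#' without a gene qualifier are skipped with a warning). A gene split over
#' several records (multi-chromosome trans-splicing) is concatenated in file
#' order.
#'
#' @param file GenBank flat-file path.
#' @return named character vector: gene -> CDS sequence.
#' @export
readGenBankCDS <- function(file) {
  lines <- readLines(file)
  recEnds <- grep("^//", lines)
  if (!length(recEnds)) stop("no GenBank record terminator (//) found")
  recStarts <- c(1L, head(recEnds, -1) + 1L)
  out <- character(0)
  featIdx <- 0L
  for (r in seq_along(recEnds)) {
    rec <- .parseGenBankRecord(lines[recStarts[r]:(recEnds[r] - 1L)])
    for (f in rec$features) {
      if (f$key != "CDS") next
      featIdx <- featIdx + 1L
      gq <- grep("^/gene=", f$qualifiers, value = TRUE)
      if (!length(gq)) {
        warning(sprintf("CDS feature %d has no /gene qualifier; skipped", featIdx))
        next
      }
      gene <- gsub("^/gene=\"?|\"$", "", gq[1])
      sq <- tryCatch(.evalLocation(f$location, rec$sequence),
                     error = function(e)
                       stop(sprintf("feature %d (%s): %s", featIdx, gene,
                                    conditionMessage(e))))
      if (gene %in% names(out)) out[[gene]] <- paste0(out[[gene]], sq)
      else out[[gene]] <- sq
    }
  }
  out
}

# ---- GFF3 -------------------------------------------------------------------

#' Write annotations as GFF3
#'
#' Emits gene and CDS rows (1-based); CDS phase is computed from the
#' cumulative coding length in translation order, and all parts of a
#' trans-spliced CDS share one feature ID.
#'
#' @param annotations named list of \linkS4class{GeneAnnotation}.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeGFF3 <- function(annotations, file) {
  rows <- list()
  for (ann in annotations) {
    if (length(ann@groups) == 0) next
    p <- do.call(rbind, lapply(ann@groups, function(g) g@placements))
    p <- p[order(p$exon), , drop = FALSE]
    geneId <- sprintf("gene-%s", ann@gene)
    for (chrom in unique(p$subject_id)) {
      s <- p[p$subject_id == chrom, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = chrom, start = min(s$start), end = max(s$end),
        strand = if (all(s$strand == "-")) "-" else "+",
        type = ifelse(ann@pseudogene, "pseudogene", "gene"),
        ID = geneId, Parent = NA_character_, phase = NA_integer_,
        gene = ann@gene, stringsAsFactors = FALSE)
    }
    if (ann@pseudogene) next
    cdsId <- sprintf("cds-%s", ann@gene)
    cum <- 0L
    for (i in seq_len(nrow(p))) {
      phase <- (3L - cum %% 3L) %% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = p$subject_id[i], start = p$start[i], end = p$end[i],
        strand = p$strand[i], type = "CDS", ID = cdsId, Parent = geneId,
        phase = phase, gene = ann@gene, stringsAsFactors = FALSE)
      cum <- cum + (p$end[i] - p$start[i] + 1L)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end), strand = df$strand)
  S4Vectors::mcols(gr)$source <- "mitoPCG"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(x) if (is.na(x)) character(0) else x))
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$gene <- df$gene
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}
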