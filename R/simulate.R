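# Synthetic mitogenome, paired-read and contig simulators with truth
# manifests. Deterministic functions of (inputs, seed): every annotation and
# recovery rule can be exercised without external data.

#' Per-gene layout options for the genome simulator
#'
#' @param gene gene symbol.
#' @param mode "cis" (all exons adjacent, same strand),
#'   "trans_strand_flip" (strand vector applied per exon) or
#'   "trans_multichrom" (exons distributed over chromosomes).
#' @param strands per-exon strand vector (used by trans_strand_flip; recycled).
#' @param chroms per-exon chromosome names (used by trans_multichrom).
#' @param chrom chromosome for cis genes (default "chr1").
#' @param duplicateExon exon ordinal to plant a second copy of (or NULL).
#' @param deleteExon exon ordinal to omit (or NULL).
#' @param wideIntronAfter exon ordinal after which the intron is made larger
#'   than the splitting threshold (or NULL).
#' @param frameshiftAfter bp offset into the spliced CDS after which one base
#'   is deleted in the planted copy (or NULL).
#' @return a layout-option list for \code{\link{makeGenome}}.
#' @export
geneLayout <- function(gene, mode = c("cis", "trans_strand_flip",
                                      "trans_multichrom"),
                       strands = NULL, chroms = NULL, chrom = "chr1",
                       duplicateExon = NULL, deleteExon = NULL,
                       wideIntronAfter = NULL, frameshiftAfter = NULL) {
  mode <- match.arg(mode)
  if (mode == "trans_strand_flip" && is.null(strands))
    stop("trans_strand_flip requires a strand vector")
  if (mode == "trans_multichrom" && is.null(chroms))
    stop("trans_multichrom requires per-exon chromosomes")
  if (!is.null(duplicateExon) && !is.null(deleteExon) &&
      duplicateExon == deleteExon)
    stop("cannot both duplicate and delete the same exon")
  list(gene = gene, mode = mode, strands = strands, chroms = chroms,
       chrom = chrom, duplicateExon = duplicateExon, deleteExon = deleteExon,
       wideIntronAfter = wideIntronAfter, frameshiftAfter = frameshiftAfter)
}

#' All-cis default layout for a gene set
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param genes gene subset (default: all).
#' @param chrom chromosome name.
#' @return list of \code{\link{geneLayout}} options.
#' @export
defaultLayout <- function(library, genes = NULL, chrom = "chr1") {
  if (is.null(genes)) genes <- names(library@genes)
  lapply(genes, geneLayout, chrom = chrom)
}

# Delete one base at spliced-CDS offset `after` across the exon sequence set.
.applyFrameshift <- function(exonSeqs, after) {
  lens <- nchar(exonSeqs)
  ends <- cumsum(lens)
  hit <- which(ends >= after + 1L)[1]
  if (is.na(hit)) stop("frameshiftAfter beyond the CDS")
  off <- after + 1L - c(0L, ends)[hit]
  exonSeqs[hit] <- paste0(substr(exonSeqs[hit], 1, off - 1L),
                          substr(exonSeqs[hit], off + 1L, lens[hit]))
  exonSeqs
}

#' Generate a synthetic mitogenome with a truth manifest
#'
#' Plants the selected reference genes on one or more chromosomes with random
#' intergenic spacers and introns, realizing the requested structural options
#' (strand flips and multi-chromosome arrangements for trans-splicing,
#' duplicate or deleted exons, oversized introns, frameshifts). Cis introns
#' are drawn well below the splitting threshold; \code{wideIntronAfter}
#' introns are drawn above it so both split outcomes are exercised.
#' Deterministic under \code{seed}.
#'
#' @param library a \linkS4class{ReferenceLibrary}.
#' @param layout list of \code{\link{geneLayout}} options (default: all genes
#'   cis on chr1).
#' @param seed integer RNG seed.
#' @param intergenic c(min, max) spacer length (default 2000-3500 bp).
#' @param intron c(min, max) cis intron length (default 300-1200 bp).
#' @param threshold intron threshold used to size wide introns (default: the
#'   library default).
#' @return list(genome = named character, manifest = data.frame with one row
#'   per planted exon copy: gene, exon, chrom, start, end, strand, duplicate,
#'   mode).
#' @export
makeGenome <- function(library, layout = defaultLayout(library), seed = 1L,
                       intergenic = c(2000, 3500), intron = c(300, 1200),
                       threshold = NULL) {
  stopifnot(methods::is(library, "ReferenceLibrary"))
  if (is.null(threshold)) threshold <- library@defaultIntronThreshold
  withSeed(seed, {
    chromParts <- list()   # chrom -> list of character pieces
    chromLen <- integer(0) # chrom -> current length
    manifest <- list()
    addPiece <- function(chrom, piece) {
      if (is.null(chromParts[[chrom]])) {
        chromParts[[chrom]] <<- list()
        chromLen[chrom] <<- 0L
      }
      chromParts[[chrom]][[length(chromParts[[chrom]]) + 1L]] <<- piece
      chromLen[chrom] <<- chromLen[chrom] + nchar(piece)
    }
    spacer <- function(chrom, lo, hi)
      addPiece(chrom, randomDNA(as.integer(runif(1, lo, hi))))
    plantExon <- function(gene, exon, chrom, sq, strand, duplicate, mode) {
      planted <- if (strand == "-") revComp(sq) else sq
      start <- chromLen[chrom] + 1L
      addPiece(chrom, planted)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        gene = gene, exon = exon, chrom = chrom, start = start,
        end = chromLen[chrom], strand = strand, duplicate = duplicate,
        mode = mode, stringsAsFactors = FALSE)
    }

    for (opt in layout) {
      model <- library@genes[[opt$gene]]
      if (is.null(model)) stop(sprintf("unknown gene '%s' in layout", opt$gene))
      exonSeqs <- as.character(model@exons)
      if (model@flankPad > 0)
        for (i in model@flankedExons)
          exonSeqs[i] <- substr(exonSeqs[i], model@flankPad + 1L,
                                nchar(exonSeqs[i]) - model@flankPad)
      nEx <- length(exonSeqs)
      if (!is.null(opt$frameshiftAfter))
        exonSeqs <- .applyFrameshift(exonSeqs, opt$frameshiftAfter)
      strands <- switch(opt$mode,
        cis = rep("+", nEx),
        trans_strand_flip = rep(opt$strands, length.out = nEx),
        trans_multichrom = if (is.null(opt$strands)) rep("+", nEx)
                           else rep(opt$strands, length.out = nEx))
      chroms <- switch(opt$mode,
        cis = rep(opt$chrom, nEx),
        trans_strand_flip = rep(opt$chrom, nEx),
        trans_multichrom = rep(opt$chroms, length.out = nEx))
      keep <- setdiff(seq_len(nEx), opt$deleteExon)
      for (j in seq_along(keep)) {
        i <- keep[j]
        if (j == 1L) {
          spacer(chroms[i], intergenic[1], intergenic[2])
        } else {
          prev <- keep[j - 1L]
          if (chroms[i] == chroms[prev]) {
            wide <- !is.null(opt$wideIntronAfter) && prev == opt$wideIntronAfter
            if (wide) spacer(chroms[i], threshold + 1500, threshold + 3000)
            else spacer(chroms[i], intron[1], intron[2])
          } else {
            spacer(chroms[i], intergenic[1], intergenic[2])
          }
        }
        plantExon(opt$gene, i, chroms[i], exonSeqs[i], strands[i],
                  duplicate = FALSE, mode = opt$mode)
      }
      if (!is.null(opt$duplicateExon)) {
        i <- opt$duplicateExon
        spacer(chroms[i], intergenic[1], intergenic[2])
        plantExon(opt$gene, i, chroms[i], exonSeqs[i], strands[i],
                  duplicate = TRUE, mode = opt$mode)
      }
    }
    for (chrom in names(chromParts)) spacer(chrom, 1500, 2500)
    genome <- vapply(chromParts, function(p) paste(unlist(p), collapse = ""),
                     character(1))
    list(genome = genome, manifest = do.call(rbind, manifest))
  })
}

#' Simulate error-free paired-end reads
#'
#' Uniform sampling of fixed-size fragments; read names carry the origin
#' chromosome and fragment start so truth checks can recompute coverage.
#'
#' @param genome named character vector / \code{DNAStringSet} of chromosomes.
#' @param readLen read length (default 150 bp).
#' @param coverage target per-base coverage (default 50).
#' @param insert fragment size (default 350 bp; must be >= readLen, and every
#'   chromosome must be at least this long).
#' @param seed integer RNG seed.
#' @param errorRate optional uniform substitution rate (default 0).
#' @return list(mate1, mate2): named character vectors; names
#'   \code{pair<i>:<chrom>:<fragStart>:<fragEnd>}.
#' @export
simulateReads <- function(genome, readLen = 150L, coverage = 50,
                          insert = 350L, seed = 1L, errorRate = 0) {
  gseq <- asSequenceSet(genome)
  readLen <- as.integer(readLen); insert <- as.integer(insert)
  if (readLen > insert) stop("readLen must not exceed the insert size")
  if (any(nchar(gseq) < insert))
    stop("every genome sequence must be at least one insert long")
  if (coverage < 1) stop("coverage must be >= 1")
  withSeed(seed, {
    total <- sum(nchar(gseq))
    nPairs <- max(1L, as.integer(round(coverage * total / (2 * readLen))))
    chromIdx <- sample(seq_along(gseq), nPairs, replace = TRUE,
                       prob = nchar(gseq))
    starts <- vapply(chromIdx, function(i)
      as.integer(ceiling(runif(1, 0, nchar(gseq[i]) - insert + 1))),
      integer(1))
    mutate <- function(sq) {
      if (errorRate <= 0) return(sq)
      n <- nchar(sq)
      hit <- which(runif(n) < errorRate)
      if (!length(hit)) return(sq)
      ch <- strsplit(sq, "")[[1]]
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }
    m1 <- character(nPairs); m2 <- character(nPairs)
    nms <- character(nPairs)
    for (p in seq_len(nPairs)) {
      chrom <- names(gseq)[chromIdx[p]]
      s <- starts[p]; e <- s + insert - 1L
      frag <- substr(gseq[[chrom]], s, e)
      m1[p] <- mutate(substr(frag, 1, readLen))
      m2[p] <- mutate(revComp(substr(frag, insert - readLen + 1L, insert)))
      nms[p] <- sprintf("pair%06d:%s:%d:%d", p, chrom, s, e)
    }
    names(m1) <- nms; names(m2) <- nms
    list(mate1 = m1, mate2 = m2)
  })
}

#' Write simulated read pairs as FASTQ
#'
#' @param pairs result of \code{\link{simulateReads}}.
#' @param file1,file2 output FASTQ paths.
#' @return invisibly, the two paths.
#' @export
writeFastqPair <- function(pairs, file1, file2) {
  writeReadPairSet(list(mate1 = pairs$mate1, mate2 = pairs$mate2),
                   file1, file2)
}

#' Fragment a genome into contigs, optionally inside a named exon
#'
#' Contigs tile each chromosome. A breakpoint placed inside exon e of gene g
#' guarantees two partial alignments for g.e downstream, fabricating the
#' fragmented-exon condition the recovery error log must catch. Without
#' breaks, one contig per chromosome is returned. Deterministic under
#' \code{seed}.
#'
#' @param genome named character vector / \code{DNAStringSet}.
#' @param manifest truth manifest from \code{\link{makeGenome}}.
#' @param breaks NULL, or a data.frame with columns gene, exon and optional
#'   frac (position of the break within the exon, default 0.5); positions
#'   may also be given directly via columns chrom, pos.
#' @param seed integer RNG seed (reserved for randomized break placement).
#' @return named character vector of contigs
#'   (\code{<chrom>.part<N>} or \code{<chrom>} when unbroken).
#' @export
fragmentContigs <- function(genome, manifest, breaks = NULL, seed = 1L) {
  gseq <- asSequenceSet(genome)
  cuts <- lapply(names(gseq), function(ch) integer(0))
  names(cuts) <- names(gseq)
  if (!is.null(breaks) && nrow(breaks)) {
    for (i in seq_len(nrow(breaks))) {
      if (!is.null(breaks$chrom) && !is.na(breaks$chrom[i]) &&
          !is.null(breaks$pos)) {
        ch <- breaks$chrom[i]; pos <- as.integer(breaks$pos[i])
      } else {
        row <- manifest[manifest$gene == breaks$gene[i] &
                          manifest$exon == breaks$exon[i] &
                          !manifest$duplicate, , drop = FALSE]
        if (nrow(row) == 0)
          stop(sprintf("no planted exon %s.exon%d in the manifest",
                       breaks$gene[i], breaks$exon[i]))
        frac <- if (!is.null(breaks$frac) && !is.na(breaks$frac[i]))
          breaks$frac[i] else 0.5
        ch <- row$chrom[1]
        pos <- as.integer(row$start[1] +
                            floor(frac * (row$end[1] - row$start[1])))
      }
      if (!ch %in% names(gseq) || pos < 1 || pos >= nchar(gseq[[ch]]))
        stop(sprintf("breakpoint %s:%d outside the genome", ch, pos))
      cuts[[ch]] <- sort(unique(c(cuts[[ch]], pos)))
    }
  }
  out <- character(0)
  for (ch in names(gseq)) {
    if (!length(cuts[[ch]])) {
      out[ch] <- gseq[[ch]]
      next
    }
    bounds <- c(0L, cuts[[ch]], nchar(gseq[[ch]]))
    for (j in seq_len(length(bounds) - 1L)) {
      out[sprintf("%s.part%d", ch, j)] <-
        substr(gseq[[ch]], bounds[j] + 1L, bounds[j + 1L])
    }
  }
  out
}
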