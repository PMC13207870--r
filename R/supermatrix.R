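# Concatenated supermatrix construction for ML phylogenetics.

emptyFillLog <- function() {
  data.frame(taxon = character(0), gene = character(0), start = integer(0),
             end = integer(0), action = character(0), donor = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

.alignChar <- function(x) {
  sq <- if (methods::is(x, "XStringSet"))
    stats::setNames(as.character(x), names(x))
  else toupper(x)   # toupper preserves names; as.character would drop them
  if (is.null(names(sq))) stop("alignment rows must be named by taxon")
  sq
}

#' Genes shared by all samples and the outgroup
#'
#' @param sampleGeneSets list of character vectors (gene names per sample).
#' @param outgroupGeneSet character vector of outgroup gene names.
#' @return the intersection across all sets, sorted lexicographically; an
#'   empty intersection is an error.
#' @export
sharedGenes <- function(sampleGeneSets, outgroupGeneSet) {
  stopifnot(length(sampleGeneSets) >= 1, length(outgroupGeneSet) >= 1)
  shared <- Reduce(intersect, sampleGeneSets, accumulate = FALSE)
  shared <- intersect(shared, outgroupGeneSet)
  if (!length(shared))
    stop("no gene is shared by every sample and the outgroup")
  sort(shared)
}

#' Concatenate per-gene alignments into a Supermatrix
#'
#' @param perGeneAlignments named list: gene -> named alignment
#'   (\code{DNAStringSet} or character; identical taxa, equal row lengths).
#' @param geneOrder concatenation order (default: list order).
#' @return a \linkS4class{Supermatrix} whose partitions tile 1..L.
#' @export
concatenateAlignments <- function(perGeneAlignments,
                                  geneOrder = names(perGeneAlignments)) {
  stopifnot(length(perGeneAlignments) >= 1)
  if (!all(geneOrder %in% names(perGeneAlignments)))
    stop("geneOrder contains unknown genes")
  mats <- lapply(perGeneAlignments[geneOrder], .alignChar)
  taxa <- sort(names(mats[[1]]))
  for (g in geneOrder) {
    if (!setequal(names(mats[[g]]), taxa)) {
      miss <- setdiff(taxa, names(mats[[g]]))
      extra <- setdiff(names(mats[[g]]), taxa)
      stop(sprintf("gene %s: taxon set mismatch (%s)", g,
                   paste(c(miss, extra), collapse = ", ")))
    }
    if (length(unique(nchar(mats[[g]]))) != 1)
      stop(sprintf("gene %s: rows have unequal length", g))
  }
  widths <- vapply(mats, function(m) nchar(m[[1]]), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  rows <- vapply(taxa, function(tx)
    paste(vapply(geneOrder, function(g) mats[[g]][[tx]], character(1)),
          collapse = ""), character(1))
  aln <- Biostrings::DNAStringSet(rows)
  names(aln) <- taxa
  methods::new("Supermatrix", taxa = taxa, alignment = aln,
               partitions = data.frame(gene = geneOrder,
                                       start = unname(starts),
                                       end = unname(ends),
                                       stringsAsFactors = FALSE),
               fillLog = emptyFillLog())
}

#' Fill a missing region from a conspecific sample
#'
#' A missing stretch in one taxon's row of a per-gene alignment may be filled
#' from a conspecific donor, but only when every non-missing cohort row
#' (excluding the recipient) is identical over the region's columns, i.e. the
#' region is completely conserved. Otherwise the fill is refused and the
#' alignment left untouched; every decision is logged.
#'
#' @param alignment named alignment (\code{DNAStringSet} or character).
#' @param taxon recipient row name.
#' @param region c(start, end) columns (1-based inclusive).
#' @param speciesLabels named character vector: taxon -> species label
#'   (conspecific = same label).
#' @param gene gene name for the log (default "").
#' @return list(alignment, filled (logical), log (one-row data.frame)).
#' @export
fillMissing <- function(alignment, taxon, region, speciesLabels, gene = "") {
  sq <- .alignChar(alignment)
  stopifnot(taxon %in% names(sq), length(region) == 2,
            region[1] >= 1, region[2] <= nchar(sq[[1]]),
            region[1] <= region[2])
  refuse <- function(reason) {
    list(alignment = alignment, filled = FALSE,
         log = data.frame(taxon = taxon, gene = gene, start = region[1],
                          end = region[2], action = "refused", donor = "",
                          reason = reason, stringsAsFactors = FALSE))
  }
  cut <- function(x) substr(x, region[1], region[2])
  cohort <- sq[setdiff(names(sq), taxon)]
  present <- cohort[!grepl("-", cut(cohort), fixed = TRUE)]
  if (!length(present)) return(refuse("no cohort row covers the region"))
  if (length(unique(cut(present))) > 1)
    return(refuse("region is not completely conserved in the cohort"))
  donors <- names(present)[speciesLabels[names(present)] == speciesLabels[[taxon]]]
  donors <- donors[!is.na(donors)]
  if (!length(donors)) return(refuse("no conspecific donor covers the region"))
  donor <- sort(donors)[1]
  filledRow <- sq[[taxon]]
  substr(filledRow, region[1], region[2]) <- cut(sq[[donor]])
  sq[[taxon]] <- filledRow
  out <- Biostrings::DNAStringSet(sq)
  names(out) <- names(sq)
  list(alignment = out, filled = TRUE,
       log = data.frame(taxon = taxon, gene = gene, start = region[1],
                        end = region[2], action = "filled", donor = donor,
                        reason = "region conserved", stringsAsFactors = FALSE))
}

#' Fraction of missing columns per taxon
#'
#' @param x a \linkS4class{Supermatrix}.
#' @return named numeric vector: fraction of "-" per row.
#' @export
missingFraction <- function(x) {
  stopifnot(methods::is(x, "Supermatrix"))
  sq <- as.character(x@alignment)
  vapply(sq, function(r) {
    n <- nchar(r)
    (n - nchar(gsub("-", "", r, fixed = TRUE))) / n
  }, numeric(1))
}

#' Recommend taxa for exclusion by missing-data fraction
#'
#' Samples with a large number of missing genes or extensive incomplete
#' regions after permitted fills are better excluded from the phylogenetic
#' analysis than patched further.
#'
#' @param x a \linkS4class{Supermatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.2).
#' @return character vector of taxa recommended for exclusion.
#' @export
recommendExclusion <- function(x, maxMissing = 0.2) {
  mf <- missingFraction(x)
  names(mf)[mf > maxMissing]
}

#' Drop genes before concatenation
#'
#' @param perGeneAlignments named list of per-gene alignments.
#' @param geneNames genes to remove (must all exist; removing everything is
#'   an error).
#' @return the reduced list.
#' @export
excludeGenes <- function(perGeneAlignments, geneNames) {
  unknown <- setdiff(geneNames, names(perGeneAlignments))
  if (length(unknown))
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")))
  keep <- setdiff(names(perGeneAlignments), geneNames)
  if (!length(keep)) stop("excluding all genes leaves an empty matrix")
  perGeneAlignments[keep]
}

#' Write a relaxed PHYLIP alignment
#'
#' Header "ntaxa nchar", then one "name  sequence" row per taxon (names not
#' truncated).
#'
#' @param x a \linkS4class{Supermatrix} or named alignment.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writePhylip <- function(x, file) {
  sq <- if (methods::is(x, "Supermatrix")) as.character(x@alignment)
        else .alignChar(x)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sq), nchar(sq[[1]])), con)
  writeLines(sprintf("%s  %s", names(sq), unname(sq)), con)
  invisible(file)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param file PHYLIP path written by \code{\link{writePhylip}}.
#' @return named character vector of aligned rows.
#' @export
readPhylip <- function(file) {
  lines <- readLines(file)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("malformed PHYLIP header")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr[1])
    stop(sprintf("expected %d sequence rows, found %d", hdr[1], length(body)))
  parts <- strsplit(trimws(body), "\\s+")
  out <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  names(out) <- vapply(parts, `[`, character(1), 1)
  if (any(nchar(out) != hdr[2]))
    stop("sequence length disagrees with the PHYLIP header")
  out
}

#' Write supermatrix files and the external ML command
#'
#' Writes the relaxed PHYLIP matrix, a FASTA copy, and a RAxML-style
#' partition file (\code{DNA, gene = start-end}), and renders a
#' ready-to-run external maximum-likelihood command with the requested
#' substitution model and bootstrap replicate count. The command is NOT
#' executed.
#'
#' @param x a \linkS4class{Supermatrix}.
#' @param dir output directory.
#' @param model substitution model string (default "GTR+GAMMA+I", passed
#'   through verbatim).
#' @param bootstraps bootstrap replicates (default 1000).
#' @param seed parsimony/bootstrap seed embedded in the command.
#' @return list(files, command).
#' @export
emitPhyloHandoff <- function(x, dir, model = "GTR+GAMMA+I",
                             bootstraps = 1000L, seed = 12345L) {
  stopifnot(methods::is(x, "Supermatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phy <- file.path(dir, "supermatrix.phy")
  fa <- file.path(dir, "supermatrix.fasta")
  part <- file.path(dir, "partitions.txt")
  writePhylip(x, phy)
  Biostrings::writeXStringSet(x@alignment, fa, width = 70L)
  writeLines(sprintf("DNA, %s = %d-%d", x@partitions$gene, x@partitions$start,
                     x@partitions$end), part)
  cmd <- sprintf(
    "raxmlHPC -f a -s %s -q %s -m %s -# %d -x %d -p %d -n mito_pcg",
    phy, part, model, as.integer(bootstraps), as.integer(seed),
    as.integer(seed))
  list(files = c(phylip = phy, fasta = fa, partitions = part), command = cmd)
}
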