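# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats runif
#' @importFrom utils head tail
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Random DNA string; GC ~ 45% as typical of plant mitogenomes.
randomDNA <- function(n, gc = 0.45) {
  at <- (1 - gc) / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

# Random CDS: declared start codon, stop-free body, declared stop codon
# ("NONE" for stop-less genes). len must be a multiple of 3.
randomCDS <- function(len, start = "ATG", stop = "TAA") {
  stopifnot(len %% 3 == 0, nchar(start) == 3)
  pool <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  pool <- setdiff(pool, STOP_CODONS)
  nbody <- len / 3 - 1 - (stop != "NONE")
  stopifnot(nbody >= 0)
  body <- if (nbody > 0) paste(sample(pool, nbody, replace = TRUE), collapse = "") else ""
  paste0(start, body, if (stop == "NONE") "" else stop)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce character / DNAString(Set) / FASTA path to a named character vector.
asSequenceSet <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl("[^ACGTNacgtn]", x) &&
      file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (methods::is(x, "XString")) return(stats::setNames(as.character(x), "seq"))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- if (length(x) == 1) "seq" else paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret input as a sequence set")
}

checkDNA <- function(x, what = "sequence", allowGap = FALSE) {
  pat <- if (allowGap) "[^ACGTN-]" else "[^ACGTN]"
  bad <- grepl(pat, x)
  if (any(bad)) stop(sprintf("%s contains non-ACGTN symbols", what), call. = FALSE)
  invisible(x)
}
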