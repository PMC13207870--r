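# mitoPCG

Reference-guided annotation and short-read recovery of plant mitochondrial
protein-coding genes (PCGs), with a supermatrix builder for maximum-likelihood
phylogenetics.

## The problem

Angiosperm mitogenomes (200 kb–3 Mb, often multi-chromosomal) combine several
features that defeat generic annotators and fragment short-read assemblies:

- **Trans-splicing.** Genes such as *nad1*, *nad2* and *nad5* are assembled
  from exons transcribed on opposite strands or on different chromosomes, so
  no single contiguous gene model exists on the genome axis.
- **C-to-U RNA editing of start/stop codons.** *nad1* and *nad4L* begin with
  genomic `ACG` (edited to `AUG`), *atp6* ends with genomic `CAA` (edited to
  `UAA`): the genome sequence alone mistranslates or misses the gene.
- **Non-canonical codons.** *cob* initiates at `ATT`; species variants use
  `GTG` starts or a `GGA` stop.
- **Stop-less and pseudogenized loci.** *nad6*-style genes lack a genomic
  stop codon and need a boundary decision; *rps4*, *rps14* and *sdh4* are
  pseudogene remnants that naive homology search happily "annotates".

mitoPCG is written for researchers doing organellar comparative genomics who
need (a) correct GenBank-grade PCG annotations of assembled mitogenomes and
(b) scalable recovery of PCG coding sequences from cheap Illumina data, both
driven by a curated per-lineage reference gene library.

## The method

**Exon-based annotation.** Every reference exon is located on the genome
(internal seeded k-mer aligner, or imported 12-column tabular hits; per exon
the best hit is chosen by alignment length, then identity, then score, then
position, with extra non-overlapping copies kept as duplicates). Placed
exons are grouped into transcripts in two passes:

1. *Strand/subject pass* — maximal runs of consecutively numbered exons
   sharing strand and chromosome become one transcript. The pattern
   `exon1(+), exon2(−), exon3(−), exon4(−), exon5(+)` yields transcripts
   {1}, {2,3,4}, {5}.
2. *Intron-gap pass* — within a transcript, a gap between adjacent exons
   exceeding a configurable intron-length threshold (default 5000 bp) splits
   it further; sublabels `2-1`, `2-2`, … record the split.

A gene with ≥2 transcripts is trans-spliced. A gene whose placed exon count
deviates from the reference exon count is a pseudogene
(`EXON_COUNT_MISMATCH`), as is a gene failing the optional exon-order check
(`EXON_ORDER_VIOLATION`) or absent entirely (`MISSING_GENE`).

**Codon exceptions.** RNA-edited start/stop codons are annotated on the
pre-edited genomic sequence with GenBank
`/transl_except=(pos:P..P+2,aa:Met|TERM)` qualifiers and the translation is
rendered accordingly (edited starts as `M`); non-canonical codons get
verbatim `/note=` qualifiers; stop-less genes resolve their 3′ boundary by
aligning reference forms of varying length and keeping the highest-scoring
one (score = alignment length × identity/100; ties broken by longest ORF).

**Short-read recovery.** Read pairs are assigned to a gene when *either*
mate matches its reference (union rule, so no mate is orphaned); CDSs are
rebuilt from assembled contigs by choosing the best alignment per gene/exon,
splicing exons in ordinal order, and logging what cannot be resolved
automatically — notably one exon fragmented across two contigs
(`EXON_SPLIT_ACROSS_CONTIGS`). A 22 bp exon in the *nad5* model is made
searchable by padding it with 150 bp conserved flanks that are stripped
exactly on output.

**Supermatrix.** Per-gene alignments of the samples and an outgroup (CDSs
extracted from its GenBank record) are intersected by gene name,
concatenated with a partition map (`DNA, gene = start-end`), optionally
gap-filled from a conspecific sample where the region is completely
conserved in the cohort, and handed to an external RAxML-style command with
the default model `GTR+GAMMA+I` and 1000 bootstrap replicates.

Everything is testable offline: a deterministic simulator generates
mitogenomes (cis/trans layouts, duplicate/deleted exons, oversized introns,
frameshifts), error-free paired reads, and contigs with truth manifests.

## Worked example

```r
library(mitoPCG)

lib <- buildPaperLibrary()
lib
#> ReferenceLibrary with 30 protein-coding genes (7 multi-exon)
#>   pseudogene loci: rps4, rps14, sdh4
#>   default intron threshold: 5000 bp (0 per-gene overrides)

sim <- makeGenome(lib, list(
  geneLayout("nad1", mode = "trans_strand_flip",
             strands = c("+", "-", "-", "-", "+")),
  geneLayout("cob"), geneLayout("nad4L")), seed = 101)

ann <- annotateGenome(lib, sim$genome, genes = c("nad1", "cob", "nad4L"))
ann$nad1
#> GeneAnnotation nad1: 5 exon(s) placed in 3 group(s) - trans-spliced
for (g in transcriptGroups(ann$nad1)) show(g)
#> TranscriptGroup 1 [+ on chr1]: exons 1
#> TranscriptGroup 2 [- on chr1]: exons 2,3,4
#> TranscriptGroup 3 [+ on chr1]: exons 5

qualifiers(assembly(ann$nad4L))
#> [1] "/transl_except=(pos:12875..12877,aa:Met)"
qualifiers(assembly(ann$cob))
#> [1] "/note=Translation initiates from a non-canonical ATT start codon."
substr(proteinSequence(assembly(ann$nad4L)), 1, 12)
#> [1] "MAATPHDIALSH"
```

The five-exon strand pattern is resolved into three transcripts and the gene
is flagged trans-spliced; the `ACG` start of *nad4L* is annotated as a
post-transcriptional Met (positions 12875–12877 are the codon's genomic
coordinates on the simulated chromosome) and its translation begins with
`M`; the `ATT` start of *cob* gets the byte-exact note. `writeGenBank()` and
`writeGFF3()` serialize these annotations; `recoverFromContigs()`,
`organizeOutputs()`, `concatenateAlignments()` and `emitPhyloHandoff()`
cover the recovery and phylogenetics side. A thin command-line front end
lives in `inst/scripts/mitopcg.R`.

## Limitations

The aligner is ungapped and seed-based (indel-containing homology is split
or truncated); GenBank output covers gene/CDS features only; multiple
sequence alignment, de novo assembly and tree inference are deliberately
external (MUSCLE/SPAdes/RAxML-class tools), with this package preparing
their inputs and consuming their outputs. See the methods vignette
(`vignettes/mitoPCG-methods.Rmd`) for modelling choices and defaults.
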