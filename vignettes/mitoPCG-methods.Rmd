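---
title: "Methods: annotating and recovering plant mitochondrial PCGs"
author: "mitoPCG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and recovering plant mitochondrial PCGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoPCG)
```

## Scope and model

mitoPCG annotates plant mitochondrial protein-coding genes (PCGs) against a
curated reference library and recovers their coding sequences from
short-read-derived contigs. The package's modelling commitments are:

* A **gene** is a reference model: an ordered list of exon sequences, a
  declared start and stop codon, a list of C-to-U RNA-editing sites in
  spliced-CDS coordinates, and optional alternate full-CDS forms.
* An **annotation** is a set of exon placements on the genome, grouped into
  transcripts; trans-splicing and pseudogene status are *derived* from the
  grouping, never asserted directly.
* RNA editing is annotated on the **pre-edited genomic sequence**: the
  stored CDS nucleotides are never modified; only qualifiers and the
  rendered translation change. This mirrors how GenBank submissions handle
  editing-dependent starts/stops via `transl_except`.

## The reference library

`buildPaperLibrary()` constructs the curated 30-gene *Rhodiola*-style PCG
set: seven multi-exon genes (*nad1*, *nad2*, *nad5*, *nad7* with five exons;
*nad4* four; *cox2* three; *ccmFc* two), a 22 bp minimal exon in *nad5*, ACG
starts for *nad1*/*nad4L* and a CAA stop for *atp6* (both C-to-U edited), an
ATT start for *cob*, a stop-less *nad6*, and pseudogene loci *rps4*,
*rps14*, *sdh4*. Exon sequences are synthetic stand-ins generated once from
a fixed seed: they honour the curated lengths, frames and codon exceptions,
but they are not the real gene sequences (which live in an external
database this package deliberately does not fetch). Consequences: all
structural and rule-based behaviour is fully exercised, while anything
depending on real sequence content (real divergence levels, real intron
motifs) is not.

The library round-trips through a FASTA + sidecar pair (`saveLibrary()` /
`loadLibrary()`). The sidecar is a line-oriented key/value document — chosen
over a binary or nested format because the curation workflow this package
supports involves manually adding atypical gene forms, and a text record per
gene is the easiest thing to curate and diff. Serialization is canonical
(sorted genes, fixed key order), making the save–load–save cycle
byte-identical, which the tests assert.

## Homology mapping

The internal aligner is a seeded, **ungapped** matcher: exact k-mers of the
query (default `k = 15`, sampled every `k/2` positions, so any exact overlap
of at least `k + k/2 − 1` bases is guaranteed a seed) are looked up in a
hash index of the subject; each seed diagonal is extended by taking the
maximal-scoring contiguous segment (match +1, mismatch −3; `N` never seeds
and always counts as a mismatch) and kept if it reaches the identity
(default 90%) and length thresholds. Scores are
`alignment length × identity / 100`. Both strands are searched; the
12-column tabular convention is used throughout (query coordinates forward;
`sstart > send` encodes minus). Genuinely gapped homology is out of scope
(the segment simply truncates at an indel), which is acceptable because the
package's placement unit is the exon and its fixtures are exact or
near-exact plants; users with diverged data can import hits from an external
aligner via `parseHitsTabular()`.

Placement policy: per exon the best passing hit wins by (1) alignment
length, (2) identity, (3) score, (4) smallest start — a total order, so the
result is invariant under permutation of the hit list. Additional passing
hits that do not overlap a retained placement (≥1 bp shared on the same
sequence, either strand) are kept as duplicate copies, reflecting the
multi-copy exons seen for *nad1*/*nad5* in real mitogenomes; duplicates are
reported but excluded from classification.

## Transcript grouping and classification

Grouping is two passes. The strand/subject pass makes a new transcript
whenever consecutive exon ordinals change strand, change chromosome, or skip
an ordinal (a missing exon also breaks the run; such genes are pseudogenes by
count anyway). The gap pass splits a transcript where the forward-axis
distance between adjacent placements exceeds the intron threshold. The
distance is measured between the two intervals irrespective of strand, and a
negative distance (overlapping placements) is flagged and treated as zero —
the threshold semantics then reduce to the plain
`downstream.start − upstream.end − 1` whenever ordinal order follows the
axis.

The default intron threshold is **5000 bp**. The per-gene thresholds of the
source workflow are derived from a panel of related genomes and are not
published as numbers, so here the value is configuration, not ground truth:
it comfortably exceeds the simulator's cis introns (0.3–1.2 kb) and is
exceeded by its "wide" introns (threshold + 1.5–3 kb), so both split
outcomes are exercised. Per-gene overrides are supported in the library.

A gene is trans-spliced iff it has ≥2 transcript groups and is not missing
entirely. Note one subtlety: a gene may be *both* trans-spliced and a
pseudogene (e.g. four of five exons placed in two groups) — the flags are
independent except that a missing gene is never trans-spliced. The
exon-order check (plus strand: starts increasing with ordinal; minus:
decreasing) defaults **off**, as an opt-in validation; when enabled, a
violation marks the gene a pseudogene.

## Codon rules

Translation uses the standard genetic code (table 1, the code used for
land-plant mitochondria); non-canonical codons are handled by qualifiers,
never by a custom code table. Editing sites emit
`/transl_except=(pos:P..P+2,aa:Met)` for start gains (translation rendered
`M`) and `aa:TERM` for stop gains (translation terminated there). The `pos`
value is the genomic coordinate range of the edited codon; the range form
`P..P+2` is emitted because a codon spans three bases. Stop gains use the
GenBank `TERM` token. Sites whose genomic codon is already canonical in the
annotated genome are silently skipped (nothing to except); a codon that
matches neither the genomic nor the edited form is reported and skipped
rather than guessed.

For stop-less genes the 3′ boundary is chosen by aligning every registered
reference form (primary CDS plus variants) to the region and keeping the
highest-scoring form; exact ties go to the form with the longest
identifiable ORF, then to the lexicographically smallest label so the
procedure is deterministic and permutation-invariant.

## GenBank and GFF3 output

Cis multi-exon CDSs are `join(...)`; uniform minus-strand features whose
translation order descends the axis are `complement(join(ascending))` (the
conventional form); any other strand arrangement — which trans-splicing
makes legal — falls back to `join(complement(a..b), c..d, ...)` with
segments in translation (exon-ordinal) order, because translation order is
what downstream consumers splice. Trans-spliced CDSs carry
`/trans_splicing`; genes spanning several sequence records are written as
one CDS per record sharing `/gene` plus a partner note, since the flat-file
location grammar cannot join across records (segment order across records is
then file order, a documented ambiguity). Pseudogenes are gene features with
`/pseudo` and no CDS. GFF3 is emitted through `rtracklayer`, with CDS phase
computed from cumulative coding length in translation order.

## Recovery from short reads

Read extraction uses the union rule: a pair is kept for a gene if either
mate matches that gene's reference (defaults: internal matcher with
`k = 21`, ≥95% identity over ≥50 bp — the external aligner settings of the
original workflow are unstated, so these are configuration chosen to accept
exact reads and reject random 150-mers). Contig-based reconstruction picks
the best alignment per gene/exon by aligned length; an exon whose best hit
is partial while another contig covers query positions outside that span is
declared fragmented (`EXON_SPLIT_ACROSS_CONTIGS`) and *not* auto-merged —
the log exists precisely so a human reviews those loci. Uncovered reference
positions become gap intervals in spliced-CDS coordinates; a recovered CDS
is complete iff it has none.

Outputs are organized twice — gene-wise FASTA (for SNP work) and sample-wise
FASTA (for phylogenetics) — in lexicographic order so re-runs are
byte-identical.

## Supermatrix

Gene sets are intersected across samples and outgroup by name;
concatenation records a partition map asserted post-construction to tile
`1..L`. Missing-region fills are allowed only from a conspecific donor and
only where every non-missing cohort row (the recipient excluded — the
package's reading of an underspecified rule) is identical over the region;
everything else is a logged refusal. Samples whose matrix row is more than
20% missing after permitted fills are recommended for exclusion — the
source policy states no number, so 20% is a configurable default. Missing
characters are `-`, ambiguity `N`. The handoff writes relaxed PHYLIP (names
untruncated), FASTA and a RAxML-style partition file, and renders — but
never executes — the ML command with model `GTR+GAMMA+I` and 1000 bootstrap
replicates by default. Multiple sequence alignment itself is external
(MUSCLE-class tools); the package consumes pre-aligned per-gene FASTA.

## The simulator, and what passing tests do and do not show

`makeGenome()` plants library genes on chromosomes with random intergenic
spacers (2–3.5 kb) and introns (0.3–1.2 kb), realizing cis, strand-flip and
multi-chromosome layouts, duplicate/deleted exons, oversized introns and
frameshifts, and records a truth manifest of every planted interval.
`simulateReads()` draws error-free 2×150 bp pairs from fixed-size 350 bp
fragments at a target coverage (default 50×), names carrying origin
coordinates; an optional uniform substitution rate exists for robustness
tests. `fragmentContigs()` tiles the genome into contigs, optionally
breaking inside a named exon to fabricate the split-exon condition. All
generators are pure functions of (inputs, seed); background GC is ~45%,
cosmetic only.

Because reads are error-free and plants are exact, passing tests demonstrate
the *rules* — grouping, splitting, classification, qualifier emission,
split-exon detection, exact recovery arithmetic — not robustness to
sequencing error, real intron content, chimeric assembly, or genuine
inter-species divergence. The de novo assembler is a pluggable external
step; tests bypass it with truth-derived contigs on purpose, so assembler
quality is explicitly outside what the green suite certifies.

## Numerical and procedural choices

* Internal coordinates are handled 1-based inclusive end-to-end; the
  12-column tabular, GenBank and GFF3 dialects are all 1-based, so no
  off-by-one conversion layer is needed at the interfaces.
* Small-exon cutoff for flank padding: 30 bp (captures the 22 bp case with
  margin); default flank 150 bp, stripped exactly on every output path.
* Deterministic tie-breaks everywhere a choice is made (placement order,
  variant selection, contig names, lexicographic file order), so every
  pipeline stage is reproducible and permutation-invariant.
* Test problem sizes: full 30-gene genomes (~150 kb) for end-to-end checks,
  500 bp subjects for the alignment oracle (100 instances), exhaustive
  strand × gap enumeration up to 6 exons, 10,000 random codons for the
  translation oracle — sizes chosen so the whole suite runs in about a
  minute while covering every rule at least once.

## Known limitations

Ungapped alignment only; no tRNA/rRNA annotation; no automated frameshift
discrimination (a frameshifted gene surfaces as a truncated or split
alignment, left to the error log and the missing-stop machinery); GenBank
parsing is limited to the feature grammar this package writes plus
`join`/`complement` CDS locations with `/gene` qualifiers; conserved-flank
augmentation assumes the supplied context truly contains the exon once.
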