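---
title: "lincatlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincatlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long intergenic noncoding RNAs (lincRNAs) are transcripts longer than
200 nt that lie between protein-coding genes and lack protein-coding
capacity. Cataloging them from bulk RNA-seq requires separating genuine
intergenic transcription from an assortment of look-alikes: fragments of
known genes and their unannotated UTR extensions, pseudogenes, small
structural RNAs, transcripts that merely sit close to coding genes, and
assembly artifacts supported by almost no reads. `lincatlas` implements
this discovery cascade and the downstream statistics used to
characterize the resulting catalog, together with a seeded synthetic
study in which the correct answer is known by construction, so that
every stage can be tested end to end.

# The filter cascade

Candidate transcript models (BED12 blocks; strand may be ambiguous,
`"."`, as is typical for assemblies from unstranded libraries) pass
through six stages in a fixed order. All coordinates are 0-based
half-open; all span overlaps are strand-blind unless stated.

1. **Length.** Transcripts with mature (exonic) length below 200 nt are
   removed. The definition of a lincRNA refers to RNA length, so the
   filter uses the spliced length, not the genomic span, and a
   transcript of exactly 200 nt is kept.
2. **Coding-gene proximity.** A transcript within 1 kb (inclusive) of a
   protein-coding gene on the same strand is removed; an
   ambiguous-strand transcript is tested against either strand. A
   transcript on the opposite (definite) strand is removed only when it
   overlaps the gene span by at least one base.
3. **Annotation overlap.** One base of span overlap with any non-lincRNA
   annotation (pseudogenes, small non-lincRNA ncRNAs, other-species gene
   alignments, coding sequence, alternative/extended UTR annotations)
   removes the transcript, regardless of strand.
4. **Large ORFs and their neighbors.** `find_large_orfs()` scans all six
   reading frames of the spliced sequence. A transcript is removed when
   it carries (i) a complete ATG-to-stop ORF longer than 100 amino acids
   (strict; the stop codon is not counted, the initiating Met is), or a
   truncated frame in which (ii) an ATG is followed by more than 300
   stop-free nt to the transcript edge, or (iii) a stop codon is
   preceded by more than 300 nt with no in-frame start or stop — the
   transcript may be a clipped fragment of a coding gene. In a second
   pass, remaining transcripts whose span overlaps a removed ORF carrier
   are removed as its putative UTRs. The second pass is deliberately
   non-transitive: a transcript touching only a pass-2 victim survives.
   Codons containing `N` never match start or stop codons. All
   transcripts are scanned in all six frames regardless of annotated
   strand, since most candidates have no reliable strand.
5. **Extended gene boundaries.** Assembly evidence extends many coding
   genes beyond their annotated ends; one base of overlap with an
   extended boundary removes the transcript.
6. **Expression.** Reads are counted with *full assignment*: a read
   increments every transcript whose exons any of its aligned blocks
   overlap by at least one base, with no fractional splitting. This is
   the right semantics for a candidate set full of redundant,
   slightly-shifted annotations of the same underlying transcript; an
   intron-only read does not count. FPKM = count x 10^9 / (exonic length
   x dataset total mapped reads), with the dataset-wide total (not the
   size of whatever read subset was supplied). Transcripts that never
   exceed FPKM 1 (strictly) in any dataset are removed; survivors are
   tiered at FPKM > 1, > 10, > 30, each tier containing the higher ones.

Survivors are collapsed into a minimal catalog: transcripts merge when
an exon of one overlaps an exon of the other by at least 50% of either
exon's length (inclusive, one direction suffices), merged models take
the union of member exons, and merging is iterated to a fixed point —
unioning exons can create new qualifying overlaps, and the iteration is
what makes "no two catalog entries satisfy the merge rule" actually hold.
Opposite definite strands never merge; ambiguous pairs may. Merged
models within 1 kb (inclusive, chained transitively) share a group, and
names follow `FPKM<tier>_group_<g>_transcript_<t>` with transcripts
numbered by leftmost coordinate, ties broken by end then id, so the
catalog is reproducible. FPKMs are recalculated on the merged models.

# Expression above the intergenic background

A transcript can survive the cascade yet be indistinguishable from
transcriptional noise. For each catalog entry we build an empirical
null: the entry's exact block structure is translated to positions drawn
uniformly over all valid starts in the *background space* — the
uniquely mappable genome minus every annotation, extension, candidate
transcript and catalog entry, keeping only pieces longer than 200 bp —
and scored with the same counting and the same dataset totals. The
empirical p uses the add-one estimator `p = (1 + #{null >= obs}) / (1 +
n_shuffles)`, which never returns 0. Placements are drawn once per
transcript and scored against every dataset; each dataset still has its
own null distribution of FPKMs. With one test per dataset, Bonferroni
correction multiplies each p by the number of datasets, and a transcript
is called significantly expressed when its best corrected p is at most
0.1. The default `n_shuffles` is 10,000 for the standalone function and
1,000 in the pipeline configuration, which resolves corrected p-values
comfortably below the 0.1 threshold for a six-dataset panel while
keeping a full run interactive; raise it when finer p resolution is
needed.

# Characterization statistics

* **Coverage quantitation.** Depth profiles are run-length encoded, with
  split (junction-spanning) reads counted either block-wise
  (`excluding_inferred`) or span-wise, intron included
  (`including_inferred`); the mappability mask is applied at query time.
  The threshold curve reports the mappable fraction covered at depth >=
  k; base calls weight positions by their depth (positions-at-depth x
  depth); the per-dataset fraction of reads in flattened coding exons is
  the library-type QC used to flag genomic-DNA contamination.
* **Ribosome engagement.** Each transcript's spliced sequence is tiled
  with 30-nt windows at 1-nt offsets; the score is the maximum over
  windows of ribosome-profiling reads per RNA-seq read. Windows with
  zero RNA-seq reads are skipped so the maximum stays finite; a read
  counts for a window when any block overlaps it by >= 1 nt after
  projection to transcript coordinates. Windows live in transcript
  space and are projected to the genome for counting.
* **Conservation.** The maximum mean per-base conservation score over
  50-bp windows requiring all 50 consecutive exonic bases to be scored;
  transcripts without 50 contiguously scored bases are reported as
  unscored (`NA`), never as zero.
* **Trait-associated SNPs.** Tested-SNP counts per region are scaled by
  platform contribution to published GWASs (Illumina 0.586, Affymetrix
  0.414; SNPs on both platforms count in both terms). Enrichment is the
  TAS-per-scaled-tested-SNP rate ratio between lincRNA exons and
  nonexpressed background loci, with Fisher's exact test on the rounded
  2x2 table (rounding the scaled totals costs at most half a count) and
  Wilson 95% intervals, which behave well at small counts.
* **PolyA fractionation.** Features with reads in all four
  polyA+/polyA- datasets of two cell types and FPKM > 1 in at least one
  fraction per cell type get a per-cell-type FPKM(+)/FPKM(-) ratio; the
  cross-cell-type Pearson correlation is computed on log2 ratios, the
  scale on which fold changes are symmetric.
* **ChIP signal** is the depth-normalized IP/input ratio over a
  transcript's exons; zero-input transcripts are undefined rather than
  infinite. **PET end support** asks whether a transcript's terminal
  base falls inside the oriented end block of an overlapping paired-end
  ditag cluster, testing both orientations for ambiguous strands.
* **Tissue clustering.** Features above FPKM 10 are log2-transformed
  with a pseudo-count of 1 (zero FPKM maps to 0), then rows and columns
  are alternately rescaled toward unit sum of squares (at most 100
  rounds), and samples are clustered by Euclidean distance with centroid
  linkage on squared distances.

## A note on the clustering normalization

Simultaneous unit sum of squares for all rows *and* all columns is only
attainable for square matrices: if every one of `n_r` rows has sum of
squares 1 the matrix total is `n_r`, and if every one of `n_c` columns
does it is `n_c`. For the usual tall matrix the alternating rescaling
converges to the attainable fixed point — every column at exactly 1 and
every row at the common value `n_c / n_r` — and `cluster_samples()`
reports `converged = FALSE` in that case while returning that fixed
point. Sample distances are unaffected, since the residual row factor
is a single global constant.

# The synthetic study

`simulate_all()` builds a study in which every downstream claim can be
checked against planted truth:

* **Genome.** Two chromosomes of 1 Mb by default, with ~10% of each
  masked unmappable in random 50-500 bp segments (segment totals are
  overlap-corrected so the realized fraction matches the target).
* **Features.** 150 true lincRNAs and 350 decoys, each decoy violating
  exactly one rule: short (<200 nt), proximal (100-900 bp from a coding
  gene), overlapping a pseudogene / small-RNA / UTR-extension
  annotation, carrying a real 110-180 codon ORF, overlapping such a
  carrier (placed exon-disjoint in its intron, so only the span
  overlaps), or expressed below FPKM 1 everywhere. Sixty protein-coding
  genes carry designed ORFs of at least 151 codons and serve both as
  annotation and as candidates (assemblers reassemble known genes);
  they fall at the proximity stage, being zero distance from
  themselves. Features are placed left to right with inter-unit gaps
  above 1 kb and never on unmappable segments; half of the unpaired
  genes get 0.5-5 kb extended boundaries, whose padding is reserved so
  nothing else lands inside. LincRNA-like sequences are made free of
  large ORFs by repeated in-frame stop-codon injection, verified with
  the ORF caller at generation time.
* **Expression and reads.** Active transcripts draw log-normal FPKMs
  (median 30, floored at 20 so planted lincRNAs clear the FPKM > 1
  filter with Poisson sampling margin to spare) in a tissue-specific
  on/off pattern (lincRNAs mostly single-tissue, coding genes broad).
  A polyA weight partitions each transcript's signal between
  polyA-selected and polyA-depleted fractions. Per-dataset counts are
  Poisson at the FPKM-implied mean — over-dispersion is deliberately
  omitted, since the pipeline's logic, not biological variance, is
  under test — and reads fall uniformly along the spliced transcript,
  junction-crossing reads emitted as split alignments. Uniform genomic
  background reads (125-500 per megabase per dataset, more in polyA-
  libraries) model library noise; low-expression decoys are built long
  (>= 800 nt mature) so the FPKM > 1 cutoff needs several reads, which
  noise essentially never supplies; nominal library totals are 10^7, so
  FPKM
  denominators behave like real flagstat totals even though only the
  informative reads are materialized.
* **Tracks, SNPs, clusters.** The conservation track is N(0,1) noise
  with N(2,1) windows over coding exons and 30% of lincRNA exons; SNP
  tables plant a 5-fold trait-associated enrichment in lincRNA exons
  (3-fold in coding exons) over a 4% background rate among 10,000
  tested SNPs; ribosome-profiling reads fall only on coding CDS; ChIP
  IP reads are enriched over TSS mark intervals; PET clusters bracket
  the ends of genes and half the lincRNAs.
* **Determinism.** Every sub-generator runs on its own RNG stream
  seeded by a hash of the master seed and the stream name, so adding a
  dataset never moves annotation placement, and a rerun of the pipeline
  with the same configuration is byte-identical (logs go to stderr, not
  into output files).

What the simulation does *not* emulate: sequencing errors and quality
scores, fragment-length and positional bias, isoform structure beyond
redundant overlapping models, over-dispersed expression, correlated SNP
linkage structure, or realistic conservation autocorrelation. Passing
tests therefore demonstrate that the pipeline's rules and statistics are
implemented correctly and recover planted structure — not that the
thresholds themselves are optimal for any particular real dataset.

# Numerical and design choices

* Boundary readings are fixed and tested: "less than 200 nt" removes
  199 and keeps 200; "within 1 kb" is inclusive at 1,000; the 50% merge
  criterion is inclusive and one-directional; FPKM tiers are strict.
* ">100 amino acids" counts the initiating Met and excludes the stop,
  so the smallest large ORF is 101 aa; both truncation rules are strict
  at 300 nt, measured excluding the ATG codon (downstream rule) and
  from the sequence start to the stop codon's first base (upstream
  rule).
* The background-space minimum is strict: pieces must be longer than
  200 bp.
* Problem sizes in the test suite (2x1 Mb default genome, 1,000
  pipeline shuffles, 200 oracle sequences, 500 calibration queries with
  1,000 shuffles each) were chosen so the whole suite and an end-to-end
  run stay interactive on a laptop while leaving the statistical checks
  (calibration within two binomial standard errors, fold recovery
  within two binomial standard deviations) well-powered.
* Ties in transcript numbering within a group are broken by leftmost
  start, then end, then id.

# Known limitations

* The pipeline consumes already-assembled transcript models; alignment
  and assembly are out of scope, as are PhyloCSF-style
  codon-substitution scores and coordinate liftover of legacy
  annotations.
* The extended-gene-boundary set is an input (produced synthetically
  here), not derived from reads by reference-guided assembly.
* No truth category targets the extended-gene stage in the default
  simulation, so that stage removes nothing there; it is exercised by
  its own unit tests.
* The clustering normalization cannot satisfy unit row *and* column
  sums of squares on non-square matrices (see above); the package
  converges to the attainable fixed point and says so.
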