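---
title: "Discovering spliced-leader genes from stranded RNA-seq"
author: "SLscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering spliced-leader genes from stranded RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SLscout)
```

## The problem

Dinoflagellate mRNAs mature by *trans*-splicing: a short conserved spliced
leader (SL) is transferred from an SL RNA onto the 5' end of every
pre-mRNA. In dinoflagellates the SL core is 21 nt
(`CCGTAGCCATTTTGGCTCAAG` in DNA form, with a degenerate extra base D = T/A/G
preceding it in the 22-nt consensus). Because every mature mRNA starts with
the SL, transcripts of the *SL genes themselves* are hard to isolate by
PCR: SL-anchored primers erase whatever lies upstream of the leader.
Strand-specific RNA-seq offers an alternative: in a TruSeq-stranded
library the reverse read (R2) carries the transcript sense strand, so a
read whose R2 contains the SL in sense orientation is evidence of an
SL-gene transcript, upstream sequence included.

SLscout implements that strategy as a reusable, fully tested pipeline:

1. **Orientation contract** (`readFastqPairs()`, `senseReads()`) — only
   the sense mate (R2 by default) is searched; the antisense mate is never
   reverse-complemented or merged, because strandedness *is* the method.
2. **Deduplication** (`dedupReads()`) — exact-sequence duplicates are
   removed, first occurrence kept. The key is the sequence string alone;
   pair- or UMI-aware dedup can be substituted upstream.
3. **Unit scanning** (`scanSequence()`) — leftmost-greedy non-overlapping
   calling of three unit types, with per-position priority
   FULL > VARIANT > RELICT:
   * FULL: the canonical 21-nt SL (exact by default; `maxMismatches` is a
     sensitivity knob),
   * RELICT: the 17-nt leader remnant `AGCCATTTTGGCTCAAG`, a suffix of the
     SL (relicts inside a called FULL unit are not double-counted),
   * VARIANT: the SL-like first unit in which the TCCG opening the
     D = T leader is contracted to TCG; applied to the canonical leader this
     gives the 21-nt motif `TCGTAGCCATTTTGGCTCAAG` — the SL with its first
     C replaced by T.
   Reads with at least one FULL unit are SL-containing; reads with no FULL
   unit but at least two RELICT/VARIANT units are SL-like candidates;
   single lone relicts are discarded as probable random matches.
4. **Micro-assembly** (`assembleReads()`) — greedy ungapped
   overlap-layout-consensus over each pool, with the published thresholds:
   overlap of at least 30 bp at no less than 95% identity.
5. **Classification** (`classifyConsensusSet()`) — SINGLE_SL (one FULL
   unit), TANDEM_SL (two or more FULL units), SL_LIKE (no FULL, two or
   more relict/variant units). The upstream extension, total and core
   length (total minus upstream), read support, and reads-per-million are
   reported per locus.
6. **Intron analysis** (`extractIntrons()`, `donorCheck()`,
   `motifEnrichment()`) — the candidate intron is the suffix after the
   last FULL unit (the SL ends in AAG); a valid donor starts GT or GC;
   U-rich candidate Sm-protein binding motifs are counted against a
   random-occurrence expectation.

## A worked example

```{r example}
cfg <- simConfig(errorRate = 0, seed = 42)
sim <- simulateSLLibrary(cfg)
pipe <- runPipeline(pathR1 = sim$paths[["r1"]], pathR2 = sim$paths[["r2"]])
unlist(pipe$manifest$counts)
table(pipe$calls$gene_class)
pipe$lengths
subset(pipe$enrichment, motif == "GUUUUC")
```

## Design choices

**Coordinates.** All coordinates are 1-based inclusive (`IRanges`), the
Bioconductor convention; GFF3 output therefore needs no conversion.

**Assembly is deliberately minimal.** The original analysis used a general
EST assembler; transcripts of one SL locus differ only by sequencing
errors at this scale, so SLscout uses ungapped overlaps only. That keeps
the kernel exactly checkable against a brute-force enumeration oracle
(the test suite does this on hundreds of random pairs). Gapped or
quality-weighted assembly is out of scope. Greedy order is deterministic:
reads sorted by descending length then id (C collation); each read joins
the first cluster whose *current consensus* admits a qualifying overlap;
cluster consensi are then merged to a fixed point. Overlap candidates are
ranked by length, then identity (compared exactly, by integer
cross-multiplication), then smallest offset.

**Threshold semantics.** The published thresholds are quoted as
"overlap > 30 bp, identity > 95%"; the assembler they configure is not
documented at that level, so SLscout implements `>= 30` and `>= 0.95` and
exposes both (`overlapParams()`).

**Consensus calling.** Column-wise majority vote over member bases; `N`
never votes and never matches anything; ties produce the IUPAC ambiguity
code of the tied bases; depth is the number of non-N member bases per
column.

**Tandem classification.** TANDEM_SL keys on FULL units only: a consensus
with one FULL SL followed by relicts is reported as SINGLE_SL (with its
relict count), matching the observed architecture in which tandem-SL
*genes* carry multiple AAG-terminated SL copies while many transcripts
show one SL plus relicts. Raw unit counts are always reported so loci can
be re-binned.

**Expression.** `rpm = 1e6 * locus reads / total deduplicated reads`.
The denominator is deliberately the deduplicated library size before SL
filtering; duplication of the whole library changes nothing only because
dedup runs first.

**Motif expectation.** The expected count of an n-mer under a uniform
25%-per-base background is `positionsScanned * (1/4)^n`. The source
report prints the normalisation as `1/n^4`; read literally that expression
is independent of the alphabet and has no probabilistic meaning, so
SLscout treats it as a typographical inversion of `(1/4)^n`. The literal
form remains available (`motifEnrichment(..., expected = "literal")`) for
replication. A GC-weighted background is a possible extension; the
uniform default matches the "random occurrence" framing. The intron 3'
boundary is not modelled (no acceptor site is defined): candidates run to
the consensus end.

**Motif panel.** The U-rich motifs are reported inconsistently in the
source material (one motif listed twice, another appearing only in a
second list); the default panel is the union
CUUUG, CUUUUG, GUUUA, GUUUUC, GUUUUA, UUUAA (`uRichMotifs()`).

## What the simulator emulates — and what it does not

`simConfig()` defaults encode the study conditions: the census of
16 single-SL, one 2-unit tandem, one 3-unit tandem and 13 SL-like loci;
100-nt paired reads; inserts of ~200 bp (SD 10%); R2 = sense strand.
Sequencing error defaults to 0.1% substitutions (typical Illumina);
truth-recovery checks run error-free. 500 background read pairs stand in
for the non-SL transcriptome at desk scale; because decoys are uniform
random, the false SL hit rate is analytically ~`4^-21` per position.

Locus geometry deserves a note. Observed SL loci span 103–292 bp, and the
study itself points out those lengths are likely *underestimates*, because
loci are only seen as far as SL-anchored reads reach. SLscout's assembly
input is SL-containing reads only, so a recovered consensus can never
extend more than one read length beyond the SL block. Planted loci are
therefore confined to the read-recoverable portion of that envelope
(upstream extension 20–30 bp, SL intron 62–75 bp, giving single-SL loci
of 103–126 bp and tandem loci up to ~184 bp; SL-like loci use 27–40 bp
upstream and 34–50 bp downstream). Planting longer loci would make
truth-versus-recovery comparisons measure the read length, not the
pipeline.

Two further generator decisions matter:

* **Unit spacers.** Tandem and SL-like unit repeats are separated by
  4–8 bp random spacers (configurable, including 0 for strict adjacency —
  the real arrangement is not documented at base resolution). Without
  spacers, distinct loci share identical unit blocks longer than 30 bp
  (SL·SL = 42 bp), and reads whose unit block lies flush at a read end
  would legitimately satisfy the 30 bp / 95% rule *across* loci, making
  any assembler chimera-prone. Spacers keep every cross-locus identity
  block at or below 21 bp.
* **Separability screen.** Each new locus is rejection-sampled until, at
  every ungapped offset against every earlier locus, every 30-column
  window carries at least 3 mismatches. This provably excludes any
  qualifying overlap window of any length (a window of length L has at
  least `3*floor(L/30) > 0.05*L` mismatches), encoding the implicit
  assumption that downstream sequence diversity distinguishes loci.
* **Fragment phases.** R2 start positions are drawn *without replacement*
  from the admissible phases `1..L-99`; surplus depth is drawn with
  replacement and so plants exact duplicates for the dedup stage. Real
  libraries are millions of reads deep and saturate every phase of a
  ~120 bp locus; stratified sampling reproduces that saturation at a desk
  scale depth of 20, where independent draws would instead leave random
  end-truncations that reflect the downsampling, not the method.

Not emulated: indels, quality-score structure, PCR-duplicate families
(dedup is exercised with planted exact duplicates instead), rRNA or
genomic contamination, poly(A) tails (whether SL transcripts are
polyadenylated is itself uncertain), and secondary structure. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative model, not performance on real libraries — on real
data, cluster counts can differ from the published 18/13 because the
original assembler's algorithm is not fully documented.

## Problem sizes and runtime

The test suite and the acceptance script use the full census
(31 loci, depth 20, 500 background pairs → ~1,100 read pairs), which runs
the whole pipeline in well under a minute on one CPU; kernel-versus-oracle
checks run 200 random overlap pairs and all ~8,000 two-letter strings up
to length 12 against an exhaustive unit-calling oracle.

## Limitations

* Ungapped assembly: an indel-bearing read lowers identity and may seed a
  spurious cluster rather than shift an alignment.
* No acceptor-site calling: "intron" means "candidate intron suffix".
* Genome verification (`verifyInGenome()`) is substring search with
  mismatches, adequate for hundreds of consensi, not a general aligner.
* Expression estimates are rough read-count ratios, as in the source
  analysis; no length or composition normalisation is attempted.
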