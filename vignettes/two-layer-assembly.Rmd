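---
title: "Two-layer assembly of short-fragment ancient DNA libraries: methods and design notes"
author: "aDNAssembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer assembly: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

DNA recovered from archaeological material is fragmented into very short
molecules, typically 44–172 bp. Paired-end sequencing of such fragments
almost always reads through the far end of the molecule into the library
adapter, and forward/reverse mates overlap, so after adapter clipping and
mate merging the read-length spectrum is wide and bimodal: a broad hump of
full-fragment merged reads plus a spike at the instrument read length from
molecules longer than the read. A de Bruijn graph assembler must commit to
one k-mer size: small k keeps the short reads but cannot separate repeats,
large k resolves repeats but discards every read shorter than k. No single
k suits a library whose reads span 25–190 bp.

The package implements a two-layer strategy around this tension:

1. **Layer 1** runs an *independent* de Bruijn assembly for each of several
   k-mer sizes (default 37, 47, …, 127), so every part of the read-length
   spectrum is exploited by at least one assembly.
2. A **read-support filter** maps the reads back to each assembly and
   discards contigs supported by no read. De Bruijn graphs chain k-mers from
   different reads; a path no single read supports may be a chimera of
   k-mer-scale coincidences.
3. **Layer 2** pools the surviving contigs of all k, removes duplicates and
   contained sequences, merges unambiguously overlapping contigs, builds an
   exact suffix–prefix overlap (string) graph, removes transitively implied
   edges, spells maximal unbranched paths, and drops final contigs below
   1,000 bp.

Because contigs from different k start and stop at different genomic
positions, pooling them gives layer 2 junction information no single-k
assembly has, which is where the improvement in contiguity comes from.

## The simulator: what it emulates, and what it does not

`simConfig()` / `simulateLibrary()` generate a genome, fragments, and paired
FASTQ with full ground truth. The defaults model a typical short-fragment
library: fragments drawn from a normal distribution (mean 88 bp, sd 20 bp),
rounded and clipped to [44, 172] bp; 101 bp paired-end reads; read-through
into a 33 bp adapter followed by `A`/Q2 padding; a two-level quality model
(Q37 for correct bases, Q15 for erroneous ones when error–quality coupling
is on); and terminal deamination.

**Fragment positions.** Fragments are produced by a molecule-fragmentation
model: each of about `targetCoverage` genome copies is cut into consecutive
fragments whose lengths follow the configured model; the terminal remainder
of each copy is kept only when it reaches the minimum length. We chose this
over drawing fragment start positions uniformly in the interior because
uniform interior sampling leaves the first and last few dozen bases of a
linear genome essentially uncovered (the expected number of fragments
starting exactly at base 0 is far below 1 at realistic coverage), so no
assembler could ever reconstruct the sequence end-to-end, and because random
breakage of whole molecules is how aDNA fragments actually arise. The
marginal position of a fragment under random per-copy breakpoints is still
near-uniform.

**Damage.** Post-mortem cytosine deamination is modelled as C→T at
5'-offset *i* with probability `damageRate5p * damageDecay^i`, and
symmetrically G→A from the 3' end (the complementary-strand convention).
The defaults (rate 0.1, decay 0.5) follow the exponentially decaying
terminal profile that is standard in the damage-modelling literature;
`udg = TRUE` sets the rate to zero, emulating a UDG-treated library. Real
rates vary by sample and treatment; these defaults are conventions, not
measurements.

**What the simulator does not model:** metagenomic background reads,
library PCR duplicates, indel sequencing errors, quality decay along the
read, reference bias. Tests passing on these simulations therefore
demonstrate the algorithmic contracts (graph construction, overlap
detection, filtering, evaluation arithmetic) and the qualitative two-layer
effect — not performance on real metagenomic aDNA.

## Preprocessing

Adapter clipping removes, for each read, everything 3' of the leftmost
position where the remaining suffix matches a prefix of the adapter with at
most a 10% mismatch fraction. The scan repeats to a fixpoint, which makes
the operation idempotent by construction. The minimum match length defaults
to **1**: molecules one or two bases shorter than the read length retain
one or two adapter bases, and with any larger threshold those remnants
survive clipping and prevent the pair from merging (the merge model aligns
a forward suffix to a reverse-complement prefix and has no staggered case).
The cost of the aggressive threshold is the occasional loss of a few
genuine terminal bases that happen to match the adapter start; the mate
covers these positions, so merged reads are unaffected.

Quality trimming removes 3' bases below Q20 and discards reads shorter than
25 bp. Merging selects the best suffix–prefix overlap (≥ 10 bp, mismatch
fraction ≤ 0.05) by score = matches − mismatches, breaking ties towards the
longest overlap; at disagreeing positions the higher-quality base wins with
quality `max(2, |q1 − q2|)`, ties take the forward base.

The three assembly inputs follow the standard treatments: *merged* (merged
pairs + unmergeable reads as singles), *paired* (complete pairs only),
*combined* (every surviving read under unique ids). Layer 1 assembles all
three as single-end input — with almost all pairs overlapping, the insert
size carries essentially no extra information, so the de Bruijn stage uses
contigs only, no scaffolding.

## Layer 1 numerical choices

- k must be odd so no k-mer equals its own reverse complement; k-mers are
  stored canonically (lexicographic minimum of k-mer and reverse
  complement) and the graph is traversed bidirected.
- Cleaning: edges below multiplicity 2 are dropped (a single error-free read
  never outvotes two agreeing ones), dead-end paths shorter than 2k bp are
  clipped iteratively, and simple two-path bubbles with identical flanking
  k-mers collapse onto the higher mean-coverage path (ties: lexicographically
  smaller spelling). These defaults mirror conventional short-read assembler
  settings and are configurable.
- Contigs are maximal unbranched paths; each k-mer is spelled exactly once.
  Determinism: seeds are visited in lexicographic order, output contigs are
  emitted in canonical orientation and sorted, so the result is independent
  of read input order.

## The read-support filter

A read supports a contig when an exact 15-mer seed extends (ungapped,
either strand) to an alignment covering ≥ 90% of the read at ≥ 95%
identity. The aligner is deliberately minimal: the filter needs a
presence/absence decision, not an optimal alignment, and the simulator
introduces no indels, so substitution-only extension loses nothing here.
Support thresholds operationalise "supported by any read" strictly and are
exposed in the configuration. Removal is a pure subset operation — contigs
with at least one supporting read survive unchanged.

## Layer 2 numerical choices

- Overlaps are **exact** and at least 45 bp. Exactness follows string-graph
  practice on pre-assembled input: first-layer contigs are consensus
  sequences, so residual errors should already be averaged out. 45 bp is
  far above the length at which random contig ends collide (4^45 ≫ any
  desk-scale genome) yet well below typical contig overlap at pooled multi-k
  scale.
- Containment handling: contained and duplicate contigs (either strand) are
  removed before graph construction; among equal duplicates the
  lexicographically smallest id survives.
- `fmMerge()` merges a pair only when each involved contig end has exactly
  one overlap partner, iterating to a fixpoint; merged sequences are stored
  in canonical orientation, which (with id-sorted candidate order) makes the
  result independent of input order.
- The overlap graph marks an edge reducible when two consecutive overlaps
  imply it with exactly consistent lengths (transitive reduction). Final
  contigs are maximal unbranched paths over irreducible edges; paths stop at
  branches — no repeat-resolution heuristics are attempted in layer 2, the
  gains come from pooling k values.
- The final length filter (default 1,000 bp) is applied after spelling.

Known limitation: near-identical but not exactly overlapping contigs (e.g.
from diverged repeat copies) are neither merged nor removed, so some
redundancy can persist in the final set; coverage evaluation uses union
semantics so this does not inflate coverage.

## Evaluation

Contigs are mapped to the reference by exact 31-mer seeds grouped by
diagonal with ungapped X-drop extension (match +1, mismatch −3, drop 12);
split alignments are allowed, accepted alignments are non-overlapping on
the contig and must reach 90% identity. On the error-free simulations used
throughout the tests the alignments are exact, so this contract is fully
oracle-checkable against per-base arithmetic. Reported statistics follow
the usual conventions: contig counts/N50/mean/longest over *mapped* contigs
of at least the evaluation cutoff (default 1,000 bp); gaps are maximal
uncovered reference intervals of any length ≥ 1 (the simplest defensible
definition — no minimum gap size); the coverage curve recomputes the
covered fraction keeping only contigs of at least each threshold (defaults
1,000–10,000 bp in 500 bp steps) and is non-increasing by construction;
repeat resolution is the fraction of annotated repeat bases that fall in
gaps (undefined and reported as NA when no repeat bases are annotated).
Bases covered by several contigs count once; depth beyond 1 is available
from the alignments for redundancy analysis.

## Study sizes and reproducibility

The test suite and the acceptance script exercise the full pipeline on a
50 kb genome with two planted exact 100 bp repeat families (three copies
each) at 30× coverage — large enough that the ten first-layer assemblies
populate the whole k range and the planted repeats sit strictly between the
smallest and largest k − 1, small enough that the complete study runs in a
couple of minutes on one core. Unit-level checks use 2–20 kb genomes.
Every stage draws its randomness from the configured seed (the compiled
code uses R's RNG), so a pipeline run is a pure function of its
configuration: reruns produce byte-identical FASTQ, FASTA and report files,
which the test suite asserts.

## Degenerate inputs

Zero coverage yields empty fragment sets; empty read sets yield empty
graphs; a k larger than every read yields an empty assembly with a warning,
and a k list in which *every* k exceeds the longest read aborts the
pipeline with a stage-labelled diagnostic. Empty contig sets propagate as
empty reports flagged accordingly; repeat resolution without annotated
repeats is NA, never 0/0.
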