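# aDNAssembly

De novo assembly of short-fragment (ancient DNA style) sequencing libraries
in R, built around a two-layer strategy: many de Bruijn assemblies with
different k-mer sizes in the first layer, merged through an exact
string-overlap graph in the second.

## The problem

Ancient DNA survives as very short molecules, typically 44–172 bp.
Paired-end sequencing of such fragments reads through the molecule into the
library adapter, and mates overlap; after clipping and merging, read
lengths range from the trimming minimum up to ~190 bp, with a spike at the
instrument read length. A de Bruijn assembler must choose one k: every read
shorter than k is invisible to the graph, while repeats longer than k − 1
cannot be separated. No single k fits a library whose read lengths span
that whole range — which is exactly the situation for anyone attempting
reference-free reconstruction of an ancient genome (to find rearrangements
or deletions that reference mapping cannot reveal).

## The method

1. **Preprocess** — adapter clipping (semi-global suffix–prefix match,
   fixpoint, mismatch fraction ≤ 0.1), 3' quality trimming (Q20, minimum
   25 bp), and overlap merging of mates (≥ 10 bp overlap, higher-quality
   base wins at disagreements). Three standard treatments are produced:
   merged, paired, combined single-end.
2. **Layer 1** — for each odd k in 37, 47, …, 127, build the canonical
   (bidirected) de Bruijn graph over the reads, clean it (multiplicity ≥ 2,
   tip clipping < 2k bp, simple bubble popping), and spell maximal
   unbranched paths as contigs.
3. **Read-incoherence filter** — map the reads back to each assembly
   (exact 15-mer seeds, ungapped extension, ≥ 95% identity over ≥ 90% of
   the read) and remove every contig supported by no read.
4. **Layer 2** — pool all per-k contigs under unique ids, remove exact and
   contained duplicates (either strand), merge unambiguous overlaps to a
   fixpoint, build the graph of all maximal exact suffix–prefix overlaps
   ≥ 45 bp, mark transitively implied edges, spell maximal unbranched paths
   over the irreducible edges, and drop contigs below 1,000 bp.
5. **Evaluate** — map contigs to a reference (seed–chain–extend, split
   alignments allowed): contig counts, N50, mean and longest contig over
   mapped contigs ≥ 1,000 bp; number of reference gaps; covered fraction;
   coverage as a function of the minimum contig length (1,000–10,000 bp);
   and the fraction of annotated repeat bases left unresolved (in gaps).

A seeded simulator generates aDNA-like libraries (fragment-length model,
adapter read-through, terminal C→T/G→A deamination with geometric decay,
two-level qualities) with complete ground truth, so the entire pipeline is
testable without real data.

## Worked example

Simulate a 20 kb genome with one exact 100 bp repeat family (3 copies) at
30× coverage, run three first-layer k values and the second layer, and
compare:

```r
library(aDNAssembly)

cfg <- simConfig(genomeLength = 20000,
                 repeatSpecs = data.frame(unitLength = 100, copies = 3,
                                          divergence = 0),
                 targetCoverage = 30, errorRate = 0, damageRate5p = 0,
                 seed = 7)
pc  <- pipelineConfig(sim = cfg, kList = c(37L, 57L, 77L),
                      outDir = tempfile(), seed = 7)
res <- runTwoLayer(pc, verbose = FALSE)
res$reports$layer2
#> AssemblyReport [layer2]
#>   contigs >= cutoff: 4 | N50 8,356 | mean 5033.8 | longest 8,564
#>   gaps: 0 | covered: 100.0% | unresolved repeats: 0.0%
print(res$comparison, digits = 4)
#>     assembly nContigs  n50 meanLength longest nGaps coverage repeatUnresolved
#> 1 layer1_k37        4 8315       4978    8504     3   0.9957           0.2867
#> 2 layer1_k57        4 8335       5008    8544     0   1.0000           0.0000
#> 3 layer1_k77        1 1883       1883    1883     2   0.0941           1.0000
#> 4     layer2        4 8356       5034    8564     0   1.0000           0.0000
```

Reading the table: at k = 37 the 100 bp repeats break the assembly — three
reference gaps, 28.7% of repeat bases unresolved. At k = 77 only the
longest merged reads carry k-mers, so the assembly is sparse (9.4%
coverage). The second layer pools all three: it covers the genome
completely with zero gaps, fully resolves the annotated repeats, and its
N50 and longest contig are at least as good as the best single k — the
characteristic two-layer improvement. Every stage is seeded; rerunning the
same configuration reproduces the outputs byte for byte.

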