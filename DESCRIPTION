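Package: aDNAssembly
Title: Two-Layer De Novo Assembly for Ancient DNA Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for de novo assembly of short-fragment (ancient DNA style)
    paired-end sequencing libraries. Provides a seeded simulator of aDNA-like
    libraries (short fragments, adapter read-through, terminal cytosine
    deamination), read preprocessing (adapter clipping, quality trimming,
    overlap merging of read pairs), a first assembly layer running an
    independent de Bruijn graph assembly for each of several k-mer sizes, a
    read-support filter that removes read-incoherent contigs, a second
    assembly layer that pools the per-k contigs and merges them through an
    exact suffix-prefix overlap (string) graph, and reference-based
    evaluation (N50 and contig statistics, gap analysis, coverage by minimum
    contig length, repeat resolution).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'aDNAssembly-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'evaluate.R'
    'io.R'
    'layer1.R'
    'layer2.R'
    'pipeline.R'
    'preprocess.R'
    'simdata.R'
    'support.R'
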