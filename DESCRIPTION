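Package: tulip
Title: Sparse-Seed Scaffolding of Uncorrected Long Reads
Version: 0.4.1
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assembles genome scaffolds from noisy long reads without read
    correction or all-versus-all overlap, by aligning reads to a sparse set of
    short, genome-unique seed sequences. Seeds become nodes of a bidirected
    graph whose links record apparent inter-seed distance and read-count
    evidence; local graph simplification (span resolution and repeat severing)
    yields linear scaffold models, which are laid out as uncorrected sequence
    together with per-scaffold long-read bundles for downstream consensus
    polishing. Includes seed selection from merged short-read pairs with
    canonical k-mer abundance filtering, a nanopore-like read simulator with
    per-chemistry error presets and ground-truth alignments, and assembly
    evaluation utilities (contiguity statistics, truth-based misjoin
    accounting, k-mer spectrum correlation, orthologue-count summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
biocViews: Assembly, Sequencing, LongRead, QualityControl
RoxygenNote: 7.3.3
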