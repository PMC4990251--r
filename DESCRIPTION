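Package: npminer
Title: Neuropeptide Precursor Mining in Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in silico pipeline for discovering neuropeptide and peptide
    hormone precursor transcripts in nucleotide transcriptome assemblies.
    Builds a curated query peptide set by keyword filtering of annotation
    records, runs a six-frame translated Smith-Waterman homology search with
    E-value based candidate selection, annotates candidate precursors (open
    reading frames, signal peptide, prohormone convertase cleavage sites),
    derives mature peptides with post-translational modification prediction
    (C-terminal amidation, N-terminal pyroglutamate, tyrosine sulfation,
    disulfide bridges, insulin B-C-A architecture), and classifies peptides
    into families by motif and architecture rules. Includes a synthetic
    transcriptome generator with machine-readable ground truth for
    benchmarking every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
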