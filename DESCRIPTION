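Package: kepmine
Title: Mining and Maturation Modelling of KEX2-Processed Repeat Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens predicted fungal proteomes for KEX2-processed repeat
    proteins (KEPs): secreted precursors carrying tandem repeats of short core
    peptides flanked by dibasic KEX2 cleavage sites. Precursors are cleaved in
    silico at dibasic motifs, cleavage products are compared pairwise with a
    two-tier Smith-Waterman identity screen, and candidates are filtered on
    signal-peptide presence, cleavage-site count and protein length. A
    maturation model composes KEX2 endoproteolysis with KEX1 carboxypeptidase
    trimming, STE13 dipeptidyl-aminopeptidase trimming, N-terminal
    pyroglutamate formation and optional C-terminal truncation to predict
    secreted peptides with monoisotopic masses, which can be matched against
    observed peptidomics masses at ppm tolerance. Includes a deterministic
    synthetic-proteome generator with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, SequenceMatching, Annotation
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cleavage.R'
    'io.R'
    'kepmine-package.R'
    'massmatch.R'
    'maturation.R'
    'mining.R'
    'simulate.R'
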