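Package: intuitMotif
Title: Intuitionistic Fuzzy Set Scoring of DNA Sequences Against
    Transcription Factor Binding Site Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores DNA sequences against transcription factor binding
    site (TFBS) motifs built from aligned binding-site sequences using an
    intuitionistic fuzzy set (IFS) representation of all pairwise position
    combinations, in which each base pair carries both a membership and a
    non-membership degree. Implements the IFS score together with three
    reference scores (the independent-position log-odds PWM score, a
    dependency-grouped extension based on pairwise contingency testing,
    and an all-pairs dinucleotide weight-matrix score), a sliding-window
    scanner over FASTA sequences with a SNP allele-comparison protocol,
    and a synthetic motif-insertion benchmark with precision-recall and
    ROC evaluation over a third-order Markov background.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'motif-model.R'
    'baseline-scores.R'
    'intuit-score.R'
    'scorer.R'
    'scanner.R'
    'benchmark.R'
    'io.R'
    'fixtures.R'
    'show-methods.R'
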