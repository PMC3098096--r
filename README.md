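# intuitMotif

Intuitionistic fuzzy set (IFS) scoring of DNA sequences against
transcription factor binding site (TFBS) motifs, with three reference
scores, a sliding-window scanner, a SNP allele-comparison protocol and a
synthetic motif-insertion benchmark.

## The science

A TFBS motif is a set of `t` aligned binding-site sequences of width `n`.
The classical position weight matrix (PWM) scores a candidate window by
summing per-position log-odds, which assumes the motif positions are
independent — an assumption real binding sites violate. `intuitMotif`
instead represents the motif as one **intuitionistic fuzzy set per
unordered pair of positions**, over the universe of the 16 possible base
pairs. Each base pair gets

* a **membership** degree `mu = P2 + (1 - P2) * (P1(b1,i) + P1(b2,j)) / 2`
  — the smoothed joint probability pulled up by the marginal conservation
  of the two bases, and
* a **non-membership** degree `nu = ((IC_i + IC_j)/2) * (1 - mu)` — the
  unclaimed mass converted into evidence *against* in proportion to the
  mean information content of the two columns.

By construction `mu + nu <= 1`; the remainder is *hesitancy*. This gives
the model the distinction a PWM cannot make: an unobserved base at a
conserved position is disproof, while the same base at a variable position
is merely uninformative. A window's score sums `mu * (max(nu) - nu)` over
all `n(n-1)/2` position pairs and min–max normalizes into `[0, 1]`.

Three reference scores are implemented on the same probability model: the
independence PWM score, a dependency-grouped score (chi-square/G-test
contingency testing with multiple-testing correction, greedy order-2
grouping), and an all-pairs dinucleotide weight-matrix score.

## Worked example

The bundled Dof3 motif (a synthetic reconstruction of JASPAR MA0021.1; 21
sites, width 6, invariant `AAAG` prefix — see
`?dof3Example` for exactly what is and is not faithful in the
reconstruction) with two probe windows: `AAAGGT` mismatches the site
family only at the poorly conserved 3' positions, `TAAGCG` mismatches at
the invariant first position.

```r
library(intuitMotif)

ex <- dof3Example()
scorer <- motifScorer(ex$motif)
round(rbind(AAAGGT = scoreAllMethods(scorer, "AAAGGT"),
            TAAGCG = scoreAllMethods(scorer, "TAAGCG")), 3)
#>        intuit indep   dep   mat
#> AAAGGT  0.788 0.818 0.818 0.664
#> TAAGCG  0.681 0.827 0.827 0.667
```

The PWM (`indep`) scores the two windows almost identically — each carries
one off-consensus base — and even scores the conserved-position mismatch
*higher*. The IFS score separates them by more than 0.1 in the right
direction. The MZF1 fixture reproduces the companion behaviour: a mutated
outlier site scores well below a mutated consensus site.

```r
mz <- mzf1Example()
sm <- motifScorer(mz$motif)
score(scoreWindow(sm, "GGAGGG", "intuit"))   # mutated outlier
#> [1] 0.5161485
score(scoreWindow(sm, "TGGGGT", "intuit"))   # mutated consensus site
#> [1] 0.7230087
```

Scanning a sequence reports 0-based half-open hits on both strands:

```r
seqs <- c(prom = paste0(strrep("T", 12), "AAAGGA", strrep("T", 12)))
scanSequences(seqs, scorer, method = "intuit", threshold = 0.8)
#>   seq_id start end strand motif method     score
#> 1   prom    12  18      +  Dof3 intuit 0.8662831
```

Other entry points: `trainMarkov` / `makeBenchmark` /
`evaluateBenchmark` (synthetic benchmark with PR/ROC curves),
`snpWindowScan` / `selectAlleleSensitive` (allele comparison around a
SNP), `readSites` / `readCountMatrix` (FASTA site sets, JASPAR PFM and
TRANSFAC matrices; count-only matrices support the independence score
only), and the `exec/intuitmotif` command-line tool (`score`, `scan`,
`bench generate|evaluate`, `snp`, `model dump`).

See the vignette (`vignettes/intuitionistic-motif-scoring.Rmd`) for the
model derivation, the synthetic-reconstruction rationale and the
benchmark protocol.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "intuitMotif", load_package = "installed")'
```

The suite contains unit and property tests for every module (including
naive re-implementations of all four scores used as oracles on exhaustive
window enumerations) plus an acceptance file,
`tests/testthat/test-acceptance.R`, whose blocks assert published target
values. Two acceptance blocks contain expectations that are currently red
by design rather than weakened:

* the worked-example block asserts literature values for `indep`/`mat`
  and a second `intuit` value that depend on the original site alignment
  and background composition, which are not fully recoverable from the
  published count matrices (the bundled sites are maximum-entropy
  reconstructions; measured values are 0.818 vs 0.839, 0.664 vs 0.672 and
  0.681 vs 0.687);
* the scaled-benchmark block asserts PR-AUC superiority of the IFS score
  over the dinucleotide score, which does not hold on cleanly simulated
  motifs where the dinucleotide score's *ranking* is near-perfect; the
  precision comparisons at the working thresholds 0.7/0.8 — the
  calibration claim — all pass.

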