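test_that("trainMarkov recovers transition probabilities from long sequences", {
  set.seed(666)
  ## order-1 chain with a strong A->C preference
  P <- matrix(c(0.1, 0.7, 0.1, 0.1,
                0.4, 0.2, 0.2, 0.2,
                0.25, 0.25, 0.25, 0.25,
                0.1, 0.1, 0.1, 0.7), 4L, 4L, byrow = TRUE)
  e <- integer(20000L); e[1L] <- 1L
  for (i in 2:20000) e[i] <- sample.int(4L, 1L, prob = P[e[i - 1L], ])
  s <- paste(BASES[e], collapse = "")
  bg <- trainMarkov(s, order = 1L)
  expect_equal(unname(bg@transition), P, tolerance = 0.05)
  expect_equal(rowSums(bg@transition), setNames(rep(1, 4L), BASES))
})

test_that("trainMarkov handles order 0 and rejects empty input", {
  bg <- trainMarkov("AAAC", order = 0L)
  expect_equal(unname(bg@transition[1L, ]),
               (c(3, 1, 0, 0) + 1) / 8)      # pseudocount 1
  expect_error(trainMarkov(character(0)), "no training sequences")
  expect_error(trainMarkov("ACGT", order = -1L), "order must be >= 0")
})

test_that("uniformMarkov samples sequences with roughly uniform composition", {
  set.seed(777)
  bg <- uniformMarkov(order = 3L)
  s <- sampleBackground(bg, 8000L)
  expect_equal(nchar(s), 8000L)
  comp <- table(factor(strsplit(s, "")[[1L]], levels = BASES)) / 8000
  expect_true(all(abs(comp - 0.25) < 0.03))
  expect_error(sampleBackground(bg, 2L), "length must be >=")
})

test_that("sampled sequences reflect the trained background", {
  set.seed(888)
  ## heavily AT-rich training text
  train <- paste(sample(c("A", "T", "A", "T", "G"), 5000L, replace = TRUE),
                 collapse = "")
  bg <- trainMarkov(train, order = 2L)
  s <- sampleBackground(bg, 4000L)
  comp <- table(factor(strsplit(s, "")[[1L]], levels = BASES)) / 4000
  expect_gt(comp[["A"]] + comp[["T"]], 0.6)
})

test_that("makeBenchmark inserts the recorded sites at the recorded positions", {
  set.seed(999)
  motifs <- lapply(1:3, function(k) randomMotif(t = 8L, n = 6L,
                                                name = paste0("m", k)))
  ds <- makeBenchmark(motifs, uniformMarkov(3L), seed = 42L)
  expect_length(ds@sequences, 3L)
  L <- nchar(ds@sequences)
  expect_true(all(L >= 200L & L <= 500L))
  expect_true(all(table(ds@truth$seq_id) >= 2L &
                  table(ds@truth$seq_id) <= 6L))
  ## ground truth matches the sequence content exactly
  for (r in seq_len(nrow(ds@truth))) {
    tr <- ds@truth[r, ]
    expect_identical(substr(ds@sequences[[tr$seq_id]], tr$start + 1L, tr$end),
                     tr$site)
  }
  ## and unmutated inserted sites come from the motif's site list
  for (r in seq_len(nrow(ds@truth))) {
    m <- motifs[[match(ds@truth$motif[r], vapply(motifs, motifName,
                                                 character(1L)))]]
    expect_true(ds@truth$site[r] %in% sites(m))
  }
})

test_that("mutated benchmarks change each inserted site by exactly one base", {
  set.seed(123)
  m <- randomMotif(t = 6L, n = 8L, name = "mut")
  ds <- makeBenchmark(list(m), uniformMarkov(3L), mutate = TRUE, seed = 7L)
  for (r in seq_len(nrow(ds@truth))) {
    ins <- ds@truth$site[r]
    dists <- vapply(sites(m), function(s)
      sum(strsplit(s, "")[[1L]] != strsplit(ins, "")[[1L]]), integer(1L))
    expect_equal(min(dists), 1L)
  }
  expect_true(all(ds@truth$mutated))
})

test_that("insertions never overlap within a sequence", {
  set.seed(321)
  m <- randomMotif(t = 5L, n = 7L, name = "ov")
  for (seed in 1:5) {
    ds <- makeBenchmark(list(m), uniformMarkov(3L), seed = seed)
    st <- sort(ds@truth$start)
    if (length(st) > 1L) expect_true(all(diff(st) >= 7L))
  }
})

test_that("evaluateBenchmark reproduces hand-computed confusion counts", {
  ## two sequences, synthetic tracks, known truth
  ds <- new("BenchmarkDataset",
            sequences = c(a = strrep("A", 10L), b = strrep("A", 10L)),
            truth = data.frame(seq_id = c("a", "a", "b"),
                               motif = "m", start = c(0L, 5L, 2L),
                               end = c(3L, 8L, 5L), site = "AAA",
                               mutated = FALSE),
            params = list())
  tracks <- list(a = c(0.9, 0.1, 0.2, 0.1, 0.1, 0.8, 0.1, 0.75),
                 b = c(0.1, 0.1, 0.3, 0.85, 0.1, 0.1, 0.1, 0.1))
  ev <- evaluateBenchmark(ds, tracks, thresholds = c(0.5, 0.95))
  r1 <- ev@curve[1L, ]   # threshold 0.5
  ## calls >= 0.5: a0 (TP), a5 (TP), a7 (FP), b3 (FP); truth b2 missed (FN)
  expect_equal(r1$TP, 2L); expect_equal(r1$FP, 2L)
  expect_equal(r1$FN, 1L); expect_equal(r1$TN, 11L)
  expect_equal(r1$precision, 0.5)
  expect_equal(r1$recall, 2 / 3)
  expect_equal(r1$FPR, 2 / 13)
  ## threshold 0.95: no calls at all -> precision NA, not 0
  r2 <- ev@curve[2L, ]
  expect_equal(r2$TP, 0L)
  expect_true(is.na(r2$precision))
  expect_equal(precisionAt(ev, 0.5), 0.5)
})

test_that("ROC AUC from the threshold sweep agrees with pROC", {
  set.seed(2024)
  lab <- c(rep(TRUE, 30L), rep(FALSE, 300L))
  sc <- ifelse(lab, rnorm(330, 0.7, 0.12), rnorm(330, 0.35, 0.12))
  sc <- pmin(pmax(sc, 0), 1)
  ds <- new("BenchmarkDataset",
            sequences = c(a = strrep("A", 3L)),
            truth = data.frame(seq_id = "a", motif = "m",
                               start = which(lab) - 1L,
                               end = which(lab) + 1L, site = "AA",
                               mutated = FALSE),
            params = list())
  ## a single fake track whose starts are 0 .. 329
  ev <- evaluateBenchmark(ds, list(a = sc),
                          thresholds = seq(0, 1, by = 0.001))
  ref <- pROC::auc(pROC::roc(response = lab, predictor = sc,
                             direction = "<", quiet = TRUE))
  expect_equal(ev@rocAUC, as.numeric(ref), tolerance = 0.005)
})

test_that("a discriminating scorer yields higher AUC than a random one", {
  set.seed(1357)
  m <- randomMotif(t = 8L, n = 6L, name = "auc")
  ds <- makeBenchmark(list(m), uniformMarkov(3L), seed = 11L)
  scr <- motifScorer(m)
  tracks <- scoreTracks(ds, list(auc = scr), method = "intuit")
  ev <- evaluateBenchmark(ds, tracks)
  rnd <- lapply(tracks, function(tr) runif(length(tr)))
  evR <- evaluateBenchmark(ds, rnd)
  expect_gt(ev@rocAUC, 0.9)
  expect_lt(abs(evR@rocAUC - 0.5), 0.25)
})

test_that("writeBenchmark exports FASTA plus truth table losslessly", {
  set.seed(24)
  m <- randomMotif(t = 4L, n = 5L, name = "io")
  ds <- makeBenchmark(list(m), uniformMarkov(2L), seed = 3L)
  fa <- tempfile(fileext = ".fa"); tr <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, tr)))
  writeBenchmark(ds, fa, tr)
  back <- readFasta(fa)
  expect_identical(unname(back), unname(ds@sequences))
  truth <- read.table(tr, header = TRUE, sep = "\t")
  expect_equal(truth$start, ds@truth$start)
  expect_equal(truth$site, ds@truth$site)
})
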