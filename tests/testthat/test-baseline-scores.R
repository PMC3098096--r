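scorerFixture <- function(sites, name = "fix", a = 0.001,
                          bg = rep(0.25, 4)) {
  motifScorer(siteMotif(sites, name), a = a, bg = bg)
}

test_that("PWM weights are log2 odds against the background", {
  m <- siteMotif(c("AA", "AC", "AG", "AT"), "toy")
  pm <- probabilityModel(motifCounts(m), a = 0.001)
  pwm <- buildPWM(pm)
  expect_equal(pwm@W["A", 1L], log2(1 / 0.25))        # = 2
  expect_equal(pwm@W["C", 1L], log2(0.001 / 0.25))
  expect_equal(pwm@wMin, apply(pwm@W, 2L, min))
  expect_equal(pwm@wMax, apply(pwm@W, 2L, max))
})

test_that("scIndep gives 1 to the consensus, 0 to the anti-consensus", {
  m <- siteMotif(c("ACGT", "ACGT", "ACGT"), "cons")
  pwm <- buildPWM(probabilityModel(motifCounts(m)))
  expect_equal(score(scIndep("ACGT", pwm)), 1)
  expect_equal(score(scIndep("TTTA", pwm)), 0)   # worst base everywhere
  mid <- score(scIndep("ACGA", pwm))
  expect_gt(mid, 0); expect_lt(mid, 1)
})

test_that("scIndep rejects bad windows with clear errors", {
  m <- siteMotif(c("ACGT", "ACGT", "ACGT"))
  pwm <- buildPWM(probabilityModel(motifCounts(m)))
  expect_error(scIndep("ACG", pwm), "length 3 does not match motif width 4")
  expect_error(scIndep("ACGN", pwm), "non-ACGT")
  ## lowercase windows are accepted
  expect_equal(score(scIndep("acgt", pwm)), 1)
})

test_that("scIndep matches the naive reference on all windows of random motifs", {
  set.seed(202)
  for (rep in 1:5) {
    n <- sample(2:4, 1L)
    m <- randomMotif(t = sample(4:10, 1L), n = n)
    pwm <- buildPWM(probabilityModel(motifCounts(m)))
    rm <- refModel(sites(m))
    for (S in allWindows(n))
      expect_equal(score(scIndep(S, pwm)), refIndep(S, rm), tolerance = 1e-12)
  }
})

test_that("chi-square pair test matches stats::chisq.test on full tables", {
  set.seed(303)
  m <- randomMotif(t = 40L, n = 3L)
  cnt <- motifCounts(m)
  for (p in seq_len(ncol(cnt@pairs))) {
    i <- cnt@pairs[1L, p]; j <- cnt@pairs[2L, p]
    obs <- matrix(cnt@F2[, p], 4L, 4L, byrow = TRUE)
    res <- testPairDependency(cnt, i, j, method = "chi2")
    keepR <- rowSums(obs) > 0; keepC <- colSums(obs) > 0
    ref <- suppressWarnings(
      stats::chisq.test(obs[keepR, keepC, drop = FALSE], correct = FALSE))
    expect_equal(res$stat, unname(ref$statistic), tolerance = 1e-10)
    ## df stays fixed at 9 by design, so p comes from pchisq(stat, 9)
    expect_equal(res$p, pchisq(res$stat, 9L, lower.tail = FALSE))
    expect_identical(res$df, 9L)
  }
})

test_that("G-test statistic matches the hand-rolled likelihood ratio", {
  m <- siteMotif(rep(c("AT", "TA", "AA"), 7L), "g")
  cnt <- motifCounts(m)
  obs <- matrix(cnt@F2[, "1-2"], 4L, 4L, byrow = TRUE)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  nz <- obs > 0
  expect_equal(testPairDependency(cnt, 1L, 2L, method = "gtest")$stat,
               2 * sum(obs[nz] * log(obs[nz] / exp[nz])))
})

test_that("dependencyStructure finds linked pairs and partitions greedily", {
  ## positions 1-2 perfectly linked, position 3 independent noise
  set.seed(404)
  third <- sample(BASES, 40L, replace = TRUE)
  sites <- paste0(rep(c("AT", "TA"), 20L), third)
  deps <- dependencyStructure(motifCounts(siteMotif(sites, "dep3")))
  expect_equal(ncol(deps@depPairs), 1L)
  expect_equal(unname(deps@depPairs[, 1L]), c(1L, 2L))
  expect_equal(deps@independent, 3L)
  ## each position appears exactly once across the partition (validity)
  expect_true(validObject(deps))
})

test_that("dependencyStructure on independent data keeps all positions independent", {
  ## all 16 combinations equally often: exactly independent
  sites <- as.vector(outer(BASES, BASES, paste0))
  deps <- dependencyStructure(motifCounts(siteMotif(sites, "unif")))
  expect_equal(ncol(deps@depPairs), 0L)
  expect_equal(deps@independent, 1:2)
  expect_error(dependencyStructure(motifCounts(siteMotif(sites)), alpha = 1),
               "alpha must lie in \\(0, 1\\)")
})

test_that("scDep reduces exactly to scIndep when no pairs are dependent", {
  set.seed(505)
  for (rep in 1:5) {
    n <- sample(2:5, 1L)
    m <- randomMotif(t = 6L, n = n)
    cnt <- motifCounts(m)
    pm <- probabilityModel(cnt)
    pwm <- buildPWM(pm)
    deps <- dependencyStructure(cnt, alpha = 1e-12)  # nothing significant
    if (ncol(deps@depPairs) > 0L) next
    for (S in sample(allWindows(n), 8L))
      expect_equal(score(scDep(S, pwm, deps, pm)), score(scIndep(S, pwm)),
                   tolerance = 1e-12)
  }
})

test_that("scDep matches the naive reference given the same partition", {
  set.seed(606)
  sites <- paste0(rep(c("AT", "TA"), 15L),
                  sample(BASES, 30L, replace = TRUE))
  m <- siteMotif(sites, "dep3")
  cnt <- motifCounts(m)
  pm <- probabilityModel(cnt)
  pwm <- buildPWM(pm)
  deps <- dependencyStructure(cnt)
  rm <- refModel(sites(m))
  for (S in allWindows(3L))
    expect_equal(score(scDep(S, pwm, deps, pm)),
                 refDep(S, rm, deps@independent, deps@depPairs),
                 tolerance = 1e-12)
})

test_that("pair weights are the log-odds of the joint probabilities", {
  m <- siteMotif(c("AT", "TA", "AT", "TA"), "w")
  pm <- probabilityModel(motifCounts(m), a = 0.001)
  w <- pairWeights(pm, 1L, 2L)
  expect_named(w, as.vector(t(outer(BASES, BASES, paste0))))
  expect_equal(unname(w["AT"]), log2(pm@P2["AT", "1-2"] / (1 / 16)))
  expect_error(pairWeights(pm, 2L, 1L), "no pair")
})

test_that("scMat matches the naive reference on all windows of random motifs", {
  set.seed(707)
  for (rep in 1:4) {
    n <- sample(2:4, 1L)
    m <- randomMotif(t = sample(4:10, 1L), n = n)
    ppwm <- buildPairPWM(probabilityModel(motifCounts(m)))
    rm <- refModel(sites(m))
    for (S in allWindows(n))
      expect_equal(score(scMat(S, ppwm)), refMat(S, rm), tolerance = 1e-12)
  }
})

test_that("scMat rewards observed dinucleotide pairings over unobserved ones", {
  m <- siteMotif(rep(c("AT", "TA"), 10L), "linked")
  ppwm <- buildPairPWM(probabilityModel(motifCounts(m)))
  expect_gt(score(scMat("AT", ppwm)), score(scMat("AA", ppwm)))
})

test_that("writeDependencyStructure round-trips the test table", {
  m <- siteMotif(rep(c("ATG", "TAC"), 10L), "rt")
  deps <- dependencyStructure(motifCounts(m))
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeDependencyStructure(deps, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$i, deps@tests$i)
  expect_equal(back$p.adj, deps@tests$p.adj, tolerance = 1e-12)
  expect_equal(back$dependent, deps@tests$dependent)
})
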