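#' Build a scoring engine for a motif
#'
#' Derives, from the aligned sites of a motif, everything needed to evaluate
#' the four sequence--motif scores: the smoothed probability model, the
#' log-odds PWM, the all-pairs dinucleotide weight matrix, the positional
#' dependency partition and the intuitionistic fuzzy set model.
#'
#' @param motif a \linkS4class{SiteMotif}, or a count-only motif input from
#'   \code{\link{readCountMatrix}} (in which case only the
#'   independence score is available).
#' @param a smoothing parameter (default 0.001; smaller values than the
#'   often-quoted 0.01 sharpen discrimination).
#' @param bg background base probabilities, default uniform.
#' @param alpha significance level for dependency testing.
#' @param depMethod contingency test, "chi2" or "gtest".
#' @param correction multiple-testing correction, "bonferroni" or "bh".
#' @return a \linkS4class{MotifScorer}.
#' @examples
#' sc <- motifScorer(siteMotif(c("AA", "AA", "CC", "CC"), "toy"))
#' score(scoreWindow(sc, "AA", "intuit"))
#' @export
motifScorer <- function(motif, a = 0.001, bg = rep(0.25, 4), alpha = 0.05,
                        depMethod = c("chi2", "gtest"),
                        correction = c("bonferroni", "bh")) {
  depMethod <- match.arg(depMethod)
  correction <- match.arg(correction)
  if (is(motif, "MotifInput")) return(countOnlyScorer(motif, a, bg))
  stopifnot(is(motif, "SiteMotif"))
  cnt <- motifCounts(motif)
  pm <- probabilityModel(cnt, a = a, bg = bg)
  deps <- dependencyStructure(cnt, alpha = alpha, method = depMethod,
                              correction = correction)
  new("MotifScorer", motif = motif, hasSites = TRUE, pm = pm,
      pwm = buildPWM(pm), ppwm = buildPairPWM(pm), deps = deps,
      depWeights = buildDepWeights(pm, deps),
      ifs = ifsModel(pm, name = motifName(motif)))
}

SCORE_METHODS <- c("intuit", "indep", "dep", "mat")

#' Score one window with one method
#'
#' @param scorer a \linkS4class{MotifScorer}.
#' @param S DNA window of the motif width.
#' @param method one of "intuit", "indep", "dep", "mat".
#' @return a \linkS4class{ScoreResult}.
#' @export
scoreWindow <- function(scorer, S, method = SCORE_METHODS) {
  stopifnot(is(scorer, "MotifScorer"))
  method <- match.arg(method, SCORE_METHODS)
  if (!scorer@hasSites && method != "indep")
    stop("motif '", motifName(scorer@motif), "' was loaded from a count ",
         "matrix only: no joint (dinucleotide) information is available, ",
         "so only method = \"indep\" can be computed; supply aligned ",
         "binding-site sequences for \"", method, "\"")
  nm <- motifName(scorer@motif)
  switch(method,
    indep  = scIndep(S, scorer@pwm, motif = nm),
    dep    = scDep(S, scorer@pwm, scorer@deps, scorer@pm, motif = nm),
    mat    = scMat(S, scorer@ppwm, motif = nm),
    intuit = scIntuit(S, scorer@ifs))
}

#' Score all four methods on one window
#'
#' @param scorer a \linkS4class{MotifScorer}.
#' @param S DNA window.
#' @return named numeric of normalized scores.
#' @export
scoreAllMethods <- function(scorer, S) {
  vapply(SCORE_METHODS, function(m) score(scoreWindow(scorer, S, m)),
         numeric(1L))
}

## Vectorized normalized scores of every width-n window of an encoded
## sequence. Windows containing a non-ACGT character come back NA.
## Used by the scanner and the benchmark; identical numbers to
## scoreWindow(), just computed with table lookups across all windows.
scoreTrack <- function(scorer, seqEnc, method = SCORE_METHODS) {
  method <- match.arg(method, SCORE_METHODS)
  if (!scorer@hasSites && method != "indep")
    stop("count-only motif input supports only method = \"indep\"")
  n <- ncol(scorer@pwm@W)
  L <- length(seqEnc)
  if (L < n) return(numeric(0))
  nw <- L - n + 1L
  offs <- function(i) seqEnc[i:(i + nw - 1L)]
  raw <- numeric(nw)
  if (method == "indep") {
    for (i in seq_len(n)) raw <- raw + scorer@pwm@W[cbind(offs(i), i)]
    return(clamp((raw - sum(scorer@pwm@wMin)) /
                 (sum(scorer@pwm@wMax) - sum(scorer@pwm@wMin))))
  }
  if (method == "mat" || method == "intuit") {
    M <- if (method == "mat") scorer@ppwm@W else scorer@ifs@score
    pairs <- if (method == "mat") scorer@ppwm@pairs else scorer@ifs@pairs
    lo <- if (method == "mat") sum(scorer@ppwm@wMin) else sum(scorer@ifs@scMin)
    hi <- if (method == "mat") sum(scorer@ppwm@wMax) else sum(scorer@ifs@scMax)
    for (p in seq_len(ncol(pairs))) {
      rows <- pairRow(offs(pairs[1L, p]), offs(pairs[2L, p]))
      raw <- raw + M[cbind(rows, p)]
    }
    return(clamp((raw - lo) / (hi - lo)))
  }
  ## dep
  lo <- 0; hi <- 0
  for (i in scorer@deps@independent) {
    raw <- raw + scorer@pwm@W[cbind(offs(i), i)]
    lo <- lo + scorer@pwm@wMin[i]; hi <- hi + scorer@pwm@wMax[i]
  }
  dp <- scorer@deps@depPairs
  for (k in seq_len(ncol(dp))) {
    wk <- scorer@depWeights[[k]]
    raw <- raw + wk[pairRow(offs(dp[1L, k]), offs(dp[2L, k]))]
    lo <- lo + min(wk); hi <- hi + max(wk)
  }
  clamp((raw - lo) / (hi - lo))
}
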