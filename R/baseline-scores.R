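## ---- independence PWM score -------------------------------------------

#' Build the log-odds position weight matrix
#'
#' \code{W(b,i) = log2(P(b,i) / P(b))} with the smoothed single-position
#' probabilities, plus cached per-position minima and maxima used by the
#' min--max normalization.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @return a \linkS4class{MotifPWM}.
#' @export
buildPWM <- function(pm) {
  stopifnot(is(pm, "MotifProbModel"))
  W <- log2(pm@P1 / pm@bg)
  new("MotifPWM", W = W,
      wMin = apply(W, 2L, min), wMax = apply(W, 2L, max), bg = pm@bg)
}

windowCheck <- function(S, n) {
  S <- toupper(S)
  if (nchar(S) != n)
    stop("window length ", nchar(S), " does not match motif width ", n)
  e <- encodeDNA(S)
  if (anyNA(e)) stop("window '", S, "' contains a non-ACGT character")
  list(S = S, e = e)
}

#' Independence-assuming PWM score
#'
#' Sums the per-position log-odds weights of the window and normalizes by
#' the summed per-position minima and maxima.
#'
#' @param S DNA window of the motif width.
#' @param pwm a \linkS4class{MotifPWM}.
#' @param motif optional motif name for the result.
#' @return a \linkS4class{ScoreResult}.
#' @export
scIndep <- function(S, pwm, motif = "") {
  stopifnot(is(pwm, "MotifPWM"))
  n <- ncol(pwm@W)
  w <- windowCheck(S, n)
  terms <- pwm@W[cbind(w$e, seq_len(n))]
  names(terms) <- seq_len(n)
  raw <- sum(terms)
  new("ScoreResult", method = "indep", raw = raw,
      normalized = normalizeScore(raw, sum(pwm@wMin), sum(pwm@wMax)),
      terms = terms, sequence = w$S, motif = motif)
}

## ---- positional dependency testing ------------------------------------

## Pearson chi-square / likelihood-ratio G statistic on the 4 x 4 observed
## table of a position pair, expectations from the marginals. Zero-marginal
## rows and columns contribute nothing; df is fixed at 9 (the 4 x 4 design),
## as the score contract specifies, rather than reduced for empty levels.
pairStatistic <- function(obs, method = c("chi2", "gtest")) {
  method <- match.arg(method)
  t <- sum(obs)
  exp <- outer(rowSums(obs), colSums(obs)) / t
  keep <- exp > 0
  if (method == "chi2") {
    stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  } else {
    nz <- keep & obs > 0
    stat <- 2 * sum(obs[nz] * log(obs[nz] / exp[nz]))
  }
  stat
}

#' Test dependency between two motif positions
#'
#' Pearson chi-square or likelihood-ratio G test on the 4 x 4 contingency
#' table of observed base pairs at positions \code{i < j}, with expectations
#' from the marginals and df = 9.
#'
#' @param counts a \linkS4class{MotifCounts}.
#' @param i,j positions, \code{i < j}.
#' @param method "chi2" (default) or "gtest".
#' @return list with \code{stat}, \code{p} and \code{df}.
#' @export
testPairDependency <- function(counts, i, j, method = c("chi2", "gtest")) {
  stopifnot(is(counts, "MotifCounts"))
  method <- match.arg(method)
  if (!(i >= 1L && j <= counts@n && i < j)) stop("need 1 <= i < j <= n")
  key <- paste(i, j, sep = "-")
  obs <- matrix(counts@F2[, key], 4L, 4L, byrow = TRUE,
                dimnames = list(DNA_BASES, DNA_BASES))  # rows b1, cols b2
  stat <- pairStatistic(obs, method)
  list(stat = stat, p = pchisq(stat, df = 9L, lower.tail = FALSE), df = 9L)
}

#' Build the positional dependency structure
#'
#' Tests all n(n-1)/2 position pairs, corrects the p-values, and partitions
#' the positions greedily: significant pairs are visited in order of
#' ascending corrected p and kept whenever both positions are still free, so
#' each position joins at most one order-2 group; the rest stay independent.
#'
#' @param counts a \linkS4class{MotifCounts}.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param method "chi2" or "gtest".
#' @param correction "bonferroni" (default) or "bh".
#' @return a \linkS4class{DependencyStructure}.
#' @export
dependencyStructure <- function(counts, alpha = 0.05,
                                method = c("chi2", "gtest"),
                                correction = c("bonferroni", "bh")) {
  stopifnot(is(counts, "MotifCounts"))
  method <- match.arg(method)
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  pairs <- counts@pairs
  np <- ncol(pairs)
  res <- lapply(seq_len(np), function(p)
    testPairDependency(counts, pairs[1L, p], pairs[2L, p], method))
  tests <- data.frame(
    i = pairs[1L, ], j = pairs[2L, ],
    stat = vapply(res, `[[`, numeric(1L), "stat"),
    p = vapply(res, `[[`, numeric(1L), "p"))
  tests$p.adj <- p.adjust(tests$p, method = if (correction == "bh") "BH" else "bonferroni")
  sig <- which(tests$p.adj < alpha)
  sig <- sig[order(tests$p.adj[sig], tests$p[sig])]
  taken <- logical(counts@n)
  keep <- integer(0)
  for (p in sig) {
    ij <- c(tests$i[p], tests$j[p])
    if (!any(taken[ij])) { taken[ij] <- TRUE; keep <- c(keep, p) }
  }
  tests$dependent <- seq_len(np) %in% keep
  dep <- rbind(tests$i[keep], tests$j[keep])
  if (length(keep) == 0L) dep <- matrix(integer(0), 2L, 0L)
  new("DependencyStructure", tests = tests, alpha = alpha, method = method,
      correction = correction, independent = which(!taken), depPairs = dep)
}

#' Log-odds weights of a dependent position pair
#'
#' \code{W(b1,b2,i,j) = log2(P(b1,b2,i,j) / (P(b1) P(b2)))}, the order-2
#' generalization of the PWM weight.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param i,j the position pair, \code{i < j}.
#' @return named numeric of 16 weights (AA, AC, ..., TT).
#' @export
pairWeights <- function(pm, i, j) {
  stopifnot(is(pm, "MotifProbModel"))
  key <- paste(i, j, sep = "-")
  if (!key %in% colnames(pm@P2)) stop("no pair (", i, ", ", j, ") in model")
  bgpair <- as.vector(outer(pm@bg, pm@bg))
  setNames(log2(pm@P2[, key] / bgpair), DNA_PAIRS)
}

buildDepWeights <- function(pm, deps) {
  wl <- lapply(seq_len(ncol(deps@depPairs)), function(k)
    pairWeights(pm, deps@depPairs[1L, k], deps@depPairs[2L, k]))
  names(wl) <- if (length(wl)) paste(deps@depPairs[1L, ], deps@depPairs[2L, ], sep = "-")
  wl
}

#' Dependency-grouped PWM score
#'
#' Sums single-position log-odds weights over the independent positions and
#' 16-entry pair weights over the dependent position pairs of the partition;
#' normalized by the summed per-term minima and maxima. With an
#' all-independent partition this reduces exactly to \code{\link{scIndep}}.
#'
#' @param S DNA window of the motif width.
#' @param pwm a \linkS4class{MotifPWM}.
#' @param deps a \linkS4class{DependencyStructure}.
#' @param pm the \linkS4class{MotifProbModel} (for the pair weights).
#' @param motif optional motif name.
#' @return a \linkS4class{ScoreResult}.
#' @export
scDep <- function(S, pwm, deps, pm, motif = "") {
  stopifnot(is(pwm, "MotifPWM"), is(deps, "DependencyStructure"),
            is(pm, "MotifProbModel"))
  n <- ncol(pwm@W)
  w <- windowCheck(S, n)
  terms <- numeric(0)
  lo <- 0; hi <- 0
  for (i in deps@independent) {
    terms[as.character(i)] <- pwm@W[w$e[i], i]
    lo <- lo + unname(pwm@wMin[i]); hi <- hi + unname(pwm@wMax[i])
  }
  if (ncol(deps@depPairs)) {
    wl <- buildDepWeights(pm, deps)
    for (k in seq_along(wl)) {
      i <- deps@depPairs[1L, k]; j <- deps@depPairs[2L, k]
      wk <- wl[[k]]
      terms[names(wl)[k]] <- wk[pairRow(w$e[i], w$e[j])]
      lo <- lo + min(wk); hi <- hi + max(wk)
    }
  }
  raw <- sum(terms)
  new("ScoreResult", method = "dep", raw = raw,
      normalized = normalizeScore(raw, lo, hi),
      terms = terms, sequence = w$S, motif = motif)
}

## ---- all-pairs dinucleotide matrix score ------------------------------

#' Build the all-pairs dinucleotide weight matrix
#'
#' For every unordered position pair, 16 weights
#' \code{log2(P(b1,b2,i,j)/(P(b1)P(b2))) +
#' log2(P(b1,b2,i,j)/(P(b1,i)P(b2,j)))}: a background log-odds term plus a
#' mutual-information-like term against the single-position model. Base-2
#' logarithms throughout (min--max normalization makes the base immaterial).
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @return a \linkS4class{PairPWM}.
#' @export
buildPairPWM <- function(pm) {
  stopifnot(is(pm, "MotifProbModel"))
  np <- ncol(pm@pairs)
  bgpair <- as.vector(outer(pm@bg, pm@bg))
  W <- matrix(0, 16L, np, dimnames = dimnames(pm@P2))
  for (p in seq_len(np)) {
    i <- pm@pairs[1L, p]; j <- pm@pairs[2L, p]
    marg <- as.vector(outer(pm@P1[, j], pm@P1[, i]))  # b2 fastest
    W[, p] <- log2(pm@P2[, p] / bgpair) + log2(pm@P2[, p] / marg)
  }
  new("PairPWM", W = W, pairs = pm@pairs,
      wMin = apply(W, 2L, min), wMax = apply(W, 2L, max))
}

#' All-pairs dinucleotide matrix score
#'
#' Sums the pair weights of the window over all n(n-1)/2 position pairs and
#' normalizes by the summed per-pair minima and maxima (an outer bound, as
#' pair terms share bases; the normalized value always lies in [0, 1]).
#'
#' @param S DNA window of the motif width.
#' @param ppwm a \linkS4class{PairPWM}.
#' @param motif optional motif name.
#' @return a \linkS4class{ScoreResult}.
#' @export
scMat <- function(S, ppwm, motif = "") {
  stopifnot(is(ppwm, "PairPWM"))
  n <- max(ppwm@pairs)
  w <- windowCheck(S, n)
  np <- ncol(ppwm@pairs)
  rows <- pairRow(w$e[ppwm@pairs[1L, ]], w$e[ppwm@pairs[2L, ]])
  terms <- ppwm@W[cbind(rows, seq_len(np))]
  names(terms) <- colnames(ppwm@pairs)
  raw <- sum(terms)
  new("ScoreResult", method = "mat", raw = raw,
      normalized = normalizeScore(raw, sum(ppwm@wMin), sum(ppwm@wMax)),
      terms = terms, sequence = w$S, motif = motif)
}

#' Serialize a dependency structure
#'
#' Writes the per-pair test results as tab-delimited text
#' (i, j, stat, p, p.adj, dependent).
#'
#' @param deps a \linkS4class{DependencyStructure}.
#' @param path output file.
#' @export
writeDependencyStructure <- function(deps, path) {
  stopifnot(is(deps, "DependencyStructure"))
  write.table(deps@tests, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
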