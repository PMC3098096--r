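#' Build single-position and pairwise count tables
#'
#' Tallies \code{F(b, i)}, the occurrences of base \code{b} at position
#' \code{i} over the aligned sites, and the joint counts
#' \code{F(b1, b2, i, j)} for every unordered position pair \code{i < j}.
#'
#' @param motif a \linkS4class{SiteMotif}.
#' @return a \linkS4class{MotifCounts}.
#' @examples
#' cnt <- motifCounts(siteMotif(c("AC", "AG", "TC", "TG")))
#' cnt@F1           # column sums all equal t = 4
#' @export
motifCounts <- function(motif) {
  stopifnot(is(motif, "SiteMotif"))
  validObject(motif)
  s <- sites(motif)
  n <- motifWidth(motif)
  t <- siteCount(motif)
  enc <- vapply(s, encodeDNA, integer(n))      # n x t
  F1 <- matrix(0L, 4L, n, dimnames = list(DNA_BASES, seq_len(n)))
  for (i in seq_len(n)) {
    tab <- tabulate(enc[i, ], nbins = 4L)
    F1[, i] <- tab
  }
  pairs <- positionPairs(n)
  np <- ncol(pairs)
  F2 <- matrix(0L, 16L, np, dimnames = list(DNA_PAIRS, colnames(pairs)))
  for (p in seq_len(np)) {
    rows <- pairRow(enc[pairs[1L, p], ], enc[pairs[2L, p], ])
    F2[, p] <- tabulate(rows, nbins = 16L)
  }
  new("MotifCounts", F1 = F1, F2 = F2, pairs = pairs, t = t, n = n)
}

#' Build the smoothed probability model
#'
#' Corrected probabilities with additive smoothing:
#' \code{P(b,i) = F(b,i)/t + a} and
#' \code{P(b1,b2,i,j) = F(b1,b2,i,j)/t + a^2}, both clamped at 1 (a fully
#' conserved column would otherwise exceed 1 by at most \code{a}).
#'
#' @param counts a \linkS4class{MotifCounts}.
#' @param a smoothing parameter per base; default 0.001.
#' @param bg background base probabilities (default uniform); must be
#'   strictly positive and sum to 1.
#' @return a \linkS4class{MotifProbModel}.
#' @export
probabilityModel <- function(counts, a = 0.001, bg = rep(0.25, 4)) {
  stopifnot(is(counts, "MotifCounts"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("smoothing parameter a must be a single value > 0")
  bg <- checkProbVector(bg)
  P1 <- clamp(counts@F1 / counts@t + a, hi = 1)
  P2 <- clamp(counts@F2 / counts@t + a * a, hi = 1)
  new("MotifProbModel", P1 = P1, P2 = P2, pairs = counts@pairs,
      a = a, bg = bg, t = counts@t, n = counts@n)
}

#' Per-base normalized information content
#'
#' \code{(2 + P(b,p) * log2(P(b,p))) / 2}, clamped into \code{[0, 1]}. Equals
#' 1 for a certain base (P = 1) and approaches 1 again as P tends to 0; its
#' minimum over P is at P = 1/e.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param b base, one of "A", "C", "G", "T".
#' @param p position, 1-based.
#' @return scalar in \code{[0, 1]}.
#' @export
informationContent <- function(pm, b, p) {
  stopifnot(is(pm, "MotifProbModel"))
  if (!b %in% DNA_BASES) stop("base must be one of A, C, G, T")
  if (p < 1L || p > pm@n) stop("position ", p, " out of range 1..", pm@n)
  P <- pm@P1[b, p]
  clamp((2 + P * log2(P)) / 2)
}

#' Per-position (column) normalized information content
#'
#' The Shannon information content of a motif column scaled into
#' \code{[0, 1]}: \code{(2 + sum_b P(b,p) * log2 P(b,p)) / 2}. This is the
#' conservation measure used to set the tolerated non-membership of a
#' position in the IFS model: a conserved column has IC near 1, a uniform
#' column has IC near 0.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param p position, 1-based; if missing, all positions.
#' @return numeric in \code{[0, 1]}.
#' @export
positionInformationContent <- function(pm, p) {
  stopifnot(is(pm, "MotifProbModel"))
  ic <- clamp((2 + colSums(pm@P1 * log2(pm@P1))) / 2)
  if (missing(p)) return(unname(ic))
  if (any(p < 1L | p > pm@n)) stop("position out of range 1..", pm@n)
  unname(ic[p])
}

#' Mutual information between motif positions
#'
#' \code{M_ij = sum over 16 base pairs of P(b1,b2,i,j) *
#' log2(P(b1,b2,i,j) / (P(b1,i) P(b2,j)))}, computed for all unordered pairs
#' and mirrored into a symmetric n x n matrix (diagonal zero).
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @return symmetric n x n numeric matrix.
#' @export
mutualInformation <- function(pm) {
  stopifnot(is(pm, "MotifProbModel"))
  n <- pm@n
  M <- matrix(0, n, n)
  for (p in seq_len(ncol(pm@pairs))) {
    i <- pm@pairs[1L, p]; j <- pm@pairs[2L, p]
    Pij <- pm@P2[, p]
    marg <- as.vector(outer(pm@P1[, j], pm@P1[, i]))  # rows AA..TT, b2 fastest
    M[i, j] <- M[j, i] <- sum(Pij * log2(Pij / marg))
  }
  M
}

#' Joint information content of a motif
#'
#' Sum over all unordered position pairs of
#' \code{sum_{b1,b2} P(b1,b2,i,j) log2(P(b1,b2,i,j) / (P(b1) P(b2)))},
#' a log-odds of the joint model against the background. A motif diagnostic;
#' it does not enter any of the four scores.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @return scalar.
#' @export
jointInformationContent <- function(pm) {
  stopifnot(is(pm, "MotifProbModel"))
  bgpair <- as.vector(outer(pm@bg, pm@bg))  # symmetric product; b2 fastest
  sum(vapply(seq_len(ncol(pm@pairs)), function(p) {
    Pij <- pm@P2[, p]
    sum(Pij * log2(Pij / bgpair))
  }, numeric(1L)))
}
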