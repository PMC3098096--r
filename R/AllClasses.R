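#' Aligned binding-site motif
#'
#' A TFBS motif represented by its \code{t} aligned binding-site sequences of
#' common width \code{n} over the DNA alphabet \code{A, C, G, T}.
#'
#' @slot name motif name.
#' @slot sites character vector of aligned, uppercase binding-site sequences.
#' @export
setClass("SiteMotif", representation(name = "character", sites = "character"))

setValidity("SiteMotif", function(object) {
  s <- object@sites
  if (length(s) < 2L) return("a motif needs at least t = 2 aligned sites")
  w <- nchar(s)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    return(sprintf("site %d has length %d, expected %d", bad, w[bad], w[1L]))
  }
  if (w[1L] < 2L) return("motif width must be at least n = 2")
  for (k in seq_along(s)) {
    pos <- regexpr("[^ACGT]", s[k])
    if (pos > 0L)
      return(sprintf("site %d ('%s') has illegal character '%s' at position %d",
                     k, s[k], substr(s[k], pos, pos), pos))
  }
  TRUE
})

#' Construct a SiteMotif
#'
#' @param sites character vector of aligned binding-site sequences (or a
#'   \code{Biostrings::DNAStringSet}); lowercase is accepted and uppercased.
#' @param name motif name.
#' @return a \linkS4class{SiteMotif}.
#' @examples
#' siteMotif(c("AC", "AG", "TC", "TG"), name = "toy")
#' @export
siteMotif <- function(sites, name = "motif") {
  if (is(sites, "XStringSet")) sites <- as.character(sites)
  new("SiteMotif", name = as.character(name), sites = toupper(unname(sites)))
}

#' Single-position and pairwise count tables
#'
#' @slot F1 4 x n matrix of per-position base counts F(b, i).
#' @slot F2 16 x n(n-1)/2 matrix of joint counts F(b1, b2, i, j) for i < j;
#'   rows ordered AA, AC, ..., TT, columns labelled "i-j".
#' @slot pairs 2 x n(n-1)/2 integer matrix of position pairs.
#' @slot t number of sites.
#' @slot n motif width.
#' @export
setClass("MotifCounts", representation(
  F1 = "matrix", F2 = "matrix", pairs = "matrix",
  t = "integer", n = "integer"))

setValidity("MotifCounts", function(object) {
  if (!all(colSums(object@F1) == object@t))
    return("per-position counts must sum to t at every position")
  if (ncol(object@F2) && !all(colSums(object@F2) == object@t))
    return("pairwise counts must sum to t for every position pair")
  if (any(object@F1 < 0) || any(object@F2 < 0))
    return("counts must be non-negative")
  TRUE
})

#' Smoothed probability model of a motif
#'
#' Corrected probabilities \code{P(b,i) = min(1, F(b,i)/t + a)} and
#' \code{P(b1,b2,i,j) = min(1, F(b1,b2,i,j)/t + a^2)} together with a
#' background distribution.
#'
#' @slot P1 4 x n matrix of smoothed single-position probabilities.
#' @slot P2 16 x npair matrix of smoothed joint probabilities.
#' @slot pairs 2 x npair position-pair matrix.
#' @slot a additive smoothing parameter per base.
#' @slot bg named background probabilities over A, C, G, T.
#' @slot t,n site count and motif width.
#' @export
setClass("MotifProbModel", representation(
  P1 = "matrix", P2 = "matrix", pairs = "matrix",
  a = "numeric", bg = "numeric", t = "integer", n = "integer"))

setValidity("MotifProbModel", function(object) {
  if (object@a <= 0) return("smoothing parameter a must be > 0")
  if (any(object@P1 <= 0) || any(object@P1 > 1)) return("P1 entries must lie in (0, 1]")
  if (ncol(object@P2) && (any(object@P2 <= 0) || any(object@P2 > 1)))
    return("P2 entries must lie in (0, 1]")
  if (abs(sum(object@bg) - 1) > 1e-9) return("background must sum to 1")
  TRUE
})

#' Position weight matrix (log-odds)
#'
#' @slot W 4 x n matrix of log2(P(b,i) / P(b)).
#' @slot wMin,wMax per-position minimum and maximum weight.
#' @slot bg background used.
#' @export
setClass("MotifPWM", representation(
  W = "matrix", wMin = "numeric", wMax = "numeric", bg = "numeric"))

#' Pairwise (dinucleotide) weight matrix
#'
#' 16 rows by n(n-1)/2 pair-columns of weights combining a log-odds term
#' against the background and a mutual-information-like term against the
#' single-position model.
#'
#' @slot W 16 x npair weight matrix.
#' @slot pairs 2 x npair position-pair matrix.
#' @slot wMin,wMax per-pair-column minimum and maximum weight.
#' @export
setClass("PairPWM", representation(
  W = "matrix", pairs = "matrix", wMin = "numeric", wMax = "numeric"))

#' Positional dependency structure
#'
#' Result of contingency testing over all position pairs plus the greedy
#' partition into independent positions and dependent order-2 pairs used by
#' the dependency-grouped score.
#'
#' @slot tests data.frame with columns i, j, stat, p, p.adj, dependent.
#' @slot alpha significance level (after correction).
#' @slot method "chi2" or "gtest".
#' @slot correction "bonferroni" or "bh".
#' @slot independent integer vector of independent positions.
#' @slot depPairs 2 x k matrix of dependent position pairs.
#' @export
setClass("DependencyStructure", representation(
  tests = "data.frame", alpha = "numeric", method = "character",
  correction = "character", independent = "integer", depPairs = "matrix"))

setValidity("DependencyStructure", function(object) {
  n <- max(c(object@independent, object@depPairs, object@tests$j))
  used <- c(object@independent, as.vector(object@depPairs))
  if (length(used) != n || anyDuplicated(used))
    return("every motif position must appear exactly once across the partition")
  TRUE
})

#' Intuitionistic fuzzy set representation of a motif
#'
#' One 16-entry membership/non-membership table per unordered position pair,
#' with cached per-pair maxima of the non-membership degree and the min/max
#' attainable raw pair scores.
#'
#' @slot name motif name.
#' @slot n motif width.
#' @slot pairs 2 x npair position-pair matrix.
#' @slot mu,nu 16 x npair membership and non-membership tables.
#' @slot score 16 x npair raw pair-score table mu * (max(nu) - nu).
#' @slot maxNu per-pair maximum non-membership.
#' @slot scMin,scMax per-pair minimum and maximum raw pair score.
#' @export
setClass("IFSMotifModel", representation(
  name = "character", n = "integer", pairs = "matrix",
  mu = "matrix", nu = "matrix", score = "matrix",
  maxNu = "numeric", scMin = "numeric", scMax = "numeric"))

setValidity("IFSMotifModel", function(object) {
  tol <- 1e-9
  if (any(object@mu < -tol) || any(object@mu > 1 + tol))
    return("membership degrees must lie in [0, 1]")
  if (any(object@nu < -tol) || any(object@nu > 1 + tol))
    return("non-membership degrees must lie in [0, 1]")
  if (any(object@mu + object@nu > 1 + tol))
    return("mu + nu must not exceed 1")
  if (any(object@scMax < object@scMin))
    return("per-pair score maximum below minimum")
  TRUE
})

#' Scoring engine for one motif
#'
#' Bundles the probability model, PWM, pair PWM, dependency structure and IFS
#' model of a motif so that any of the four scores can be evaluated on a
#' window or slid along a sequence.
#'
#' @slot motif the \linkS4class{SiteMotif} (empty sites if built from a
#'   count matrix only).
#' @slot hasSites FALSE when built from a count-only matrix; joint-probability
#'   scores are then unavailable.
#' @slot pm \linkS4class{MotifProbModel}.
#' @slot pwm \linkS4class{MotifPWM}.
#' @slot ppwm \linkS4class{PairPWM}.
#' @slot deps \linkS4class{DependencyStructure}.
#' @slot depWeights list with per-dependent-pair 16-entry log2 weights and
#'   normalization bounds for the dependency-grouped score.
#' @slot ifs \linkS4class{IFSMotifModel}.
#' @export
setClass("MotifScorer", representation(
  motif = "SiteMotif", hasSites = "logical", pm = "MotifProbModel",
  pwm = "MotifPWM", ppwm = "PairPWM", deps = "DependencyStructure",
  depWeights = "list", ifs = "IFSMotifModel"))

#' A single sequence-vs-motif score
#'
#' @slot method one of "indep", "dep", "mat", "intuit".
#' @slot raw raw (unnormalized) score.
#' @slot normalized min-max normalized score in [0, 1].
#' @slot terms per-position or per-pair contributions.
#' @slot sequence the scored window.
#' @slot motif motif name.
#' @export
setClass("ScoreResult", representation(
  method = "character", raw = "numeric", normalized = "numeric",
  terms = "numeric", sequence = "character", motif = "character"))

#' Markov background model
#'
#' Order-k Markov chain over A, C, G, T with additive smoothing: an initial
#' distribution over k-mers and conditional next-base probabilities.
#'
#' @slot order Markov order (0 = i.i.d.).
#' @slot initial named probability vector over the 4^order starting k-mers.
#' @slot transition 4^order x 4 matrix of P(next base | preceding k-mer).
#' @export
setClass("MarkovBackground", representation(
  order = "integer", initial = "numeric", transition = "matrix"))

setValidity("MarkovBackground", function(object) {
  if (any(object@transition < 0)) return("transition probabilities must be >= 0")
  if (any(abs(rowSums(object@transition) - 1) > 1e-9))
    return("each conditional distribution must sum to 1")
  if (abs(sum(object@initial) - 1) > 1e-9)
    return("initial distribution must sum to 1")
  TRUE
})

#' Synthetic motif-insertion benchmark dataset
#'
#' @slot sequences named character vector of DNA sequences.
#' @slot truth data.frame: seq_id, motif, start (0-based), end, site, mutated.
#' @slot params list of generation parameters (seed, ranges, mutate flag).
#' @export
setClass("BenchmarkDataset", representation(
  sequences = "character", truth = "data.frame", params = "list"))

#' Threshold-swept evaluation curves
#'
#' @slot curve data.frame with per-threshold TP, FP, FN, TN, precision,
#'   recall and FPR.
#' @slot prAUC trapezoid area under the precision-recall curve.
#' @slot rocAUC trapezoid area under the ROC curve.
#' @export
setClass("EvalCurves", representation(
  curve = "data.frame", prAUC = "numeric", rocAUC = "numeric"))
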