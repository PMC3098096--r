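#' Membership degree of a base pair
#'
#' The degree to which the base pair \code{(b1, b2)} belongs to the motif at
#' positions \code{(i, j)}: the smoothed joint probability, pulled up by the
#' individual conservation of the two bases,
#' \code{P(b1,b2,i,j) + (1 - P(b1,b2,i,j)) * (P(b1,i) + P(b2,j)) / 2},
#' clamped into \code{[0, 1]}.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param i,j positions, \code{i < j}.
#' @param b1,b2 bases.
#' @return scalar in \code{[0, 1]}.
#' @export
membership <- function(pm, i, j, b1, b2) {
  stopifnot(is(pm, "MotifProbModel"))
  key <- paste(i, j, sep = "-")
  Pj <- pm@P2[paste0(b1, b2), key]
  clamp(Pj + (1 - Pj) * (pm@P1[b1, i] + pm@P1[b2, j]) / 2)
}

#' Non-membership degree of a base pair
#'
#' The degree to which the base pair does \emph{not} belong to the motif:
#' the complement of the membership scaled by the mean column information
#' content of the two positions,
#' \code{((IC_i + IC_j) / 2) * (1 - mu)}. Conserved position pairs (high IC)
#' tolerate little uncertainty -- unclaimed membership mass turns into
#' non-membership -- while poorly conserved pairs leave it as hesitancy,
#' so that \code{mu + nu <= 1} always holds.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param i,j positions, \code{i < j}.
#' @param mu the membership degree of the same base pair.
#' @return scalar in \code{[0, 1]}.
#' @export
nonMembership <- function(pm, i, j, mu) {
  stopifnot(is(pm, "MotifProbModel"))
  ic <- positionInformationContent(pm)
  clamp(((ic[i] + ic[j]) / 2) * (1 - mu))
}

#' Build the intuitionistic fuzzy set model of a motif
#'
#' Represents the motif as one intuitionistic fuzzy set per unordered
#' position pair, each over the universe of the 16 base pairs, with
#' membership and non-membership degrees from \code{\link{membership}} and
#' \code{\link{nonMembership}}. Caches, per pair, the maximum
#' non-membership and the minimum/maximum attainable raw pair scores used
#' for normalization.
#'
#' @param pm a \linkS4class{MotifProbModel}.
#' @param name motif name carried through to the model.
#' @return an \linkS4class{IFSMotifModel}.
#' @export
ifsModel <- function(pm, name = "motif") {
  stopifnot(is(pm, "MotifProbModel"))
  np <- ncol(pm@pairs)
  ic <- positionInformationContent(pm)
  mu <- nu <- sc <- matrix(0, 16L, np, dimnames = dimnames(pm@P2))
  for (p in seq_len(np)) {
    i <- pm@pairs[1L, p]; j <- pm@pairs[2L, p]
    Pj <- pm@P2[, p]
    marg <- (rep(pm@P1[, i], each = 4L) + rep(pm@P1[, j], 4L)) / 2
    mu[, p] <- clamp(Pj + (1 - Pj) * marg)
    nu[, p] <- clamp(((ic[i] + ic[j]) / 2) * (1 - mu[, p]))
    sc[, p] <- mu[, p] * (max(nu[, p]) - nu[, p])
  }
  m <- new("IFSMotifModel", name = name, n = pm@n, pairs = pm@pairs,
           mu = mu, nu = nu, score = sc,
           maxNu = apply(nu, 2L, max),
           scMin = apply(sc, 2L, min), scMax = apply(sc, 2L, max))
  validObject(m)
  m
}

#' Raw IFS pair score
#'
#' \code{mu(b1,b2) * (max(nu) - nu(b1,b2))} for positions \code{(i, j)}:
#' membership weighted by how far the pair sits below the worst
#' non-membership seen at those positions. Always non-negative; the base
#' pair attaining the maximum non-membership scores 0.
#'
#' @param model an \linkS4class{IFSMotifModel}.
#' @param i,j positions, \code{i < j}.
#' @param b1,b2 bases.
#' @return scalar raw pair score.
#' @export
pairScore <- function(model, i, j, b1, b2) {
  stopifnot(is(model, "IFSMotifModel"))
  model@score[paste0(b1, b2), paste(i, j, sep = "-")]
}

#' Min--max normalized IFS pair score
#'
#' The raw pair score rescaled by the exact minimum and maximum over the 16
#' base pairs of that position pair.
#'
#' @inheritParams pairScore
#' @return scalar in \code{[0, 1]}.
#' @export
normalizedPairScore <- function(model, i, j, b1, b2) {
  stopifnot(is(model, "IFSMotifModel"))
  key <- paste(i, j, sep = "-")
  unname(normalizeScore(model@score[paste0(b1, b2), key],
                        model@scMin[[key]], model@scMax[[key]]))
}

#' Intuitionistic fuzzy score of a window against a motif
#'
#' Sums the raw IFS pair scores of the window over all n(n-1)/2 position
#' pairs and applies a single min--max normalization with bounds equal to
#' the summed per-pair minima and maxima (the same normalization the
#' dinucleotide matrix score uses), yielding a score in \code{[0, 1]}. The
#' per-pair normalized scores are kept as the result's terms.
#'
#' @param S DNA window of the motif width.
#' @param model an \linkS4class{IFSMotifModel}.
#' @return a \linkS4class{ScoreResult} with method "intuit".
#' @export
scIntuit <- function(S, model) {
  stopifnot(is(model, "IFSMotifModel"))
  w <- windowCheck(S, model@n)
  np <- ncol(model@pairs)
  rows <- pairRow(w$e[model@pairs[1L, ]], w$e[model@pairs[2L, ]])
  rawTerms <- model@score[cbind(rows, seq_len(np))]
  raw <- sum(rawTerms)
  rng <- model@scMax - model@scMin
  terms <- ifelse(rng > 0, (rawTerms - model@scMin) / rng, 1)
  names(terms) <- colnames(model@pairs)
  new("ScoreResult", method = "intuit", raw = raw,
      normalized = normalizeScore(raw, sum(model@scMin), sum(model@scMax)),
      terms = terms, sequence = w$S, motif = model@name)
}
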