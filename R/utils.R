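#' @import methods
#' @importFrom stats pchisq p.adjust runif setNames
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## 16 ordered base pairs, second base varying fastest: AA, AC, ..., TT
DNA_PAIRS <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))

## map A,C,G,T -> 1..4 (anything else, incl. N, -> NA)
encodeDNA <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES)
}

## row index into a 16-row pair table for encoded bases e1, e2
pairRow <- function(e1, e2) (e1 - 1L) * 4L + e2

## all unordered position pairs i < j as a 2 x npair integer matrix
positionPairs <- function(n) {
  if (n < 2L) stop("motif width must be at least 2")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  p <- t(unname(idx))
  dimnames(p) <- list(c("i", "j"), paste(p[1L, ], p[2L, ], sep = "-"))
  p
}

checkProbVector <- function(bg) {
  if (length(bg) != 4L || any(!is.finite(bg)) || any(bg <= 0))
    stop("background must be four strictly positive probabilities")
  if (abs(sum(bg) - 1) > 1e-9)
    stop("background probabilities must sum to 1 (got ", sum(bg), ")")
  if (is.null(names(bg))) names(bg) <- DNA_BASES
  bg[DNA_BASES]
}

## clamp into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Min--max score normalization
#'
#' Rescales a raw score into \code{[0, 1]} given the minimum and maximum
#' attainable raw scores, \code{(raw - minSC) / (maxSC - minSC)}, clamping
#' against floating-point drift. A degenerate range (\code{maxSC == minSC})
#' returns 1 when the raw score attains the bound, with a warning.
#'
#' @param raw numeric raw score(s).
#' @param minSC,maxSC attainable minimum and maximum of the raw score.
#' @return numeric in \code{[0, 1]}.
#' @export
normalizeScore <- function(raw, minSC, maxSC) {
  if (maxSC < minSC) stop("maxSC must be >= minSC")
  if (maxSC == minSC) {
    warning("degenerate score range (max == min); returning 1 at the bound")
    return(ifelse(raw == maxSC, 1, 0))
  }
  clamp((raw - minSC) / (maxSC - minSC))
}
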