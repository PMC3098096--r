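BASES <- c("A", "C", "G", "T")

## random motif of t sites, width n, with some column structure so that
## conservation varies across positions
randomMotif <- function(t = 8L, n = 4L, name = "rand") {
  cons <- sample(BASES, n, replace = TRUE)
  p <- runif(n, 0.3, 0.95)   # per-column conservation
  sites <- vapply(seq_len(t), function(k) {
    paste(ifelse(runif(n) < p, cons, sample(BASES, n, replace = TRUE)),
          collapse = "")
  }, character(1L))
  siteMotif(sites, name)
}

allWindows <- function(n) {
  do.call(paste0, expand.grid(rep(list(BASES), n))[, n:1, drop = FALSE])
}

## ---- naive reference implementations ----------------------------------
## Straight transcriptions of the scoring formulas with nested loops and no
## caching, kept deliberately independent of the package internals.

refModel <- function(msites, a = 0.001, bg = rep(0.25, 4)) {
  names(bg) <- BASES
  t <- length(msites); n <- nchar(msites[1L])
  ch <- strsplit(msites, "")
  P1 <- function(b, i) min(1, sum(vapply(ch, function(x) x[i] == b, logical(1))) / t + a)
  P2 <- function(b1, b2, i, j)
    min(1, sum(vapply(ch, function(x) x[i] == b1 && x[j] == b2, logical(1))) / t + a^2)
  list(t = t, n = n, a = a, bg = bg, P1 = P1, P2 = P2)
}

refIndep <- function(S, rm) {
  s <- strsplit(S, "")[[1L]]
  W <- function(b, i) log2(rm$P1(b, i) / rm$bg[[b]])
  raw <- 0; lo <- 0; hi <- 0
  for (i in seq_len(rm$n)) {
    raw <- raw + W(s[i], i)
    ws <- vapply(BASES, W, numeric(1L), i = i)
    lo <- lo + min(ws); hi <- hi + max(ws)
  }
  (raw - lo) / (hi - lo)
}

refMat <- function(S, rm) {
  s <- strsplit(S, "")[[1L]]
  raw <- 0; lo <- 0; hi <- 0
  for (i in seq_len(rm$n - 1L)) for (j in (i + 1L):rm$n) {
    w <- function(b1, b2)
      log2(rm$P2(b1, b2, i, j) / (rm$bg[[b1]] * rm$bg[[b2]])) +
      log2(rm$P2(b1, b2, i, j) / (rm$P1(b1, i) * rm$P1(b2, j)))
    raw <- raw + w(s[i], s[j])
    ws <- outer(BASES, BASES, Vectorize(w))
    lo <- lo + min(ws); hi <- hi + max(ws)
  }
  (raw - lo) / (hi - lo)
}

refDep <- function(S, rm, independent, depPairs) {
  s <- strsplit(S, "")[[1L]]
  raw <- 0; lo <- 0; hi <- 0
  for (i in independent) {
    W <- function(b) log2(rm$P1(b, i) / rm$bg[[b]])
    raw <- raw + W(s[i])
    ws <- vapply(BASES, W, numeric(1L))
    lo <- lo + min(ws); hi <- hi + max(ws)
  }
  for (k in seq_len(ncol(depPairs))) {
    i <- depPairs[1L, k]; j <- depPairs[2L, k]
    w <- function(b1, b2) log2(rm$P2(b1, b2, i, j) / (rm$bg[[b1]] * rm$bg[[b2]]))
    raw <- raw + w(s[i], s[j])
    ws <- outer(BASES, BASES, Vectorize(w))
    lo <- lo + min(ws); hi <- hi + max(ws)
  }
  (raw - lo) / (hi - lo)
}

refIntuit <- function(S, rm) {
  s <- strsplit(S, "")[[1L]]
  icCol <- function(p) {
    v <- 2 + sum(vapply(BASES, function(b) {
      P <- rm$P1(b, p); P * log2(P)
    }, numeric(1L)))
    min(1, max(0, v / 2))
  }
  raw <- 0; lo <- 0; hi <- 0
  for (i in seq_len(rm$n - 1L)) for (j in (i + 1L):rm$n) {
    mu <- function(b1, b2) {
      Pj <- rm$P2(b1, b2, i, j)
      min(1, max(0, Pj + (1 - Pj) * (rm$P1(b1, i) + rm$P1(b2, j)) / 2))
    }
    nu <- function(b1, b2)
      min(1, max(0, ((icCol(i) + icCol(j)) / 2) * (1 - mu(b1, b2))))
    nus <- outer(BASES, BASES, Vectorize(nu))
    sc <- function(b1, b2) mu(b1, b2) * (max(nus) - nu(b1, b2))
    raw <- raw + sc(s[i], s[j])
    scs <- outer(BASES, BASES, Vectorize(sc))
    lo <- lo + min(scs); hi <- hi + max(scs)
  }
  (raw - lo) / (hi - lo)
}
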