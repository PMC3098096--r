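#' Train a Markov background model from sequences
#'
#' Counts (k)-mer to next-base transitions over the training sequences with
#' an additive pseudocount of 1, and the starting-(k)-mer distribution the
#' same way, then normalizes.
#'
#' @param seqs character vector of DNA training sequences (or DNAStringSet).
#' @param order Markov order; default 3.
#' @return a \linkS4class{MarkovBackground}.
#' @export
trainMarkov <- function(seqs, order = 3L) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  seqs <- toupper(seqs)
  if (!length(seqs) || all(nchar(seqs) == 0L)) stop("no training sequences")
  kmers <- apply(expand.grid(rep(list(DNA_BASES), max(order, 1L)))[
    , rev(seq_len(max(order, 1L))), drop = FALSE], 1L, paste, collapse = "")
  if (order == 0L) kmers <- ""
  nk <- max(4L^order, 1L)
  trans <- matrix(1, nk, 4L, dimnames = list(if (order) kmers else "",
                                             DNA_BASES))
  init <- rep(1, nk)
  names(init) <- rownames(trans)
  for (s in seqs) {
    e <- encodeDNA(s)
    L <- length(e)
    if (L < order + 1L) next
    ## context index: little-endian over the k preceding bases
    if (order == 0L) {
      tab <- tabulate(e[!is.na(e)], nbins = 4L)
      trans[1L, ] <- trans[1L, ] + tab
      init[1L] <- init[1L] + 1
      next
    }
    ctx <- rep(0L, L - order)
    okc <- rep(TRUE, L - order)
    for (k in seq_len(order)) {
      b <- e[(k):(L - order + k - 1L)]
      okc <- okc & !is.na(b)
      ctx <- ctx * 4L + (b - 1L)
    }
    ctx <- ctx + 1L
    nxt <- e[(order + 1L):L]
    ok <- okc & !is.na(nxt)
    for (ix in which(ok)) trans[ctx[ix], nxt[ix]] <- trans[ctx[ix], nxt[ix]] + 1
    if (ok[1L]) init[ctx[1L]] <- init[ctx[1L]] + 1
  }
  new("MarkovBackground", order = order,
      initial = init / sum(init),
      transition = trans / rowSums(trans))
}

#' Uniform Markov background
#'
#' A background under which every base is equally likely regardless of
#' context; the fallback when no training sequences are supplied.
#'
#' @param order Markov order; default 3.
#' @return a \linkS4class{MarkovBackground}.
#' @export
uniformMarkov <- function(order = 3L) {
  order <- as.integer(order)
  nk <- max(4L^order, 1L)
  kmers <- if (order) apply(expand.grid(rep(list(DNA_BASES), order))[
    , rev(seq_len(order)), drop = FALSE], 1L, paste, collapse = "") else ""
  new("MarkovBackground", order = order,
      initial = setNames(rep(1 / nk, nk), kmers),
      transition = matrix(0.25, nk, 4L, dimnames = list(kmers, DNA_BASES)))
}

#' Sample a background sequence
#'
#' Draws a sequence of the requested length from the Markov model using R's
#' global random number generator (set a seed for reproducibility).
#'
#' @param bg a \linkS4class{MarkovBackground}.
#' @param length sequence length, at least the Markov order.
#' @return a DNA string.
#' @export
sampleBackground <- function(bg, length) {
  stopifnot(is(bg, "MarkovBackground"))
  length <- as.integer(length)
  if (length < bg@order) stop("length must be >= the Markov order")
  k <- bg@order
  if (k == 0L) {
    return(paste(sample(DNA_BASES, length, replace = TRUE,
                        prob = bg@transition[1L, ]), collapse = ""))
  }
  start <- sample(length(bg@initial), 1L, prob = bg@initial)
  out <- integer(length)
  ## unpack the starting k-mer (big-endian in the kmer string)
  sk <- encodeDNA(names(bg@initial)[start])
  m <- min(k, length)
  out[seq_len(m)] <- sk[seq_len(m)]
  if (length > k) {
    ctx <- start - 1L
    for (pos in (k + 1L):length) {
      nb <- sample.int(4L, 1L, prob = bg@transition[ctx + 1L, ])
      out[pos] <- nb
      ctx <- (ctx * 4L + (nb - 1L)) %% (4L^k)
    }
  }
  paste(DNA_BASES[out], collapse = "")
}

mutateSite <- function(site) {
  pos <- sample.int(nchar(site), 1L)
  old <- substr(site, pos, pos)
  new <- sample(setdiff(DNA_BASES, old), 1L)
  substr(site, pos, pos) <- new
  site
}

#' Generate a synthetic motif-insertion benchmark dataset
#'
#' For each motif: one background sequence of uniform-random length (200 to
#' 500 bp by default), into which a uniform-random number of binding sites
#' (2 to 6) drawn with replacement from the motif's real sites are
#' substituted in place at non-overlapping random offsets. With
#' \code{mutate = TRUE} each inserted site additionally receives one random
#' single-base substitution, emulating putative sites that are near but not
#' identical to the known ones. Ground truth records every insertion.
#'
#' @param motifs list of \linkS4class{SiteMotif} objects.
#' @param bg a \linkS4class{MarkovBackground}.
#' @param nSites integer range (length 2) of sites per sequence.
#' @param lengths integer range (length 2) of sequence lengths.
#' @param mutate give each inserted site a single random substitution.
#' @param seed optional integer seed, recorded in the dataset parameters.
#' @param maxTries placement retries before reducing the site count.
#' @return a \linkS4class{BenchmarkDataset}.
#' @export
makeBenchmark <- function(motifs, bg, nSites = c(2L, 6L),
                          lengths = c(200L, 500L), mutate = FALSE,
                          seed = NULL, maxTries = 200L) {
  if (is(motifs, "SiteMotif")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, is, logical(1L), "SiteMotif")),
            is(bg, "MarkovBackground"))
  if (!is.null(seed)) set.seed(seed)
  seqs <- character(0)
  truth <- list()
  for (m in motifs) {
    n <- motifWidth(m)
    L <- sample(lengths[1L]:lengths[2L], 1L)
    if (n >= L) stop("motif '", motifName(m), "' wider than the sequences")
    s <- sampleBackground(bg, L)
    want <- sample(nSites[1L]:nSites[2L], 1L)
    placed <- integer(0)          # 1-based starts
    tries <- 0L
    while (length(placed) < want && tries < maxTries) {
      tries <- tries + 1L
      st <- sample.int(L - n + 1L, 1L)
      if (!any(abs(placed - st) < n)) placed <- c(placed, st)
    }
    if (length(placed) < want)
      warning("could only place ", length(placed), " of ", want,
              " sites for motif '", motifName(m), "'")
    id <- motifName(m)
    for (st in sort(placed)) {
      site <- sample(sites(m), 1L)
      if (mutate) site <- mutateSite(site)
      substr(s, st, st + n - 1L) <- site
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = id, motif = motifName(m), start = st - 1L, end = st - 1L + n,
        site = site, mutated = mutate)
    }
    seqs[[id]] <- s
  }
  ## overlapping insertions could clobber earlier sites; re-read the truth
  truth <- do.call(rbind, truth)
  truth$site <- substr(seqs[truth$seq_id], truth$start + 1L, truth$end)
  new("BenchmarkDataset", sequences = seqs, truth = truth,
      params = list(seed = seed, nSites = nSites, lengths = lengths,
                    mutate = mutate, order = bg@order))
}

#' Per-position score tracks of a benchmark dataset
#'
#' Scores every window start of every sequence with the motif that was
#' inserted into it.
#'
#' @param dataset a \linkS4class{BenchmarkDataset}.
#' @param scorers named list of \linkS4class{MotifScorer} objects, names
#'   matching the dataset's motif names.
#' @param method scoring method.
#' @return named list of numeric score tracks (one value per window start).
#' @export
scoreTracks <- function(dataset, scorers, method = "intuit") {
  stopifnot(is(dataset, "BenchmarkDataset"))
  lapply(setNames(nm = names(dataset@sequences)), function(id) {
    scoreTrack(scorers[[id]], encodeDNA(dataset@sequences[[id]]), method)
  })
}

trapezoid <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  o <- order(x)
  sum(diff(x[o]) * (head(y[o], -1L) + y[o][-1L]) / 2)
}

#' Evaluate score tracks against the ground truth
#'
#' A window is called positive at threshold theta when its score is at
#' least theta; a positive is a true positive exactly when its start equals
#' a recorded insertion start. Sweeps the thresholds, computes TP/FP/FN/TN,
#' precision, recall and the false-positive rate per threshold, and
#' trapezoid areas under the precision-recall and ROC curves. Precision is
#' NA (not 0) at thresholds with no positive calls.
#'
#' @param dataset a \linkS4class{BenchmarkDataset}.
#' @param tracks output of \code{\link{scoreTracks}}.
#' @param thresholds thresholds to sweep; by default 0 to 1 in steps of 0.01.
#' @return an \linkS4class{EvalCurves}.
#' @export
evaluateBenchmark <- function(dataset, tracks,
                              thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(is(dataset, "BenchmarkDataset"))
  lab <- list(); sc <- list()
  for (id in names(dataset@sequences)) {
    tr <- tracks[[id]]
    if (is.null(tr)) stop("no track for sequence '", id, "'")
    starts <- seq_along(tr) - 1L
    truthStarts <- dataset@truth$start[dataset@truth$seq_id == id]
    lab[[id]] <- starts %in% truthStarts
    sc[[id]] <- tr
  }
  lab <- unlist(lab, use.names = FALSE)
  sc <- unlist(sc, use.names = FALSE)
  ok <- !is.na(sc)
  lab <- lab[ok]; sc <- sc[ok]
  P <- sum(lab); N <- sum(!lab)
  rows <- lapply(thresholds, function(th) {
    pos <- sc >= th
    TP <- sum(pos & lab); FP <- sum(pos & !lab)
    data.frame(threshold = th, TP = TP, FP = FP, FN = P - TP,
               TN = N - FP,
               precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
               recall = if (P > 0) TP / P else NA_real_,
               FPR = if (N > 0) FP / N else NA_real_)
  })
  curve <- do.call(rbind, rows)
  new("EvalCurves", curve = curve,
      prAUC = trapezoid(curve$recall, curve$precision),
      rocAUC = trapezoid(curve$FPR, curve$recall))
}

#' Precision at a threshold
#'
#' @param curves an \linkS4class{EvalCurves}.
#' @param threshold threshold value present in the sweep.
#' @return precision TP/(TP+FP) at that threshold (NA if no positives).
#' @export
precisionAt <- function(curves, threshold) {
  stopifnot(is(curves, "EvalCurves"))
  ix <- which.min(abs(curves@curve$threshold - threshold))
  curves@curve$precision[ix]
}

#' Export a benchmark dataset
#'
#' Writes the sequences as FASTA and the ground truth as tab-delimited text
#' (seq_id, motif, start, end, site, mutated).
#'
#' @param dataset a \linkS4class{BenchmarkDataset}.
#' @param fastaPath,truthPath output files.
#' @export
writeBenchmark <- function(dataset, fastaPath, truthPath) {
  stopifnot(is(dataset, "BenchmarkDataset"))
  writeFasta(dataset@sequences, fastaPath)
  write.table(dataset@truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
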