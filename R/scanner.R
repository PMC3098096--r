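#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around
#' \code{Biostrings::reverseComplement}; accepts A, C, G, T and N.
#'
#' @param S character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revComp <- function(S) {
  if (any(grepl("[^ACGTNacgtn]", S)))
    stop("revComp accepts only A, C, G, T and N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(S))))
}

emptyHits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
              strand = character(0), motif = character(0),
              method = character(0), score = numeric(0))
}

#' Scan sequences with a motif scorer
#'
#' Slides the motif window along each sequence, scores every position with
#' the requested method on the requested strands, and returns the windows
#' whose normalized score reaches the threshold. Minus-strand windows are
#' scored on the reverse complement but reported in forward coordinates.
#' Windows containing non-ACGT characters are skipped. Hit coordinates are
#' 0-based half-open.
#'
#' @param seqs named character vector of DNA sequences (or a
#'   \code{DNAStringSet}).
#' @param scorer a \linkS4class{MotifScorer}.
#' @param method scoring method; default "intuit".
#' @param threshold minimum normalized score to report; default 0.7.
#' @param strands "both" (default) or "forward".
#' @param bestPerPosition when scanning both strands, keep only the
#'   higher-scoring strand at each start (ties go to the forward strand).
#' @return data.frame of hits (seq_id, start, end, strand, motif, method,
#'   score) sorted by sequence, start, then strand.
#' @export
scanSequences <- function(seqs, scorer, method = "intuit", threshold = 0.7,
                          strands = c("both", "forward"),
                          bestPerPosition = FALSE) {
  strands <- match.arg(strands)
  stopifnot(is(scorer, "MotifScorer"))
  if (is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  seqs <- toupper(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- ncol(scorer@pwm@W)
  out <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    if (L < n) {
      warning("sequence '", id, "' is shorter than the motif width; skipped")
      next
    }
    enc <- encodeDNA(seqs[[id]])
    fwd <- scoreTrack(scorer, enc, method)
    starts <- seq_along(fwd) - 1L
    hits <- data.frame(seq_id = id, start = starts, end = starts + n,
                       strand = "+", score = fwd)
    if (strands == "both") {
      rcEnc <- rev(5L - enc)  # A<->T, C<->G on the reversed sequence
      rvTrack <- scoreTrack(scorer, rcEnc, method)
      ## window starting at s on the minus strand covers forward [L-s-n, L-s)
      rstarts <- L - (seq_along(rvTrack) - 1L) - n
      rhits <- data.frame(seq_id = id, start = rstarts, end = rstarts + n,
                          strand = "-", score = rvTrack)
      hits <- rbind(hits, rhits)
      if (bestPerPosition) {
        hits <- hits[order(hits$start, hits$strand), ]
        byStart <- split(seq_len(nrow(hits)), hits$start)
        sel <- vapply(byStart, function(ix) {
          sc <- hits$score[ix]
          sc[is.na(sc)] <- -Inf
          ix[which.max(sc)]  # "+" sorts first, so ties go forward
        }, integer(1L))
        hits <- hits[sort(sel), ]
      }
    }
    out[[id]] <- hits
  }
  if (!length(out)) return(emptyHits())
  hits <- do.call(rbind, out)
  hits <- hits[!is.na(hits$score) & hits$score >= threshold, , drop = FALSE]
  hits$motif <- motifName(scorer@motif)
  hits$method <- method
  hits <- hits[order(hits$seq_id, hits$start, hits$strand),
               c("seq_id", "start", "end", "strand", "motif", "method", "score")]
  rownames(hits) <- NULL
  hits
}

#' Score every motif window overlapping a SNP for both alleles
#'
#' Implements the allele-comparison protocol: each width-n window that
#' covers the polymorphic base is scored twice, once per allele, on both
#' strands. Offsets are labelled \code{-(n-1) .. 0} relative to the SNP
#' (offset 0 puts the SNP at the first window position); minus-strand
#' windows are the reverse complements of the same forward windows.
#'
#' @param promoter DNA sequence containing the SNP.
#' @param snpPos 1-based position of the SNP in \code{promoter}.
#' @param alleles length-2 character, e.g. \code{c("G", "T")}.
#' @param scorer a \linkS4class{MotifScorer} (or a named list of them, one
#'   per TF).
#' @param method scoring method; default "intuit".
#' @param strands "both" (default) or "forward".
#' @return data.frame with columns tf, offset, start (1-based), strand and
#'   one score column per allele (\code{score_<allele>}).
#' @export
snpWindowScan <- function(promoter, snpPos, alleles, scorer,
                          method = "intuit", strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is(scorer, "MotifScorer")) scorer <- list(scorer)
  promoter <- toupper(promoter)
  L <- nchar(promoter)
  if (snpPos < 1L || snpPos > L) stop("snpPos outside the sequence")
  if (length(alleles) != 2L) stop("exactly two alleles required")
  alleles <- toupper(alleles)
  variants <- vapply(alleles, function(al) {
    v <- promoter
    substr(v, snpPos, snpPos) <- al
    v
  }, character(1L))
  out <- list()
  for (k in seq_along(scorer)) {
    sc <- scorer[[k]]
    n <- ncol(sc@pwm@W)
    tf <- motifName(sc@motif)
    offsets <- seq(-(n - 1L), 0L)
    starts <- snpPos + offsets        # 1-based window starts
    ok <- starts >= 1L & starts + n - 1L <= L
    if (!all(ok))
      warning("SNP within ", n - 1L, " bp of the edge of the sequence for '",
              tf, "'; only ", sum(ok), " of ", n, " windows scored")
    for (w in which(ok)) {
      st <- starts[w]
      wins <- substr(variants, st, st + n - 1L)
      strandSet <- if (strands == "both") c("+", "-") else "+"
      for (sd in strandSet) {
        ws <- if (sd == "+") wins else revComp(wins)
        scs <- vapply(ws, function(x) {
          e <- encodeDNA(x)
          if (anyNA(e)) return(NA_real_)
          score(scoreWindow(sc, x, method))
        }, numeric(1L))
        out[[length(out) + 1L]] <- data.frame(
          tf = tf, offset = offsets[w], start = st, strand = sd,
          s1 = scs[[1L]], s2 = scs[[2L]])
      }
    }
  }
  res <- do.call(rbind, out)
  names(res)[5:6] <- paste0("score_", alleles)
  rownames(res) <- NULL
  res
}

#' Filter allele comparisons for allele-sensitive putative binding
#'
#' Keeps windows that (i) score at least \code{cutoff} for one allele and
#' (ii) differ between the alleles by at least \code{delta}, then retains
#' the best window per TF (highest maximal score; ties resolved toward the
#' smaller offset).
#'
#' @param comparisons output of \code{\link{snpWindowScan}}.
#' @param cutoff high-score requirement, default 0.7.
#' @param delta minimum between-allele score difference, default 0.10.
#' @return filtered data.frame.
#' @export
selectAlleleSensitive <- function(comparisons, cutoff = 0.7, delta = 0.10) {
  stopifnot(cutoff > 0, cutoff < 1, delta >= 0)
  scCols <- grep("^score_", names(comparisons))
  if (length(scCols) != 2L) stop("expected two score_<allele> columns")
  s1 <- comparisons[[scCols[1L]]]; s2 <- comparisons[[scCols[2L]]]
  best <- pmax(s1, s2)
  keep <- !is.na(best) & best >= cutoff & abs(s1 - s2) >= delta
  res <- comparisons[keep, , drop = FALSE]
  if (!nrow(res)) return(res)
  res <- res[order(res$tf, -pmax(res[[scCols[1L]]], res[[scCols[2L]]]),
                   res$offset), ]
  res <- res[!duplicated(res$tf), , drop = FALSE]
  rownames(res) <- NULL
  res
}
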