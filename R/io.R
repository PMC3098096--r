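#' Count-only motif input
#'
#' A motif loaded from a position frequency matrix (JASPAR PFM or TRANSFAC
#' count block). Carries no aligned sites, hence no joint (dinucleotide)
#' information: usable by the independence score only.
#'
#' @slot name motif name.
#' @slot counts 4 x n count matrix, rows A, C, G, T.
#' @export
setClass("MotifInput", representation(name = "character", counts = "matrix"))

## scorer for a count-only input: PWM/indep only
countOnlyScorer <- function(input, a, bg) {
  counts <- input@counts
  t <- sum(counts[, 1L])
  n <- ncol(counts)
  bg <- checkProbVector(bg)
  P1 <- clamp(counts / t + a, hi = 1)
  pairs <- positionPairs(n)
  pm <- new("MotifProbModel",
            P1 = P1, P2 = matrix(numeric(0), 16L, 0L),
            pairs = matrix(integer(0), 2L, 0L), a = a, bg = bg,
            t = as.integer(t), n = as.integer(n))
  motif <- new("SiteMotif", name = input@name,
               sites = rep(strrep("A", n), 2L))   # placeholder, not used
  new("MotifScorer", motif = motif, hasSites = FALSE, pm = pm,
      pwm = buildPWM(pm),
      ppwm = new("PairPWM", W = matrix(numeric(0), 16L, 0L),
                 pairs = matrix(integer(0), 2L, 0L),
                 wMin = numeric(0), wMax = numeric(0)),
      deps = new("DependencyStructure",
                 tests = data.frame(i = integer(0), j = integer(0),
                                    stat = numeric(0), p = numeric(0),
                                    p.adj = numeric(0),
                                    dependent = logical(0)),
                 alpha = NA_real_, method = "none", correction = "none",
                 independent = seq_len(n),
                 depPairs = matrix(integer(0), 2L, 0L)),
      depWeights = list(),
      ifs = new("IFSMotifModel", name = input@name, n = as.integer(n),
                pairs = matrix(integer(0), 2L, 0L),
                mu = matrix(numeric(0), 16L, 0L),
                nu = matrix(numeric(0), 16L, 0L),
                score = matrix(numeric(0), 16L, 0L),
                maxNu = numeric(0), scMin = numeric(0), scMax = numeric(0)))
}

#' Read aligned binding sites
#'
#' Accepts FASTA (headers become site ids) or one site per line. Lowercase
#' is uppercased; ragged lengths, non-ACGT characters or fewer than two
#' sites raise a validation error naming the offending line.
#'
#' @param path input file.
#' @param name motif name; defaults to the file name without extension.
#' @return a \linkS4class{SiteMotif}.
#' @export
readSites <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sites file: ", path)
  if (startsWith(lines[[1L]], ">")) {
    isHdr <- startsWith(lines, ">")
    grp <- cumsum(isHdr)
    if (grp[1L] == 0L) stop("FASTA body before the first header in ", path)
    seqs <- vapply(split(lines[!isHdr], grp[!isHdr]), paste, character(1L),
                   collapse = "")
    ids <- sub("^>\\s*", "", lines[isHdr])
    sites <- setNames(seqs, make.unique(ids[as.integer(names(seqs))]))
  } else {
    sites <- lines
  }
  motif <- new("SiteMotif", name = name, sites = toupper(unname(sites)))
  validObject(motif)
  motif
}

#' Read a JASPAR PFM or TRANSFAC count matrix
#'
#' Parses count-only motif matrices. The JASPAR dialect is a 4-row A/C/G/T
#' block, optionally bracketed (\code{A [ 1 2 3 ]}) and optionally preceded
#' by a \code{>} header. The TRANSFAC dialect is the \code{01..NN} row
#' block with A C G T column order, terminated by \code{XX}. The result is
#' flagged as carrying no joint information: it can drive the independence
#' score but not the dependency, dinucleotide-matrix or IFS scores.
#'
#' @param path input file.
#' @param dialect "jaspar" or "transfac".
#' @return a \linkS4class{MotifInput}.
#' @export
readCountMatrix <- function(path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  name <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "jaspar") {
    if (length(lines) && startsWith(lines[[1L]], ">")) {
      name <- sub("^>\\s*", "", lines[[1L]])
      lines <- lines[-1L]
    }
    if (length(lines) < 4L) stop("JASPAR PFM needs 4 count rows in ", path)
    rows <- lapply(lines[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
      if (anyNA(v)) stop("malformed PFM row in ", path, ": '", l, "'")
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("PFM rows have unequal lengths in ", path)
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
  } else {
    hdr <- grep("^P0|^PO", lines)
    if (!length(hdr)) stop("no P0 header line in TRANSFAC matrix ", path)
    ord <- strsplit(lines[hdr[1L]], "\\s+")[[1L]][-1L]
    if (!setequal(toupper(substr(ord, 1L, 1L))[1:4], DNA_BASES))
      stop("unexpected base order in TRANSFAC header of ", path)
    idLine <- grep("^ID\\s", lines, value = TRUE)
    if (length(idLine)) name <- sub("^ID\\s+", "", idLine[[1L]])
    body <- grep("^[0-9]+\\s", lines, value = TRUE)
    if (!length(body)) stop("no count rows in TRANSFAC matrix ", path)
    rows <- lapply(body, function(l) {
      v <- strsplit(l, "\\s+")[[1L]]
      num <- suppressWarnings(as.numeric(v[2:5]))
      if (anyNA(num)) stop("malformed TRANSFAC row in ", path, ": '", l, "'")
      num
    })
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- toupper(substr(ord, 1L, 1L))[1:4]
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  if (length(unique(colSums(counts))) != 1L)
    warning("column sums of ", path, " are not constant; ragged site counts?")
  new("MotifInput", name = name, counts = counts)
}

#' Read a FASTA file of DNA sequences
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (empty, with a
#'   warning, for an empty file).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write DNA sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write scan hits
#'
#' Tab-delimited hits (full precision) or 6-column BED with the normalized
#' score scaled by 1000 and rounded. BED coordinates are 0-based half-open,
#' matching the internal hit representation.
#'
#' @param hits data.frame from \code{\link{scanSequences}}.
#' @param path output file.
#' @param format "tsv" (default) or "bed".
#' @export
writeHits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(chrom = hits$seq_id, start = hits$start,
                      end = hits$end,
                      name = paste(hits$motif, hits$method, sep = "_"),
                      score = as.integer(round(hits$score * 1000)),
                      strand = hits$strand)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Dump motif models as JSON
#'
#' Serializes the IFS model (per pair: 16 mu, 16 nu, the maximum
#' non-membership and the score bounds), the PWM and the probability model
#' of a scorer for inspection or regression snapshots.
#'
#' @param scorer a \linkS4class{MotifScorer}.
#' @param path output JSON file.
#' @export
dumpModel <- function(scorer, path) {
  stopifnot(is(scorer, "MotifScorer"))
  obj <- list(
    motif = motifName(scorer@motif),
    n = scorer@pm@n, t = scorer@pm@t,
    a = scorer@pm@a, bg = as.list(scorer@pm@bg),
    pwm = apply(scorer@pwm@W, 2L, identity, simplify = FALSE),
    ifs = if (scorer@hasSites) lapply(
      seq_len(ncol(scorer@ifs@pairs)), function(p) list(
        i = scorer@ifs@pairs[1L, p], j = scorer@ifs@pairs[2L, p],
        mu = as.list(setNames(scorer@ifs@mu[, p], DNA_PAIRS)),
        nu = as.list(setNames(scorer@ifs@nu[, p], DNA_PAIRS)),
        max_nu = scorer@ifs@maxNu[[p]],
        sc_min = scorer@ifs@scMin[[p]], sc_max = scorer@ifs@scMax[[p]]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
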