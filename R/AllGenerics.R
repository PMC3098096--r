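#' @rdname SiteMotif-class
#' @param object,x an object.
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname SiteMotif-class
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname SiteMotif-class
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname SiteMotif-class
#' @export
setGeneric("siteCount", function(x) standardGeneric("siteCount"))

#' @export
setMethod("motifName", "SiteMotif", function(x) x@name)
#' @export
setMethod("sites", "SiteMotif", function(x) x@sites)
#' @export
setMethod("motifWidth", "SiteMotif", function(x) nchar(x@sites[1L]))
#' @export
setMethod("siteCount", "SiteMotif", function(x) length(x@sites))

#' Normalized score accessor
#' @param x a \linkS4class{ScoreResult}.
#' @return the normalized score in [0, 1].
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname score
#' @export
setMethod("score", "ScoreResult", function(x) x@normalized)

#' Raw score accessor
#' @param x a \linkS4class{ScoreResult}.
#' @export
setGeneric("rawScore", function(x) standardGeneric("rawScore"))
#' @rdname rawScore
#' @export
setMethod("rawScore", "ScoreResult", function(x) x@raw)

#' Per-term contributions of a score
#' @param x a \linkS4class{ScoreResult}.
#' @export
setGeneric("scoreTerms", function(x) standardGeneric("scoreTerms"))
#' @rdname scoreTerms
#' @export
setMethod("scoreTerms", "ScoreResult", function(x) x@terms)
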