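#' @describeIn SiteMotif-class compact display with consensus.
#' @export
setMethod("show", "SiteMotif", function(object) {
  n <- motifWidth(object)
  F1 <- motifCounts(object)@F1
  cons <- paste(DNA_BASES[apply(F1, 2L, which.max)], collapse = "")
  cat("SiteMotif '", object@name, "': t = ", siteCount(object),
      " sites, width n = ", n, "\n  consensus: ", cons, "\n", sep = "")
})

#' @describeIn MotifProbModel-class compact display.
#' @export
setMethod("show", "MotifProbModel", function(object) {
  cat("MotifProbModel: n = ", object@n, ", t = ", object@t,
      ", a = ", object@a, ", ", ncol(object@P2), " position pairs\n", sep = "")
})

#' @describeIn IFSMotifModel-class compact display.
#' @export
setMethod("show", "IFSMotifModel", function(object) {
  cat("IFSMotifModel '", object@name, "': width ", object@n, ", ",
      ncol(object@pairs), " pairwise IFS tables (16 base pairs each)\n",
      sep = "")
})

#' @describeIn ScoreResult-class one-line display with 3-decimal score.
#' @export
setMethod("show", "ScoreResult", function(object) {
  cat(sprintf("ScoreResult [%s] %s vs %s: score %.3f (raw %.4g)\n",
              object@method, object@sequence,
              if (nzchar(object@motif)) object@motif else "motif",
              object@normalized, object@raw))
})

#' @describeIn DependencyStructure-class compact display.
#' @export
setMethod("show", "DependencyStructure", function(object) {
  cat("DependencyStructure (", object@method, ", ", object@correction,
      ", alpha = ", object@alpha, "): ",
      ncol(object@depPairs), " dependent pair(s), ",
      length(object@independent), " independent position(s)\n", sep = "")
})

#' @describeIn MotifScorer-class compact display.
#' @export
setMethod("show", "MotifScorer", function(object) {
  cat("MotifScorer for '", motifName(object@motif), "' (n = ",
      object@pm@n, ", t = ", object@pm@t, ")",
      if (!object@hasSites) " [count-only: indep score only]", "\n", sep = "")
})

#' @describeIn BenchmarkDataset-class compact display.
#' @export
setMethod("show", "BenchmarkDataset", function(object) {
  cat("BenchmarkDataset: ", length(object@sequences), " sequence(s), ",
      nrow(object@truth), " inserted site(s)",
      if (isTRUE(object@params$mutate)) " (mutated)", "\n", sep = "")
})

#' @describeIn EvalCurves-class compact display with AUCs.
#' @export
setMethod("show", "EvalCurves", function(object) {
  cat(sprintf("EvalCurves: %d thresholds, PR-AUC %.3f, ROC-AUC %.3f\n",
              nrow(object@curve), object@prAUC, object@rocAUC))
})
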