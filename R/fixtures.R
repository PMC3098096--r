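#' Bundled example motifs
#'
#' Two small plant/vertebrate zinc-finger motifs used throughout the
#' documentation and tests.
#'
#' \code{dof3Example()} returns a synthetic reconstruction of the
#' Arabidopsis Dof3 motif: its per-position base counts equal the published
#' JASPAR MA0021.1 frequency matrix (21 sites, width 6; the 5' half AAAG is
#' invariant), and the unobservable pairing between the two variable 3'
#' positions is filled in with the maximum-entropy integer contingency
#' table consistent with those counts. It is therefore faithful at the
#' single-position level and synthetic at the dinucleotide level. Two probe
#' sequences accompany it: one deviating only at the poorly conserved 3'
#' positions and one with a single mismatch at the invariant first
#' position.
#'
#' \code{mzf1Example()} likewise reconstructs the MZF1 (five-finger) motif
#' from the JASPAR MA0056.1 counts (20 sites, width 6, consensus TGGGGA),
#' with a constructed site pairing that contains the outlier site GGAGGA
#' (lacking the near-invariant G at position 3) and the non-outlier site
#' TGGGGA. Single-base 3' mutants of both, GGAGGG and TGGGGT, are included
#' as probes for outlier discrimination.
#'
#' @return a list with elements \code{motif} (a \linkS4class{SiteMotif})
#'   and \code{probes} (named character vector).
#' @examples
#' ex <- dof3Example()
#' sc <- motifScorer(ex$motif)
#' scoreAllMethods(sc, ex$probes[["poorly_conserved_mismatch"]])
#' @export
dof3Example <- function() {
  motif <- readSites(system.file("extdata", "dof3_sites_synthetic.fa",
                                 package = "intuitMotif"), name = "Dof3")
  list(motif = motif,
       probes = c(poorly_conserved_mismatch = "AAAGGT",
                  conserved_mismatch = "TAAGCG"))
}

#' @rdname dof3Example
#' @export
mzf1Example <- function() {
  motif <- readSites(system.file("extdata", "mzf1_sites_synthetic.fa",
                                 package = "intuitMotif"), name = "MZF1")
  list(motif = motif,
       probes = c(outlier = "GGAGGA", non_outlier = "TGGGGA",
                  mutated_outlier = "GGAGGG", mutated_non_outlier = "TGGGGT"))
}
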