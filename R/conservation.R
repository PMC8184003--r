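#' Read a base-wise conservation score track
#'
#' Imports a bedGraph (or bigWig, where the local rtracklayer build supports
#' it) conservation track, e.g. primate phastCons, as a `GRanges` with a
#' `score` column in [0, 1].
#'
#' @param path bedGraph/bigWig file.
#' @return `GRanges` with a numeric `score` metadata column.
#' @export
readScoreTrack <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", tolower(path))) "bigwig" else "bedgraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (!"score" %in% colnames(S4Vectors::mcols(gr))) {
    stop("score track has no score column: ", path)
  }
  gr
}

#' Fraction of conserved positions over a set of intervals
#'
#' Computes, over the union of the given intervals (overlaps across
#' transcripts are merged so no base is counted twice), the fraction of
#' positions whose conservation score exceeds `threshold`. Positions with no
#' defined score are excluded from the denominator and reported separately.
#'
#' @param intervals `GRanges` of intervals (typically a gene's exons).
#' @param scores `GRanges` score track from [readScoreTrack()], or a plain
#'   numeric vector of per-base scores when `intervals` is omitted.
#' @param threshold Score above which a base counts as conserved
#'   (strict `>`; default 0.9, the phastCons convention used here).
#' @param geneId Label carried into the result.
#' @return `data.frame` with columns `gene_id`, `n_sites` (scored positions),
#'   `n_conserved`, `frac_conserved` (`NA` with a flag when no position has a
#'   score) and `n_missing` (positions without a score).
#' @examples
#' conservedFraction(scores = c(0.95, 0.5, 0.91, 0.2))  # 0.5
#' @export
conservedFraction <- function(intervals = NULL, scores, threshold = 0.9,
                              geneId = "gene") {
  if (is.numeric(scores)) {
    ok <- !is.na(scores)
    nSites <- sum(ok)
    nCons <- sum(scores[ok] > threshold)
    nMissing <- sum(!ok)
  } else {
    stopifnot(is(scores, "GRanges"), !is.null(intervals))
    iv <- GenomicRanges::reduce(intervals)
    hits <- GenomicRanges::intersect(iv, scores, ignore.strand = TRUE)
    # per-base accounting via overlap widths against the (disjoint) track
    ov <- GenomicRanges::findOverlaps(scores, iv, ignore.strand = TRUE)
    covered <- GenomicRanges::pintersect(
      scores[S4Vectors::queryHits(ov)], iv[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE)
    w <- GenomicRanges::width(covered)
    sc <- S4Vectors::mcols(scores)$score[S4Vectors::queryHits(ov)]
    defined <- !is.na(sc)
    nSites <- sum(w[defined])
    nCons <- sum(w[defined & sc > threshold])
    nMissing <- sum(GenomicRanges::width(iv)) - nSites
    stopifnot(sum(GenomicRanges::width(hits)) ==
                sum(w))  # track assumed non-self-overlapping
  }
  frac <- if (nSites > 0) nCons / nSites else NA_real_
  out <- data.frame(gene_id = geneId, n_sites = nSites, n_conserved = nCons,
                    frac_conserved = frac, n_missing = nMissing,
                    stringsAsFactors = FALSE)
  if (nSites == 0) attr(out, "flag") <- "no scored positions"
  out
}

#' Classify a lncRNA as conserved or other
#'
#' A lncRNA counts as conserved when strictly more than `cutoff` of its
#' scored exonic positions exceed the conservation threshold; the screen
#' default (5% of sites with phastCons > 0.9) separates lncRNAs like HOTAIR
#' (about 8% conserved sites) from young, repeat-derived ones like ESRG
#' (about 0.7%).
#'
#' @param profile One-row `data.frame` from [conservedFraction()].
#' @param cutoff Conserved-fraction cutoff (strict `>`; default 0.05).
#' @return `"conserved"` or `"other"`.
#' @export
classifyLncrnaConservation <- function(profile, cutoff = 0.05) {
  if (profile$n_sites[1] <= 0 || is.na(profile$frac_conserved[1])) {
    stop("conservation profile has no scored sites")
  }
  if (profile$frac_conserved[1] > cutoff) "conserved" else "other"
}
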