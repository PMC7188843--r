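## Overlap counters used by the enrichment analyses. Implemented on
## GenomicRanges interval queries; tests check them against brute-force
## quadratic scans.

## accept PAI-record columns or a generic chrom/bp1/bp2 frame
.asPairFrame <- function(x) {
  if (is(x, "PaiSet")) x <- paiSignificant(x)
  x <- as.data.frame(x)
  if (all(c("chrom", "bp1", "bp2") %in% names(x))) return(x)
  if (all(c("expo_chr", "expo_bp", "outcome_bp") %in% names(x)))
    return(data.frame(chrom = x$expo_chr, bp1 = x$expo_bp,
                      bp2 = x$outcome_bp, stringsAsFactors = FALSE))
  .stopf("pair frame needs chrom/bp1/bp2 or expo_chr/expo_bp/outcome_bp")
}

## per-point list of overlapping subject indices
.hitList <- function(chrom, bp, subject) {
  ov <- GenomicRanges::findOverlaps(.pointRanges(chrom, bp), subject)
  out <- vector("list", length(bp))
  h <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  out[as.integer(names(h))] <- h
  out
}

#' Which probe pairs fall in TADs?
#'
#' In the default "same" mode a pair counts when both probe positions lie
#' inside one and the same TAD interval; the "any" mode only requires each
#' probe to be inside some TAD.
#'
#' @param pairs a [PaiSet-class], its significant records, or a data.frame
#'   with `chrom, bp1, bp2` columns.
#' @param tads `GRanges` of TAD intervals.
#' @param mode "same" or "any".
#' @return logical vector, one element per pair.
#' @export
pairInTads <- function(pairs, tads, mode = c("same", "any")) {
  mode <- match.arg(mode)
  pf <- .asPairFrame(pairs)
  if (!nrow(pf)) return(logical(0))
  h1 <- .hitList(pf$chrom, pf$bp1, tads)
  h2 <- .hitList(pf$chrom, pf$bp2, tads)
  if (mode == "same")
    mapply(function(a, b) length(intersect(a, b)) > 0, h1, h2)
  else
    lengths(h1) > 0 & lengths(h2) > 0
}

#' @rdname pairInTads
#' @return `pairOverlapTads`: the count of overlapping pairs.
#' @export
pairOverlapTads <- function(pairs, tads, mode = c("same", "any")) {
  sum(pairInTads(pairs, tads, mode))
}

#' Which probe pairs land on chromatin-contact loop anchors?
#'
#' A pair counts when one probe falls in a loop's first anchor (padded by
#' `pad` bp on each side) and the other in its second anchor, in either
#' orientation; both probes in the same anchor do not count.
#'
#' @param pairs as in [pairInTads()].
#' @param loops `S4Vectors::Pairs` of anchor ranges (see [readIntervals()]),
#'   optionally subset beforehand by loop p-value.
#' @param pad anchor padding in bp (default 0: anchors as given).
#' @return logical vector, one element per pair.
#' @export
pairInLoops <- function(pairs, loops, pad = 0) {
  pf <- .asPairFrame(pairs)
  if (!nrow(pf)) return(logical(0))
  a1 <- S4Vectors::first(loops)
  a2 <- S4Vectors::second(loops)
  if (pad > 0) {
    a1 <- GenomicRanges::resize(a1, GenomicRanges::width(a1) + 2 * pad,
                                fix = "center")
    a2 <- GenomicRanges::resize(a2, GenomicRanges::width(a2) + 2 * pad,
                                fix = "center")
  }
  p1a1 <- .hitList(pf$chrom, pf$bp1, a1)
  p1a2 <- .hitList(pf$chrom, pf$bp1, a2)
  p2a1 <- .hitList(pf$chrom, pf$bp2, a1)
  p2a2 <- .hitList(pf$chrom, pf$bp2, a2)
  mapply(function(i, j, k, l)
    length(intersect(i, l)) > 0 || length(intersect(k, j)) > 0,
    p1a1, p1a2, p2a1, p2a2)
}

#' @rdname pairInLoops
#' @return `pairOverlapLoops`: the count of overlapping pairs.
#' @export
pairOverlapLoops <- function(pairs, loops, pad = 0) {
  sum(pairInLoops(pairs, loops, pad))
}

#' Count sites whose centred window touches a feature
#'
#' Each site is expanded to a window of `window` bp total (half on either
#' side) and counted when the window intersects at least one feature
#' interval; the default 10 kb window reproduces the "10 Kb region centred
#' around each DNAm site" convention.
#'
#' @param sites data.frame with `chrom, bp` columns.
#' @param features `GRanges`.
#' @param window total window size in bp.
#' @return `siteInWindow`: logical per site; `siteWindowOverlap`: the count.
#' @export
siteInWindow <- function(sites, features, window = 10000) {
  stopifnot(window > 0)
  half <- window / 2
  w <- GenomicRanges::GRanges(
    as.character(sites$chrom),
    IRanges::IRanges(start = pmax(1, sites$bp - half), end = sites$bp + half))
  GenomicRanges::countOverlaps(w, features) > 0
}

#' @rdname siteInWindow
#' @export
siteWindowOverlap <- function(sites, features, window = 10000) {
  sum(siteInWindow(sites, features, window))
}

#' Chromatin-state label of probe positions
#'
#' Assigns each probe the `label` of the state interval containing it;
#' probes covered by no interval are "unannotated". When a position is
#' covered by several intervals the first in sorted order wins.
#'
#' @param probes data.frame with `chrom, bp`.
#' @param states labelled `GRanges` (metadata column `label`).
#' @return character vector of state labels.
#' @export
stateAtProbes <- function(probes, states) {
  h <- .hitList(probes$chrom, probes$bp, states)
  vapply(h, function(i) if (length(i)) S4Vectors::mcols(states)$label[i[1]]
         else "unannotated", character(1))
}
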