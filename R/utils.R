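## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a pipeline seed and an analysis name
#'
#' Each resampling analysis draws its randomness from a sub-seed derived by a
#' fixed hash of the pipeline seed and the analysis name, so adding or
#' reordering analyses never perturbs the null sets of the others.
#'
#' The hash is `(seed * 7919 + sum_k k * utf8(name)_k) mod (2^31 - 512)`,
#' kept strictly inside the 32-bit integer range R requires of seeds.
#'
#' @param seed integer pipeline seed.
#' @param name character scalar naming the analysis.
#' @return an integer usable with [set.seed()].
#' @export
deriveSeed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (2^31 - 512))
}

#' Normalise chromosome naming
#'
#' Mixed "chr1"/"1" conventions across BED sources are reconciled by either
#' stripping or adding the "chr" prefix; the default leaves names untouched.
#'
#' @param x character vector of chromosome names.
#' @param style one of "asis", "strip", "add".
#' @return character vector.
#' @export
normChrom <- function(x, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "strip") sub("^chr", "", x)
  else if (style == "add") ifelse(grepl("^chr", x), x, paste0("chr", x))
  else x
}

## GRanges of width-1 points from 1-based positions
.pointRanges <- function(chrom, bp) {
  GenomicRanges::GRanges(as.character(chrom),
                         IRanges::IRanges(start = bp, width = 1))
}

## message-level logging collected by readers/scans
.logMsg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
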