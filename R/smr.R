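## SMR ratio test and supporting instrument logic.
##
## The ratio estimate of the effect of an exposure DNAm site on an outcome
## DNAm site through an instrument SNP z is b_xy = b_zy / b_zx, tested with
## a two-sided Wald test whose chi-square(1) statistic is
## t_smr = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2), z = b/se.

#' Harmonise allele coding of summary rows to a reference coding
#'
#' Rows whose (a1, a2) is the reverse of the reference have their effect
#' sign flipped and frequency complemented; rows whose allele pair does not
#' match the reference at all are dropped. Strand-ambiguous A/T and C/G
#' SNPs can optionally be dropped.
#'
#' @param stats data.frame with at least `snp_id, a1, a2, freq, b`.
#' @param ref data.frame `snp_id, a1, a2` giving the target coding.
#' @param ambiguous "keep" or "drop" A/T and C/G SNPs.
#' @return `stats` aligned to `ref`, possibly with fewer rows; the number of
#'   dropped mismatches is attached as attribute `"nDropped"`.
#' @export
alignAlleles <- function(stats, ref, ambiguous = c("keep", "drop")) {
  ambiguous <- match.arg(ambiguous)
  idx <- match(stats$snp_id, ref$snp_id)
  keep <- !is.na(idx)
  stats <- stats[keep, , drop = FALSE]
  idx <- idx[keep]
  ra1 <- ref$a1[idx]; ra2 <- ref$a2[idx]
  same <- stats$a1 == ra1 & stats$a2 == ra2
  flip <- stats$a1 == ra2 & stats$a2 == ra1
  if (ambiguous == "drop") {
    pair <- paste0(pmin(stats$a1, stats$a2), pmax(stats$a1, stats$a2))
    amb <- pair %in% c("AT", "CG")
    same <- same & !amb; flip <- flip & !amb
  }
  nDropped <- sum(keep) - sum(same | flip) + sum(!keep)
  out <- stats[same | flip, , drop = FALSE]
  fl <- flip[same | flip]
  out$b[fl] <- -out$b[fl]
  if ("freq" %in% names(out)) out$freq[fl] <- 1 - out$freq[fl]
  tmp <- out$a1[fl]; out$a1[fl] <- out$a2[fl]; out$a2[fl] <- tmp
  attr(out, "nDropped") <- nDropped
  out
}

#' Select the top instrument SNP for a probe
#'
#' The instrument is the cis SNP with the smallest association p-value,
#' provided it reaches `pThreshold` (default 5e-8); ties on p are broken by
#' larger |z|, then smaller position, then lexical SNP id.
#'
#' @param stats cis summary rows for one probe (columns `snp_id, snp_bp, b,
#'   se, p` at least).
#' @param pThreshold genome-wide instrument threshold.
#' @return the selected row (1-row data.frame), or NULL when no SNP passes.
#' @export
topInstrument <- function(stats, pThreshold = 5e-8) {
  ok <- is.finite(stats$p) & stats$p < pThreshold
  if (!any(ok)) return(NULL)
  s <- stats[ok, , drop = FALSE]
  z2 <- (s$b / s$se)^2
  o <- order(s$p, -z2, s$snp_bp, s$snp_id)
  s[o[1], , drop = FALSE]
}

#' The SMR ratio test at one instrument
#'
#' @param bzx,sezx instrument effect and SE on the exposure.
#' @param bzy,sezy instrument effect and SE on the outcome (allele-aligned
#'   with the exposure coding).
#' @return list with `b_xy`, `se_xy`, `t_smr` (chi-square, 1 df) and `p_smr`
#'   (two-sided Wald).
#' @examples
#' smrTest(0.5, 0.05, 0.2, 0.05)
#' @export
smrTest <- function(bzx, sezx, bzy, sezy) {
  stopifnot(sezx > 0, sezy > 0)
  if (bzx == 0) .stopf("invalid instrument: b_zx = 0")
  z2x <- (bzx / sezx)^2
  z2y <- (bzy / sezy)^2
  t <- z2x * z2y / (z2x + z2y)
  bxy <- bzy / bzx
  list(b_xy = bxy,
       se_xy = if (t > 0) abs(bxy) / sqrt(t) else Inf,
       t_smr = t,
       p_smr = pchisq(t, df = 1, lower.tail = FALSE))
}

#' Variance in DNAm explained by a cis-mQTL
#'
#' `q2 = 2 p (1 - p) b^2` for an SD-unit effect `b` at allele frequency `p`;
#' when the frequency is unavailable, the z-statistic fallback
#' `q2 = z^2 / (z^2 + n - 2)` is used.
#'
#' @param b,se effect and SE (SD units).
#' @param freq effect-allele frequency, or NA.
#' @param n sample size, or NA.
#' @return q2 in \[0, 1\], or NA when neither freq nor n is available.
#' @export
varianceExplained <- function(b, se, freq = NA, n = NA) {
  out <- rep(NA_real_, length(b))
  hasF <- !is.na(freq)
  out[hasF] <- 2 * freq[hasF] * (1 - freq[hasF]) * b[hasF]^2
  hasN <- !hasF & !is.na(n)
  z2 <- (b[hasN] / se[hasN])^2
  out[hasN] <- z2 / (z2 + n[hasN] - 2)
  out
}
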