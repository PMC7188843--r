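#' Build an LdMatrix from reference-panel allele counts
#'
#' Computes signed Pearson correlations between SNP allele-count columns.
#' Monomorphic columns cannot be correlated and are dropped with a warning.
#'
#' @param genotypes samples x SNPs matrix of {0,1,2} counts with SNP ids as
#'   column names (e.g. from [readGenotypeMatrix()] or [readLdVcf()]).
#' @param alleles data.frame `snp_id, a1, a2` saying which allele the counts
#'   refer to; defaults to the matrix's `"alleles"` attribute.
#' @return an [LdMatrix-class].
#' @export
ldFromGenotypes <- function(genotypes, alleles = attr(genotypes, "alleles")) {
  if (is.null(colnames(genotypes)))
    .stopf("genotype matrix must carry SNP ids as column names")
  v <- apply(genotypes, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " monomorphic SNP(s) dropped from LD matrix")
    genotypes <- genotypes[, v > 0, drop = FALSE]
  }
  snps <- colnames(genotypes)
  if (is.null(alleles))
    alleles <- data.frame(snp_id = snps, a1 = NA_character_,
                          a2 = NA_character_, stringsAsFactors = FALSE)
  al <- alleles[match(snps, alleles$snp_id), , drop = FALSE]
  r <- crossprod(scale(genotypes)) / (nrow(genotypes) - 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  new("LdMatrix", snps = snps, a1 = as.character(al$a1),
      a2 = as.character(al$a2), r = unname(r))
}

#' Extract an aligned LD sub-matrix
#'
#' Returns the correlation sub-matrix for `snps`, sign-aligned to a target
#' allele coding: SNPs whose panel `a1` is the target's `a2` have their
#' correlation signs flipped (flipping the counted allele negates all of a
#' SNP's correlations).
#'
#' @param ld an [LdMatrix-class].
#' @param snps SNP ids to extract (must be present).
#' @param a1,a2 target allele coding per SNP; when NULL, no alignment.
#' @return correlation matrix with dimnames `snps`.
#' @keywords internal
.ldSubmatrix <- function(ld, snps, a1 = NULL, a2 = NULL) {
  idx <- match(snps, ld@snps)
  if (anyNA(idx)) .stopf("SNP(s) absent from LD matrix: %s",
                         paste(snps[is.na(idx)], collapse = ", "))
  r <- ld@r[idx, idx, drop = FALSE]
  if (!is.null(a1)) {
    pa1 <- ld@a1[idx]; pa2 <- ld@a2[idx]
    sgn <- ifelse(is.na(pa1) | (pa1 == a1 & pa2 == a2), 1,
                  ifelse(pa1 == a2 & pa2 == a1, -1, NA))
    if (anyNA(sgn))
      .stopf("allele mismatch between LD panel and summary data for %s",
             paste(snps[is.na(sgn)], collapse = ", "))
    r <- r * tcrossprod(sgn)
  }
  dimnames(r) <- list(snps, snps)
  r
}
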