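## HEIDI: heterogeneity in dependent instruments.
##
## Under pleiotropy (one shared causal variant) the ratio estimate b_xy is
## identical at every SNP in LD with the causal variant, so the differences
## d_i = b_xy(i) - b_xy(top) are jointly zero. d-hat ~ MVN(d, V) with V
## derived from the summary statistics and reference-panel LD; HEIDI tests
## d = 0 with the statistic T = sum_i d_i^2 / V_ii, whose null distribution
## is a weighted sum of 1-df chi-squares with weights the eigenvalues of the
## correlation matrix of d.

#' Select HEIDI instruments by significance with LD pruning
#'
#' Keeps the top SNP plus, in order of exposure significance, SNPs with
#' exposure `p < pInclude` whose pairwise r^2 with every retained SNP is at
#' most `r2Cap` and whose r^2 with the top SNP is at least `r2MinTop`
#' (components nearly independent of the instrument carry no information on
#' heterogeneity at the top signal). Truncated to `maxSnps` total.
#'
#' @param stats exposure cis rows (`snp_id, b, se, p`), allele-aligned.
#' @param ldr signed correlation matrix with dimnames covering the SNPs.
#' @param topSnp id of the top instrument (always retained).
#' @param pInclude inclusion threshold, default 1.57e-3 (z^2 > 10).
#' @param r2Cap pairwise pruning cap, default 0.9.
#' @param r2MinTop minimum r^2 with the top SNP, default 0.05.
#' @param maxSnps maximum instruments including the top, default 20.
#' @return character vector of retained SNP ids (top first).
#' @export
heidiSelectSnps <- function(stats, ldr, topSnp, pInclude = 1.57e-3,
                            r2Cap = 0.9, r2MinTop = 0.05, maxSnps = 20L) {
  stopifnot(topSnp %in% stats$snp_id, topSnp %in% rownames(ldr))
  cand <- stats[stats$snp_id != topSnp &
                  is.finite(stats$p) & stats$p < pInclude &
                  stats$snp_id %in% rownames(ldr), , drop = FALSE]
  cand <- cand[order(cand$p, cand$snp_id), , drop = FALSE]
  keep <- topSnp
  for (s in cand$snp_id) {
    if (length(keep) >= maxSnps) break
    r2top <- ldr[s, topSnp]^2
    if (r2top < r2MinTop || r2top > r2Cap) next
    if (all(ldr[s, keep]^2 <= r2Cap)) keep <- c(keep, s)
  }
  keep
}

#' HEIDI difference vector and its covariance
#'
#' First-order delta-method covariance of the per-SNP ratio estimates:
#' cov(b_xy(i), b_xy(j)) = b_xy(i) b_xy(j) r_ij
#' \[1/(z_zx(i) z_zx(j)) + 1/(z_zy(i) z_zy(j))\], with the covariance of the
#' differences d_i = b_xy(i) - b_xy(top) obtained by the usual contrast
#' expansion. Sample overlap between the exposure and outcome scans is
#' ignored (cross-trait covariance 0); the null-calibration experiment in
#' [nullOverlapExperiment()] checks this empirically. V is symmetrised and
#' eigenvalue-floored at zero.
#'
#' @param bzx,sezx,bzy,sezy equal-length vectors of exposure / outcome
#'   effects and SEs, allele-aligned, ordered as `snps`.
#' @param ldr signed correlation matrix of the SNPs (same order).
#' @param topIndex index of the top instrument within the vectors.
#' @return list `d` (length k-1), `V` ((k-1) x (k-1)), `bxy` (length k).
#' @export
heidiCovariance <- function(bzx, sezx, bzy, sezy, ldr, topIndex = 1L) {
  k <- length(bzx)
  stopifnot(k >= 3, length(sezx) == k, length(bzy) == k, length(sezy) == k,
            nrow(ldr) == k, topIndex >= 1, topIndex <= k)
  zx <- bzx / sezx
  zy <- bzy / sezy
  if (any(zx == 0) || any(zy == 0))
    .stopf("degenerate z-statistic (z = 0) among HEIDI instruments")
  bxy <- bzy / bzx
  C <- tcrossprod(bxy) * ldr * (1 / tcrossprod(zx) + 1 / tcrossprod(zy))
  oth <- setdiff(seq_len(k), topIndex)
  V <- C[oth, oth, drop = FALSE] -
    outer(C[oth, topIndex], rep(1, k - 1)) -
    outer(rep(1, k - 1), C[oth, topIndex]) +
    C[topIndex, topIndex]
  V <- (V + t(V)) / 2
  ee <- eigen(V, symmetric = TRUE)
  V <- ee$vectors %*% (pmax(ee$values, 0) * t(ee$vectors))
  V <- (V + t(V)) / 2
  list(d = bxy[oth] - bxy[topIndex], V = V, bxy = bxy)
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' P(sum_k lambda_k chi^2_1 > q), by Satterthwaite moment matching
#' (scaled chi-square with matched mean and variance) or by numerically
#' exact Imhof quadrature of the characteristic-function inversion
#' integral.
#'
#' @param q observed statistic.
#' @param lambda non-negative weights.
#' @param method "satterthwaite" or "imhof".
#' @return upper-tail probability in (0, 1\].
#' @export
weightedChisqTail <- function(q, lambda, method = c("satterthwaite", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(1)
  if (q <= 0) return(1)
  if (method == "satterthwaite") {
    s1 <- sum(lambda); s2 <- sum(lambda^2)
    kappa <- s2 / s1
    nu <- s1^2 / s2
    pchisq(q / kappa, df = nu, lower.tail = FALSE)
  } else {
    integrand <- function(u) {
      theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      val <- sin(theta) / (u * rho)
      val[u == 0] <- 0.5 * (sum(lambda) - q)
      val
    }
    I <- integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12,
                   stop.on.error = FALSE)$value
    p <- 0.5 + I / pi
    min(max(p, 1e-300), 1)
  }
}

#' The HEIDI heterogeneity test
#'
#' Statistic T = sum_i d_i^2 / V_ii; null distribution a weighted sum of
#' 1-df chi-squares with weights the eigenvalues of the correlation matrix
#' of d. Components with zero variance are degenerate and dropped; fewer
#' than two informative components yield NA.
#'
#' @param d difference vector from [heidiCovariance()].
#' @param V its covariance matrix.
#' @param method tail approximation, see [weightedChisqTail()].
#' @return list `p_heidi` (NA when degenerate), `T`, `nsnp` (instruments
#'   used, including the top SNP).
#' @export
heidiTest <- function(d, V, method = c("satterthwaite", "imhof")) {
  method <- match.arg(method)
  vd <- diag(as.matrix(V))
  ok <- vd > 1e-30
  if (sum(ok) < 2)
    return(list(p_heidi = NA_real_, T = NA_real_, nsnp = sum(ok) + 1L))
  d <- d[ok]
  V <- as.matrix(V)[ok, ok, drop = FALSE]
  sdv <- sqrt(diag(V))
  Tstat <- sum((d / sdv)^2)
  R <- V / tcrossprod(sdv)
  lam <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(p_heidi = weightedChisqTail(Tstat, pmax(lam, 0), method = method),
       T = Tstat, nsnp = length(d) + 1L)
}
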