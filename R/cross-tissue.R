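## Cross-tissue comparison of PAI effect estimates: replication rates, the
## error-corrected effect correlation rb, and the Fisher-transformation
## test for a difference between two expression correlations.

#' Replication of significant pairs in a second tissue
#'
#' Matches the significant pairs of a discovery tissue to the records of a
#' replication tissue on (exposure, outcome) identity and counts
#' replication at the Bonferroni level (`p_smr < alpha / n_available` and
#' HEIDI pass) and at the nominal level (`p_smr < 0.05` and HEIDI pass).
#' Replicated pairs whose effect signs disagree between tissues are listed.
#'
#' @param sigA data.frame of significant discovery records (needs
#'   `expo_probe, outcome_probe, b_xy, p_smr, p_heidi`).
#' @param recordsB data.frame of replication-tissue records, same columns.
#' @param alpha family-wise error rate for the Bonferroni level.
#' @param heidiCut HEIDI cutoff applied in the replication tissue.
#' @return list of counts, rates (percent), the Bonferroni threshold used,
#'   and the sign-discordant replicated pair table.
#' @export
replicationSummary <- function(sigA, recordsB, alpha = 0.05,
                               heidiCut = 0.01) {
  keyA <- paste(sigA$expo_probe, sigA$outcome_probe)
  keyB <- paste(recordsB$expo_probe, recordsB$outcome_probe)
  m <- match(keyA, keyB)
  avail <- !is.na(m) & is.finite(recordsB$p_smr[m])
  nAvail <- sum(avail)
  if (nAvail == 0) .stopf("no discovery pair matched in the replication set")
  a <- sigA[avail, , drop = FALSE]
  b <- recordsB[m[avail], , drop = FALSE]
  thr <- bonferroniThreshold(nAvail, alpha)
  heidiOk <- !is.na(b$p_heidi) & b$p_heidi > heidiCut
  repBonf <- b$p_smr < thr & heidiOk
  repNom <- b$p_smr < 0.05 & heidiOk
  disc <- repBonf & sign(a$b_xy) != sign(b$b_xy)
  list(nAvailable = nAvail,
       nReplicatedBonferroni = sum(repBonf),
       nReplicatedNominal = sum(repNom),
       rateBonferroni = 100 * mean(repBonf),
       rateNominal = 100 * mean(repNom),
       threshold = thr,
       signDiscordant = data.frame(
         expo_probe = a$expo_probe[disc], outcome_probe = a$outcome_probe[disc],
         b_xy_a = a$b_xy[disc], b_xy_b = b$b_xy[disc],
         stringsAsFactors = FALSE))
}

#' Correlation of true effects between two tissues (rb)
#'
#' Estimates the correlation of the underlying (true) pair effects from two
#' vectors of estimated effects with their standard errors, correcting the
#' observed variances for estimation error:
#' `rb = cov(b1, b2) / sqrt((var(b1) - mean(se1^2)) (var(b2) - mean(se2^2)))`.
#' The cross-tissue error covariance is taken as zero (independent
#' cohorts); a nonzero error correlation can be supplied for overlapping
#' samples. The standard error is a leave-one-out jackknife over pairs, and
#' the estimate is clamped to \[-1, 1\] with a flag.
#'
#' @param b1,se1,b2,se2 equal-length effect and SE vectors (>= 3 pairs).
#' @param errorCorrelation correlation of the estimation errors between the
#'   two data sets (0 for independent samples).
#' @return list `rb`, `se_rb`, `n_pairs`, `clamped`.
#' @export
rbEstimate <- function(b1, se1, b2, se2, errorCorrelation = 0) {
  n <- length(b1)
  stopifnot(n >= 3, length(se1) == n, length(b2) == n, length(se2) == n)
  core <- function(b1, se1, b2, se2) {
    v1 <- var(b1) - mean(se1^2)
    v2 <- var(b2) - mean(se2^2)
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    cv <- cov(b1, b2) - errorCorrelation * mean(se1 * se2)
    cv / sqrt(v1 * v2)
  }
  rb <- core(b1, se1, b2, se2)
  if (is.na(rb)) {
    warning("error-corrected variance is non-positive; rb undefined")
    return(list(rb = NA_real_, se_rb = NA_real_, n_pairs = n, clamped = FALSE))
  }
  jack <- vapply(seq_len(n), function(i)
    core(b1[-i], se1[-i], b2[-i], se2[-i]), numeric(1))
  jack <- jack[!is.na(jack)]
  seJack <- if (length(jack) >= 2)
    sqrt((length(jack) - 1) / length(jack) *
           sum((jack - mean(jack))^2)) else NA_real_
  clamped <- abs(rb) > 1
  list(rb = max(-1, min(1, rb)), se_rb = seJack, n_pairs = n,
       clamped = clamped)
}

#' Test for a difference between two Pearson correlations
#'
#' Fisher z-transformation: `z_k = atanh(r_k)`, statistic
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal p-value.
#'
#' @param r1,r2 sample correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list `statistic`, `p`.
#' @export
fisherRDifference <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(statistic = z, p = 2 * pnorm(-abs(z)))
}
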