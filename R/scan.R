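## Genome-wide PAI scan: bait definition, pair enumeration, orientation,
## SMR + HEIDI per pair, multiple-testing control and summaries.

#' Bonferroni significance threshold
#'
#' @param nTests number of tests performed (>= 1).
#' @param alpha family-wise error rate.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(10416)  # 4.8e-6
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  if (length(nTests) != 1 || !is.finite(nTests) || nTests < 1)
    .stopf("nTests must be a single number >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / nTests
}

## promoter intervals (indices into `promoters`) containing a 1-based point
.promoterHits <- function(chrom, bp, promoters) {
  ov <- GenomicRanges::findOverlaps(.pointRanges(chrom, bp), promoters)
  split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
}

#' Define bait probes for the scan
#'
#' Baits are probes located inside a promoter interval, outside any
#' blacklist region, and carrying at least one cis instrument at the
#' configured threshold. Each bait's top instrument and the variance in
#' DNAm it explains (q2, used for pair orientation) are recorded.
#'
#' @param mqtl an [MqtlTable-class].
#' @param promoters `GRanges` of promoter intervals.
#' @param cfg a [scanConfig()].
#' @return data.frame of baits (`probe_id, chrom, bp, gene, top_snp,
#'   top_p, q2, promoter_idx`), sorted by (chrom, bp, probe_id).
#' @export
defineBaits <- function(mqtl, promoters, cfg = scanConfig()) {
  pr <- probeInfo(mqtl)
  hits <- .promoterHits(pr$chrom, pr$bp, promoters)
  inProm <- as.character(seq_len(nrow(pr))) %in% names(hits)
  if (!is.null(cfg$blacklist)) {
    bl <- GenomicRanges::countOverlaps(.pointRanges(pr$chrom, pr$bp),
                                       cfg$blacklist) > 0
    inProm <- inProm & !bl
  }
  idx <- which(inProm)
  rows <- lapply(idx, function(i) {
    cs <- cisStats(mqtl, pr$probe_id[i])
    top <- topInstrument(cs, cfg$instrumentP)
    if (is.null(top)) return(NULL)
    data.frame(probe_id = pr$probe_id[i], chrom = pr$chrom[i], bp = pr$bp[i],
               gene = if ("gene" %in% names(pr)) pr$gene[i] else NA_character_,
               top_snp = top$snp_id, top_p = top$p,
               q2 = varianceExplained(top$b, top$se, top$freq, top$n),
               stringsAsFactors = FALSE)
  })
  baits <- do.call(rbind, rows)
  if (is.null(baits) || !nrow(baits))
    .stopf("no bait probes: no promoter probe has an instrument at p < %g",
           cfg$instrumentP)
  baits <- baits[order(baits$chrom, baits$bp, baits$probe_id), , drop = FALSE]
  rownames(baits) <- NULL
  baits
}

#' Enumerate candidate outcome probes for one bait
#'
#' All probes on the bait's chromosome within the pairing window, excluding
#' the bait itself and any probe lying inside one of the bait's own promoter
#' intervals (interactions within a promoter are not tested).
#'
#' @param bait one row of [defineBaits()] output.
#' @param probes probe annotation data.frame (`probe_id, chrom, bp`).
#' @param promoters `GRanges` of promoter intervals.
#' @param cfg a [scanConfig()].
#' @return data.frame of candidate probes.
#' @export
enumeratePairs <- function(bait, probes, promoters, cfg = scanConfig()) {
  cand <- probes[probes$chrom == bait$chrom &
                   abs(probes$bp - bait$bp) <= cfg$pairWindow &
                   probes$probe_id != bait$probe_id, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  baitProm <- GenomicRanges::findOverlaps(
    .pointRanges(bait$chrom, bait$bp), promoters)
  baitProm <- S4Vectors::subjectHits(baitProm)
  if (length(baitProm)) {
    inBaitProm <- GenomicRanges::countOverlaps(
      .pointRanges(cand$chrom, cand$bp), promoters[baitProm]) > 0
    cand <- cand[!inBaitProm, , drop = FALSE]
  }
  cand[order(cand$bp, cand$probe_id), , drop = FALSE]
}

#' Orient a promoter-promoter pair
#'
#' For two probes in different promoter regions the probe whose top
#' cis-mQTL explains more DNAm variance is the exposure; ties are broken by
#' the smaller top-instrument p-value, then the smaller position. When q2
#' is undefined on either side the orientation falls back to the smaller
#' top-instrument p directly.
#'
#' @param a,b bait rows (from [defineBaits()]).
#' @return list `exposure`, `outcome` (the two rows, ordered).
#' @export
orientPromoterPair <- function(a, b) {
  pick <- function(first) if (first) list(exposure = a, outcome = b)
  else list(exposure = b, outcome = a)
  if (!is.na(a$q2) && !is.na(b$q2) && a$q2 != b$q2) return(pick(a$q2 > b$q2))
  if (a$top_p != b$top_p) return(pick(a$top_p < b$top_p))
  pick(a$bp <= b$bp)
}

## SMR + HEIDI for one exposure/outcome probe pair; returns a 1-row record
.testPair <- function(expoStats, outStats, top, ld, cfg) {
  rec <- list(b_xy = NA_real_, se_xy = NA_real_, t_smr = NA_real_,
              p_smr = NA_real_, nsnp_heidi = NA_integer_,
              p_heidi = NA_real_, status = "ok")
  out <- alignAlleles(outStats, expoStats, ambiguous = cfg$ambiguousSnps)
  oi <- match(top$snp_id, out$snp_id)
  if (is.na(oi)) {
    rec$status <- "no_outcome_stat"
    return(rec)
  }
  s <- smrTest(top$b, top$se, out$b[oi], out$se[oi])
  rec[c("b_xy", "se_xy", "t_smr", "p_smr")] <-
    s[c("b_xy", "se_xy", "t_smr", "p_smr")]

  shared <- intersect(expoStats$snp_id, out$snp_id)
  shared <- intersect(shared, ldSnps(ld))
  es <- expoStats[match(shared, expoStats$snp_id), , drop = FALSE]
  ## only instrument-eligible SNPs (plus the top) can enter HEIDI; drop the
  ## rest before touching the LD matrix
  es <- es[es$snp_id == top$snp_id |
             (is.finite(es$p) & es$p < cfg$heidiPInclude), , drop = FALSE]
  shared <- es$snp_id
  if (!top$snp_id %in% shared) {
    rec$status <- "no_ld_top"
    return(rec)
  }
  ldr <- tryCatch(
    .ldSubmatrix(ld, shared, a1 = es$a1, a2 = es$a2),
    error = function(e) NULL)
  if (is.null(ldr)) {
    rec$status <- "ld_mismatch"
    return(rec)
  }
  sel <- heidiSelectSnps(es, ldr, top$snp_id,
                         pInclude = cfg$heidiPInclude,
                         r2Cap = cfg$heidiR2Cap,
                         r2MinTop = cfg$heidiR2MinTop,
                         maxSnps = cfg$heidiMaxSnps)
  if (length(sel) < cfg$heidiMinSnps) {
    rec$nsnp_heidi <- length(sel)
    rec$status <- "heidi_too_few"
    return(rec)
  }
  ei <- match(sel, es$snp_id)
  oi2 <- match(sel, out$snp_id)
  hc <- tryCatch(
    heidiCovariance(es$b[ei], es$se[ei], out$b[oi2], out$se[oi2],
                    ldr[sel, sel, drop = FALSE], topIndex = 1L),
    error = function(e) NULL)
  if (is.null(hc)) {
    rec$status <- "heidi_degenerate"
    return(rec)
  }
  ht <- heidiTest(hc$d, hc$V, method = cfg$heidiMethod)
  rec$p_heidi <- ht$p_heidi
  rec$nsnp_heidi <- ht$nsnp
  rec
}

#' Run the promoter-anchored interaction scan
#'
#' For every bait and candidate outcome probe: harmonise alleles, run the
#' SMR ratio test at the bait's top instrument and the HEIDI test over the
#' selected instruments, then apply Bonferroni and HEIDI classification via
#' [classifySignificant()]. Promoter-promoter pairs are tested in exactly
#' one orientation (higher q2 as exposure) so no (A,B)/(B,A) duplicates
#' occur. Per-pair failures (no outcome statistic at the instrument, no LD
#' coverage, degenerate covariance) are recorded in the `status` column and
#' never abort the scan. Output is deterministic given the inputs.
#'
#' @param mqtl an [MqtlTable-class].
#' @param promoters `GRanges` of promoter intervals.
#' @param ld an [LdMatrix-class], or a genotype matrix (samples x SNPs,
#'   passed through [ldFromGenotypes()]).
#' @param cfg a [scanConfig()].
#' @return a [PaiSet-class].
#' @export
runPaiScan <- function(mqtl, promoters, ld, cfg = scanConfig()) {
  if (!is(ld, "LdMatrix")) ld <- ldFromGenotypes(ld)
  baits <- defineBaits(mqtl, promoters, cfg)
  probes <- probeInfo(mqtl)
  baitIds <- baits$probe_id
  statsByProbe <- split(mqtlStats(mqtl), mqtlStats(mqtl)$probe_id)

  recs <- list()
  for (bi in seq_len(nrow(baits))) {
    bait <- baits[bi, , drop = FALSE]
    cand <- enumeratePairs(bait, probes, promoters, cfg)
    if (!nrow(cand)) next
    expoStats <- statsByProbe[[bait$probe_id]]
    top <- topInstrument(expoStats, cfg$instrumentP)
    for (ci in seq_len(nrow(cand))) {
      outProbe <- cand[ci, , drop = FALSE]
      ## promoter-promoter pairs: test only in the chosen orientation
      if (outProbe$probe_id %in% baitIds) {
        other <- baits[baits$probe_id == outProbe$probe_id, , drop = FALSE]
        ori <- orientPromoterPair(bait, other)
        if (ori$exposure$probe_id != bait$probe_id) next
      }
      outStats <- statsByProbe[[outProbe$probe_id]]
      rec <- if (is.null(outStats))
        list(b_xy = NA_real_, se_xy = NA_real_, t_smr = NA_real_,
             p_smr = NA_real_, nsnp_heidi = NA_integer_,
             p_heidi = NA_real_, status = "no_outcome_stats")
      else .testPair(expoStats, outStats, top, ld, cfg)
      recs[[length(recs) + 1L]] <- data.frame(
        expo_probe = bait$probe_id, expo_chr = bait$chrom,
        expo_bp = bait$bp, expo_gene = bait$gene,
        outcome_probe = outProbe$probe_id, outcome_bp = outProbe$bp,
        top_snp = top$snp_id,
        b_xy = rec$b_xy, se_xy = rec$se_xy, t_smr = rec$t_smr,
        p_smr = rec$p_smr, nsnp_heidi = rec$nsnp_heidi,
        p_heidi = rec$p_heidi,
        distance = abs(outProbe$bp - bait$bp),
        status = rec$status, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(expo_probe = character(0))
  rownames(records) <- NULL
  pai <- new("PaiSet", records = records,
             nTests = sum(is.finite(records$p_smr)),
             config = unclass(cfg))
  classifySignificant(pai, cfg)
}

#' Classify scan records as significant PAIs
#'
#' `pass_smr`: SMR p strictly below the Bonferroni threshold
#' `alpha / nTests`, with `nTests` the number of pairs with a computed SMR
#' p-value. `pass_heidi`: HEIDI p strictly above the cutoff (NA fails,
#' conservatively, unless `heidiNaPass`). A PAI passes both.
#'
#' @param pai a [PaiSet-class].
#' @param cfg a [scanConfig()].
#' @return the [PaiSet-class] with `pass_smr`, `pass_heidi`, `is_pai`
#'   columns and the Bonferroni threshold stored in `config$smrThreshold`.
#' @export
classifySignificant <- function(pai, cfg = scanConfig()) {
  r <- pai@records
  nT <- sum(is.finite(r$p_smr))
  if (nrow(r)) {
    thr <- if (nT >= 1) bonferroniThreshold(nT, cfg$alpha) else NA_real_
    r$pass_smr <- is.finite(r$p_smr) & !is.na(thr) & r$p_smr < thr
    r$pass_heidi <- ifelse(is.na(r$p_heidi), isTRUE(cfg$heidiNaPass),
                           r$p_heidi > cfg$heidiCutoff)
    r$is_pai <- r$pass_smr & r$pass_heidi
  } else thr <- NA_real_
  cfgOut <- unclass(cfg)
  cfgOut$smrThreshold <- thr
  new("PaiSet", records = r, nTests = as.integer(nT), config = cfgOut)
}

#' Summarise a classified scan
#'
#' @param pai a [PaiSet-class] after classification.
#' @return list with counts (tested pairs, significant PAIs, unique probes,
#'   unique exposures, genes), per-bait outcome counts, and the distance
#'   distribution of the significant PAIs (mean, median, type-7 quantiles,
#'   fraction beyond 1 Mb).
#' @export
summarizePais <- function(pai) {
  r <- paiRecords(pai)
  sig <- paiSignificant(pai)
  perBait <- if (nrow(sig)) as.numeric(table(sig$expo_probe)) else numeric(0)
  d <- sig$distance
  list(nTested = nrow(r),
       nTests = nTests(pai),
       nPai = nrow(sig),
       nUniqueProbes = length(unique(c(sig$expo_probe, sig$outcome_probe))),
       nExposures = length(unique(sig$expo_probe)),
       nGenes = length(unique(sig$expo_gene[!is.na(sig$expo_gene)])),
       outcomesPerBait = list(mean = if (length(perBait)) mean(perBait) else NA,
                              median = if (length(perBait)) median(perBait) else NA),
       distance = list(
         mean = if (length(d)) mean(d) else NA,
         median = if (length(d)) median(d) else NA,
         quantiles = if (length(d))
           quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7)
         else setNames(rep(NA_real_, 5),
                       c("5%", "25%", "50%", "75%", "95%")),
         fracOver1Mb = if (length(d)) mean(d > 1e6) else NA))
}
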