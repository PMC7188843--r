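## Resampling- and contingency-based enrichment of predicted interactions
## against external annotations. Null sets are matched on a covariate
## (pair distance, probe DNAm variance, gene-pair distance) by binning the
## tested universe and drawing controls from each target's bin.

#' Draw covariate-matched control sets from a universe
#'
#' The universe is binned on a matching covariate; each null set replaces
#' every target by a uniform draw from the target's bin. Distance matching
#' uses 20 equal-width bins of log10(distance) over the universe range;
#' variance matching uses deciles (`binType = "quantile"`, `nBins = 10`).
#' Empty bins escalate symmetrically to adjacent bins until a donor exists.
#'
#' @param targetValues covariate values of the target set.
#' @param universeValues covariate values of the universe (the pairs/probes/
#'   genes actually tested, which controls are drawn from).
#' @param nSets number of null sets.
#' @param nBins number of bins.
#' @param binType "width" (equal-width bins) or "quantile".
#' @param logScale bin on log10 of the covariate (positive values only).
#' @param seed integer seed; see [deriveSeed()] for sub-seed derivation.
#' @return integer matrix (`nSets` x `length(targetValues)`) of indices into
#'   the universe.
#' @export
sampleMatchedControls <- function(targetValues, universeValues, nSets = 1000,
                                  nBins = 20, binType = c("width", "quantile"),
                                  logScale = TRUE, seed = 1L) {
  binType <- match.arg(binType)
  stopifnot(length(universeValues) >= 1, nSets >= 1)
  tv <- as.numeric(targetValues)
  uv <- as.numeric(universeValues)
  if (logScale) {
    stopifnot(all(tv > 0), all(uv > 0))
    tv <- log10(tv); uv <- log10(uv)
  }
  breaks <- if (binType == "width")
    seq(min(uv), max(uv), length.out = nBins + 1)
  else unique(quantile(uv, seq(0, 1, length.out = nBins + 1), type = 7))
  nb <- length(breaks) - 1L
  cutBin <- function(x) pmin(pmax(findInterval(x, breaks,
                                               rightmost.closed = TRUE,
                                               all.inside = TRUE), 1L), nb)
  ub <- cutBin(uv)
  tb <- cutBin(tv)
  byBin <- split(seq_along(uv), factor(ub, levels = seq_len(nb)))
  pools <- lapply(seq_len(nb), function(b) {
    w <- 0L
    repeat {
      lo <- max(1L, b - w); hi <- min(nb, b + w)
      pool <- unlist(byBin[lo:hi], use.names = FALSE)
      if (length(pool)) return(pool)
      w <- w + 1L
    }
  })
  set.seed(seed)
  out <- matrix(0L, nrow = nSets, ncol = length(tv))
  for (j in seq_along(tv)) {
    pool <- pools[[tb[j]]]
    out[, j] <- if (length(pool) == 1L) rep.int(pool, nSets)
    else sample(pool, nSets, replace = TRUE)
  }
  out
}

#' Empirical enrichment against a resampling null
#'
#' The (r+1)/(R+1) estimator: for the enrichment direction,
#' `p = (#\{null >= observed\} + 1) / (R + 1)`; for depletion the
#' inequality flips. With 1000 null sets and no null value reaching the
#' observed statistic, the p-value is reported at its floor and flagged
#' truncated (displayed as "< 0.001").
#'
#' @param observed observed statistic.
#' @param nullValues numeric vector of resampled statistics.
#' @param direction "greater" (enrichment) or "less" (depletion).
#' @return an [EnrichmentResult-class].
#' @export
empiricalEnrichment <- function(observed, nullValues,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(nullValues) >= 1)
  R <- length(nullValues)
  r <- if (direction == "greater") sum(nullValues >= observed)
  else sum(nullValues <= observed)
  nm <- mean(nullValues)
  fold <- if (nm != 0) observed / nm else NA_real_
  if (nm == 0) warning("null mean is 0; fold enrichment undefined")
  new("EnrichmentResult", observed = as.numeric(observed),
      nullValues = as.numeric(nullValues), fold = fold,
      empiricalP = (r + 1) / (R + 1), truncated = r == 0L,
      direction = direction)
}

#' Loop enrichment by 2x2 contingency tables over a threshold sweep
#'
#' For each loop p-value threshold t, loops with `p <= t` are called
#' significant and every tested pair is classified (predicted vs not) x
#' (in a significant loop vs not). Fold enrichment is the ratio of the
#' in-loop proportions, significance by two-sided Fisher's exact test, and
#' a 95% CI on the fold from the normal approximation on the log scale.
#'
#' @param universePairs pair frame of all tested pairs (see [pairInTads()]).
#' @param predicted logical vector marking the predicted subset.
#' @param loops `Pairs` with a `p` metadata column.
#' @param pThresholds numeric vector of thresholds.
#' @param pad anchor padding in bp.
#' @return data.frame, one row per threshold: counts, fold, CI, Fisher p.
#' @export
fisherLoopEnrichment <- function(universePairs, predicted, loops,
                                 pThresholds = c(0.05, 0.01, 1e-3, 1e-4),
                                 pad = 0) {
  pf <- .asPairFrame(universePairs)
  stopifnot(length(predicted) == nrow(pf), is.logical(predicted))
  lp <- S4Vectors::mcols(loops)$p
  if (is.null(lp)) .stopf("loops must carry a p metadata column")
  N <- nrow(pf)
  out <- lapply(pThresholds, function(t) {
    sig <- loops[lp <= t]
    inLoop <- if (length(sig)) pairInLoops(pf, sig, pad) else
      rep(FALSE, N)
    a <- sum(predicted & inLoop); b <- sum(predicted & !inLoop)
    cc <- sum(!predicted & inLoop); dd <- N - a - b - cc
    if ((a + b) == 0 || (a + cc) == 0) {
      return(data.frame(p_threshold = t, a = a, b = b, c = cc, d = dd,
                        fold = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        fisher_p = NA_real_))
    }
    fold <- (a / (a + b)) / ((a + cc) / N)
    seLog <- sqrt(max(0, 1 / max(a, 0.5) - 1 / (a + b) +
                        1 / (a + cc) - 1 / N))
    fp <- fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE))$p.value
    data.frame(p_threshold = t, a = a, b = b, c = cc, d = dd, fold = fold,
               ci_lo = exp(log(fold) - 1.96 * seLog),
               ci_hi = exp(log(fold) + 1.96 * seLog),
               fisher_p = fp)
  })
  do.call(rbind, out)
}

#' Enrichment of promoter-interacting DNAm sites in chromatin states
#'
#' Maps the PIDSs (outcome probes of significant PAIs) to state categories
#' by position and compares the per-state proportions to null sets of
#' control probes matched on DNAm variance (deciles over the universe),
#' drawn from the probes tested in the analysis.
#'
#' @param pids probe data.frame (`chrom, bp, dnam_variance`).
#' @param states labelled `GRanges` of chromatin states.
#' @param universe probe data.frame of all tested outcome probes, with
#'   `dnam_variance`.
#' @param nSets number of null sets.
#' @param seed integer seed.
#' @return named list of [EnrichmentResult-class], one per state label plus
#'   "unannotated" (states with zero observed and null proportion omitted).
#' @export
pidsStateEnrichment <- function(pids, states, universe, nSets = 1000,
                                seed = 1L) {
  stopifnot(all(c("dnam_variance") %in% names(pids)),
            all(c("dnam_variance") %in% names(universe)))
  obsLab <- stateAtProbes(pids, states)
  uniLab <- stateAtProbes(universe, states)
  labels <- sort(unique(c(obsLab, uniLab)))
  ctrl <- sampleMatchedControls(pids$dnam_variance, universe$dnam_variance,
                                nSets = nSets, nBins = 10,
                                binType = "quantile", logScale = FALSE,
                                seed = deriveSeed(seed, "pids_state"))
  prop <- function(lab) vapply(labels, function(s) mean(lab == s), numeric(1))
  obsP <- prop(obsLab)
  nullP <- t(apply(ctrl, 1, function(idx) prop(uniLab[idx])))
  out <- lapply(seq_along(labels), function(i) {
    if (obsP[i] == 0 && all(nullP[, i] == 0)) return(NULL)
    empiricalEnrichment(obsP[i], nullP[, i], "greater")
  })
  names(out) <- labels
  out[!vapply(out, is.null, logical(1))]
}

## unique eQTLs of each pair's own gene within +/- window/2 of its outcome
## probe, counted once across pairs
.countEqtlHits <- function(pairs, eqtlByGene, window) {
  half <- window / 2
  hit <- character(0)
  for (i in seq_len(nrow(pairs))) {
    e <- eqtlByGene[[pairs$gene[i]]]
    if (is.null(e)) next
    w <- e$chrom == pairs$chrom[i] & abs(e$bp - pairs$outcome_bp[i]) <= half
    if (any(w)) hit <- c(hit, e$snp_id[w])
  }
  length(unique(hit))
}

#' Enrichment of cis-eQTLs in PIDS windows of their target genes
#'
#' Observed statistic: the number of distinct eQTLs falling within a
#' centred window (default 10 kb) of at least one PIDS predicted for the
#' eQTL's own target gene. The null maps the same eQTL list onto
#' distance-matched control gene-probe pairs resampled from the tested
#' universe (each control pair keeps its own bait gene).
#'
#' @param eqtls data.frame (`snp_id, chrom, bp, gene, p`).
#' @param sigPairs significant pairs: data.frame with `gene, chrom,
#'   outcome_bp, distance` (gene = the bait promoter's gene).
#' @param universePairs all tested pairs, same columns.
#' @param window total window in bp.
#' @param nSets,seed resampling controls.
#' @return an [EnrichmentResult-class].
#' @export
eqtlPidsEnrichment <- function(eqtls, sigPairs, universePairs,
                               window = 10000, nSets = 1000, seed = 1L) {
  need <- c("gene", "chrom", "outcome_bp", "distance")
  stopifnot(all(need %in% names(sigPairs)), all(need %in% names(universePairs)))
  eqtlByGene <- split(eqtls, eqtls$gene)
  obs <- .countEqtlHits(sigPairs, eqtlByGene, window)
  ctrl <- sampleMatchedControls(sigPairs$distance, universePairs$distance,
                                nSets = nSets,
                                seed = deriveSeed(seed, "eqtl_pids"))
  nulls <- vapply(seq_len(nSets), function(s) {
    .countEqtlHits(universePairs[ctrl[s, ], , drop = FALSE],
                   eqtlByGene, window)
  }, numeric(1))
  empiricalEnrichment(obs, nulls, "greater")
}

#' Enrichment of genes across expression-activity groups
#'
#' Genes are summarised by their median TPM across samples and split into
#' five groups: inactive (median TPM < 0.1) plus quartiles of the active
#' genes (quartile breaks computed over the active universe genes). The
#' observed per-group counts of the genes of interest are compared to
#' counts of randomly resampled universe genes.
#'
#' @param genes character vector of genes of interest.
#' @param tpm gene x sample TPM matrix.
#' @param universe character vector of universe genes.
#' @param nSets,seed resampling controls.
#' @return list: `groups` (per-gene assignment), `counts` (observed),
#'   `results` (named list of [EnrichmentResult-class] per group),
#'   `nMissing` (genes of interest absent from the matrix).
#' @export
expressionGroupEnrichment <- function(genes, tpm, universe, nSets = 1000,
                                      seed = 1L) {
  universe <- intersect(universe, rownames(tpm))
  stopifnot(length(universe) >= 5)
  present <- intersect(genes, rownames(tpm))
  nMissing <- length(genes) - length(present)
  med <- apply(tpm[universe, , drop = FALSE], 1, median)
  active <- med >= 0.1
  qs <- quantile(med[active], c(0.25, 0.5, 0.75), type = 7)
  grp <- function(g) {
    m <- med[g]
    ifelse(m < 0.1, "inactive",
           ifelse(m <= qs[1], "Q1",
                  ifelse(m <= qs[2], "Q2", ifelse(m <= qs[3], "Q3", "Q4"))))
  }
  lev <- c("inactive", "Q1", "Q2", "Q3", "Q4")
  cnt <- function(g) table(factor(grp(g), levels = lev))
  obs <- cnt(present)
  set.seed(deriveSeed(seed, "expression_groups"))
  nulls <- t(vapply(seq_len(nSets), function(s)
    as.numeric(cnt(sample(universe, length(present)))), numeric(length(lev))))
  colnames(nulls) <- lev
  res <- lapply(lev, function(g)
    empiricalEnrichment(as.numeric(obs[g]), nulls[, g], "greater"))
  names(res) <- lev
  list(groups = setNames(grp(present), present),
       counts = obs, results = res, nMissing = nMissing)
}

#' Co-expression enrichment of promoter-promoter interacting gene pairs
#'
#' Observed statistic: the mean Pearson correlation of expression across
#' samples over the gene pairs of interest. The null resamples
#' distance-matched control gene pairs from the tested universe. Pairs with
#' a gene absent from the matrix or with zero expression variance are
#' dropped (and counted).
#'
#' @param genePairs data.frame (`gene1, gene2, distance`).
#' @param tpm gene x sample TPM matrix.
#' @param universePairs data.frame of tested gene pairs, same columns.
#' @param nSets,seed resampling controls.
#' @return an [EnrichmentResult-class] with attributes `nDropped` and
#'   `pairR` (per-pair correlations of the target set).
#' @export
coexpressionEnrichment <- function(genePairs, tpm, universePairs,
                                   nSets = 1000, seed = 1L) {
  pairCor <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      g1 <- df$gene1[i]; g2 <- df$gene2[i]
      if (!g1 %in% rownames(tpm) || !g2 %in% rownames(tpm))
        return(NA_real_)
      x <- tpm[g1, ]; y <- tpm[g2, ]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    }, numeric(1))
  }
  rObs <- pairCor(genePairs)
  nDropped <- sum(is.na(rObs))
  rUni <- pairCor(universePairs)
  ok <- !is.na(rUni)
  ctrl <- sampleMatchedControls(genePairs$distance[!is.na(rObs)],
                                universePairs$distance[ok],
                                nSets = nSets,
                                seed = deriveSeed(seed, "coexpression"))
  rUniOk <- rUni[ok]
  nulls <- vapply(seq_len(nSets), function(s) mean(rUniOk[ctrl[s, ]]),
                  numeric(1))
  res <- empiricalEnrichment(mean(rObs, na.rm = TRUE), nulls, "greater")
  attr(res, "nDropped") <- nDropped
  attr(res, "pairR") <- rObs
  res
}
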