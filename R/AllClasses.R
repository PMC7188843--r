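#' @import methods
#' @importFrom stats cor pchisq pnorm pt qnorm quantile rbinom rnorm runif
#'   sd var median fisher.test ks.test integrate setNames complete.cases
#' @importFrom utils head
NULL

## column contracts shared by validity methods and readers
.MQTL_COLS <- c("probe_id", "probe_chr", "probe_bp", "snp_id", "snp_chr",
                "snp_bp", "a1", "a2", "freq", "b", "se", "p", "n")
.MQTL_MANDATORY <- setdiff(.MQTL_COLS, c("freq", "n"))

.PROBE_COLS <- c("probe_id", "chrom", "bp")

#' MqtlTable: validated cis-mQTL summary statistics
#'
#' Holds per-probe cis-mQTL summary statistics (SNP metadata plus association
#' effect, standard error, p-value and sample size), restricted to a cis
#' window around each probe, together with probe annotation. Effects are in
#' standard-deviation units of DNA methylation level per copy of the effect
#' allele `a1`.
#'
#' @slot stats `data.frame` with columns `probe_id, probe_chr, probe_bp,
#'   snp_id, snp_chr, snp_bp, a1, a2, freq, b, se, p, n` (freq/n may be NA).
#' @slot probes `data.frame` of probe annotation (`probe_id, chrom, bp`, and
#'   optionally `gene`, `dnam_variance`).
#' @slot nRejected integer, rows dropped by validation on read.
#' @slot cisWindow numeric, the cis window (bp) rows were validated against.
#'
#' @export
setClass("MqtlTable",
  representation(stats = "data.frame", probes = "data.frame",
                 nRejected = "integer", cisWindow = "numeric"),
  prototype(nRejected = 0L, cisWindow = 2e6))

setValidity("MqtlTable", function(object) {
  st <- object@stats
  msg <- character()
  miss <- setdiff(.MQTL_COLS, names(st))
  if (length(miss))
    msg <- c(msg, paste("stats missing columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(st)) {
    if (any(st$se <= 0, na.rm = TRUE)) msg <- c(msg, "se must be > 0")
    if (any(st$p <= 0 | st$p > 1, na.rm = TRUE)) msg <- c(msg, "p must be in (0,1]")
    if (any(st$a1 == st$a2)) msg <- c(msg, "a1 and a2 must differ")
    bad <- !is.na(st$freq) & (st$freq <= 0 | st$freq >= 1)
    if (any(bad)) msg <- c(msg, "freq must be in (0,1)")
    if (anyDuplicated(st[, c("probe_id", "snp_id")]))
      msg <- c(msg, "duplicate (probe_id, snp_id) rows")
    if (length(object@cisWindow) == 1 && is.finite(object@cisWindow)) {
      far <- abs(st$snp_bp - st$probe_bp) > object@cisWindow
      if (any(far)) msg <- c(msg, "SNP outside the cis window of its probe")
    }
  }
  pm <- setdiff(.PROBE_COLS, names(object@probes))
  if (length(pm))
    msg <- c(msg, paste("probes missing columns:", paste(pm, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' LdMatrix: signed SNP correlation matrix from a reference panel
#'
#' Pairwise signed correlations r_ij between SNP allele counts, aligned to
#' each SNP's `a1` coding (counts of `a1` copies).
#'
#' @slot snps character vector of SNP ids (row/column order of `r`).
#' @slot a1,a2 effect / other allele the counts refer to.
#' @slot r symmetric numeric matrix of correlations, unit diagonal.
#'
#' @export
setClass("LdMatrix",
  representation(snps = "character", a1 = "character", a2 = "character",
                 r = "matrix"))

setValidity("LdMatrix", function(object) {
  m <- object@r
  k <- length(object@snps)
  msg <- character()
  if (!is.numeric(m) || nrow(m) != k || ncol(m) != k)
    msg <- c(msg, "r must be a k x k numeric matrix matching snps")
  if (length(object@a1) != k || length(object@a2) != k)
    msg <- c(msg, "a1/a2 must match snps in length")
  if (!length(msg) && k) {
    if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) msg <- c(msg, "r must have unit diagonal")
    if (any(abs(m) > 1 + 1e-8)) msg <- c(msg, "|r| must be <= 1")
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) msg <- c(msg, "r must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' PaiSet: results of a promoter-anchored interaction scan
#'
#' One row per exposure–outcome test: the SMR ratio estimate and Wald test,
#' the HEIDI heterogeneity test, and the pass flags assigned by
#' [classifySignificant()].
#'
#' @slot records `data.frame` of per-pair results (see [runPaiScan()]).
#' @slot nTests integer, number of pairs with a computed SMR p-value (the
#'   Bonferroni denominator).
#' @slot config list, the [scanConfig()] the scan was run with.
#'
#' @export
setClass("PaiSet",
  representation(records = "data.frame", nTests = "integer", config = "list"),
  prototype(nTests = 0L, config = list()))

#' EnrichmentResult: observed statistic against a resampling null
#'
#' @slot observed observed statistic.
#' @slot nullValues numeric vector, the resampled null distribution.
#' @slot fold observed / mean(null).
#' @slot empiricalP (r+1)/(R+1) empirical p-value.
#' @slot truncated TRUE when no null value reaches the observed value, i.e.
#'   the p-value is reported at its resolution floor.
#' @slot direction "greater" (enrichment) or "less" (depletion).
#'
#' @export
setClass("EnrichmentResult",
  representation(observed = "numeric", nullValues = "numeric",
                 fold = "numeric", empiricalP = "numeric",
                 truncated = "logical", direction = "character"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (!length(object@nullValues)) msg <- c(msg, "nullValues must be non-empty")
  R <- length(object@nullValues)
  if (length(object@empiricalP) == 1 &&
      (object@empiricalP < 1 / (R + 1) - 1e-12 || object@empiricalP > 1))
    msg <- c(msg, "empiricalP outside [1/(R+1), 1]")
  if (!object@direction %in% c("greater", "less"))
    msg <- c(msg, "direction must be 'greater' or 'less'")
  if (length(msg)) msg else TRUE
})
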