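## Readers and writers for the external formats the pipeline touches.
## Intervals are carried internally as GRanges (1-based, closed), converted
## from/to the 0-based half-open BED convention only at the I/O boundary;
## point features (probes, SNPs) are 1-based positions throughout.

#' Construct an MqtlTable from in-memory tables
#'
#' @param stats data.frame of probe-SNP summary rows (see [readMqtlSummary()]
#'   for the column contract).
#' @param probes optional probe annotation (`probe_id, chrom, bp` plus
#'   optional `gene`, `dnam_variance`); derived from `stats` when absent.
#' @param nRejected integer count of rows dropped by upstream validation.
#' @param cisWindow cis window in bp the rows are validated against.
#' @return an [MqtlTable-class] object.
#' @export
MqtlTable <- function(stats, probes = NULL, nRejected = 0L, cisWindow = 2e6) {
  stats <- as.data.frame(stats)
  if (!"freq" %in% names(stats)) stats$freq <- NA_real_
  if (!"n" %in% names(stats)) stats$n <- NA_real_
  stats <- stats[, .MQTL_COLS, drop = FALSE]
  if (is.null(probes)) {
    u <- !duplicated(stats$probe_id)
    probes <- data.frame(probe_id = stats$probe_id[u],
                         chrom = stats$probe_chr[u],
                         bp = stats$probe_bp[u],
                         stringsAsFactors = FALSE)
  }
  new("MqtlTable", stats = stats, probes = as.data.frame(probes),
      nRejected = as.integer(nRejected), cisWindow = cisWindow)
}

#' Read cis-mQTL summary statistics
#'
#' Reads a tab-separated file with header columns `probe_id, probe_chr,
#' probe_bp, snp_id, snp_chr, snp_bp, a1, a2, freq, b, se, p, n`; the
#' `freq` and `n` columns are optional (frequency is needed only for the
#' 2p(1-p)b^2 variance-explained formula, which has a z-based fallback).
#' Effects must be in SD units of DNAm level per copy of `a1`.
#'
#' Rows failing validation (se <= 0, p outside (0,1], identical alleles,
#' frequency outside (0,1), SNP outside the cis window) are dropped and
#' counted in `nRejected()`. Duplicate (probe, snp) rows keep the row with
#' the smaller p-value.
#'
#' @param path file path.
#' @param probes optional probe annotation data.frame or TSV path
#'   (`probe_id, chrom, bp[, gene, dnam_variance]`).
#' @param cisWindow cis window in bp (default 2 Mb).
#' @param chromStyle chromosome naming normalisation, see [normChrom()].
#' @param verbose emit a message per validation problem class.
#' @return an [MqtlTable-class].
#' @export
readMqtlSummary <- function(path, probes = NULL, cisWindow = 2e6,
                            chromStyle = "asis", verbose = FALSE) {
  st <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  miss <- setdiff(.MQTL_MANDATORY, names(st))
  if (length(miss))
    .stopf("mQTL file %s missing mandatory column(s): %s", path,
           paste(miss, collapse = ", "))
  if (!"freq" %in% names(st)) st$freq <- NA_real_
  if (!"n" %in% names(st)) st$n <- NA_real_
  st$probe_chr <- normChrom(st$probe_chr, chromStyle)
  st$snp_chr <- normChrom(st$snp_chr, chromStyle)

  bad <- (!is.finite(st$se) | st$se <= 0) |
    (!is.finite(st$p) | st$p <= 0 | st$p > 1) |
    (st$a1 == st$a2) |
    (!is.na(st$freq) & (st$freq <= 0 | st$freq >= 1)) |
    (st$probe_bp < 1 | st$snp_bp < 1) |
    (abs(st$snp_bp - st$probe_bp) > cisWindow)
  nRej <- sum(bad)
  if (nRej) .logMsg(verbose, nRej, " row(s) rejected by validation in ", path)
  st <- st[!bad, , drop = FALSE]

  ## duplicate (probe, snp): keep the smaller p, deterministically
  o <- order(st$probe_id, st$snp_id, st$p, st$snp_bp)
  st <- st[o, , drop = FALSE]
  dup <- duplicated(st[, c("probe_id", "snp_id")])
  if (any(dup))
    .logMsg(verbose, sum(dup), " duplicate (probe, snp) row(s) collapsed")
  st <- st[!dup, , drop = FALSE]
  rownames(st) <- NULL

  if (is.character(probes)) probes <- readProbeTable(probes, chromStyle)
  MqtlTable(st, probes = probes, nRejected = nRej, cisWindow = cisWindow)
}

#' Read a probe annotation table
#'
#' TSV with header `probe_id, chrom, bp` and optional `gene`,
#' `dnam_variance` columns.
#'
#' @inheritParams readMqtlSummary
#' @return data.frame.
#' @export
readProbeTable <- function(path, chromStyle = "asis") {
  pr <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  miss <- setdiff(.PROBE_COLS, names(pr))
  if (length(miss))
    .stopf("probe table %s missing column(s): %s", path,
           paste(miss, collapse = ", "))
  pr$chrom <- normChrom(pr$chrom, chromStyle)
  pr
}

#' Read interval (BED) or paired-interval (BEDPE) annotations
#'
#' BED3+ rows become a `GRanges` (column 4, when present, is kept as the
#' `label` metadata column). BEDPE6+ rows become an `S4Vectors::Pairs` of
#' anchor ranges; a numeric 7th column, when present, is kept as per-loop
#' `p` (the dialect used by loop sets carrying interaction p-values).
#' Input coordinates are 0-based half-open and are converted to the 1-based
#' closed convention of `GRanges`.
#'
#' @param path file path (whitespace-separated, no header; `#` lines skipped).
#' @param kind "bed" or "bedpe".
#' @param chromStyle see [normChrom()].
#' @return `GRanges` (bed) or `Pairs` (bedpe), sorted.
#' @export
readIntervals <- function(path, kind = c("bed", "bedpe"), chromStyle = "asis") {
  kind <- match.arg(kind)
  tab <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                         fill = TRUE, skip = "",
                                         blank.lines.skip = TRUE))
  tab <- tab[!grepl("^#", tab[[1]]), , drop = FALSE]
  need <- if (kind == "bed") 3L else 6L
  if (ncol(tab) < need)
    .stopf("%s: expected at least %d columns for %s", path, need, kind)
  checkNum <- function(s, e, what) {
    bad <- !is.finite(s) | !is.finite(e) | s < 0
    if (any(bad))
      .stopf("%s: malformed %s interval at line(s) %s", path, what,
             paste(head(which(bad), 5), collapse = ", "))
    s >= e   # empty/inverted intervals: rejected, not fatal
  }
  if (kind == "bed") {
    s <- suppressWarnings(as.numeric(tab[[2]]))
    e <- suppressWarnings(as.numeric(tab[[3]]))
    rej <- checkNum(s, e, "bed")
    if (any(rej)) warning(sum(rej), " interval(s) with start >= end rejected")
    gr <- GenomicRanges::GRanges(normChrom(tab[[1]][!rej], chromStyle),
                                 IRanges::IRanges(start = s[!rej] + 1,
                                                  end = e[!rej]))
    if (ncol(tab) >= 4)
      S4Vectors::mcols(gr)$label <- as.character(tab[[4]][!rej])
    GenomicRanges::sort(gr)
  } else {
    s1 <- as.numeric(tab[[2]]); e1 <- as.numeric(tab[[3]])
    s2 <- as.numeric(tab[[5]]); e2 <- as.numeric(tab[[6]])
    rej <- checkNum(s1, e1, "bedpe anchor1") | checkNum(s2, e2, "bedpe anchor2")
    if (any(rej)) {
      warning(sum(rej), " loop(s) with start >= end rejected")
      tab <- tab[!rej, , drop = FALSE]
      s1 <- s1[!rej]; e1 <- e1[!rej]; s2 <- s2[!rej]; e2 <- e2[!rej]
    }
    a1 <- GenomicRanges::GRanges(normChrom(tab[[1]], chromStyle),
                                 IRanges::IRanges(start = s1 + 1, end = e1))
    a2 <- GenomicRanges::GRanges(normChrom(tab[[4]], chromStyle),
                                 IRanges::IRanges(start = s2 + 1, end = e2))
    pr <- S4Vectors::Pairs(a1, a2)
    if (ncol(tab) >= 7 && is.numeric(tab[[7]]))
      S4Vectors::mcols(pr)$p <- tab[[7]]
    pr
  }
}

.PAI_OUT_COLS <- c("expo_probe", "expo_chr", "expo_bp", "outcome_probe",
                   "outcome_bp", "top_snp", "b_xy", "se_xy", "p_smr",
                   "nsnp_heidi", "p_heidi", "distance", "pass_smr",
                   "pass_heidi")

#' Write / read a PAI result table
#'
#' Writes the per-pair results of a scan as TSV with a fixed column set and
#' deterministic row order (chromosome, exposure position, outcome position).
#'
#' @param x a [PaiSet-class] or a records data.frame.
#' @param path output path.
#' @return `writePaiTable` the path invisibly; `readPaiTable` a data.frame.
#' @export
writePaiTable <- function(x, path) {
  r <- if (is(x, "PaiSet")) paiRecords(x) else as.data.frame(x)
  if (nrow(r)) {
    for (cc in setdiff(.PAI_OUT_COLS, names(r))) r[[cc]] <- NA
    r <- r[order(r$expo_chr, r$expo_bp, r$outcome_bp, r$outcome_probe),
           .PAI_OUT_COLS, drop = FALSE]
  } else {
    r <- as.data.frame(setNames(rep(list(logical(0)), length(.PAI_OUT_COLS)),
                                .PAI_OUT_COLS))
  }
  data.table::fwrite(r, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writePaiTable
#' @export
readPaiTable <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}

#' Read an eQTL list
#'
#' TSV with header `snp_id, chrom, bp, gene, p`.
#'
#' @inheritParams readMqtlSummary
#' @return data.frame.
#' @export
readEqtlTable <- function(path, chromStyle = "asis") {
  e <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  miss <- setdiff(c("snp_id", "chrom", "bp", "gene", "p"), names(e))
  if (length(miss))
    .stopf("eQTL table %s missing column(s): %s", path,
           paste(miss, collapse = ", "))
  e$chrom <- normChrom(e$chrom, chromStyle)
  e
}

#' Read a gene-by-sample TPM expression matrix
#'
#' TSV whose first column (`gene`) labels rows; remaining columns are
#' per-sample TPM values.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
readTpmMatrix <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read an allele-count genotype matrix
#'
#' Plain TSV, header row of SNP ids, one row per sample, entries in
#' {0, 1, 2} counting copies of each SNP's effect allele. An optional
#' companion allele table (`snp_id, a1, a2`) records which allele the counts
#' refer to and is attached as the `"alleles"` attribute.
#'
#' @param path genotype TSV path.
#' @param allelesPath optional allele table TSV path.
#' @return integer matrix (samples x SNPs).
#' @export
readGenotypeMatrix <- function(path, allelesPath = NULL) {
  g <- as.matrix(data.table::fread(path, sep = "\t", header = TRUE))
  storage.mode(g) <- "integer"
  if (any(!g %in% 0:2)) .stopf("%s: genotype entries must be 0/1/2", path)
  if (!is.null(allelesPath)) {
    al <- as.data.frame(data.table::fread(allelesPath, sep = "\t",
                                          header = TRUE))
    attr(g, "alleles") <- al
  }
  g
}

#' Read an LD reference from a VCF
#'
#' Extracts diploid genotypes from the GT field and counts ALT alleles, so
#' the returned matrix is coded with `a1 = ALT`, `a2 = REF`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return integer matrix (samples x SNPs) with an `"alleles"` attribute.
#' @export
readLdVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stopf("readLdVcf() needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  g <- t(counts)
  colnames(g) <- v@fix[, "ID"]
  attr(g, "alleles") <- data.frame(snp_id = v@fix[, "ID"],
                                   a1 = v@fix[, "ALT"], a2 = v@fix[, "REF"],
                                   stringsAsFactors = FALSE)
  g
}

#' Scan configuration
#'
#' Bundles the tunable thresholds of the PAI scan. Defaults follow the
#' published analysis conventions: 2 Mb cis and pairing windows, instrument
#' p < 5e-8, Bonferroni at alpha = 0.05 over the tested pairs, HEIDI filter
#' p > 0.01, instrument inclusion p < 1.57e-3 (z^2 > 10), LD pruning
#' r^2 <= 0.9 with a lower bound of 0.05 on r^2 with the top SNP, at most
#' 20 and at least 3 HEIDI instruments.
#'
#' @param cisWindow,pairWindow windows in bp.
#' @param instrumentP exposure instrument p-value threshold.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param heidiCutoff HEIDI rejection cutoff (pairs with p below it fail).
#' @param heidiPInclude,heidiR2Cap,heidiR2MinTop,heidiMaxSnps,heidiMinSnps
#'   HEIDI instrument-selection parameters (see [heidiSelectSnps()]).
#' @param heidiMethod "satterthwaite" (fast default) or "imhof" (numerically
#'   exact quadrature).
#' @param heidiNaPass should pairs with NA HEIDI p count as passing? Default
#'   FALSE (conservative).
#' @param blacklist optional `GRanges` of excluded regions (e.g. the MHC).
#' @param ambiguousSnps "keep" or "drop" strand-ambiguous A/T, C/G SNPs at
#'   allele harmonisation.
#' @param chromStyle chromosome naming normalisation applied on read.
#' @return a named list of class `scanConfig`.
#' @export
scanConfig <- function(cisWindow = 2e6, pairWindow = 2e6, instrumentP = 5e-8,
                       alpha = 0.05, heidiCutoff = 0.01,
                       heidiPInclude = 1.57e-3, heidiR2Cap = 0.9,
                       heidiR2MinTop = 0.05, heidiMaxSnps = 20L,
                       heidiMinSnps = 3L, heidiMethod = "satterthwaite",
                       heidiNaPass = FALSE, blacklist = NULL,
                       ambiguousSnps = c("keep", "drop"),
                       chromStyle = "asis") {
  stopifnot(cisWindow > 0, pairWindow > 0,
            instrumentP > 0, instrumentP < 1, alpha > 0, alpha < 1,
            heidiCutoff > 0, heidiCutoff < 1)
  cfg <- list(cisWindow = cisWindow, pairWindow = pairWindow,
              instrumentP = instrumentP, alpha = alpha,
              heidiCutoff = heidiCutoff, heidiPInclude = heidiPInclude,
              heidiR2Cap = heidiR2Cap, heidiR2MinTop = heidiR2MinTop,
              heidiMaxSnps = as.integer(heidiMaxSnps),
              heidiMinSnps = as.integer(heidiMinSnps),
              heidiMethod = heidiMethod, heidiNaPass = heidiNaPass,
              blacklist = blacklist,
              ambiguousSnps = match.arg(ambiguousSnps),
              chromStyle = chromStyle)
  class(cfg) <- c("scanConfig", "list")
  cfg
}

#' Read a scan configuration from a YAML key/value file
#'
#' Keys mirror the arguments of [scanConfig()]; a `blacklist` key gives a
#' BED path read via [readIntervals()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `scanConfig` list.
#' @export
readScanConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$blacklist) && is.character(vals$blacklist))
    vals$blacklist <- readIntervals(vals$blacklist, "bed")
  known <- names(formals(scanConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    .stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(scanConfig, vals)
}
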