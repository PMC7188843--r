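## Synthetic cohorts with the statistical structure the method assumes:
## LD-structured diploid genotypes, methylation pairs generated under
## pleiotropy, linkage or a shared-sample null, and the per-SNP association
## scans that turn them into summary statistics.

#' Simulate LD-structured diploid genotypes
#'
#' Haplotypes follow a first-order binary Markov chain along the SNPs with
#' neighbour correlation `ldDecay`, so the correlation between SNPs i and j
#' decays as `ldDecay^|i-j|` in closed form. Two independent haplotypes are
#' summed into allele counts. Allele frequencies are a region-level draw
#' from `mafRange` plus a small per-SNP jitter: near-equal margins are what
#' makes the target neighbour correlation attainable (two Bernoulli margins
#' far apart bound the achievable correlation well below 1).
#'
#' @param n individuals.
#' @param m SNPs.
#' @param ldDecay per-SNP-step correlation rho in \[0, 1).
#' @param mafRange range the region-level allele frequency is drawn from.
#' @param seed optional integer seed; NULL continues the current RNG stream.
#' @param jitter half-width of the per-SNP frequency jitter.
#' @return n x m integer matrix of {0,1,2} counts with SNP ids as column
#'   names and an `"alleles"` attribute (counts refer to `a1`).
#' @export
simulateGenotypes <- function(n, m, ldDecay = 0.8, mafRange = c(0.1, 0.5),
                              seed = NULL, jitter = 0.02) {
  stopifnot(n >= 1, m >= 1, ldDecay >= 0, ldDecay < 1)
  if (!is.null(seed)) set.seed(seed)
  p0 <- runif(1, mafRange[1], mafRange[2])
  p <- pmin(pmax(p0 + runif(m, -jitter, jitter), 0.02), 0.98)
  nh <- 2L * n
  H <- matrix(0L, nh, m)
  drawCol <- function(j, prev) {
    if (j == 1L || is.null(prev)) return(rbinom(nh, 1L, p[j]))
    pj <- p[j]; pk <- p[j - 1L]
    s <- sqrt(pj * (1 - pj) / (pk * (1 - pk)))
    p1 <- pmin(pmax(pj + ldDecay * s * (prev - pk), 0), 1)
    rbinom(nh, 1L, p1)
  }
  for (j in seq_len(m)) {
    for (try in 1:20) {
      H[, j] <- drawCol(j, if (j > 1L) H[, j - 1L] else NULL)
      g <- H[1:n, j] + H[(n + 1L):nh, j]
      if (var(g) > 0) break
    }
  }
  geno <- H[1:n, , drop = FALSE] + H[(n + 1L):nh, , drop = FALSE]
  colnames(geno) <- sprintf("snp%d", seq_len(m))
  attr(geno, "alleles") <- data.frame(snp_id = colnames(geno),
                                      a1 = "A", a2 = "G",
                                      stringsAsFactors = FALSE)
  attr(geno, "maf") <- p
  geno
}

#' Simulation scenario parameters
#'
#' @param kind "pleiotropy" (one shared causal SNP and a direct
#'   exposure-to-outcome effect `bXy`), "linkage" (two distinct causal SNPs
#'   in LD `rLink` = r^2 between them, no direct effect), or
#'   "null_overlap" (genetic effect on the exposure only, with residual
#'   correlation `rP` between the two phenotypes, emulating an
#'   exposure/outcome pair measured in one overlapping sample).
#' @param q2 variance in the exposure explained by its causal SNP.
#' @param bXy true exposure-to-outcome effect (pleiotropy only; |bXy| < 1
#'   so the outcome variance stays at 1).
#' @param rLink target r^2 between the two causal SNPs (linkage only).
#' @param rP residual phenotypic correlation (null_overlap only).
#' @param causalIndex column index of the (first) causal SNP; defaults to
#'   the middle SNP.
#' @return a named list.
#' @export
simScenario <- function(kind = c("pleiotropy", "linkage", "null_overlap"),
                        q2 = 0.1, bXy = 0, rLink = 0.2, rP = 0,
                        causalIndex = NULL) {
  kind <- match.arg(kind)
  stopifnot(q2 >= 0, q2 < 1, abs(rP) < 1)
  if (kind == "pleiotropy") stopifnot(bXy^2 < 1)
  list(kind = kind, q2 = q2, bXy = bXy, rLink = rLink, rP = rP,
       causalIndex = causalIndex)
}

#' Simulate an exposure/outcome methylation pair
#'
#' Methylation is simulated on a standardised continuous scale (unit
#' variance in expectation), matching the SD-unit effects of the summary
#' statistics the method consumes.
#'
#' @param genotypes matrix from [simulateGenotypes()].
#' @param scenario a [simScenario()].
#' @return list `x`, `y` (length-n phenotypes), `causal` (causal column
#'   indices), `scenario`.
#' @export
simulateMethylationPair <- function(genotypes, scenario) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  c1 <- scenario$causalIndex
  if (is.null(c1)) c1 <- (m + 1L) %/% 2L
  g1 <- genotypes[, c1]
  beta <- if (scenario$q2 > 0) sqrt(scenario$q2) / sd(g1) else 0
  kind <- scenario$kind
  if (kind == "pleiotropy") {
    x <- g1 * beta + rnorm(n, 0, sqrt(1 - scenario$q2))
    y <- scenario$bXy * x + rnorm(n, 0, sqrt(1 - scenario$bXy^2))
    causal <- c1
  } else if (kind == "linkage") {
    rr <- cor(genotypes[, c1], genotypes)^2
    rr[c1] <- NA
    c2 <- which.min(abs(rr - scenario$rLink))
    g2 <- genotypes[, c2]
    beta2 <- if (scenario$q2 > 0) sqrt(scenario$q2) / sd(g2) else 0
    x <- g1 * beta + rnorm(n, 0, sqrt(1 - scenario$q2))
    y <- g2 * beta2 + rnorm(n, 0, sqrt(1 - scenario$q2))
    causal <- c(c1, c2)
  } else {
    sdEy2 <- 1 - scenario$rP^2 / (1 - scenario$q2)
    if (sdEy2 <= 0)
      .stopf("unreachable residual correlation: need |rP| < sqrt(1 - q2) = %.3f",
             sqrt(1 - scenario$q2))
    ex <- rnorm(n, 0, sqrt(1 - scenario$q2))
    x <- g1 * beta + ex
    y <- scenario$rP / (1 - scenario$q2) * ex + rnorm(n, 0, sqrt(sdEy2))
    causal <- c1
  }
  list(x = x, y = y, causal = causal, scenario = scenario)
}

#' Per-SNP association scan of a phenotype
#'
#' Simple linear regression of the (sample-standardised) phenotype on each
#' SNP's allele count: closed-form OLS slope, standard error and two-sided
#' t-test p-value, vectorised across SNPs. Monomorphic SNPs yield NA rows.
#'
#' @param genotypes n x m allele-count matrix.
#' @param phenotype length-n numeric vector.
#' @param positions optional SNP positions (bp); defaults to the column
#'   index.
#' @return data.frame `snp_id, snp_bp, a1, a2, freq, b, se, p, n` (effects
#'   in SD units of the phenotype).
#' @export
associationScan <- function(genotypes, phenotype, positions = NULL) {
  n <- nrow(genotypes)
  stopifnot(length(phenotype) == n, n > 3)
  y <- (phenotype - mean(phenotype)) / sd(phenotype)
  gc <- scale(genotypes, center = TRUE, scale = FALSE)
  Sxx <- colSums(gc^2)
  Sxy <- as.numeric(crossprod(gc, y))
  b <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- pmax(sum(y^2) - b^2 * Sxx, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / (n - 2) / Sxx), NA_real_)
  tt <- b / se
  p <- 2 * pt(-abs(tt), df = n - 2)
  al <- attr(genotypes, "alleles")
  data.frame(snp_id = colnames(genotypes),
             snp_bp = if (is.null(positions)) seq_len(ncol(genotypes))
             else positions,
             a1 = if (is.null(al)) "A" else al$a1,
             a2 = if (is.null(al)) "G" else al$a2,
             freq = colMeans(genotypes) / 2,
             b = b, se = se, p = p, n = n,
             stringsAsFactors = FALSE)
}

## SMR + HEIDI on one simulated exposure/outcome pair; shared by the
## calibration and power experiments
.simSmrHeidi <- function(geno, x, y, instrumentP, cfg) {
  sx <- associationScan(geno, x)
  top <- topInstrument(sx, instrumentP)
  if (is.null(top)) return(NULL)
  sy <- associationScan(geno, y)
  oi <- match(top$snp_id, sy$snp_id)
  s <- smrTest(top$b, top$se, sy$b[oi], sy$se[oi])
  ldr <- cor(geno)
  dimnames(ldr) <- list(colnames(geno), colnames(geno))
  pHeidi <- NA_real_
  sel <- heidiSelectSnps(sx, ldr, top$snp_id,
                         pInclude = cfg$heidiPInclude,
                         r2Cap = cfg$heidiR2Cap,
                         r2MinTop = cfg$heidiR2MinTop,
                         maxSnps = cfg$heidiMaxSnps)
  if (length(sel) >= cfg$heidiMinSnps) {
    ei <- match(sel, sx$snp_id)
    yi <- match(sel, sy$snp_id)
    hc <- tryCatch(
      heidiCovariance(sx$b[ei], sx$se[ei], sy$b[yi], sy$se[yi],
                      ldr[sel, sel, drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(hc))
      pHeidi <- heidiTest(hc$d, hc$V, method = cfg$heidiMethod)$p_heidi
  }
  list(bXy = s$b_xy, pSmr = s$p_smr, pHeidi = pHeidi, topSnp = top$snp_id)
}

#' Null-calibration experiment under sample overlap
#'
#' Emulates the situation where exposure and outcome methylation are
#' measured in the same cohort but share no genetics: the outcome has no
#' genetic component and correlates with the exposure only through a
#' residual correlation drawn from `rPDist`. Each replicate simulates a
#' cohort, scans both phenotypes on the same genotypes (sample overlap by
#' construction), and runs SMR and HEIDI whenever the exposure instrument
#' reaches `instrumentP`. Well-calibrated tests yield uniform p-values.
#'
#' @param nReps replicates.
#' @param n,m,ldDecay cohort shape (see [simulateGenotypes()]).
#' @param rPDist,q2Dist functions of one integer returning draws of the
#'   residual correlation and of the exposure variance explained; defaults
#'   Uniform(-0.5, 0.5) and Uniform(0.03, 0.3).
#' @param instrumentP exposure instrument threshold.
#' @param cfg a [scanConfig()] supplying the HEIDI parameters.
#' @param seed integer seed (all randomness flows from it).
#' @return list: `pSmr`, `pHeidi` (vectors), `nSkipped` (replicates without
#'   a qualifying instrument), `fracSmr05` with a 95% binomial CI, and the
#'   Kolmogorov-Smirnov p-value of `pSmr` against Uniform(0,1).
#' @export
nullOverlapExperiment <- function(nReps = 2000, n = 2000, m = 20,
                                  ldDecay = 0.8,
                                  rPDist = function(k) runif(k, -0.5, 0.5),
                                  q2Dist = function(k) runif(k, 0.03, 0.3),
                                  instrumentP = 5e-8, cfg = scanConfig(),
                                  seed = 1L) {
  set.seed(deriveSeed(seed, "null_overlap"))
  rP <- rPDist(nReps)
  q2 <- q2Dist(nReps)
  pSmr <- pHeidi <- rep(NA_real_, nReps)
  nSkipped <- 0L
  for (i in seq_len(nReps)) {
    geno <- simulateGenotypes(n, m, ldDecay)
    sim <- simulateMethylationPair(
      geno, simScenario("null_overlap", q2 = q2[i], rP = rP[i]))
    res <- .simSmrHeidi(geno, sim$x, sim$y, instrumentP, cfg)
    if (is.null(res)) { nSkipped <- nSkipped + 1L; next }
    pSmr[i] <- res$pSmr
    pHeidi[i] <- res$pHeidi
  }
  pSmr <- pSmr[!is.na(pSmr)]
  frac <- mean(pSmr < 0.05)
  ciHw <- 1.96 * sqrt(frac * (1 - frac) / length(pSmr))
  list(pSmr = pSmr, pHeidi = pHeidi[!is.na(pHeidi)],
       nSkipped = nSkipped,
       fracSmr05 = frac, fracSmr05CI = c(frac - ciHw, frac + ciHw),
       ksP = suppressWarnings(ks.test(pSmr, "punif")$p.value))
}

#' Power and rejection-rate experiment over a scenario grid
#'
#' For each grid row, simulates `nReps` cohorts, runs SMR and HEIDI on the
#' exposure/outcome pair, and tabulates the SMR rejection rate at
#' `smrThreshold`, the HEIDI rejection rate at p < 0.01, and the mean ratio
#' estimate with its relative bias (pleiotropy rows).
#'
#' @param grid data.frame with columns `kind, q2, bXy, rLink` (NA where a
#'   column does not apply to a scenario kind).
#' @param nReps replicates per grid row.
#' @param n,m,ldDecay cohort shape.
#' @param smrThreshold SMR rejection threshold.
#' @param instrumentP exposure instrument threshold.
#' @param cfg a [scanConfig()].
#' @param seed integer seed.
#' @return the grid with appended columns `nUsed, smrPower,
#'   heidiRejectRate, meanBxy, biasPct`.
#' @export
powerExperiment <- function(grid, nReps = 200, n = 2000, m = 40,
                            ldDecay = 0.9, smrThreshold = 5e-8,
                            instrumentP = 5e-8, cfg = scanConfig(),
                            seed = 1L) {
  stopifnot(nrow(grid) >= 1, all(c("kind", "q2") %in% names(grid)))
  if (!"bXy" %in% names(grid)) grid$bXy <- NA_real_
  if (!"rLink" %in% names(grid)) grid$rLink <- NA_real_
  res <- lapply(seq_len(nrow(grid)), function(gi) {
    set.seed(deriveSeed(seed, paste0("power_cell_", gi)))
    kind <- grid$kind[gi]
    bxy <- pSmr <- pHeidi <- rep(NA_real_, nReps)
    for (i in seq_len(nReps)) {
      geno <- simulateGenotypes(n, m, ldDecay)
      sc <- simScenario(kind, q2 = grid$q2[gi],
                        bXy = ifelse(is.na(grid$bXy[gi]), 0, grid$bXy[gi]),
                        rLink = ifelse(is.na(grid$rLink[gi]), 0.2,
                                       grid$rLink[gi]))
      sim <- simulateMethylationPair(geno, sc)
      r <- .simSmrHeidi(geno, sim$x, sim$y, instrumentP, cfg)
      if (is.null(r)) next
      bxy[i] <- r$bXy; pSmr[i] <- r$pSmr; pHeidi[i] <- r$pHeidi
    }
    used <- !is.na(pSmr)
    data.frame(nUsed = sum(used),
               smrPower = mean(pSmr[used] < smrThreshold),
               heidiRejectRate = mean(pHeidi[used] < 0.01, na.rm = TRUE),
               meanBxy = mean(bxy[used]),
               biasPct = if (kind == "pleiotropy" && !is.na(grid$bXy[gi]) &&
                             grid$bXy[gi] != 0)
                 100 * (mean(bxy[used]) - grid$bXy[gi]) / grid$bXy[gi]
               else NA_real_)
  })
  cbind(grid, do.call(rbind, res))
}
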