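## A complete, small, self-consistent synthetic input bundle: one ~2 Mb
## region with LD-structured genotypes for a cohort of 2,000, ~50 DNAm
## probes whose methylation is generated under known pleiotropy, linkage
## and shared-sample-null structure, the derived mQTL summary tables for
## two "tissues", and toy interval/expression annotations with planted
## signal. Everything needed to run the scan, the enrichment analyses and
## the cross-tissue comparison end to end.

.STATE_ALPHABET <- c("TssA", "Prom", "Tx", "TxWk", "TxEn", "EnhA", "EnhW",
                     "DNase", "ZNF/Rpts", "Het", "PromP", "PromBiv",
                     "ReprPC", "Quies")

## long-format association scans for many probes at once (vectorised OLS)
.multiScan <- function(geno, Y, snpBp, probes, cisWindow) {
  n <- nrow(geno)
  Yc <- scale(Y)
  gc <- scale(geno, center = TRUE, scale = FALSE)
  Sxx <- colSums(gc^2)
  B <- crossprod(gc, Yc) / Sxx           # m x P slopes
  Syy <- n - 1
  SE <- sqrt(pmax(Syy - B^2 * Sxx, 0) / (n - 2) / Sxx)
  P <- 2 * pt(-abs(B / SE), df = n - 2)
  freq <- colMeans(geno) / 2
  rows <- lapply(seq_len(ncol(Y)), function(pi) {
    keep <- abs(snpBp - probes$bp[pi]) <= cisWindow
    data.frame(probe_id = probes$probe_id[pi], probe_chr = probes$chrom[pi],
               probe_bp = probes$bp[pi], snp_id = colnames(geno)[keep],
               snp_chr = probes$chrom[pi], snp_bp = snpBp[keep],
               a1 = "A", a2 = "G", freq = freq[keep], b = B[keep, pi],
               se = SE[keep, pi], p = P[keep, pi], n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.writeBed <- function(df, path) {
  ## df: chrom, start1, end1 (1-based closed) [, label]
  out <- data.frame(df$chrom, df$start1 - 1L, df$end1)
  if (!is.null(df$label)) out <- cbind(out, df$label)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
}

#' Generate the synthetic fixture bundle
#'
#' Writes a self-consistent input set for the whole pipeline into `dir`:
#' blood and brain cis-mQTL summary TSVs derived by association scans of
#' simulated methylation on simulated LD-structured genotypes, the
#' genotype matrix (LD reference) with its allele table, a probe table,
#' promoter/TAD/state/ChIP BED files, a loop BEDPE with p-values, an eQTL
#' TSV and a TPM matrix with planted co-expression, a scan config YAML and
#' a JSON manifest of the planted truth. Two bundles written with the same
#' seed are identical.
#'
#' Planted structure: 13 promoter bait loci (instrument variance explained
#' q2 = 0.15, n = 2000); six baits drive a nearby outcome probe
#' pleiotropically (b_xy = 0.5), two baits sit in linkage with an outcome
#' driven by a distinct causal SNP at LD r^2 ~ 0.2, two outcomes share
#' only residual (sample-overlap) correlation r_p = 0.3 with their bait,
#' and three baits drive a second promoter probe (promoter-promoter
#' pairs, used for co-expression planting at r = 0.4).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; all randomness derives from it.
#' @param n,nBrain cohort sizes for the two tissues.
#' @param m number of SNPs (1 kb spacing from 1 Mb).
#' @param ldDecay per-step LD parameter.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
makeFixtureBundle <- function(dir, seed = 1L, n = 2000, nBrain = 600,
                              m = 2000, ldDecay = 0.9) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(deriveSeed(seed, "fixture_bundle"))
  chrom <- "chr1"
  snpBp <- 1e6 + (seq_len(m) - 1L) * 1000L
  q2 <- 0.15; bXy <- 0.5; rP <- 0.3; linkGap <- 8L

  nBait <- 13L
  cIdx <- 150L + 140L * (seq_len(nBait) - 1L)
  roles <- c(rep("pleiotropy", 6), rep("linkage", 2), rep("null_overlap", 2),
             rep("pmpm", 3))

  ## probe layout
  probes <- list(); meth <- list(); methBrain <- list()
  genoBlood <- simulateGenotypes(n, m, ldDecay, mafRange = c(0.15, 0.45))
  genoBrain <- simulateGenotypes(nBrain, m, ldDecay, mafRange = c(0.15, 0.45))
  addProbe <- function(id, bp, gene, xB, xR) {
    probes[[length(probes) + 1L]] <<- data.frame(
      probe_id = id, chrom = chrom, bp = bp, gene = gene,
      dnam_variance = exp(rnorm(1, 0, 0.4)), stringsAsFactors = FALSE)
    meth[[length(meth) + 1L]] <<- xB
    methBrain[[length(methBrain) + 1L]] <<- xR
  }
  drive <- function(geno, ci) {
    g <- geno[, ci]
    list(gen = g * sqrt(q2) / sd(g), resid = rnorm(nrow(geno), 0, sqrt(1 - q2)))
  }

  planted <- list(pleiotropy = NULL, linkage = NULL, null_overlap = NULL,
                  pmpm = NULL)
  for (k in seq_len(nBait)) {
    ci <- cIdx[k]
    baitId <- sprintf("cgB%02d", k)
    gene <- sprintf("GENE%02d", k)
    dB <- drive(genoBlood, ci); dR <- drive(genoBrain, ci)
    xB <- dB$gen + dB$resid; xR <- dR$gen + dR$resid
    addProbe(baitId, snpBp[ci] + 200L, gene, xB, xR)
    role <- roles[k]
    if (role == "pleiotropy") {
      outId <- sprintf("cgO%02d", k)
      addProbe(outId, snpBp[ci + 35L] + 400L, NA_character_,
               bXy * xB + rnorm(n, 0, sqrt(1 - bXy^2)),
               bXy * xR + rnorm(nBrain, 0, sqrt(1 - bXy^2)))
      planted$pleiotropy <- rbind(planted$pleiotropy,
        data.frame(expo_probe = baitId, outcome_probe = outId, gene = gene,
                   b_xy = bXy, stringsAsFactors = FALSE))
    } else if (role == "linkage") {
      outId <- sprintf("cgO%02d", k)
      e2B <- drive(genoBlood, ci + linkGap); e2R <- drive(genoBrain, ci + linkGap)
      addProbe(outId, snpBp[ci + 35L] + 400L, NA_character_,
               e2B$gen + e2B$resid, e2R$gen + e2R$resid)
      planted$linkage <- rbind(planted$linkage,
        data.frame(expo_probe = baitId, outcome_probe = outId, gene = gene,
                   r2_link = ldDecay^(2 * linkGap), stringsAsFactors = FALSE))
    } else if (role == "null_overlap") {
      outId <- sprintf("cgO%02d", k)
      gamma <- rP / (1 - q2)
      addProbe(outId, snpBp[ci + 35L] + 400L, NA_character_,
               gamma * dB$resid + rnorm(n, 0, sqrt(1 - rP^2 / (1 - q2))),
               gamma * dR$resid + rnorm(nBrain, 0, sqrt(1 - rP^2 / (1 - q2))))
      planted$null_overlap <- rbind(planted$null_overlap,
        data.frame(expo_probe = baitId, outcome_probe = outId, gene = gene,
                   r_p = rP, stringsAsFactors = FALSE))
    } else {
      partnerId <- sprintf("cgP%02d", k)
      partnerGene <- sprintf("GENE%02d", nBait + (k - 10L))
      addProbe(partnerId, snpBp[ci + 60L] + 300L, partnerGene,
               bXy * xB + rnorm(n, 0, sqrt(1 - bXy^2)),
               bXy * xR + rnorm(nBrain, 0, sqrt(1 - bXy^2)))
      planted$pmpm <- rbind(planted$pmpm,
        data.frame(expo_probe = baitId, outcome_probe = partnerId,
                   gene1 = gene, gene2 = partnerGene, b_xy = bXy,
                   stringsAsFactors = FALSE))
    }
    ## two background probes near each bait, independent of everything
    addProbe(sprintf("cgN%02d_1", k), snpBp[ci - 20L] + 150L, NA_character_,
             rnorm(n), rnorm(nBrain))
    addProbe(sprintf("cgN%02d_2", k), snpBp[ci + 55L] + 250L, NA_character_,
             rnorm(n), rnorm(nBrain))
  }
  probes <- do.call(rbind, probes)
  YB <- do.call(cbind, meth)
  YR <- do.call(cbind, methBrain)

  ## summary statistics and genotype reference
  cisWindow <- 2e6
  mqtlB <- .multiScan(genoBlood, YB, snpBp, probes, cisWindow)
  mqtlR <- .multiScan(genoBrain, YR, snpBp, probes, cisWindow)
  f <- function(x) file.path(dir, x)
  data.table::fwrite(mqtlB, f("mqtl_blood.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(mqtlR, f("mqtl_brain.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(probes, f("probes.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(as.data.frame(genoBlood), f("genotypes.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(attr(genoBlood, "alleles"), f("genotype_alleles.tsv"),
                     sep = "\t", quote = FALSE)

  ## promoters: one interval per promoter probe
  promP <- probes[grepl("^cg[BP]", probes$probe_id), , drop = FALSE]
  .writeBed(data.frame(chrom = promP$chrom, start1 = promP$bp - 400L,
                       end1 = promP$bp + 600L, label = promP$gene),
            f("promoters.bed"))

  ## TADs covering each planted bait/outcome pair, plus background TADs
  pairAll <- rbind(planted$pleiotropy[, 1:2], planted$linkage[, 1:2],
                   planted$null_overlap[, 1:2], planted$pmpm[, 1:2])
  bpOf <- function(id) probes$bp[match(id, probes$probe_id)]
  tads <- data.frame(chrom = chrom,
                     start1 = pmin(bpOf(pairAll[, 1]), bpOf(pairAll[, 2])) - 15000L,
                     end1 = pmax(bpOf(pairAll[, 1]), bpOf(pairAll[, 2])) + 15000L)
  gapStarts <- seq(1.02e6, 2.9e6, length.out = 5)
  tads <- rbind(tads, data.frame(chrom = chrom,
                                 start1 = as.integer(gapStarts),
                                 end1 = as.integer(gapStarts + 8000)))
  .writeBed(tads, f("tads.bed"))

  ## loops: anchors at the first four pleiotropic pairs (p small) plus
  ## background loops elsewhere (p large)
  lp <- planted$pleiotropy[1:4, ]
  mkAnchor <- function(bp) cbind(bp - 3000L, bp + 3000L)
  a1 <- mkAnchor(bpOf(lp$expo_probe)); a2 <- mkAnchor(bpOf(lp$outcome_probe))
  bgBp <- as.integer(seq(1.05e6, 2.85e6, length.out = 8))
  loops <- data.frame(c1 = chrom, s1 = c(a1[, 1], bgBp) - 1L,
                      e1 = c(a1[, 2], bgBp + 6000L),
                      c2 = chrom, s2 = c(a2[, 1], bgBp + 40000L) - 1L,
                      e2 = c(a2[, 2], bgBp + 46000L),
                      p = c(rep(1e-5, 4), rep(0.5, 8)))
  data.table::fwrite(loops, f("loops.bedpe"), sep = "\t",
                     col.names = FALSE, quote = FALSE)

  ## chromatin states: one 1 kb interval per probe; planted PIDSs are
  ## enhancer-labelled at twice the background rate
  pidsIds <- c(planted$pleiotropy$outcome_probe, planted$pmpm$outcome_probe)
  isPids <- probes$probe_id %in% pidsIds
  enh <- runif(nrow(probes)) < ifelse(isPids, 0.4, 0.2)
  lab <- ifelse(enh, "EnhA",
                sample(setdiff(.STATE_ALPHABET, "EnhA"), nrow(probes),
                       replace = TRUE))
  .writeBed(data.frame(chrom = probes$chrom, start1 = probes$bp - 500L,
                       end1 = probes$bp + 499L, label = lab),
            f("states.bed"))

  ## ChIP peaks: enriched at PAI probes
  paiProbes <- unique(c(pairAll[, 1], pidsIds))
  hasPeak <- runif(nrow(probes)) <
    ifelse(probes$probe_id %in% paiProbes, 0.5, 0.3)
  peaks <- data.frame(chrom = chrom,
                      start1 = probes$bp[hasPeak] - 2000L,
                      end1 = probes$bp[hasPeak] + 2000L)
  .writeBed(peaks, f("chip_peaks.bed"))

  ## eQTLs: per (promoter gene, outcome probe) combination, an eQTL lands
  ## in the outcome's 10 kb window with probability 0.3 for planted PAI
  ## pairs and 0.2 otherwise
  plantedKey <- paste(c(planted$pleiotropy$gene, planted$pmpm$gene1),
                      c(planted$pleiotropy$outcome_probe,
                        planted$pmpm$outcome_probe))
  eq <- list()
  for (g in seq_len(nrow(promP))) {
    gene <- promP$gene[g]
    for (pi in seq_len(nrow(probes))) {
      if (probes$probe_id[pi] == promP$probe_id[g]) next
      pr <- if (paste(gene, probes$probe_id[pi]) %in% plantedKey) 0.3 else 0.2
      if (runif(1) < pr)
        eq[[length(eq) + 1L]] <- data.frame(
          snp_id = sprintf("eq_%s_%s", gene, probes$probe_id[pi]),
          chrom = chrom,
          bp = probes$bp[pi] + sample(-4500:4500, 1),
          gene = gene, p = 1e-9, stringsAsFactors = FALSE)
    }
  }
  data.table::fwrite(do.call(rbind, eq), f("eqtl.tsv"), sep = "\t",
                     quote = FALSE)

  ## TPM matrix: promoter genes plus fillers; planted promoter-promoter
  ## gene pairs co-expressed at r = 0.4, eight fillers inactive
  nSamp <- 120L
  genes <- c(sort(unique(promP$gene)), sprintf("FGENE%02d", 1:24))
  mu <- exp(rnorm(length(genes), 1.2, 0.8))
  mu[grepl("^FGENE(0[1-8])$", genes)] <- 0.01
  Z <- matrix(rnorm(length(genes) * nSamp), length(genes))
  rownames(Z) <- genes
  for (i in seq_len(nrow(planted$pmpm))) {
    g1 <- planted$pmpm$gene1[i]; g2 <- planted$pmpm$gene2[i]
    Z[g2, ] <- 0.4 * Z[g1, ] + sqrt(1 - 0.16) * rnorm(nSamp)
  }
  tpm <- pmax(mu * (1 + 0.3 * Z), 0.001)
  data.table::fwrite(data.frame(gene = genes, tpm, check.names = FALSE),
                     f("tpm.tsv"), sep = "\t", quote = FALSE)

  yaml::write_yaml(list(cisWindow = cisWindow, pairWindow = 2e6,
                        instrumentP = 5e-8, alpha = 0.05,
                        heidiCutoff = 0.01), f("config.yaml"))

  manifest <- list(seed = seed, n = n, nBrain = nBrain, m = m,
                   ldDecay = ldDecay, q2 = q2, b_xy = bXy, r_p = rP,
                   chrom = chrom,
                   planted = lapply(planted, function(d)
                     if (is.null(d)) NULL else d),
                   files = list(mqtl_blood = "mqtl_blood.tsv",
                                mqtl_brain = "mqtl_brain.tsv",
                                probes = "probes.tsv",
                                genotypes = "genotypes.tsv",
                                genotype_alleles = "genotype_alleles.tsv",
                                promoters = "promoters.bed",
                                tads = "tads.bed", loops = "loops.bedpe",
                                states = "states.bed",
                                chip_peaks = "chip_peaks.bed",
                                eqtl = "eqtl.tsv", tpm = "tpm.tsv",
                                config = "config.yaml"))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
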