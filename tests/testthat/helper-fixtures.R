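## Shared fixtures, built in code. The full synthetic bundle is expensive
## (~15 s with the LD matrix and both tissue scans), so it is built once
## per test run and cached.

.paiTestCache <- new.env(parent = emptyenv())

bundleFixture <- function() {
  if (!is.null(.paiTestCache$bundle)) return(.paiTestCache$bundle)
  dir <- file.path(tempdir(), "paiscan-bundle")
  manifest <- makeFixtureBundle(dir, seed = 1L)
  mqtl <- readMqtlSummary(file.path(dir, "mqtl_blood.tsv"),
                          probes = file.path(dir, "probes.tsv"))
  mqtlBrain <- readMqtlSummary(file.path(dir, "mqtl_brain.tsv"),
                               probes = file.path(dir, "probes.tsv"))
  promoters <- readIntervals(file.path(dir, "promoters.bed"), "bed")
  geno <- readGenotypeMatrix(file.path(dir, "genotypes.tsv"),
                             file.path(dir, "genotype_alleles.tsv"))
  ld <- ldFromGenotypes(geno)
  pai <- runPaiScan(mqtl, promoters, ld, scanConfig())
  paiBrain <- runPaiScan(mqtlBrain, promoters, ld, scanConfig())
  .paiTestCache$bundle <- list(dir = dir, manifest = manifest, mqtl = mqtl,
                               mqtlBrain = mqtlBrain, promoters = promoters,
                               ld = ld, pai = pai, paiBrain = paiBrain)
  .paiTestCache$bundle
}

## a minimal one-bait region with a planted pleiotropic outcome, as an
## in-memory MqtlTable + promoters + LD
miniRegion <- function(n = 800, m = 30, seed = 11, bXy = 0.5, q2 = 0.2) {
  geno <- simulateGenotypes(n, m, ldDecay = 0.8, seed = seed)
  snpBp <- as.integer(1e6 + (seq_len(m) - 1) * 1000)
  sim <- simulateMethylationPair(geno, simScenario("pleiotropy", q2 = q2,
                                                   bXy = bXy))
  asStats <- function(y, pid, pbp) {
    s <- associationScan(geno, y, positions = snpBp)
    data.frame(probe_id = pid, probe_chr = "chr1", probe_bp = pbp,
               snp_id = s$snp_id, snp_chr = "chr1", snp_bp = s$snp_bp,
               a1 = s$a1, a2 = s$a2, freq = s$freq, b = s$b, se = s$se,
               p = s$p, n = s$n, stringsAsFactors = FALSE)
  }
  baitBp <- snpBp[(m + 1) %/% 2] + 100L
  outBp <- baitBp + 8000L
  stats <- rbind(asStats(sim$x, "cgE", baitBp), asStats(sim$y, "cgO", outBp))
  probes <- data.frame(probe_id = c("cgE", "cgO"), chrom = "chr1",
                       bp = c(baitBp, outBp), stringsAsFactors = FALSE)
  list(mqtl = MqtlTable(stats, probes),
       promoters = GenomicRanges::GRanges(
         "chr1", IRanges::IRanges(baitBp - 400L, baitBp + 400L)),
       ld = ldFromGenotypes(geno), geno = geno, sim = sim)
}

## recode every allele in an MqtlTable (a1 <-> a2, b -> -b, freq -> 1-freq);
## the statistics of any allele-aware analysis must be invariant to this
flipMqtlCoding <- function(mqtl) {
  st <- mqtlStats(mqtl)
  st$b <- -st$b
  st$freq <- 1 - st$freq
  tmp <- st$a1; st$a1 <- st$a2; st$a2 <- tmp
  MqtlTable(st, probes = probeInfo(mqtl), cisWindow = mqtl@cisWindow)
}

## brute-force O(n*m) interval containment of 1-based points
bruteInPoint <- function(bp, starts, ends) {
  vapply(bp, function(x) any(x >= starts & x <= ends), logical(1))
}

expect_equal_tol <- function(x, y, tol) expect_lt(abs(x - y), tol)
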