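.gr <- function(starts, ends, chrom = "chr1", label = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  if (!is.null(label)) S4Vectors::mcols(g)$label <- label
  g
}

test_that("TAD overlap counts pairs inside one and the same TAD", {
  tads <- .gr(c(1, 100001), c(100000, 200000))
  pairs <- data.frame(chrom = "chr1",
                      bp1 = c(5000, 95000, 150000),
                      bp2 = c(50000, 150000, 190000))
  expect_equal(pairInTads(pairs, tads), c(TRUE, FALSE, TRUE))
  expect_equal(pairOverlapTads(pairs, tads), 2L)
  ## "any" mode only needs each probe inside some TAD
  expect_equal(pairInTads(pairs, tads, "any"), c(TRUE, TRUE, TRUE))
})

test_that("TAD overlap equals a brute-force scan on random instances", {
  set.seed(8)
  starts <- sort(sample.int(1e6, 20))
  tads <- .gr(starts, starts + sample(2e4:1e5, 20, TRUE))
  pairs <- data.frame(chrom = "chr1", bp1 = sample.int(1.2e6, 100),
                      bp2 = sample.int(1.2e6, 100))
  fast <- pairInTads(pairs, tads)
  slow <- vapply(seq_len(100), function(i) {
    any(pairs$bp1[i] >= GenomicRanges::start(tads) &
          pairs$bp1[i] <= GenomicRanges::end(tads) &
          pairs$bp2[i] >= GenomicRanges::start(tads) &
          pairs$bp2[i] <= GenomicRanges::end(tads))
  }, logical(1))
  expect_equal(fast, slow)
})

test_that("loop overlap requires opposite anchors, either orientation", {
  loops <- S4Vectors::Pairs(.gr(1000, 2000), .gr(50000, 51000))
  pairs <- data.frame(chrom = "chr1",
                      bp1 = c(1500, 50500, 1200, 1500),
                      bp2 = c(50500, 1500, 1800, 30000))
  expect_equal(pairInLoops(pairs, loops),
               c(TRUE, TRUE, FALSE, FALSE))  # same-anchor pair not counted
  ## padding extends the anchors
  pairs2 <- data.frame(chrom = "chr1", bp1 = 900, bp2 = 50500)
  expect_false(pairInLoops(pairs2, loops))
  expect_true(pairInLoops(pairs2, loops, pad = 200))
})

test_that("loop overlap equals brute force on random instances", {
  set.seed(9)
  a1s <- sample.int(5e5, 15); a2s <- sample.int(5e5, 15)
  loops <- S4Vectors::Pairs(.gr(a1s, a1s + 5000), .gr(a2s, a2s + 5000))
  pairs <- data.frame(chrom = "chr1", bp1 = sample.int(6e5, 80),
                      bp2 = sample.int(6e5, 80))
  fast <- pairInLoops(pairs, loops)
  slow <- vapply(seq_len(80), function(i) {
    in1 <- function(x) x >= a1s & x <= a1s + 5000
    in2 <- function(x) x >= a2s & x <= a2s + 5000
    any((in1(pairs$bp1[i]) & in2(pairs$bp2[i])) |
          (in1(pairs$bp2[i]) & in2(pairs$bp1[i])))
  }, logical(1))
  expect_equal(fast, slow)
})

test_that("centred-window site overlap respects the boundary", {
  feats <- .gr(104900, 105100)
  ## site 4.9 kb from the feature edge is inside a 10 kb window; 5.1 kb out
  expect_true(siteInWindow(data.frame(chrom = "chr1", bp = 100000),
                           feats, 10000))
  expect_false(siteInWindow(data.frame(chrom = "chr1", bp = 99799),
                            feats, 10000))
  set.seed(10)
  fs <- sample.int(1e6, 40)
  feats2 <- .gr(fs, fs + 1000)
  sites <- data.frame(chrom = "chr1", bp = sample.int(1e6, 120))
  fast <- siteInWindow(sites, feats2, 10000)
  slow <- vapply(sites$bp, function(x)
    any(x + 5000 >= fs & x - 5000 <= fs + 1000), logical(1))
  expect_equal(fast, slow)
})

test_that("matched control sampling respects bins and seeds", {
  set.seed(3)
  uni <- 10^runif(500, 3, 6)
  targets <- sample(uni, 40)
  ctrl <- sampleMatchedControls(targets, uni, nSets = 50, seed = 7)
  expect_equal(dim(ctrl), c(50L, 40L))
  ## matching contract: controls land in the target's log10 bin
  breaks <- seq(min(log10(uni)), max(log10(uni)), length.out = 21)
  binOf <- function(x) findInterval(log10(x), breaks,
                                    rightmost.closed = TRUE, all.inside = TRUE)
  for (s in c(1, 25)) {
    expect_equal(binOf(uni[ctrl[s, ]]), binOf(targets))
  }
  ## determinism under the same seed
  ctrl2 <- sampleMatchedControls(targets, uni, nSets = 50, seed = 7)
  expect_identical(ctrl, ctrl2)
})

test_that("empirical enrichment uses the (r+1)/(R+1) estimator", {
  nulls <- 1:1000
  ## observed beats all nulls: floor p, truncated flag
  r <- empiricalEnrichment(2000, nulls)
  expect_equal(enrichP(r), 1 / 1001)
  expect_true(r@truncated)
  ## observed at the null median
  r2 <- empiricalEnrichment(500, nulls)
  expect_equal(enrichP(r2), (501 + 1) / 1001, tolerance = 1e-12)
  expect_false(r2@truncated)
  ## printed-value arithmetic: 548 observed vs null mean 415
  r3 <- empiricalEnrichment(548, rep(415, 1000))
  expect_equal(round(enrichFold(r3), 2), 1.32)
  ## monotone non-increasing in observed
  ps <- vapply(c(100, 500, 900, 1100), function(o)
    enrichP(empiricalEnrichment(o, nulls)), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("self-null resampling gives fold near 1", {
  set.seed(21)
  uni <- data.frame(distance = 10^runif(400, 3.2, 5.8),
                    hit = runif(400) < 0.3)
  idx <- sample.int(400, 60)
  obs <- sum(uni$hit[idx])
  ctrl <- sampleMatchedControls(uni$distance[idx], uni$distance,
                                nSets = 400, seed = 5)
  nulls <- vapply(1:400, function(s) sum(uni$hit[ctrl[s, ]]), numeric(1))
  r <- empiricalEnrichment(obs, nulls)
  expect_lt(abs(r@observed - mean(nulls)), 3 * sd(nulls))
})

test_that("Fisher loop enrichment matches the hypergeometric oracle", {
  ## direct contingency check through the public interface: build a
  ## universe whose in-loop status is planted, then verify counts/fold
  loops <- S4Vectors::Pairs(.gr(1000, 2000), .gr(9000, 10000))
  S4Vectors::mcols(loops)$p <- 0.001
  uni <- data.frame(chrom = "chr1",
                    bp1 = c(rep(1500, 130), rep(100, 870)),
                    bp2 = c(rep(9500, 130), rep(200, 870)))
  predicted <- c(rep(TRUE, 30), rep(FALSE, 100), rep(TRUE, 70),
                 rep(FALSE, 800))
  res <- fisherLoopEnrichment(uni, predicted, loops, pThresholds = 0.01)
  expect_equal(c(res$a, res$b, res$c, res$d), c(30, 70, 100, 800))
  expect_equal(res$fold, (30 / 100) / (130 / 1000))
  ## Fisher p against the exact hypergeometric tail computed directly
  oracle <- fisher.test(matrix(c(30, 70, 100, 800), 2, byrow = TRUE))$p.value
  expect_equal(res$fisher_p, oracle)
  ## predicted == universe: fold 1 at every threshold
  res2 <- fisherLoopEnrichment(uni, rep(TRUE, 1000), loops,
                               pThresholds = c(0.01, 1))
  expect_equal(res2$fold, c(1, 1))
})

test_that("state enrichment recovers a planted 2x enhancer signal", {
  set.seed(33)
  nU <- 1500
  bp <- seq(1000, by = 2000, length.out = nU)
  isEnh <- runif(nU) < 0.2
  states <- .gr(bp - 500, bp + 499,
                label = ifelse(isEnh, "EnhA", "Quies"))
  uni <- data.frame(chrom = "chr1", bp = bp,
                    dnam_variance = exp(rnorm(nU, 0, 0.5)))
  ## plant: PIDSs drawn preferentially from enhancer probes to double the rate
  enhIdx <- which(isEnh); bgIdx <- which(!isEnh)
  pids <- uni[c(sample(enhIdx, 80), sample(bgIdx, 120)), ]  # 40% EnhA
  res <- pidsStateEnrichment(pids, states, uni, nSets = 300, seed = 2)
  fold <- enrichFold(res$EnhA)
  expect_lt(abs(res$EnhA@observed - 2 * mean(nullValues(res$EnhA))),
            3 * sd(nullValues(res$EnhA)))
  expect_gt(fold, 1.5)
  expect_lt(enrichP(res$EnhA), 0.05)
  ## proportions over all states sum to 1
  labs <- stateAtProbes(uni, states)
  expect_equal(sum(table(labs)) / nU, 1)
})

test_that("eQTL enrichment honours the gene-matching rule", {
  eq <- data.frame(snp_id = c("e1", "e2"), chrom = "chr1",
                   bp = c(100500, 100500), gene = c("G1", "G2"),
                   p = 1e-9)
  sig <- data.frame(gene = "G1", chrom = "chr1", outcome_bp = 100000,
                    distance = 50000)
  uni <- rbind(sig, data.frame(gene = "G3", chrom = "chr1",
                               outcome_bp = 5e5, distance = 50000))
  ## only the eQTL of the pair's own gene counts
  expect_equal(PAIscan:::.countEqtlHits(sig, split(eq, eq$gene), 10000), 1L)
  expect_equal(PAIscan:::.countEqtlHits(
    transform(sig, gene = "G9"), split(eq, eq$gene), 10000), 0L)
})

test_that("eQTL enrichment recovers a planted 1.5x signal", {
  set.seed(55)
  nPairs <- 1200
  genes <- sprintf("G%03d", sample.int(60, nPairs, TRUE))
  uni <- data.frame(gene = genes, chrom = "chr1",
                    outcome_bp = seq(1e5, by = 2e4, length.out = nPairs),
                    distance = 10^runif(nPairs, 3.5, 5.5))
  sig <- uni[sample.int(nPairs, 150), ]
  isSig <- paste(uni$gene, uni$outcome_bp) %in%
    paste(sig$gene, sig$outcome_bp)
  hit <- runif(nPairs) < ifelse(isSig, 0.3, 0.2)
  eq <- data.frame(snp_id = sprintf("e%d", which(hit)), chrom = "chr1",
                   bp = uni$outcome_bp[hit] + sample(-4000:4000, sum(hit), TRUE),
                   gene = uni$gene[hit], p = 1e-9)
  res <- eqtlPidsEnrichment(eq, sig, uni, nSets = 300, seed = 9)
  expect_lt(abs(res@observed - 1.5 * mean(nullValues(res))),
            3 * sd(nullValues(res)))
  expect_gt(enrichFold(res), 1.15)
})

test_that("expression groups conserve counts and detect planted activity", {
  set.seed(66)
  genes <- sprintf("g%03d", 1:200)
  med <- c(rep(0.01, 40), 10^runif(160, -0.5, 3))
  tpm <- matrix(rep(med, 10), ncol = 10)  # constant across samples
  rownames(tpm) <- genes
  ## planted: interest genes all from the top quartile of active genes
  act <- genes[med >= 0.1]
  q3 <- quantile(med[med >= 0.1], 0.75, type = 7)
  interest <- sample(act[med[match(act, genes)] > q3], 25)
  res <- expressionGroupEnrichment(interest, tpm, genes, nSets = 300,
                                   seed = 4)
  expect_equal(sum(res$counts), 25)
  expect_gt(enrichFold(res$results$Q4), 2.5)
  expect_lt(enrichP(res$results$Q4), 0.05)
  ## per-set conservation
  expect_equal(res$nMissing, 0L)
  ## self-null: random interest set gives fold near 1 in every group
  interest2 <- sample(genes, 50)
  res2 <- expressionGroupEnrichment(interest2, tpm, genes, nSets = 300,
                                    seed = 5)
  for (g in names(res2$results)) {
    nv <- nullValues(res2$results[[g]])
    expect_lt(abs(res2$results[[g]]@observed - mean(nv)),
              3 * max(sd(nv), 0.5))
  }
})

test_that("co-expression enrichment recovers planted correlation", {
  set.seed(44)
  nG <- 120; nS <- 150
  genes <- sprintf("g%03d", 1:nG)
  Z <- matrix(rnorm(nG * nS), nG, dimnames = list(genes, NULL))
  ## planted pairs correlated at 0.4
  planted <- data.frame(gene1 = genes[1:20], gene2 = genes[21:40],
                        distance = 10^runif(20, 4, 5.5))
  for (i in 1:20)
    Z[planted$gene2[i], ] <- 0.4 * Z[planted$gene1[i], ] +
      sqrt(1 - 0.16) * rnorm(nS)
  tpm <- 5 * (1 + 0.3 * Z)
  uniPairs <- data.frame(gene1 = sample(genes[41:80], 300, TRUE),
                         gene2 = sample(genes[81:120], 300, TRUE),
                         distance = 10^runif(300, 4, 5.5))
  res <- coexpressionEnrichment(planted, tpm, uniPairs, nSets = 300,
                                seed = 3)
  expect_lt(abs(res@observed - 0.4), 3 * max(sd(nullValues(res)), 0.05))
  expect_true(res@truncated)
  ## identical expression vectors give r = 1
  tpm2 <- rbind(a = 1:10, b = 1:10, c = 10:1)
  one <- coexpressionEnrichment(
    data.frame(gene1 = "a", gene2 = "b", distance = 1000), tpm2,
    data.frame(gene1 = "a", gene2 = "c", distance = 1000), nSets = 10,
    seed = 1)
  expect_equal(one@observed, 1)
  ## mean r invariant to per-gene affine rescaling
  tpm3 <- tpm; tpm3["g001", ] <- 100 + 7 * tpm3["g001", ]
  res3 <- coexpressionEnrichment(planted, tpm3, uniPairs, nSets = 10,
                                 seed = 3)
  expect_equal(res3@observed, res@observed, tolerance = 1e-12)
})
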