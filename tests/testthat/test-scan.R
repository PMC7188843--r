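.toyMqtl <- function() {
  ## 5 probes on chr1: two in promoters, one of those without a 5e-8
  ## instrument, one in the blacklist region
  probes <- data.frame(probe_id = sprintf("cg%d", 1:5), chrom = "chr1",
                       bp = c(1000L, 5000L, 9000L, 50000L, 200000L),
                       stringsAsFactors = FALSE)
  st <- do.call(rbind, lapply(1:5, function(i)
    data.frame(probe_id = probes$probe_id[i], probe_chr = "chr1",
               probe_bp = probes$bp[i], snp_id = sprintf("rs%d", i),
               snp_chr = "chr1", snp_bp = probes$bp[i] + 10L, a1 = "A",
               a2 = "G", freq = 0.3, b = 0.5, se = 0.05,
               p = c(1e-20, 1e-3, 1e-20, 1e-20, 1e-20)[i], n = 1000L,
               stringsAsFactors = FALSE)))
  MqtlTable(st, probes)
}

test_that("Bonferroni thresholds reproduce printed values", {
  expect_equal(bonferroniThreshold(10416), 0.05 / 10416)
  expect_equal(signif(bonferroniThreshold(10416), 2), 4.8e-6)
  expect_equal(signif(bonferroniThreshold(11082), 3), 4.51e-6)
  expect_equal(bonferroniThreshold(1), 0.05)
  expect_error(bonferroniThreshold(0))
})

test_that("bait definition needs promoter membership and an instrument", {
  mq <- .toyMqtl()
  prom <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(900, 4900), c(1100, 5100)))  # cg1, cg2
  baits <- defineBaits(mq, prom)
  expect_equal(baits$probe_id, "cg1")  # cg2 lacks a 5e-8 instrument

  ## blacklisted promoter probe excluded
  cfg <- scanConfig(blacklist = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(500, 1500)))
  expect_error(defineBaits(mq, prom, cfg), "no bait")

  ## invariant to promoter row order
  baits2 <- defineBaits(mq, rev(prom))
  expect_equal(baits, baits2)
})

test_that("pair enumeration applies window and same-promoter exclusion", {
  probes <- data.frame(probe_id = c("b", "near", "far", "sameprom"),
                       chrom = "chr1",
                       bp = c(1e6, 1e6 + 5e5, 1e6 + 2.1e6, 1e6 + 100),
                       stringsAsFactors = FALSE)
  prom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6 - 200, 1e6 + 200))
  bait <- data.frame(probe_id = "b", chrom = "chr1", bp = 1e6)
  cand <- enumeratePairs(bait, probes, prom, scanConfig())
  expect_equal(cand$probe_id, "near")  # far outside 2 Mb, sameprom excluded
})

test_that("pair enumeration equals a brute-force filter on random layouts", {
  set.seed(12)
  probes <- data.frame(probe_id = sprintf("p%03d", 1:200),
                       chrom = sample(c("chr1", "chr2"), 200, TRUE),
                       bp = sample.int(6e6, 200), stringsAsFactors = FALSE)
  prom <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 20, TRUE),
    IRanges::IRanges(start = sort(sample.int(6e6, 20)), width = 2000))
  cfg <- scanConfig()
  for (i in sample.int(200, 5)) {
    bait <- probes[i, ]
    cand <- enumeratePairs(bait, probes, prom, cfg)
    ## brute force
    own <- which(bruteInPoint(bait$bp,
                              GenomicRanges::start(prom), GenomicRanges::end(prom)) &
                   as.character(GenomicRanges::seqnames(prom)) == bait$chrom)
    keep <- vapply(seq_len(nrow(probes)), function(j) {
      p <- probes[j, ]
      if (p$probe_id == bait$probe_id) return(FALSE)
      if (p$chrom != bait$chrom || abs(p$bp - bait$bp) > cfg$pairWindow)
        return(FALSE)
      !any(own > 0 &
             bruteInPoint(p$bp, GenomicRanges::start(prom)[own],
                          GenomicRanges::end(prom)[own]))
    }, logical(1))
    expect_setequal(cand$probe_id, probes$probe_id[keep])
  }
})

test_that("promoter-promoter orientation follows q2 with documented ties", {
  a <- data.frame(probe_id = "A", bp = 100, q2 = 0.10, top_p = 1e-10)
  b <- data.frame(probe_id = "B", bp = 200, q2 = 0.04, top_p = 1e-20)
  expect_equal(orientPromoterPair(a, b)$exposure$probe_id, "A")
  b$q2 <- 0.10  # tie on q2: smaller top p
  expect_equal(orientPromoterPair(a, b)$exposure$probe_id, "B")
  b$top_p <- 1e-10  # tie again: smaller bp
  expect_equal(orientPromoterPair(a, b)$exposure$probe_id, "A")
  a$q2 <- NA  # q2 undefined: fall back to top p
  expect_equal(orientPromoterPair(a, b)$exposure$probe_id, "A")
})

test_that("significance classification is strict and conservative on NA", {
  r <- data.frame(expo_probe = "e", expo_chr = "chr1", expo_bp = 1,
                  outcome_probe = sprintf("o%d", 1:10), outcome_bp = 2,
                  p_smr = c(0.05 / 10, 1e-9, rep(0.5, 8)),
                  p_heidi = c(0.5, NA, rep(0.5, 8)), distance = 1)
  pai <- new("PaiSet", records = r, nTests = 10L)
  cl <- classifySignificant(pai, scanConfig())
  rec <- paiRecords(cl)
  ## exactly at the threshold fails (strict inequality)
  expect_false(rec$pass_smr[1])
  ## significant SMR but NA HEIDI is not a PAI
  expect_true(rec$pass_smr[2])
  expect_false(rec$pass_heidi[2])
  expect_false(rec$is_pai[2])
  ## NA pass-through mode
  cl2 <- classifySignificant(pai, scanConfig(heidiNaPass = TRUE))
  expect_true(paiRecords(cl2)$is_pai[2])
})

test_that("scan summaries compute counts and distance quantiles", {
  r <- data.frame(expo_probe = "e", expo_chr = "chr1", expo_bp = 1,
                  expo_gene = "G1", outcome_probe = sprintf("o%d", 1:4),
                  outcome_bp = 2, p_smr = 1e-12, p_heidi = 0.5,
                  distance = c(10e3, 20e3, 30e3, 2e6))
  pai <- classifySignificant(new("PaiSet", records = r, nTests = 4L),
                             scanConfig())
  s <- summarizePais(pai)
  expect_equal(s$nPai, 4L)
  expect_equal(s$distance$median, 25e3)
  expect_equal(s$distance$fracOver1Mb, 0.25)
  expect_equal(unname(s$distance$quantiles["25%"]),
               unname(quantile(r$distance, 0.25, type = 7)))

  empty <- classifySignificant(
    new("PaiSet", records = r[0, ], nTests = 0L), scanConfig())
  s0 <- summarizePais(empty)
  expect_equal(s0$nPai, 0L)
  expect_true(is.na(s0$distance$median))
})

test_that("repeated scans of the same inputs are identical", {
  mr <- miniRegion(seed = 19)
  p1 <- paiRecords(runPaiScan(mr$mqtl, mr$promoters, mr$ld))
  p2 <- paiRecords(runPaiScan(mr$mqtl, mr$promoters, mr$ld))
  expect_identical(p1, p2)
})
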