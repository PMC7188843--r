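## random PSD correlation matrix of dimension k
.randCorr <- function(k, n = 50) {
  x <- matrix(rnorm(n * k), n)
  cor(x)
}

test_that("instrument selection prunes strong LD and keeps the top SNP", {
  st <- data.frame(snp_id = c("top", "s2"), b = c(0.5, 0.45),
                   se = 0.05, p = c(1e-20, 1e-15))
  ldr <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("top", "s2"),
                                                  c("top", "s2")))
  expect_equal(heidiSelectSnps(st, ldr, "top"), "top")  # r2 = 1 pruned

  ## 30 eligible SNPs in acceptable LD with the top: exactly 20 kept,
  ## the 20 most significant
  set.seed(5)
  ids <- c("top", sprintf("s%02d", 1:30))
  k <- length(ids)
  ldr2 <- matrix(0.1, k, k)                    # mutually weak LD
  ldr2[1, ] <- ldr2[, 1] <- 0.4                # r2 = 0.16 with top
  diag(ldr2) <- 1
  dimnames(ldr2) <- list(ids, ids)
  st2 <- data.frame(snp_id = ids, b = 0.5, se = 0.05,
                    p = c(1e-30, 10^-(29:0)))
  sel <- heidiSelectSnps(st2, ldr2, "top")
  expect_length(sel, 20L)
  expect_equal(sel, c("top", sprintf("s%02d", 1:19)))  # smallest p first
})

test_that("greedy selection never violates the pruning constraints", {
  set.seed(99)
  for (rep in 1:20) {
    k <- 15
    ids <- c("top", sprintf("s%d", 1:(k - 1)))
    ldr <- .randCorr(k, n = 30)
    dimnames(ldr) <- list(ids, ids)
    st <- data.frame(snp_id = ids, b = 0.5, se = 0.05,
                     p = c(1e-20, runif(k - 1, 1e-12, 1e-4)))
    sel <- heidiSelectSnps(st, ldr, "top")
    expect_true("top" %in% sel)
    sub <- ldr[sel, sel, drop = FALSE]^2
    expect_true(all(sub[upper.tri(sub)] <= 0.9 + 1e-12))
    nonTop <- setdiff(sel, "top")
    if (length(nonTop))
      expect_true(all(ldr[nonTop, "top"]^2 >= 0.05 - 1e-12))
  }
})

test_that("HEIDI covariance matches Monte-Carlo sampling of the ratios", {
  set.seed(7)
  g <- simulateGenotypes(4000, 5, ldDecay = 0.8, seed = 3)
  R <- cor(g)
  bzx <- c(0.45, 0.40, 0.35, 0.30, 0.28); sezx <- rep(0.01, 5)
  bzy <- bzx * 0.5; sezy <- rep(0.02, 5)
  hc <- heidiCovariance(bzx, sezx, bzy, sezy, R, topIndex = 1)
  nmc <- 20000
  L1 <- chol(R * tcrossprod(sezx)); L2 <- chol(R * tcrossprod(sezy))
  BX <- matrix(rnorm(nmc * 5), nmc) %*% L1 + rep(bzx, each = nmc)
  BY <- matrix(rnorm(nmc * 5), nmc) %*% L2 + rep(bzy, each = nmc)
  BXY <- BY / BX
  D <- BXY[, 2:5] - BXY[, 1]
  Vemp <- cov(D)
  mcse <- sqrt((Vemp^2 + tcrossprod(diag(Vemp))) / nmc)
  expect_lt(max(abs(hc$V - Vemp) / mcse), 3)
})

test_that("degenerate and floored covariances behave as documented", {
  ## identical stats in perfect LD: d = 0 and V singular at 0
  R <- matrix(1, 3, 3)
  hc <- heidiCovariance(rep(0.5, 3), rep(0.05, 3), rep(0.25, 3),
                        rep(0.05, 3), R)
  expect_equal(hc$d, rep(0, 2))
  expect_true(all(abs(diag(hc$V)) < 1e-15))
  expect_true(is.na(heidiTest(hc$d, hc$V)$p_heidi))

  ## diagonal of V is never negative after flooring
  set.seed(17)
  for (rep in 1:100) {
    k <- sample(3:8, 1)
    R <- .randCorr(k)
    hc <- heidiCovariance(runif(k, 0.2, 0.6), runif(k, 0.01, 0.05),
                          runif(k, -0.3, 0.3), runif(k, 0.01, 0.05), R)
    expect_true(all(diag(hc$V) >= -1e-15))
  }
})

test_that("HEIDI reduces to a plain chi-square for independent components", {
  expect_equal(weightedChisqTail(11.07, rep(1, 5)),
               pchisq(11.07, 5, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(weightedChisqTail(11.07, rep(1, 5), "imhof"),
               pchisq(11.07, 5, lower.tail = FALSE), tolerance = 1e-6)
  ## d = 0 gives p = 1
  V <- diag(3) * 0.01
  expect_equal(heidiTest(rep(0, 3), V)$p_heidi, 1)
})

test_that("Imhof quadrature matches Monte-Carlo tail probabilities", {
  set.seed(77)
  lam <- c(5, 1, 0.3, 0.1, 0.01)  # strongly skewed spectrum
  q <- 12
  nmc <- 2e5
  x <- colSums(lam * matrix(rchisq(5 * nmc, 1), 5))
  pMC <- mean(x > q)
  pI <- weightedChisqTail(q, lam, "imhof")
  expect_lt(abs(pI - pMC), 3 * sqrt(pMC * (1 - pMC) / nmc))
})

test_that("Satterthwaite tracks Imhof with known accuracy by p-value band", {
  ## two-moment matching is accurate near the centre and degrades in the
  ## far tail; assert the bands measured on LD-realistic eigen-spectra
  set.seed(41)
  nMod <- nTail <- 0
  for (rep in 1:200) {
    m <- sample(5:20, 1)
    g <- simulateGenotypes(400, m, ldDecay = runif(1, 0.5, 0.95))
    lam <- eigen(cor(g)[-1, -1], only.values = TRUE)$values
    q <- runif(1, 0.5, 4) * sum(lam)
    pI <- weightedChisqTail(q, lam, "imhof")
    if (pI < 1e-4 || pI > 0.5) next
    pS <- weightedChisqTail(q, lam, "satterthwaite")
    rel <- abs(pS - pI) / pI
    if (pI >= 0.05) { expect_lt(rel, 0.15); nMod <- nMod + 1 }
    else { expect_lt(rel, 1.0); nTail <- nTail + 1 }
  }
  expect_gt(nMod, 50)
  expect_gt(nTail, 20)
})

test_that("HEIDI p-values are calibrated under pleiotropy and reject linkage", {
  set.seed(23)
  nRep <- 120
  pPle <- pLink <- rep(NA_real_, nRep)
  cfg <- scanConfig()
  for (i in seq_len(nRep)) {
    g <- simulateGenotypes(1500, 30, ldDecay = 0.9)
    simP <- simulateMethylationPair(g, simScenario("pleiotropy", q2 = 0.15,
                                                   bXy = 0.5))
    r <- PAIscan:::.simSmrHeidi(g, simP$x, simP$y, 5e-8, cfg)
    if (!is.null(r)) pPle[i] <- r$pHeidi
    simL <- simulateMethylationPair(g, simScenario("linkage", q2 = 0.15,
                                                   rLink = 0.2))
    r <- PAIscan:::.simSmrHeidi(g, simL$x, simL$y, 5e-8, cfg)
    if (!is.null(r)) pLink[i] <- r$pHeidi
  }
  rejP <- mean(pPle < 0.01, na.rm = TRUE)
  rejL <- mean(pLink < 0.01, na.rm = TRUE)
  expect_lt(rejP, 0.10)      # near-nominal under the shared-causal null
  expect_gt(rejL, rejP + 0.2)  # linkage rejected far more often
})
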