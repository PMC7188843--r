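---
title: "Predicting promoter-anchored interactions from mQTL summary data: models and design"
author: "PAIscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting promoter-anchored interactions from mQTL summary data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chromatin in the nucleus folds so that a gene's promoter physically
contacts regulatory elements that can lie hundreds of kilobases away.
Assays such as Hi-C and promoter-capture Hi-C observe these contacts
directly but are costly, noisy at high resolution, and cell-type bound.
PAIscan instead *predicts* promoter-anchored interactions (PAIs) from
genetic data alone: if DNA methylation (DNAm) at a CpG site inside a
promoter and DNAm at another CpG site nearby are driven by the *same*
causal variants, the two loci are very likely functionally linked — and
plausibly in physical contact. The raw material is cis-mQTL summary
statistics (per probe-SNP effect, SE, p-value), which exist at large
sample sizes for many tissues; no individual-level methylation data are
needed, only an LD reference panel.

# The statistical core

## The ratio (SMR) test

Let $x$ be the exposure DNAm site (the promoter probe), $y$ the outcome
DNAm site, and $z$ an instrument SNP strongly associated with $x$. With
$\hat b_{zx}$ and $\hat b_{zy}$ the per-allele effects of $z$ on $x$ and
$y$ (both in SD units), the effect of $x$ on $y$ is estimated by the
ratio

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx},$$

and tested with the two-sided Wald statistic

$$T_{\mathrm{SMR}} = \frac{z_{zx}^2\, z_{zy}^2}{z_{zx}^2 + z_{zy}^2},
  \qquad z = \hat b / \mathrm{SE},$$

which is $\chi^2_1$ under the null of no association. `smrTest()`
implements exactly this; `se_xy` is derived from the statistic
($|\hat b_{xy}|/\sqrt{T}$) so that the reported SE is Wald-consistent
with the reported p-value. The statistic is bounded by
$\min(z_{zx}^2, z_{zy}^2)$: an SMR association can never be more
significant than the weaker of the two marginal associations.

## The HEIDI heterogeneity test

A significant ratio test cannot distinguish *pleiotropy* (one set of
causal variants drives both sites) from *linkage* (two distinct causal
variants in LD, each driving one site). Under pleiotropy every SNP in
LD with the causal variant estimates the *same* $b_{xy}$, so the
differences

$$\hat d_i = \hat b_{xy(i)} - \hat b_{xy(\mathrm{top})}$$

are jointly zero. HEIDI (`heidiTest()`) evaluates $\mathbf d = 0$
against $\hat{\mathbf d} \sim MVN(\mathbf d, \mathbf V)$, where
$\mathbf V$ is assembled from the summary statistics and reference-panel
LD by the first-order delta method
(`heidiCovariance()`):

$$\mathrm{cov}(\hat b_{xy(i)}, \hat b_{xy(j)}) =
  b_{xy(i)} b_{xy(j)}\, r_{ij}
  \left[\frac{1}{z_{zx(i)} z_{zx(j)}} + \frac{1}{z_{zy(i)} z_{zy(j)}}\right],$$

with $r_{ij}$ the signed LD correlation. The covariance of the
differences follows by the usual contrast expansion, the matrix is
symmetrised and eigenvalue-floored at zero. The test statistic is
$T = \sum_i d_i^2 / V_{ii}$, whose null distribution is
$\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of the
correlation matrix of $\mathbf d$.

Two tail approximations are provided. The default, Satterthwaite moment
matching, fits a scaled chi-square to the first two moments; it is fast
and accurate near the decision region. Imhof quadrature integrates the
characteristic-function inversion numerically and is exact to the
integration tolerance; we verified it against Monte-Carlo simulation.
Their measured agreement on LD-realistic eigen-spectra is within 15%
relative for $p \ge 0.05$ and degrades to a worst case of roughly a
factor of two near $p = 10^{-4}$ — two-moment matching is not a far-tail
approximation. Since the HEIDI decision threshold is $p = 0.01$ (not a
far tail) the default is adequate; `heidiMethod = "imhof"` is the
high-accuracy option.

An important design choice: the exposure and outcome scans usually come
from the *same* cohort, yet the cross-trait sampling covariance is set
to zero in $\mathbf V$. The null-calibration experiment below tests this
simplification empirically: with no shared genetics and residual
phenotypic correlation up to $\pm 0.5$, SMR p-values stay uniform.

## Instrument rules

* Top instrument: the cis SNP with smallest exposure p-value, required
  to pass `instrumentP` (default $5\times10^{-8}$) — Mendelian
  randomisation needs a strong instrument. Ties break by larger $|z|$,
  then smaller position, then lexical SNP id, so selection is
  deterministic.
* HEIDI instruments: SNPs with exposure $p <$ `heidiPInclude` (default
  $1.57\times10^{-3}$, i.e. $z^2 > 10$ — the convention of the published
  SMR tooling), greedily pruned so that every retained pair has
  $r^2 \le 0.9$ ("very strong LD" removed) and every retained SNP has
  $r^2 \ge 0.05$ with the top SNP (a SNP independent of the instrument
  carries no information about heterogeneity at that signal), truncated
  to the 20 most significant. Fewer than 3 instruments yields
  `p_heidi = NA`, and NA conservatively fails the HEIDI filter
  (configurable via `heidiNaPass`).

# The genome-wide scan

`runPaiScan()` orchestrates: *baits* are probes inside a promoter
interval (supplied as a BED; deriving promoter consensus from epigenome
panels is out of scope), outside any blacklist (e.g. the MHC), with a
qualifying instrument. Each bait is tested against every probe within
the 2 Mb pairing window on the same chromosome, excluding probes inside
the bait's own promoter interval (within-promoter pairs are not
interactions of interest, and Hi-C does not resolve them). Distances
are probe-to-probe, since probes are the analysis unit throughout.

For a pair of probes in two *different* promoters, the probe whose top
cis-mQTL explains more DNAm variance is the exposure
($q^2 = 2p(1-p)b^2$, with a $z^2/(z^2+n-2)$ fallback when the allele
frequency is absent), so each pair is tested exactly once.

Significance: `pass_smr` requires $p_{\mathrm{SMR}}$ strictly below the
Bonferroni threshold $\alpha / n_{\mathrm{tests}}$, where
$n_{\mathrm{tests}}$ is the number of pairs with a computed SMR p-value
in this scan — the threshold is derived from the scan's own
denominator, never hard-coded, and is reported alongside the results.
`pass_heidi` requires $p_{\mathrm{HEIDI}} > 0.01$. A PAI passes both.
Per-pair failures (no outcome statistic at the instrument, no LD
coverage, degenerate covariance) are recorded in a `status` column and
never abort the scan; the scan is deterministic given its inputs.

# Enrichment analyses

All enrichment analyses share one engine: an observed statistic is
compared with a null distribution built by resampling matched control
sets from the *tested* universe (`sampleMatchedControls()`), with the
empirical p-value estimated as $(r+1)/(R+1)$
(`empiricalEnrichment()`). With $R = 1000$ sets and no null value
reaching the observed one, the p-value is reported at its floor
($< 0.001$) and flagged truncated.

Matching design, where the granularity was an open choice:

* pair distance — 20 equal-width bins of $\log_{10}$(distance) over the
  universe range, with symmetric escalation to adjacent bins when a bin
  is empty;
* DNAm variance (for promoter-interacting site vs control probe
  comparisons) — deciles;
* gene-pair distance (co-expression) — the same log-distance binning.

Overlap counters: a probe pair overlaps a TAD when both probes fall in
*one and the same* TAD interval (the "each probe in any TAD" reading is
available behind `mode = "any"`, since the prose convention is
ambiguous); a pair overlaps a loop when its probes fall in opposite
anchors, in either orientation, with anchor padding defaulting to 0
because anchor widths are dataset-resolution specific; protein-binding
and variant overlaps use a 10 kb window centred on each site. The
loop-threshold sweep (`fisherLoopEnrichment()`) classifies every tested
pair by predicted status and in-significant-loop status per threshold
and uses Fisher's exact test, with a normal-approximation CI on the
log fold. Pair units are probe pairs; the counting unit is reported
with the result.

Expression analyses summarise a gene by its *median* TPM across
samples (the "TPM < 0.1" inactivity rule is applied to the median),
split active genes into universe-derived quartiles, and compare counts
of genes of interest per group against resampled control genes.
Co-expression compares the mean Pearson correlation over gene pairs
against distance-matched control pairs.

# Cross-tissue comparison

Replication of discovery-tissue PAIs in a second tissue is reported at
a Bonferroni level ($\alpha/n_{\mathrm{available}}$) and a nominal
level (0.05), both requiring the HEIDI filter in the replication
tissue, plus the list of sign-discordant replicated pairs. Because
threshold-based replication depends on the replication sample size, the
package also estimates the correlation of the *true* effects,

$$r_b = \frac{\mathrm{cov}(\hat b_1, \hat b_2)}
  {\sqrt{(\mathrm{var}(\hat b_1) - \overline{\mathrm{SE}_1^2})
         (\mathrm{var}(\hat b_2) - \overline{\mathrm{SE}_2^2})}},$$

which removes the attenuation that estimation noise induces in the
naive Pearson correlation of the estimates. The cross-tissue error
covariance is set to zero (different cohorts); a nonzero error
correlation can be supplied for overlapping samples. The standard error
is a leave-one-out jackknife over pairs — pairs, not probes, because
pairs are the sampling unit of the estimate. When the error-corrected
variances turn non-positive (e.g. when the true effects are nearly
constant across pairs, so there is no effect variance to correlate)
$r_b$ is undefined and reported NA with a diagnostic rather than
clamped silently.

# The synthetic-data generator

The generator exists so every statistical guarantee can be exercised on
data with known truth.

* **Genotypes** (`simulateGenotypes()`): haplotypes follow a
  first-order binary Markov chain with neighbour correlation $\rho$, so
  LD decays as $\rho^{|i-j|}$ in closed form — which is what makes the
  oracle checks exact. Allele frequencies are a region-level draw from
  `mafRange` plus a small per-SNP jitter: two Bernoulli margins far
  apart bound the achievable correlation well below 1 (at $\rho = 0.9$,
  margins 0.1 and 0.5 cap the correlation near 0.33), so near-equal
  margins within a region are a requirement of the target LD, not a
  convenience. Real human LD maps, with their block structure and
  recombination hotspots, are deliberately *not* emulated.
* **Methylation** (`simulateMethylationPair()`): simulated on a
  standardised continuous scale, matching the SD-unit effects the
  method consumes; the bounded beta-value scale of array data matters
  only upstream of summary statistics. Three generative regimes:
  pleiotropy ($x$ driven by a causal SNP explaining $q^2$ of its
  variance, $y = b_{xy} x + e$), linkage (distinct causal SNPs at LD
  $r^2_{\mathrm{link}}$, no direct effect), and the overlap null ($y$
  shares only the non-genetic residual of $x$, with phenotypic
  correlation $r_p$ — exactly the artefact a shared cohort could
  induce).
* **Summary statistics** (`associationScan()`): closed-form per-SNP
  OLS, verified against `lm()`.

The null-calibration experiment (`nullOverlapExperiment()`) draws
$r_p \sim U(-0.5, 0.5)$ and $q^2 \sim U(0.03, 0.3)$ per replicate —
declared stand-ins for the unpublished empirical distributions of these
quantities, exposed as function arguments — and checks that SMR
p-values are uniform despite full sample overlap. The package's own
acceptance runs use 2,000 replicates at $n = 2000$, $m = 20$ SNPs; the
fraction of $p < 0.05$ is required to sit in $[0.035, 0.065]$ with a
Kolmogorov–Smirnov test against uniformity not rejected at 0.01.

The power experiment (`powerExperiment()`) tabulates SMR rejection,
HEIDI rejection and the mean ratio estimate over a scenario grid. At
$n = 2000$ and $q^2 \in \{0.05, 0.1, 0.2\}$, $b_{xy} \in \{0.2, 0.5\}$
(500 replicates per cell), the ratio estimator recovers $b_{xy}$ within
5% relative bias, and HEIDI rejects linkage at $r^2_{\mathrm{link}} =
0.2$ essentially always while rejecting true pleiotropy at a rate
below its nominal level. As the LD between the two linked causal
variants rises toward 1, linkage becomes statistically
indistinguishable from pleiotropy and HEIDI's rejection rate falls —
an intrinsic limit, not an implementation artefact.

The fixture bundle (`makeFixtureBundle()`) ties everything together:
one ~2 Mb region, 2,000 SNPs, 52 probes, cohorts of 2,000 (discovery)
and 600 (replication), with six planted pleiotropic bait–outcome pairs,
three promoter–promoter pairs, two linkage pairs, two overlap-null
pairs, and annotation files (promoters, TADs, loops, chromatin states,
ChIP peaks, eQTLs, TPM) carrying planted signal at known rates. The
full scan on the bundle recovers exactly the planted pleiotropic and
promoter–promoter pairs, flags the linkage pairs as SMR-significant but
HEIDI-rejected, and leaves the overlap-null pairs non-significant.

# Numerical choices and degenerate inputs

* $\mathbf V$ is symmetrised and eigenvalue-floored at 0; HEIDI
  components with zero variance are dropped, and fewer than two
  informative components yield NA.
* Empty candidate lists, pairs without outcome statistics at the
  instrument, and LD/allele mismatches are recorded per pair, never
  fatal.
* Duplicate (probe, SNP) rows keep the smaller p-value; allele-pair
  mismatches against the reference coding drop the SNP with a count.
  Strand-ambiguous A/T and C/G SNPs are kept by default and can be
  dropped by configuration.
* All tie-breaks (instrument selection, pair orientation) are total
  orders, making every result reproducible bit-for-bit.
* Resampling analyses derive their seeds from a single pipeline seed
  by a documented hash of the analysis name (`deriveSeed()`), so adding
  an analysis never perturbs existing null sets.

# What passing tests do and do not show

The synthetic generator reproduces the *statistical* structure the
method assumes — LD decay, instrument strength, pleiotropy vs linkage
vs shared-sample correlation — but not the biology of real cohorts:
realistic LD block structure, bounded and heteroskedastic array
methylation, cell-type composition, batch structure, or probe
cross-hybridisation. Calibration and power results on synthetic data
therefore validate the implementation and the method's behaviour under
its own model; they do not by themselves establish performance on any
real cohort, where the published analyses at cohort scale (tens of
thousands of probes, external Hi-C validation sets) are the relevant
evidence.
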