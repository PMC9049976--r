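---
title: "Methods: two-sample MR for epigenetic age acceleration and cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for epigenetic age acceleration and cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockmr)
```

## The problem

Epigenetic clocks predict biological age from DNA methylation; their
*acceleration* (predicted minus chronological age, in years) associates
with cancer in observational cohorts, but such associations are vulnerable
to confounding and reverse causation. Two-sample Mendelian randomization
sidesteps both by using germline variants as instruments: SNP–exposure
effects $\gamma_j$ (per-allele years of clock acceleration) come from one
GWAS, SNP–outcome effects $\Gamma_j$ (per-allele log odds of cancer) from
another, and under the instrumental-variable assumptions the per-SNP Wald
ratio $\theta_j = \Gamma_j / \gamma_j$ estimates the causal log odds ratio
per year of acceleration. `clockmr` implements that full design — the four
clocks (HannumAge, Intrinsic HorvathAge, PhenoAge, GrimAge) against five
cancers (breast, ovarian, prostate, lung, colorectal) with per-source
estimates pooled across UK Biobank, FinnGen and the international
consortia — as generic, reusable machinery.

## Harmonisation

Both GWAS must report effects for the same allele. For each shared rsid the
outcome association is re-oriented onto the exposure's effect allele:
identical allele pairs are copied; swapped pairs get $\Gamma \to -\Gamma$
and $\mathrm{eaf} \to 1-\mathrm{eaf}$; for non-palindromic single-nucleotide
pairs the strand complement (and swapped complement) is resolved the same
way. Palindromic SNPs (A/T, C/G) are strand-ambiguous by construction, so
orientation is inferred from allele frequency: when the minor allele
frequency is below 0.3 (strict) in *both* datasets, the orientation that
makes the minor alleles coincide is chosen; at or above 0.3 in either
dataset the SNP is excluded (`palindromic_high_maf`), since a frequency
near 0.5 cannot identify the strand. Requiring the frequency check in both
datasets, and excluding palindromic SNPs when either frequency is missing
(`palindromic_missing_eaf`), are the conservative choices; the threshold is
a parameter. Partially overlapping allele sets are excluded as
`strand_mismatch`, disjoint ones as `allele_mismatch`; indels pass through
with exact matching only. These rules make harmonisation invariant to how
either file happens to label its alleles, which the test suite asserts on
randomised fixtures.

## Instrument selection and strength

Instruments are variants with exposure $P < 5\times10^{-8}$ (strict),
pruned by greedy clumping: candidates are ordered by ascending p-value
(ties: larger $|\beta/SE|$, then rsid, for determinism) and accepted iff
their $r^2$ with every accepted variant is below 0.001. The LD reference is
an explicit local matrix; pairs absent from it count as independent with a
warning, and no distance window is applied by default (the rule is purely
$r^2$; a window would be redundant given an explicit reference).
Instruments missing from the outcome GWAS may be replaced by the available
variant with maximal $r^2 > 0.8$ (ties: smaller outcome p-value, then
rsid). Strength uses the summary-statistic identities
$$ r^2_j = \frac{2\beta^2 p(1-p)}{2\beta^2 p(1-p) + 2Np(1-p)SE^2},
   \qquad F_j = \frac{r^2_j (N-2)}{1-r^2_j}, $$
with $p$ the minor allele frequency; $F \le 10$ flags conventional
weakness. Total variance explained is $\sum_j r^2_j$.

## Estimators

All estimators act on the harmonised table, dropping excluded rows.

- **IVW** is weighted regression of $\Gamma$ on $\gamma$ through the
  origin with weights $1/SE_\Gamma^2$ — identically the inverse-variance
  mean of Wald ratios with first-order delta weights. The
  *multiplicative random-effects* form (the default, and the study's main
  method) multiplies the fixed-effect standard error by the residual SD
  $\hat\phi = \sqrt{Q/(k-1)}$ with **no flooring at 1**, matching the
  convention of the standard MR tooling; the fixed form uses unit residual
  variance. Cochran's $Q$ with $k-1$ df quantifies per-SNP heterogeneity.
  With $k$ small the MRE z-statistic is approximately $t_{k-1}$ rather than
  normal (at $k=4$, a nominal 5% normal test rejects a true null roughly
  14% of the time), which is why the calibration checks below use the
  fixed form on data that are homogeneous by construction.
- **MR-Egger** frees the intercept after orienting $\gamma_j \ge 0$; the
  slope is the causal estimate and the intercept the average directional
  pleiotropy. Standard errors are scaled by $\max(1, \hat\phi)$ (flooring
  *is* applied here, per the method's original description) and inference
  uses $t_{k-2}$.
- **Weighted median**: order Wald ratios, give the $j$-th ordered ratio
  cumulative percentile $p_j = \sum_{i\le j} w_i - w_j/2$ with normalised
  inverse-variance weights, and interpolate linearly at 0.5. Standard
  errors come from a parametric bootstrap resampling
  $(\hat\gamma_j, \hat\Gamma_j)$ from their normal sampling distributions
  (default 1,000 draws; the seed is an explicit argument).
- **Weighted mode**: the maximiser of a weighted Gaussian KDE of the
  ratios with bandwidth $\varphi \cdot 0.9\min(SD, MAD)/k^{1/5}$
  ($\varphi = 1$ by default); bootstrap standard errors as above.
- **Wald ratio** variance uses the first-order delta method
  $SE_\Gamma/|\gamma|$ (the tooling convention); a second-order option
  adds the $SE_\gamma$ term.
- **Steiger**: per-SNP variance explained in exposure versus outcome.
  Continuous traits use the $r^2$ identity above; binary traits use the
  observed-scale pseudo-$r^2$, $2p(1-p)\,b^2\,K(1-K)$ with $K$ the case
  fraction (a liability-scale option rescales by
  $K(1-K)/\phi(\Phi^{-1}(K))^2$). The direction is exposure→outcome iff
  the summed exposure $r^2$ exceeds the outcome's; the p-value is a
  z-test on the difference of Fisher-transformed correlations; filtering
  retains SNPs with $r^2_{\mathrm{exposure}} > r^2_{\mathrm{outcome}}$.

Confidence intervals are normal-theory except MR-Egger's $t_{k-2}$. ORs are
$e^\theta$ with exponentiated limits; all arithmetic stays on the log
scale.

## Meta-analysis and multiplicity

Per-outcome estimates from different study sources are pooled by
fixed-effect inverse-variance weighting; the pooled variance is exactly
$1/\sum SE_i^{-2}$. Heterogeneity is $I^2 = \max(0, (Q - df)/Q)\cdot 100$
with a test-based confidence interval on the $\ln H$ scale (Higgins &
Thompson); with two studies that interval is reported as `NA` — at $k=2$
the $\ln H$ variance approximation has no usable degrees of freedom, which
also matches how such results are conventionally reported. Study-overlap
exclusions (colorectal pools GECCO + FinnGen only, because UK Biobank
participants are inside GECCO) are plan configuration, not code.
Benjamini–Hochberg q-values use a configurable family size $m$ so partial
runs stay comparable to the full 20-test design (4 clocks × 5 cancers);
`bh_fdr()` itself defaults to $m =$ the number of p-values supplied, the
only default consistent with $q = p$ for a single test.

## Power

For a binary outcome with case fraction $K$, an instrument set explaining
$R^2$ of the exposure, and total outcome sample $N$, the causal log OR
$\ln(\mathrm{OR})$ attenuates on the observed (0/1) scale to
$\ln(\mathrm{OR})\,K(1-K)$ while the IVW estimator's variance is
$K(1-K)/(N R^2)$, giving the Wald-test noncentrality
$$ \mathrm{NCP} = \ln(\mathrm{OR})^2 \, N \, R^2 \, K(1-K) $$
and power $P\{\chi^2_1(\mathrm{NCP}) > \chi^2_{1,1-\alpha}\}$. Among the
binary-outcome approximations used by MR power calculators we adopt this
observed-scale attenuation form because it is the one whose 80%-power
detectable-OR grid over the study design (four clock $R^2$ values ×
five cancer meta-analyses) reproduces the published 1.04–1.39 range; it
also agrees with simulating the estimator itself to within two percentage
points at the design points the tests check. `min_detectable_or()` inverts
the formula by bisection to $10^{-4}$ on the OR scale; the protective
direction returns the reciprocal.

## The synthetic-data generator

`simulate_two_sample()` emulates the statistical structure the pipeline
assumes, not any particular cohort:

- The exposure is continuous with unit variance (years of clock
  acceleration); true effects are scaled so $\sum_j 2p_j(1-p_j)\gamma_j^2$
  equals the target $R^2$ exactly, with per-SNP shares uniform within
  ±25% of equal and random signs. The tight spread mirrors published
  instrument sets, whose F-statistics cluster (e.g. 31–45 for a
  4-SNP, 0.47% set at $N = 34{,}710$) rather than spanning orders of
  magnitude — and guarantees the instruments are genome-wide significant,
  as selected instruments are by construction.
- Observed effects are truths plus normal noise:
  $SE_\gamma = 1/\sqrt{2p(1-p)N}$ for the exposure and the
  logistic-score approximation
  $SE_\Gamma = 1/\sqrt{2p(1-p)\,n_{\mathrm{case}}n_{\mathrm{control}}/N}$
  for the outcome. Pleiotropy $\alpha_j$ enters
  $\Gamma_j = \theta\gamma_j + \alpha_j$ on the exposure-increasing
  orientation: balanced (mean 0), directional (mean $\mu_p$), or
  correlated ($\alpha_j = q_c u_j$ with the confounder loading $u_j$ also
  added to $\gamma_j$ — the configuration under which a null $\theta$
  still produces a biased IVW estimate, the caveat that motivates
  genome-wide pleiotropy-aware methods).
- Reverse-causal SNPs are planted with exposure z-score 8 (just past
  selection) and an outcome effect sized to explain a fixed multiple
  (default 4×) of their exposure variance — the margin that lets Steiger
  filtering identify them essentially deterministically.
- LD blocks duplicate lead SNPs into proxies with effects shrunk by
  $\sqrt{r^2}$, inheriting the lead's alleles and frequency (a deliberate
  simplification: real proxies need an allele translation table), plus the
  matching $r^2$ reference.
- One master seed drives fixed per-stage substreams (frequencies, effects,
  pleiotropy, the two noise layers), so the same seed reproduces the draw
  byte-for-byte while stages stay separately reproducible.

`scenario_presets()` pins the four clock-like configurations
(9 / 24 / 11 / 4 SNPs explaining 1.48 / 4.41 / 1.86 / 0.47%, exposure
$N = 34{,}710$) with outcome sizes equal to the colorectal meta-analysis
(61,153 cases / 241,353 controls), the scale of the study's headline
result.

**What passing tests do and do not show.** The generator draws independent
instruments with exactly known noise, no sample overlap between the two
GWAS, no selection of instruments on the observed exposure data (the
two-sample design's separation is taken as given), and logistic-score
rather than genuinely binary outcomes. Calibration results on it (nominal
type-I error, ~95% CI coverage, power agreeing with the formula) therefore
validate the estimators and the pipeline plumbing — not robustness to
winner's curse, cryptic overlap, or real LD structure. One real-data
phenomenon *is* reproduced: with instruments of moderate strength
(mean $F \approx 41$ for the GrimAge-like preset), exposure measurement
error attenuates the mean IVW estimate toward the null by a factor
$\approx 1/(1+1/\bar F)$, i.e. about 2–3% relative. The recovery check
accordingly asserts the mean estimate within 0.01 on the log-OR scale
(1% on the OR scale) of the planted $\ln(1.12)$, a band that contains this
inherent dilution but would catch any implementation error of consequence.

## Problem sizes and numerical choices

The test suite runs 2,000 replicates for the calibration, type-I-error and
robustness checks (Monte-Carlo SE ≈ 0.5 percentage points on a 5% rate),
300 for Steiger direction, 100-fixture oracle sweeps at $10^{-10}$, and
1,000 random p-vectors for the FDR oracle — sizes chosen so the whole
suite completes in minutes while keeping Monte-Carlo error well inside
every asserted band. Bisection tolerance is $10^{-4}$ (OR scale); p-values
are floored at $10^{-300}$ to avoid underflow to an invalid zero; ties in
clumping and proxy choice are broken deterministically as described above;
degenerate inputs (single instrument, identical ratios, zero $\gamma$)
reduce to the documented special cases or fail with informative errors.

## Known limitations

Genome-wide pleiotropy-aware models (Bayesian correlated-pleiotropy
analysis, LD-score genetic correlations) are out of scope, as are
GWAS-VCF input, genome-build liftover, multi-allelic variants, and
computing LD from genotypes. The weighted mode is unreliable with very few
SNPs (its published caveat); MR-Egger at $k = 4$ is close to
uninformative, visible in the worked example's interval. Binary-exposure
Steiger calculations use the observed-scale approximation unless the
liability option is chosen; neither is exact for parental-history
(GWAS-by-proxy) outcomes, whose effect scale differs from direct
case-control GWAS and is deliberately left uncorrected.
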