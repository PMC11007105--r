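---
title: "Methods: two-sample Mendelian randomization screens with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization screens with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Observational associations between circulating proteins and disease are
confounded and reverse-causation-prone. Two-sample Mendelian randomization
(MR) sidesteps both by using genetic variants as instruments: a SNP that
robustly shifts a protein's level, and that affects disease only through the
protein, identifies the protein's causal effect from two independent GWAS —
one for the exposure (here, protein levels measured in a pQTL study), one
for the outcome (a disease case-control GWAS). `mrscreen` implements the
full screening workflow: instrument selection and QC, allele harmonization,
five estimators, sensitivity diagnostics, cross-cohort meta-analysis with
Bonferroni control, and a synthetic-data generator with known ground truth
so that every stage is testable without access to the original cohorts.

## The model

For SNP $j$, let $\hat\gamma_j$ (SE $\sigma_{X_j}$) be its association with
the exposure in SD units and $\hat\Gamma_j$ (SE $\sigma_{Y_j}$) its
association with the outcome in log-odds. Each valid instrument gives a
Wald ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order
delta-method SE $\sigma_{Y_j}/|\hat\gamma_j|$.

**IVW.** The inverse-variance-weighted estimate combines the ratios with
weights $w_j = \hat\gamma_j^2/\sigma_{Y_j}^2$:
$\hat\beta = \sum w_j \hat\beta_j / \sum w_j$, equivalent to weighted
regression of $\hat\Gamma$ on $\hat\gamma$ through the origin. The
fixed-effect SE is $(\sum w_j)^{-1/2}$; the primary estimator is the
multiplicative random-effects (MRE) variant, which inflates the SE by
$\sqrt{\max(1, Q/(J-1))}$ with Cochran's
$Q = \sum w_j (\hat\beta_j - \hat\beta)^2$, so heterogeneity widens the
interval but can never shrink it.

**MR-Egger.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ with a
free intercept, after orienting each SNP so $\hat\gamma_j \ge 0$. The slope
is consistent under InSIDE (direct effects independent of instrument
strength); the intercept estimates the mean directional pleiotropic effect.
SEs use a multiplicative overdispersion scale floored at 1 and a
$t_{J-2}$ reference.

**Weighted median.** The inverse-variance-weighted median of the ratios,
consistent while instruments carrying at least half the weight are valid.
The SE comes from a seeded parametric bootstrap (default 1000 draws).

**Maximum likelihood.** Joint normal model
$\hat\gamma_j \sim N(\gamma_j, \sigma_{X_j}^2)$,
$\hat\Gamma_j \sim N(b\,\gamma_j, \sigma_{Y_j}^2)$ with the per-SNP
$\gamma_j$ profiled out in closed form; $b$ is found by one-dimensional
profile maximization and its SE from the profile curvature. Unlike IVW it
models exposure-side measurement error, which is why its bias is smaller
when instruments are only moderately strong.

**Sensitivity.** Cochran's $Q$ (the same $Q$ that scales the MRE interval —
one source of truth), the Egger intercept test, and the Steiger
directionality test, which compares the variance the instruments explain in
the exposure against the outcome. For binary outcomes the log-odds effects
are converted with the logistic-variance approximation
$r^2 = v/(v + \pi^2/3)$, $v = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$, and
the effective sample size $4/(1/\text{cases} + 1/\text{controls})$ is used.
A tie ($r^2_{exp} = r^2_{out}$) is conservatively reported as *not* the
correct direction. Steiger is reported at pair level (aggregated over
instruments), not applied as a per-SNP filter.

**Meta-analysis.** Per-protein estimates from named cohorts are pooled by
inverse variance (fixed effect), switching to DerSimonian–Laird random
effects when the between-cohort $I^2 = \max(0, (Q-\mathrm{df})/Q)$ exceeds
30% (strict inequality; with two cohorts $I^2$ has one degree of freedom
and is volatile — this is documented behaviour, not smoothed away).
Significance is tiered against an explicit Bonferroni family size: below
$\alpha/m$, "nominal" between $\alpha/m$ and $\alpha$, else null. The
family size $m$ is always passed explicitly, never inferred from the data,
so multiplicity cannot drift silently.

## Instrument QC pipeline

`run_pair()` applies, in order: genome-wide significance
($p < 5\times10^{-8}$, strict), greedy p-value-ranked LD clumping
($r^2 < 0.001$ within 10,000 kb when positions are available; ties broken
lexicographically by rsID so the result is independent of input order), an
offline exclusion list standing in for confounder-database lookups,
harmonization, and the weak-instrument filter
$F = R^2(N-2)/(1-R^2) \ge 10$ with
$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$. When EAF is unavailable the
$F \approx (\beta/\mathrm{SE})^2$ fallback is used and flagged.

Harmonization joins on rsID only, detects allele swaps (outcome beta
negated, EAF complemented), drops non-concordant allele sets, and removes
palindromic (A/T, C/G) variants outright under the default strict policy.
An opt-in `maf_infer` policy retains palindromes whose frequencies are
unambiguous on both sides (both outside [0.42, 0.58] and on the same side
of 0.5); strand inference by complement matching is deliberately not
attempted — removal, not inference, is the default resolution of ambiguity.
Outcome-side EAF may be missing (common in older disease GWAS); it is only
required on the exposure side, for F statistics and Steiger.

## The synthetic world

`sim_config()` / `simulate_pair()` generate paired summary statistics with
known truth. Defaults describe the world this kind of screen lives in:

* exposure N = 14,824 (a pooled pQTL panel); outcome N = 898,130 for a
  large T2D meta-analysis, 22,326 for a replication cohort; complication
  endpoints use FinnGen-shaped case counts (hundreds to thousands of cases
  against ~308,000 controls);
* per-SNP exposure variance explained averages 0.005 (F ≈ 74) with a
  lognormal spread (sdlog = 1), because real instrument panels span roughly
  two orders of magnitude in F — equally strong instruments would both be
  unrealistic and leave MR-Egger's slope practically unidentifiable;
* standard errors follow $1/\sqrt{2N\,\mathrm{maf}(1-\mathrm{maf})}$; MAFs
  are uniform on (0.05, 0.45);
* pleiotropic direct effects are drawn independently of instrument strength
  (InSIDE holds by construction) and are anchored to the
  exposure-increasing allele, so a nonzero mean is genuinely directional;
* binary outcomes are emitted directly on the log-odds scale — no
  individual-level liability simulation. This is an approximation: it
  reproduces the estimator geometry exactly but not logistic-regression
  finite-sample artefacts;
* palindromic variants and swapped-allele reporting are injected at
  configurable rates to exercise harmonization.

What a green test does establish: estimator algebra, QC semantics,
calibration under the null, robustness semantics (median vs IVW under
contamination, Egger under directional pleiotropy), and directionality.
What it does not: realism of genome-wide LD (blocks are synthetic and
block-diagonal), selection effects in the original pQTL study, sample
overlap (assumed absent, as in a two-sample design), or anything about the
true biology of any specific protein.

`simulate_screen_study()` scales this up to a coherent exposures × outcomes
world: each protein has its own instrument panel, outcomes observe every
panel through a matrix of true causal effects, and each outcome carries its
own polygenic loci that touch no protein — which is what makes the reverse
direction analysable (and null, when the world is built forward-causal).

## Numerical choices

* Ratio-based IVW carries an intrinsic weak-instrument attenuation of order
  $b/\bar F$; at the default $\bar F \approx 72$ this is ~1.4% of the
  effect, well inside one estimator SD. Tests therefore compare mean
  recovery against the estimator's sampling SD, not against the
  (vanishingly small) SE of a 1000-replicate mean, which no ratio estimator
  could meet.
* The MRE scale and the Egger overdispersion scale are floored at 1:
  underdispersion never narrows intervals.
* MR-Egger refuses a panel whose oriented exposure effects are all equal
  (slope unidentifiable) with an informative error.
* The maximum-likelihood profile is optimized on an interval that widens
  geometrically until the optimum is interior; a non-concave profile at the
  optimum raises an error rather than returning a bogus SE.
* Weighted-median interpolation clamps at the extreme ratios when the
  median weight falls outside the cumulative midpoints.
* Clumping ties on p-value break lexicographically by rsID; missing LD
  pairs count as $r^2 = 0$; a missing position disables the window test for
  that pair rather than discarding the SNP.
* All stochastic steps (bootstrap, simulation) take explicit seeds; a
  screen re-run with the same config and inputs is byte-identical,
  manifests included (no timestamps).

## Open design points, decided

* "Weighted mean" in some descriptions of this workflow is read as the
  weighted median; no sixth estimator is implemented.
* The Bonferroni thresholds for the two screening families are
  $0.05/91 \approx 5.5\times10^{-4}$ (a 91-protein panel) and
  $0.05/20 = 2.5\times10^{-3}$ (4 proteins × 5 complications); where a
  figure caption and a methods text disagree on the former, the arithmetic
  wins.
* The 10,000 kb clumping window is applied *in addition to* pairwise
  $r^2$ when positions are supplied, and skipped otherwise — both
  behaviours are available because position files are optional.
* Palindrome orientation by outcome-side frequency before removal is not
  attempted by default (removal is the default policy).
* Reverse-direction instruments are re-derived from the outcome GWAS under
  the same thresholds; the demo analysis additionally applies the exclusion
  list to strip protein-instrument SNPs from the reverse set, standing in
  for the confounder-lookup step a live analysis would perform.
* Config files are JSON (`read_analysis_config()`): the only structured
  text format with a reader guaranteed in this package's dependency
  footprint.

## Limitations

Single-variant joins are by rsID only (no positions, no liftover, no
multi-allelic support, no proxy lookup for instruments missing in the
outcome). LD must be supplied as a precomputed pairwise $r^2$ table —
the package never computes LD from genotypes. MR-PRESSO-style outlier
removal, mode-based estimators, multivariable MR and sample-overlap
corrections are out of scope. The binary-trait variance conversion in
Steiger is a pragmatic approximation, isolated in one function
(`mrscreen:::r2_binary_logodds`) for replacement.
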