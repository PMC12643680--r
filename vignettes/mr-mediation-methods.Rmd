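---
title: "Methods: two-sample MR with product-of-coefficients mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with product-of-coefficients mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome
from GWAS summary statistics. `mrmediate` implements a *mediating* MR
design: given a collection of exposures (e.g. flow-cytometry immune-cell
traits), candidate mediators (e.g. circulating inflammatory cytokines)
and disease outcomes (e.g. lung-cancer subtypes), it screens all
exposure–mediator–outcome triples with three two-sample MR legs and
decomposes each candidate pathway's total effect into direct and
mediated components by the product-of-coefficients method.

The coefficients are

* $\beta_0$ — total effect of the exposure on the outcome (log-odds per
  SD of the exposure),
* $\beta_1$ — effect of the exposure on the mediator (SD per SD),
* $\beta_2$ — effect of the mediator on the outcome (log-odds per SD),

with indirect effect $\beta_1\beta_2$, direct effect
$\beta_0-\beta_1\beta_2$ and mediation proportion
$\beta_1\beta_2/\beta_0$.

## Instrument selection

Candidate instruments must pass a p-value threshold, survive greedy LD
clumping (retain the smallest-p SNP, remove neighbours within the window
whose $r^2$ exceeds the cutoff), and be strong by the F-statistic:

$$R^2 = \frac{\beta^2}{\beta^2 + se^2\,n}, \qquad
  F = \frac{R^2\,(n-2)}{1-R^2},$$

with $F \ge 10$ required. Two named presets ship with the package:
`"immune"` ($p<10^{-5}$, $r^2<0.1$, 500 kb — the profile used for
high-dimensional immune-trait exposures) and `"cytokine_outcome"`
($p<5\times10^{-6}$, $r^2<0.001$, 10{,}000 kb — the profile for
cytokines and disease outcomes). $R^2$ and $F$ use each record's own
sample size, so mixed-`n` GWAS tables are handled per SNP. Ties in the
clumping p-value order are broken lexicographically by SNP id so the
operation is deterministic; SNPs absent from the LD reference are
treated as LD-independent with a warning rather than discarded, keeping
the operation total on partial references.

## Harmonization

Outcome records are aligned to the exposure's effect allele: swapped
alleles flip the outcome beta, strand flips are resolved by
complementation, and palindromic SNPs (A/T, G/C) are dropped when either
effect-allele frequency is missing or inside $[0.42, 0.58]$ (otherwise
they are oriented by frequency agreement). These are the standard
two-sample conventions; the window half-width is exposed as
`palindrome_eaf_window`. Dropped rows remain in the harmonized object
with their reason and are excluded from estimation.

## Estimators

Six estimators run on the harmonized Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order weights
(the `Open Questions` of second-order weighting and NOME adjustment are
resolved in favour of the simpler first-order convention):

* **IVW (fixed effects)** — weighted regression through the origin with
  weights $1/se_{Yj}^2$; SE $=(\sum w_j \beta_{Xj}^2)^{-1/2}$.
* **IVW (multiplicative random effects)** — same point estimate; SE
  inflated by $\max\{1, \sqrt{Q/(J-1)}\}$, never below the fixed SE.
  The primary model is chosen by Cochran's Q: multiplicative random
  effects iff the Q p-value is strictly below 0.05.
* **MR-Egger** — weighted LS with intercept after orienting all
  $\beta_{Xj}\ge 0$; the intercept estimates the mean directional
  pleiotropic effect. SEs and p-values use Student's t with $J-2$ df
  from the weighted-LS fit as estimated (no floor on the residual
  scale); this keeps the intercept test exactly calibrated under the
  null, which the type-I-error suite verifies.
* **Weighted median** — ratios ordered ascending, inverse-variance
  weights normalized, estimate interpolated at cumulative percentile
  0.5; SE by seeded parametric bootstrap.
* **Simple and weighted mode** — kernel-density mode of the ratios with
  the modified Silverman bandwidth
  $0.9\,\min(sd, mad)\,J^{-1/5}$ scaled by `bandwidth_factor`
  (falling back to the non-zero of sd/mad under ties); SE by seeded
  parametric bootstrap. Bootstrap defaults: 1000 resamples, seed
  20240101, both overridable through `mr_settings()`.

Method minima are 1 instrument for the Wald ratio, 2 for IVW, median and
modes, 3 for Egger; `run_all_methods()` runs whatever is applicable. All
p-values use the normal reference except Egger's t.

## Diagnostics

* **Cochran's Q** with $J-1$ df gates the IVW model (above).
* **Egger intercept test** (t, $J-2$ df) flags directional pleiotropy;
  in the screening stage a firing intercept *downgrades* a pathway
  (flag) rather than excluding it.
* **MR-PRESSO** implements the global residual-sum-of-squares test with
  leave-one-out IVW slopes, parametric simulation of the null RSS
  distribution (empirical p with the $+1$ correction, so never 0), a
  per-SNP outlier test with Bonferroni adjustment at level 0.05, and a
  distortion test comparing the outlier-removed shift against removals
  of random subsets of the same size. Defaults: 1000 simulations,
  explicit seeds recorded in the report. When outliers are flagged the
  outlier-free IVW estimate is reported alongside the full-set fit.

## Screening and mediation

A pathway (X, M, Y) is a candidate when all three legs are significant —
by default raw primary-IVW $p<0.05$ (the primary screening threshold),
optionally the stricter Benjamini–Hochberg rule with adjustment within
each (outcome, leg-type) family — and the reverse X←Y IVW is *not*
significant at 0.05. The reverse threshold is a design choice: the
bidirectional design needs some criterion, and 0.05 mirrors the forward
threshold. Both BH modes exist because adjustment can legitimately gate
either candidate selection or only reporting.

For candidates, the indirect effect uses the first-order (Sobel) delta
variance $\beta_2^2 se_1^2+\beta_1^2 se_2^2$ (a second-order term and a
seeded Monte-Carlo interval — which emulates distribution-of-the-product
behaviour — are available by flag). When the indirect and total effects
have opposite signs the mediation is *inconsistent*: the proportion is
reported `NA` while the effect CI is still given. Total effects supplied
as odds ratios are converted with $\ln(\text{OR})$; the package never
rescales a printed coefficient silently, so a table column with a
decimal-place misprint will reproduce only when the corrected input
(e.g. $\ln$ of the printed OR) is supplied explicitly.

## The synthetic-data generators

Real immune-trait, cytokine and cancer GWAS are large downloads; all
testing runs on simulated summary statistics with known truth.

`simulate_triplet()` draws genotypes (haplotype-copy chains give
block-LD with the configured within-block $r^2$; MAF constant within a
block so marginals are preserved), builds $X$, $M$ and a binary $Y$ from
the structural model
$X=\sum_j\gamma_jG_j+\varepsilon_X$, $M=\beta_1X+\varepsilon_M$,
liability $=(\beta_0-\beta_1\beta_2)X+\beta_2M+\sum_{j\,\in\,\text{invalid}}\alpha_jG_j+\varepsilon_Y$
thresholded at the prevalence, and computes per-SNP summary statistics
in three *disjoint* cohorts by vectorized score regression (binary
traits rescaled to the logistic scale by $1/\bar p(1-\bar p)$ — the
standard large-sample conversion; per-SNP logistic fits would be
numerically identical at these effect sizes and far slower). Liability
coefficients are internally calibrated by
$k=\text{prev}(1-\text{prev})/\phi(z_\text{prev})$ so the planted
$\beta_0$, $\beta_2$ live on the reported logistic scale.

`simulate_summary_direct()` draws the per-SNP summary betas directly at
the SEs implied by cohort size, MAF and prevalence; it is the generator
for large-replicate calibration suites. `simulate_grid()` builds a
multi-trait screening panel in which each exposure and mediator has its
own instrument set and exactly one pathway carries signal — note that
$\beta_2$ is identifiable only with mediator-specific instruments, which
is why mediation-recovery exercises use the grid generator rather than
the single-panel one.

Default conditions mirror the data regime of the motivating resources:
exposure cohort 3757 (flow-cytometry immune-trait GWAS), mediator cohort
8293 (Finnish cytokine cohorts), outcome cohort 20,000 (lung-cancer
GWAS range roughly 10k–420k; the screening grid uses 50,000, the
mid-range of the larger case-control studies), 30 instruments per trait
(≈ the average instrument count per immune trait after selection),
per-SNP standardized effects `gamma_scale = 0.09` with magnitudes
uniform in $\pm30\%$ — bounded away from zero so every planted
instrument's true F exceeds 10, which a normal draw would violate — and
prevalence 0.1. Effect alleles are oriented as exposure-increasing so a
non-zero `pleio_mean` is genuinely *directional* on the ratio scale;
with symmetric random orientations a constant allele-level pleiotropic
effect would cancel in ratio space and no generator setting could
produce the directional regime the diagnostics are meant to detect. All
randomness flows from one master seed through a fixed splitting scheme
(`seed + 7919 k`), so stages can be regenerated independently.

What the generators do *not* emulate: the Sardinian immune-trait genetic
architecture, covariate adjustment, sample overlap (an overlap-free
two-sample design is hard-wired), winner's-curse from discovery in the
same sample, and fine-scale LD beyond exchangeable blocks. Passing
calibration on these simulations therefore validates the estimators and
the orchestration, not robustness to those real-data features.

## Calibration results and problem sizes

The test suite recomputes, at fixed seeds:

* IVW 95% CI coverage over 200 direct-simulator replicates at the
  default configuration (target band 93–97%);
* Egger-intercept type-I error over 1000 replicates (band 3–7%);
* delta-method CI coverage for the product over 1000 replicates with
  all $|\beta/se|\ge3$ (band 93–97%);
* weighted-median vs IVW absolute bias under 30% directional pleiotropy
  (mean pleiotropic effect 0.05), 200 replicates;
* MR-PRESSO outlier detection (planted shift of 10 ratio-units; 100
  runs) and null specificity;
* exact recovery of one planted pathway in a 5×3×2 screening grid over
  50 seeds.

These problem sizes keep the whole suite around three to four minutes on
one core while leaving the binomial noise of each empirical rate well
inside its acceptance band. The individual-level simulator is mildly
conservative (its score-test SEs overstate the IVW sampling SD by
roughly 5% at the default configuration, and the liability–logistic
conversion attenuates recovered totals by a few percent); the
direct simulator is the calibration reference, and a cross-simulator
agreement test ties the two together.

## Numerical choices and edge cases

* Strict inequalities throughout: `p < threshold` for selection,
  `q_pval < 0.05` for the IVW switch (exactly 0.05 stays fixed
  effects), `F >= f_min` for retention.
* A lone surviving instrument yields a Wald ratio flagged non-primary;
  zero instruments mark the leg non-estimable rather than failing the
  run.
* Degenerate designs (zero variance in exposure betas for Egger,
  identical ratios for the mode bandwidth) are caught explicitly.
* Empirical p-values carry the $+1$ correction and can never be 0;
  simulated p-values are floored at the smallest positive double when
  written to tables so records never violate the $p>0$ invariant.
* `direct + indirect = beta0` holds algebraically; tests assert it to
  double precision rather than bit identity.

## Known limitations

* No MR-RAPS, multivariable MR, Steiger filtering or CAUSE; exactly the
  six named estimators.
* No proxy-SNP lookup, liftover or VCF input.
* The mediation model's identifying assumptions (no mediator–outcome
  confounding, no exposure–mediator interaction) are untestable from
  summary data and are documented, not checked.
* The delta-method proportion CI treats the three coefficient estimates
  as independent, which the disjoint-cohort design supports but real
  partially-overlapping GWAS may not.
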