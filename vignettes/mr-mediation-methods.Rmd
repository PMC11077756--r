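---
title: "Methods: two-sample MR estimation, diagnostics and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation, diagnostics and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ from two independent GWAS: per-SNP exposure
associations $(\hat\beta_{Xj}, \sigma_{Xj})$ and outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$. A SNP $j$ is a valid instrument when it is
(1) robustly associated with the exposure, (2) independent of confounders
of the exposure–outcome relation, and (3) affects the outcome only through
the exposure. Under these assumptions each instrument's Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect $\theta$, and the estimators in this package are different ways of
pooling the $\hat\theta_j$ that trade efficiency against robustness to
assumption (3) failing (horizontal pleiotropy):

* **IVW** — weighted mean of ratios with weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, equivalent to weighted least
  squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin.
  Efficient when every instrument is valid. The fixed-effect standard
  error is $(\sum_j w_j)^{-1/2}$; the multiplicative random-effects
  variant inflates it by $\sqrt{\max(1, Q/(J-1))}$ where $Q$ is Cochran's
  heterogeneity statistic. `model = "auto"` uses the fixed-effect form
  when the Q test is non-significant at 0.05 and random effects otherwise,
  the branching conventionally reported alongside the Q statistic.
* **MR-Egger** — weighted regression of outcome on exposure effects *with*
  an intercept, after orienting each instrument so
  $\hat\beta_{Xj} \ge 0$. The intercept estimates the mean directional
  pleiotropic effect (its test is the pleiotropy test); the slope remains
  consistent under the InSIDE assumption (instrument strength independent
  of direct effects).
* **Weighted / simple median** — the weighted 50% percentile of the
  ratio estimates; consistent when instruments carrying at least half the
  weight are valid. The standard error comes from a parametric bootstrap
  that redraws $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from normal
  distributions centred at their observed values.
* **Weighted mode** — the argmax of a weighted normal-kernel density of
  the ratio estimates; consistent when the largest group of instruments
  sharing a causal effect is valid (zero modal pleiotropy).

Estimates on a binary outcome are on the log-odds scale and are reported
as odds ratios via `transform_to_or()`, $\exp(\hat\theta \mp z\,SE)$, with
normal (not $t$) reference distributions throughout — the convention that
reproduces the worked examples in the README.

## Instrument processing

`select_significant()` applies the genome-wide threshold $p < 5\times
10^{-8}$ (strict). `clump()` is the standard greedy pass: visit SNPs by
ascending p (ties by ascending id, for determinism), keep the best
remaining SNP, and discard neighbours within 10,000 kb whose LD $r^2$
exceeds 0.001. When no LD matrix is supplied the package falls back to a
distance-only rule that discards *all* neighbours within the window — a
deliberately conservative approximation for use without a reference
panel. `apply_exclusion_list()` removes instruments flagged by an
external confounder screen (for example, SNPs associated with adiposity
traits in a phenotype-database lookup).

`harmonize()` aligns every table to the exposure's effect allele:
identical alleles pass through, swapped alleles negate the effect,
strand-complement records are complemented and re-checked. Palindromic
SNPs (A/T, C/G) carry no strand information in their allele codes, so
they are oriented by allele frequency and dropped when the minor-allele
frequency exceeds 0.42 in either study or is missing — the conventional
"intermediate frequency" cutoff, adjustable via
`palindrome_eaf_limit`. Every input SNP lands in exactly one provenance
category (`kept`, `flipped`, `dropped_palindromic`, `dropped_unmatched`),
so stage counts always reconcile.

`instrument_strength()` reports per-SNP variance explained
$R^2_j = 2\hat\beta_j^2f_j(1-f_j) / [2\hat\beta_j^2f_j(1-f_j) +
2n\sigma_j^2f_j(1-f_j)]$ and $F_j = R^2_j(n-2)/(1-R^2_j)$, falling back to
$F_j = (\hat\beta_j/\sigma_j)^2$ when the allele frequency is missing (the
two agree to within 2% whenever the standard errors follow the GWAS
$1/\sqrt{2nf(1-f)}$ law). Instruments with $F < 10$ are flagged as
conventionally weak but not removed — filtering is the analyst's call.

## Diagnostics

`cochran_q()` is the heterogeneity test above. `leave_one_out()` refits
IVW with each instrument removed. `mr_presso()` implements the
simulation-based pleiotropy residual-sum-of-squares framework: the
observed statistic is $\sum_j(\hat\beta_{Yj} -
\hat\beta_{(-j)}\hat\beta_{Xj})^2$ with leave-one-out IVW slopes, compared
against parametric simulations of the no-pleiotropy model; per-SNP squared
residuals give outlier p-values (Bonferroni-adjusted by default, BH
optional); and, when outliers are found, a distortion test compares the
outlier-removed estimate against re-estimates after removing random
subsets of the same size. Empirical p-values carry an add-one pseudocount
so they are never exactly zero, which also means the outlier test's
smallest achievable adjusted p is $J/(n_{sims}+1)$: the simulation count
must exceed $J/\alpha$ for the outlier test to have any power, which is
why the packaged validation uses 1000–2000 simulations on sets of 30–100
instruments.

## Multivariable MR and mediation

`mvmr_ivw()` regresses outcome effects on $K$ exposure-effect columns
(no intercept, weights $1/\sigma_{Yj}^2$), giving each exposure's *direct*
effect holding the others fixed; standard errors carry the same
multiplicative overdispersion floor. Instruments are the union of the
exposures' instrument sets after joint harmonization — the prevailing
practice; an intersection can be emulated by pre-filtering the tables.
Conditional instrument strength per exposure comes from
`conditional_f()`: the other exposures' effect columns are regressed out
(weights $1/\sigma_{Xkj}^2$) and the residual Q statistic is scaled to
$F_k = Q_{xk}/(J-K+1)$, which reduces to the mean univariable
$(\hat\beta/\sigma)^2$ at $K = 1$. Measurement-error covariance between
exposures is taken as zero, appropriate for summary statistics from
non-overlapping samples and a documented limitation otherwise.

`run_mediation()` composes the four-parameter decomposition for one
mediator $M$: total effect $\theta_1$ (univariable IVW of $X$ on $Y$),
$\theta_3$ ($X$ on $M$, univariable IVW — with a single mediator the
mediator-adjusted and univariable estimands coincide), and
$\theta_2, \theta_4$ (direct effects from MVMR of $\{X, M\}$ on $Y$).
The indirect effect is the product $\theta_3\theta_4$ with the
multivariate delta-method standard error
$\sqrt{\theta_4^2SE_3^2 + \theta_3^2SE_4^2}$ — the covariance term is
omitted because the two estimates come from different regressions on
two-sample summary data. The proportion mediated,
$100\,\theta_3\theta_4/\theta_1$, is computed on the log-odds scale for a
binary outcome and flagged when the signs disagree or the magnitude
exceeds 100% (inconsistent mediation). An adding-up gap
$\theta_1 - (\theta_2 + \theta_3\theta_4)$ is reported with a
delta-method z and flagged at $|z| > 2$, but never enforced.

## The synthetic-data generator

`simulate_uvmr()` and `simulate_mediation()` generate summary statistics
directly on the effect-size scale — no individual-level genotypes, which
suffices for every estimator under test. Per SNP: minor-allele frequency
uniform on (0.05, 0.5); true exposure effects
$\gamma_j \sim N(0, \gamma_{sd}^2)$; sampling errors follow
$1/\sqrt{2nf(1-f)}$; outcome effects add $\theta\gamma_j$ plus an optional
pleiotropy draw. Defaults emulate a large exposure GWAS of a
vitamin-D-like trait (143 loci, $n$ = 417,580) against a biobank-scale
binary outcome ($n$ = 233,397, using the same sampling-variance law with
an effective sample size — an approximation on the liability/log-odds
scale) and a hormone-like mediator ($n$ = 190,000). $\gamma_{sd} = 0.05$
makes the default panel explain about 13% of exposure variance, the scale
of SNP-heritability captured by discovered loci for such traits, while
keeping selected instruments strong.

Two modelling points are deliberate:

* **Directional pleiotropy is defined in the oriented frame.** Allele
  labels are arbitrary, so a pleiotropic shift with nonzero mean is only
  meaningful relative to the exposure-increasing allele; the generator
  applies $\mathrm{sign}(\gamma_j)\,\alpha_j$. This is the frame in which
  the MR-Egger intercept estimates the mean pleiotropic effect, and the
  packaged tests confirm the intercept recovers the programmed mean.
* **The mediator has its own genetics.** Mediator effects are
  $\theta_{xm}\gamma_j + \gamma_{Mj}$ with independent
  $\gamma_{Mj} \sim N(0, \gamma_{m,sd}^2)$. Without the second component
  the true exposure- and mediator-effect vectors would be exactly
  proportional and the multivariable step would be unidentified; with it,
  the mediator contributes its own instruments, as a real hormone GWAS
  does. The default $\gamma_{m,sd} = 0.05$ keeps those instruments strong
  without inflating the mediator's implied heritability beyond plausible
  biobank values.

What the generator does **not** emulate: linkage disequilibrium (clumping
is exercised with hand-written LD matrices instead), winner's curse at the
discovery threshold, sample overlap between the two GWAS, allele-frequency
differences between studies, and case-control ascertainment beyond the
effective-n variance approximation. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data complications.

## Numerical choices

* Overdispersion scales (IVW random effects, Egger, MVMR) are floored at
  1: apparent underdispersion never shrinks a standard error.
* Empirical p-values (MR-PRESSO) use the add-one pseudocount
  $(1 + \#\{\cdot\})/(n_{sims}+1)$.
* The mode estimator's bandwidth is
  $\phi \cdot 0.9\min(sd, MAD)\,J^{-1/5}$ (MAD scaled to the normal) and
  the density is maximized over a 512-point grid spanning the ratios
  plus three bandwidths; if all ratios coincide the common ratio is
  returned without a density step.
* Bootstrap standard errors (median, mode) default to 1000 parametric
  replicates, are bit-reproducible given a seed, and leave the caller's
  RNG stream untouched. `reps = 0` skips the bootstrap (SE reported `NA`)
  — used by the packaged large replication studies, which only need point
  estimates; replicate counts of 1–99 warn.
* Clumping ties on p break by ascending SNP id; the kept set is invariant
  to input row order.
* Degenerate inputs fail loudly: zero exposure effects in a ratio
  estimator, duplicate SNP ids, fewer instruments than a method's minimum
  (1 for IVW, 2 for Q, 3 for Egger/median/mode, 4 for MR-PRESSO,
  $K+1$ for MVMR), and an all-outlier MR-PRESSO verdict are all errors;
  an exposure column of all zeros in MVMR is dropped with a warning and
  an `NA` coefficient.

## Validation problem sizes

The packaged tests validate parameter recovery with 200 replicate
datasets of 300 SNPs (univariable: all five estimators against
$\theta = 0.3$; mediation: the triangle
$\theta_{direct} = -0.3$, $\theta_{xm} = -0.05$, $\theta_{my} = 0.32$),
MR-PRESSO null calibration with 200 replicates at 1000 simulations each,
outlier sensitivity with 100 replicates at 2000 simulations, and
no-mediation confidence-interval coverage with 300 replicates. These
sizes give Monte-Carlo standard errors small enough to resolve biases
well below a tenth of a standard error.

## Known limitations

* **Summary-data MVMR attenuation.** Measurement error in the exposure
  columns attenuates multivariable coefficients by a factor of roughly
  $1 - 1/F_{cond}$. For the mediator's direct effect this bias
  (about 0.7% of $\theta_4$ at the default strengths) is real and
  detectable once Monte-Carlo error drops below it, and no defensible
  instrument-strength regime removes it; the package reports conditional
  F statistics precisely so users can gauge it. The univariable IVW
  carries the analogous, smaller $\sim 1/\bar F$ dilution.
* The multiplicative random-effects model slightly undercovers when
  heterogeneity is additive and large; the measured coverage of the
  indirect-effect interval under no mediation is about 92% at a nominal
  95%.
* Distance-only clumping is conservative; with dense local signal it
  discards more than LD-aware clumping would.
* The proportion mediated is a point decomposition on the log-odds scale;
  it is not a variance-explained measure and is unstable when the total
  effect is near zero.
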