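---
title: "Modelling HMO-microbiome-cognition associations with hierarchical interaction selection"
author: "hmotriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HMO-microbiome-cognition associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmotriad)
```

## The scientific question

Breast-fed infants receive human milk oligosaccharides (HMOs) that they
cannot digest themselves; these sugars feed specific gut bacteria, above
all *Bifidobacterium* and *Bacteroides* species, and both the sugars and
the bacteria have separately been associated with early cognitive
development. `hmotriad` implements a triad analysis that asks the three
questions jointly: which HMOs, which species, and — crucially — which
HMO-by-species *interactions* are associated with Mullen Scales of Early
Learning (MSEL) cognition scores in the first year of life.

The data layout is a longitudinal mother-infant cohort: each dyad
contributes one to four visits, and each visit provides eight milk HMO
concentrations (2'-FL, 3-FL, 3'-SL, 6'-SL, LNT, LNnT, LNFP-I, A-tetra, in
mg/L), species-level gut relative abundances, and six MSEL scores
(an early-learning composite plus five T-scored subdomains).

## The model

For one MSEL outcome the fixed-effects model is

$$
\mathrm{Mullen}_{ij} = \beta_0 + \beta_1^\top \mathrm{covariates}_{ij}
 + \sum_h \beta_{2h} \mathrm{HMO}_{hij}
 + \sum_s \beta_{3s} \mathrm{MB}_{sij}
 + \sum_{h,s} \gamma_{hs}\, \mathrm{HMO}_{hij}\mathrm{MB}_{sij}
 + b_i + \varepsilon_{ij},
$$

with a subject random intercept $b_i \sim N(0, \sigma_b^2)$ capturing the
within-infant correlation of repeated visits and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. HMO concentrations and relative
abundances are standardized first, so all effect sizes (ES) are per-SD
and comparable across predictors. The adjusting covariates — infant sex,
delivery mode, maternal education, site, and the HMO analysis batch year
(2018 reference) — are always kept in the model.

Because A-tetrasaccharide is only produced by secretor mothers with A or
AB blood type, the analysis is run three ways: unstratified, and
stratified by whether the milk's A-tetra concentration exceeds the 4.4
mg/L limit of detection. In the stratified models the standardized HMO
columns (and every interaction column) are zero-masked on out-of-stratum
rows and an unpenalized indicator for the other stratum is added; species
columns remain active for all rows. Masking rather than row-dropping
matches the explicit indicator term in the stratified model and keeps all
visits available for estimating the covariate and species effects.

## Two-step estimation

With 8 HMOs and (typically) a dozen species there are ~96 candidate
interactions for at most a couple of hundred visits, so estimation is
done in two steps.

**Step 1 — hierarchical group LASSO selection.** Interactions are only
interpretable when both parent main effects are present. We encode this
*hierarchy* with a latent overlapping group LASSO: the penalized groups
are one singleton per HMO main, one per species main, and one triplet
$\{\mathrm{HMO}_h, \mathrm{MB}_s, \mathrm{HMO}_h\times\mathrm{MB}_s\}$
per pair. In the latent expansion each group owns private copies of its
member columns, so an interaction can only enter the support through a
group that also carries its mains — the hierarchy holds *by
construction*, for every fit, not just at convergence. Group weights are
$\sqrt{\text{group size}}$; intercept, covariates and the stratum
indicator are never penalized.

The penalty $\lambda$ is chosen by 10-fold cross-validation that
partitions *subjects*, not rows — row-level folds would leak repeated
measures of the same infant across folds. Because CV is random, the whole
selection is repeated (200 repetitions by default) with fresh fold
assignments, and each group's selection frequency is recorded. The final
set is the groups selected in at least half the repetitions; the cutoff
is a convention in the spirit of stability selection, and the
frequencies are always reported so other cutoffs can be applied. If the
final set contains no interaction, the analysis falls back to the full
main-effects model: all eight HMOs plus all retained species.

The selection stage uses a plain squared loss that ignores the
within-subject correlation; the mixed model in step 2 handles the
dependence. This mirrors the two-step design where selection only needs
to rank predictive structure, not calibrate inference.

**Step 2 — random-intercept REML.** The selected terms plus all
covariates are refitted with the random-intercept linear mixed model.
The implementation profiles the restricted likelihood over a single
variance ratio $\theta = \sigma_b^2/\sigma^2$: each subject block of the
marginal covariance is $I + \theta \mathbf{1}\mathbf{1}^\top$, whose
inverse and determinant are closed-form, so one likelihood evaluation is
$O(\text{subjects} \times p^2)$. $\theta$ is estimated by scalar
minimization on $[0, 10^3]$ (boundary $\hat\theta = 0$ allowed; with
only singleton subjects the ratio is unidentifiable and the fit reduces
to OLS with a warning). Wald tests use $df = n_{\mathrm{obs}} -
p_{\mathrm{fixed}}$; Satterthwaite-type corrections are deliberately out
of scope and the df convention is recorded in the output. On balanced
intercept-only data the REML estimate reproduces the one-way ANOVA
closed form $(\mathrm{MSB}-\mathrm{MSW})/(k\,\mathrm{MSW})$, and the fit
agrees with `lme4` to numerical precision — `lme4` serves as a
cross-check in the test suite, never as the engine.

## Solver numerics

The overlapping group LASSO objective
$\tfrac{1}{2n}\lVert y - X\beta \rVert^2 + \lambda \sum_g w_g \lVert
v_g\rVert_2$ is minimized by a monotone accelerated proximal gradient
method (group soft-thresholding with backtracking line search and a
non-increase safeguard) restricted to the active set of groups, with full
KKT screening passes to admit violating groups. Warm starts traverse a
log-spaced path from $\lambda_{\max}$ (the smallest penalty at which all
penalized groups are zero, computed from the unpenalized-only residual)
down to a configurable fraction of it.

Two numerical details matter. First, convergence is certified by the KKT
optimality gap (default $10^{-6}$), not just by objective stagnation:
with T-score-scale outcomes the objective magnitude makes its
double-precision increments too coarse to certify tight gaps. A final
refinement therefore iterates the stationarity system on the identified
active set (Picard warm-up, then Newton with step halving), which
converges past the descent floor of the first-order phase. Second,
cross-validation fold fits use looser tolerances than final fits —
held-out mean squared error is insensitive at that resolution — which is
what keeps 200 stability repetitions affordable.

Non-convergence is never silent: the fit carries `converged = FALSE` and
a warning with the achieved gap.

## Preprocessing

* **Double-MAD outlier flagging.** For right-skewed abundance
  distributions a single MAD is misleading, so values below and at/above
  the median get separate MADs, and each value is scored as its absolute
  deviation over its own side's MAD (no 1.4826 consistency constant —
  the rule thresholds raw MAD ratios; values equal to the median count
  toward both sides, keeping each side non-empty). The default threshold
  is 3, and the default policy replaces flagged values with missing,
  whose rows are then excluded at design construction. The pipeline
  scores species abundances on the pseudo-log scale
  $\operatorname{asinh}(x/10^{-3})$: on the raw scale a sub-dominant
  species has median (and hence side-MADs) near zero, which would flag
  its entire positive tail and effectively delete the species. The
  pseudo-log scale is the one these compositions are routinely displayed
  and reasoned about on; the scoring functions themselves are
  scale-agnostic.
* **Species prevalence filter.** A species is retained iff its relative
  abundance summed over all samples strictly exceeds 1. This is the
  published rule; note that at 170 samples a species with mean abundance
  0.001 sums to ~0.2 and is dropped, even though such species appear in
  published species lists — the threshold is therefore configurable, and
  the discrepancy is documented rather than resolved.
* **Standardization and age residualization.** Predictors are
  standardized over *all* included samples (not within stratum), so
  stratified and unstratified effect sizes share a scale; stratified
  models then zero-mask the standardized values. Because MSEL T-scores
  are already age-normed, age is not an outcome covariate; instead the
  age trend is regressed out of each standardized predictor column by
  default (toggleable). Interaction columns are products of the processed
  mains and are not re-standardized — re-scaling them would break the
  algebra that makes the hierarchy interpretable.
* **Stratification rules.** A-tetra positivity is `concentration > 4.4
  mg/L` (strict). Secretor classification implements both printed
  conventions: the 2'-FL/3-FL ratio rule (> 6.5827) and the 2'-FL < 15
  mg/L threshold rule.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without access to the underlying cohort; its defaults emulate the study
conditions rather than any convenient setting.

* **Design**: 105 dyads; a subject is a singleton visitor with
  probability 60/105, otherwise it has $2 + \mathrm{Binomial}(2, 2/9)$
  visits (at most 4), making the expected total 170 visits. Visit ages
  are sorted uniforms on [2.9, 12] months. 36/105 of mothers produce
  detectable A-tetra, constant within mother. Covariate marginals: 38%
  male, 79% vaginal delivery, 61% graduate-level maternal education,
  sites balanced, batch years 2018/2019/2020 at 25/45/30% (the batch
  composition is not published; these are a plausible spread).
* **HMOs** are lognormal around an age-trended mean
  $\mu_h(a) = \mu_{h0} e^{s_h a}$ with the published trend signs (3-FL,
  3'-SL, A-tetra rising; the other five falling) and levels set so
  cohort-average concentrations land near published group means; A-tetra
  is exactly 0 mg/L for A-tetra-negative mothers, and 3-FL carries a
  multiplicative group offset reproducing the reported A-tetra+/−
  difference (1243 vs 1551 mg/L).
* **Microbiota** are normalized-gamma (Dirichlet-type) compositions over
  the 12 focal species plus a pooled remainder, with latent log-weights
  drifting linearly in age (*Bif. longum*/*breve* down, *Bif.
  catenulatum*/*B. vulgatus* up). Two deviations from a textbook
  Dirichlet are deliberate. A pure Dirichlet with shape `concentration ×
  mean` puts rare species' medians hundreds of orders of magnitude below
  any profiler's output, so per-species shapes are floored at 0.35 —
  preserving sparsity and right skew at realistic magnitudes. And because
  closure biases dominant species' means, the latent weights are
  calibrated by a short Monte-Carlo fixed point so the *closed*
  composition means match their targets (e.g. *Bif. longum* ≈ 0.38).
* **Outcomes** are generated from exactly the model the pipeline fits,
  on cohort-standardized predictors, with defaults $\sigma_b = 5$,
  $\sigma = 7$ (T-score units). The within-subject correlation of MSEL
  scores is not published; $\sigma_b = 5$ is a free choice giving an
  intra-class correlation of ~0.34. The composite score is by default
  simulated as its own outcome (mirroring the analysis, which treats
  each score as an outcome); a `derived` mode computes it from the four
  non-gross-motor subdomains instead. Interaction coefficients can be
  restricted to one A-tetra stratum (`gamma_stratum`) to emulate
  stratum-specific effects. The generating truth (all coefficients and
  subject intercepts) is attached to the cohort and can be exported for
  recovery tests.

What the generator does **not** emulate: sequencing noise and
compositional artifacts of taxonomic profiling, measurement error in the
HMO assay beyond lognormal dispersion, informative visit timing or
dropout, covariate-microbiome dependence (delivery mode does not shift
the composition), and any real batch structure. Passing recovery tests
therefore demonstrates that the estimation machinery is correct under
the stated model, not that the published biological findings would
replicate.

## Problem sizes used in validation

The package's simulation-based checks use: parameter recovery at 200
subjects with a planted interaction of 0.8 SD over 25 replicate seeds,
with stability selection at 50 repetitions over a 30-point penalty path
down to 0.02 of the maximum; a stratum-specific planted interaction of
5 T-score units per SD-product recovered through the stratified
pipeline over 7 seeds; solver certificates on 100 random problems
of 30–200 rows; and Wald coverage on 500 directly simulated
random-intercept data sets. These sizes are the package's validation
design; all tolerances (KKT $10^{-6}$, REML-vs-ANOVA $10^{-6}$, 3-SE
recovery bands) are properties of the methods, not of the sizes.

## Known limitations

* Only a random intercept is supported — no random slopes, no crossed
  effects. The REML profile is one-dimensional by design.
* Wald p-values use the residual df convention; with few subjects they
  are anti-conservative relative to Satterthwaite-type corrections.
* No multiple-testing adjustment is applied by default, mirroring the
  reporting convention of the analysis the package implements
  (Benjamini-Hochberg can be enabled on the report).
* Stability frequencies depend on the penalty path resolution; very
  coarse paths can merge neighbouring selection events.
* The fallback rule is all-or-nothing: a single surviving interaction
  suppresses it, even if that interaction is marginal.
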