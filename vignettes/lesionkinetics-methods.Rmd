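---
title: "Lesion-level ICI response analysis: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-level ICI response analysis: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionkinetics)
```

# The problem

Immune checkpoint inhibitors produce response patterns that whole-patient
criteria blur: a subset of patients *hyperprogress* — their tumors grow
faster after the first dose than before — and others show a *dissociated
response* in which lesions in different organs move in opposite
directions. Both phenomena are properties of individual lesions, so this
package evaluates response lesion by lesion from three consecutive CT
scans (pre-baseline, baseline, first follow-up) with segmented volumes,
and then aggregates to the patient level.

# Rule engine

## TGK and the HPDv call

For volumes $V_{-1}, V_0, V_1$ at dates $t_{-1} < t_0 < t_1$:

$$\mathrm{TGK}_{pre} = \frac{V_0 - V_{-1}}{t_0 - t_{-1}}, \qquad
  \mathrm{TGK}_{post} = \frac{V_1 - V_0}{t_1 - t_0}, \qquad
  R = \mathrm{TGK}_{post} / \mathrm{TGK}_{pre}.$$

A lesion is **HPDv** when all three clauses hold: time to treatment
failure $< 2$ months, $R \ge 2$, and $(V_1 - V_0)/V_0 \ge 0.5$. Decisions
embodied here:

- *Eligibility.* The ratio needs all three scans; lesions missing the
  pre-baseline volume or disappearing at follow-up are `NOT_EVALUABLE`
  and reported as "excluded", never silently dropped: the cohort summary
  always partitions all lesions into HPDv / non-HPDv / excluded.
- *Months to days.* 2 months = $2 \times 30.44 = 60.88$ days, with a
  strict `<` ("less than 2 months"); the ratio and increase thresholds
  are inclusive ("2 or more", "50%"). All three are arguments of
  `hpdv_criteria()`.
- *Non-positive pre-treatment growth.* When $\mathrm{TGK}_{pre} \le 0$
  the ratio is undefined and an eligible lesion is non-HPDv: a lesion
  that was stable or shrinking before treatment has no growth rate to
  double. This case is not specified by the defining clauses; treating it
  as non-HPDv is the only reading under which "growth more than doubles"
  is meaningful, and it is frozen in the rule-engine oracle tests.
- *Zero baseline volume* is an error (percent change undefined), not a
  category.

## Nelson category and dissociated response

Progression is a volume change $\ge +25\%$ between baseline and
follow-up; partial response is shrinkage $\ge 25\%$; anything between is
stable. The published wording for the partial-response clause ("a
decrease of 25% or less") is ambiguous; we implement shrinkage of *at
least* 25%, symmetric with the progression clause — the alternative
reading would make nearly every lesion a partial response. This is a
deliberate, documented interpretation and is not configurable by
accident.

A patient is **DR** when a progressing lesion and a partially responding
lesion sit in *different* organs. Two further conventions: single-lesion
patients are non-DR by definition, and DR is evaluated at the first
follow-up (the only timepoint guaranteed for all lesions), not at best
response. Same-organ discordance does not qualify under the literal
"different organs" reading; a `same_organ_counts` switch exists but is
off by default.

# Histogram radiomics

`extract_features()` computes 19 first-order features plus volume and a
2.5D area from the in-mask HU values. The exact feature list is the
standard first-order set extended with the 2.5th and 97.5th percentiles
(the 2.5th percentile is one of the reported organ-specific
discriminators). Conventions, all frozen by brute-force oracle tests:

- percentiles interpolate linearly between closest order statistics;
- variance/SD use the population ($1/n$) convention and kurtosis is the
  Pearson (non-excess) fourth standardized moment, matching common
  radiomics toolkits;
- uniformity $\sum_i p_i^2$ and entropy $-\sum_i p_i \log_2 p_i$ use a
  fixed-bin-width histogram (default 25 HU, a common CT convention)
  with edges anchored at the in-mask minimum, so both are invariant
  under intensity shifts;
- RMS uses raw values, so $\mathrm{RMS}^2 = \mathrm{mean}^2 +
  \mathrm{variance}$ exactly;
- the "2.5D area" is interpreted as the slice-wise lateral surface
  proxy: per-axial-slice in-plane boundary perimeter × slice thickness,
  with the square-contour convention (a single voxel at 1 mm in-plane
  spacing contributes 4 mm of perimeter). The source material never
  defines this feature; the choice is recorded here and in the function
  documentation.

Patches travel as plain-text CSV voxel tables (`write_patch()` /
`read_patch()`); no NIfTI/NRRD reader is bundled because no such R
package is available in the supported offline environment — the in-memory
`voxel_patch` array container is the first-class interface.

# Statistical layer

## Feature transforms

Right-skewed features are compressed before modelling. For each feature,
`choose_transform()` evaluates identity, log, square root and cube root
and keeps the transform minimizing absolute sample skewness
(deterministic tie-break in that order); features bounded in $(0,1]$ are
pre-multiplied by 1000 before the log (the conventional
$\log(x \times 1000)$ form for uniformity); features containing negative
values are cubed instead, the only admissible sign-preserving power in
the candidate family. `transform_pool()` keeps both the original and the
transformed variant, mirroring the analyzed "transformed + original"
candidate pool.

## GEE with exchangeable correlation

Lesions are clustered within patients, so HPDv discrimination uses
logistic generalized estimating equations: coefficients solve the
estimating equation with an exchangeable working correlation (all lesion
pairs of a patient share one correlation $\alpha$, moment-estimated from
Pearson residuals each iteration), and standard errors are the
Liang–Zeger robust sandwich — consistent even when the working
correlation is wrong. The solver iterates to relative coefficient
tolerance $10^{-6}$ (max 100 iterations); separation or divergence is
flagged (`converged = FALSE`), never thrown, so screening loops survive
degenerate features. With all cluster sizes 1 the fixed point is exactly
the ordinary logistic MLE, which the tests check to $10^{-6}$. The GEE is
implemented in the package (no GEE package is assumed available); its
calibration is established by simulation tests: type-I error within
[0.03, 0.08] at 500 null replicates, and slope recovery within 0.1 with
CI coverage in [0.92, 0.975] at 200 replicates of 200 clusters.

The calibration simulations generate clustered binary data through a
Gaussian-copula shared cluster factor: a latent exchangeable random
intercept that leaves the *marginal* model exactly logistic with the
nominal slope. This matters: drawing outcomes from a conditional
random-intercept logistic model attenuates the population-averaged slope
(by roughly $1/\sqrt{1 + 0.346\,\sigma_u^2}$), so the conditional slope
is the wrong recovery target for a marginal estimator. The cohort
*generator*, by contrast, intentionally uses the conditional
random-intercept form — there the target is label consistency and
controllable class balance, not marginal-slope recovery.

## Screening, model building, AUC

The univariate screen keeps features with Wald $p < 0.1$ (strictly; no
multiplicity correction, as in the source analysis). Multivariable
models are built per organ stratum (plus an all-lesion stratum, fit
independently) by backward elimination: drop the largest-$p$ term while
any $p \ge 0.05$, refit, and score the final linear predictor in-sample
for the ROC AUC. Elimination-to-empty yields an explicit intercept-only
report with AUC 0.5. AUC is the Mann–Whitney concordance with 0.5 tie
credit; its 95% CI uses the DeLong placement variance, which ignores
within-patient clustering of lesions (as the reference AUCs appear to);
`roc_auc_cluster_boot()` provides a patient-resampling bootstrap CI for
users who want clustering respected.

## Survival

Overall survival is compared between DR and non-DR patients with the
Kaplan–Meier product-limit estimator and the two-group log-rank test
(1 df). Estimation is delegated to the `survival` package; the package's
tests still verify the values against a naive risk-set tabulation oracle,
so the wrapper contract (curves as explicit step functions with numbers
at risk, $S(0) = 1$, non-increasing) is checked independently of the
library.

# The synthetic world

`generate_cohort()` draws, in order: lesion counts per patient (shifted
Poisson, mean ≈ 3.2 lesions), organs (mixture matching the observed
cohort composition), standardized synthetic features $z$, a patient
random intercept $u \sim N(0, \sigma_u^2)$, and the true HPDv label from
$\Pr(\mathrm{HPDv}) = \mathrm{logit}^{-1}(\beta_{0,\mathrm{organ}} +
\beta_\mathrm{organ}^\top z + u)$. Volumes are then *back-solved* so the
deterministic rule engine reproduces the drawn label with 100% agreement
(a tested invariant): HPDv lesions get positive pre-treatment growth, a
TGK ratio drawn $\ge 2$ and at least +50% at follow-up (the +50% floor is
applied with a $+10^{-5}$ relative guard so floating-point rounding
cannot undercut the inclusive threshold), and their host patients get TTF
drawn below 2 months; non-HPDv lesions get follow-up changes capped below
+50%, with a shrinkage tail that produces partial responses and hence
dissociated patients. Overall survival is exponential with the DR hazard
ratio applied to patients whose *generated volumes* meet the DR rule, and
censoring is an independent exponential calibrated to the requested
censoring fraction.

Stated defaults (chosen once, not tuned): 196 patients; organ mixture
(lung 0.47, bone 0.13, lymph node 0.23, liver 0.10, other 0.07); 60-day
scan intervals; per-organ intercepts at the logit of the observed
per-organ HPDv rates; effect directions mirroring the reported
organ-specific discriminators (negative standardized-uniformity and
volume effects in lung, positive uniformity in bone, positive RMS in
lymph nodes, negative 2.5th percentile in liver, positive median in
"other") with magnitudes ≈ the published log odds ratios where those are
on a log-feature scale and 0.5 where they are per-HU and hence not
transferable to standardized features; $\sigma_u = 1$; 10% missing
pre-baseline + 10% disappearing at follow-up (≈ the observed 20%
exclusion fraction); exponential OS with ~8.2-month median (plausible for
advanced NSCLC on ICI monotherapy), DR hazard ratio 2, 30% censoring.

What the generator does *not* emulate: real lesion morphology and CT
texture (patches are ellipsoids with parametric histograms), correlations
between features and volumes, informative censoring, new-lesion
appearance, and any association between TTF and the feature process
beyond the HPDv coupling. A green pipeline test therefore establishes
that the statistical machinery recovers what was injected under the
assumed clustered-logistic world — not that the published biological
effect sizes are correct.

`fixture_cohort()` is different in kind: it is *constructed*, not
sampled. Lesion class counts per organ, the DR patient set, TTF values
and volume templates are laid out so the rule engine reproduces the
published accounting exactly (621 lesions: 147 HPDv / 349 non-HPDv / 125
excluded; organ splits 80/15/24/21/7 and 154/50/90/26/29; 54 DR vs 142
non-DR among 196 patients). Per-lesion lognormal volume scaling and
±10-day date jitter add realism without touching any rule decision
(scale invariance and the ratio's date sensitivity are margin-checked).
The organ split of the excluded lesions is not published; the fixture
uses 50/18/25/14/18. The internal seed is fixed; every call returns the
identical cohort.

# Numerical and degenerate-input conventions

- Percent summaries round to one decimal; category percentages use the
  all-lesion denominator, organ shares the category denominator.
- `discretize()` assigns voxel $x$ to bin $\lfloor (x - \min)/w \rfloor$:
  half-open bins, the maximum value opens a new bin when it lands exactly
  on an edge, counts always sum to the voxel count.
- Fewer than 2 in-mask voxels (or zero variance): skewness/kurtosis are
  `NaN`, everything else is computed.
- GEE: dispersion is moment-estimated by default; $\alpha$ is clipped to
  $(-1/(n_{\max}-1), 1)$ for invertibility; compound-symmetry inverses
  use the closed form, so fits are $O(n)$ per iteration.
- All stochastic functions take explicit seeds and restore the caller's
  RNG state (`with_preserved_seed`); identical seed + config is
  bit-identical, a tested invariant.

# Known limitations

- The exact published 19-feature list and the definition of the 2.5D
  area live in an appendix that is not part of the available text; the
  implemented registry and the perimeter × thickness interpretation are
  documented choices.
- The candidate-pool accounting in the source (29 analyzed = 14
  transformed + 20 original) does not reconcile; the package reports
  both pool sizes and applies no hidden deduplication.
- In-sample AUC after selection is optimistic; no cross-validation is
  provided, matching the scope of the source analysis.
- The headline regression and survival statistics of the source (organ
  ORs, AUCs, log-rank $p = 0.04$) derive from patient CT data that are
  not available; the fixture reproduces the printed *accounting*
  marginals, and the stochastic suites establish calibration and sign
  recovery, not those headline values.
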