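---
title: "Methods: multi-site morphometry classification and the global-signal decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site morphometry classification and the global-signal decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and motivation

`morphosite` implements a complete analysis pipeline for case-control
classification of regional brain-morphometry features (grey-matter density
per atlas region, cortical thickness/area/volume, subcortical volumes)
pooled across several acquisition sites. The central methodological
problems it addresses are:

1. **Leakage-free harmonization.** Covariate and scanner effects must be
   removed without ever letting held-out (test-site) data influence a
   fitted model, because a deployable diagnostic tool cannot re-estimate
   site corrections from the very subjects it is asked to classify.
2. **Site-robust accuracy estimation.** Accuracy is estimated by
   leave-site-out cross-validation: all preprocessing and training is
   refit with one cohort held out, which exposes the between-site
   variability that single-site cross-validation hides.
3. **Attribution of the multivariate signal.** A classifier built from
   hundreds of regional features may in fact exploit a small number of
   *global* structural properties (total grey matter, hemisphere
   aggregates, ventricle size). The package quantifies this by
   residualizing regional features against a 22-member global feature set
   and re-running the entire classification pipeline, with permutation
   controls.

Because real multi-site clinical MRI tables are not redistributable, the
package ships a synthetic cohort generator with fully known ground truth;
every stage of the pipeline is tested against it.

## The generative model of the synthetic cohorts

For subject $i$ and feature $j$ the simulated value is

$$
x_{ij} = \mu_j + \beta_{j}^{\top} c_i + s_{(\text{site}(i)),j}
       + v_{(\text{vendor}(i)),j} + f_{(\text{field}(i)),j}
       + \lambda_j^{\top} g_i + \delta_{ij} + \varepsilon_{ij},
$$

with baseline $\mu_j$ (the atlas mean size), covariate effects
$c_i = (\text{age}-40, (\text{age}-40)^2, \text{sex}, \text{ICV}-1475)$
(no ICV term for thickness measures), fixed per-(site, feature) offsets
$s \sim N(0, \sigma_{\text{site}}^2)$, per-(vendor, feature) and
per-(field, feature) offsets, latent global factors $g_i$, a direct
diagnosis effect $\delta_{ij}$, and Gaussian noise
$\varepsilon_{ij} \sim N(0, \sigma^2)$ with $\sigma = 1$ defining the
feature scale.

**Global factors and mediation.** The $K$ observed factors are an
equicorrelated mixture ($\rho = 0.3$) of independent standard-normal
innovations $z_i$: $g_i = \Sigma^{1/2} z_i$. The case-control effect
enters on the innovations: each of the $K$ components is shifted by
$w\,d$ in cases, where $d$ is the total effect size (`effect_d`) and
$w \in [0,1]$ the mediation fraction (`global_mediation`). Consequences
that the tests exploit:

* the factor-space separation (Mahalanobis distance) is $w\,d\sqrt{K}$,
  so the best attainable AUC is $\Phi(w\,d\sqrt{K/2})$ — about 0.92 for
  the default $d = 0.8$, $w = 1$, $K = 6$;
* every factor-loaded feature has marginal case-control shift
  $w\,d\,\sqrt{1 + (K-1)\rho}\,\sum_k \lambda_{jk}$, positive by
  construction (loadings are positive), and recorded analytically in the
  ground-truth object;
* the marginal effect grows monotonically in $w$ at fixed $d$.

The remaining fraction $(1-w)\,d$ acts directly (in noise-SD units) on
`n_regional_informative` randomly chosen regional features, emulating
regionally specific pathology.

**Loadings scale with structure size.** Within each (family, measure)
stratum, loadings are proportional to
$\exp(0.5\,\tilde\ell_j)$ where $\tilde\ell_j$ is the standardized log
mean size; larger structures therefore carry more global signal, which
reproduces the empirical pattern that variance explained by global
measures increases with structure size.

**Designated global features are near-noiseless.** The 20 designated
global summary features (total grey matter, hemisphere aggregates,
ventricles, mean thickness, total surface area, ...) receive loading norm
6 versus about 1 for regional features, i.e. a communality of ~0.97.
Rationale: real global measures aggregate thousands of voxels or vertices,
so their measurement noise is far below that of single regional features.
This choice makes the global set span the factor space almost exactly,
which is what allows residualization against globals to remove an entirely
mediated effect down to the permutation null.

**Validation cohorts.** Besides the matched training cohorts (`SZ-like`
cases), the generator produces control-only cohorts, a `BD-like` cohort
whose cases share a configurable fraction (`bd_share`, default 0.8) of the
global-factor shift, and `ADHD-like` cohorts whose cases carry a direct
effect on a *disjoint* informative feature set (optionally with
adolescent ages 12–18, covariate support absent from adult training
data). This reproduces, qualitatively, the cross-disorder pattern the
pipeline is designed to expose: poor specificity against the disorder
sharing the global alteration, preserved specificity against the disorder
with an orthogonal signal.

**What the generator does not emulate.** Non-linear covariate effects
beyond age², longitudinal structure, missing data, heavy-tailed
measurement error, or realistic spatial correlation structure among
regions beyond the factor model. Passing tests therefore demonstrate the
*procedural* correctness and statistical calibration of the pipeline, not
performance levels to be expected on real clinical data.

## Matching and the two-step normalization

*Propensity matching* fits a logistic model of case status on age and sex
per cohort and pairs each case with the nearest unused control on the
propensity logit, in seeded random case order (greedy nearest neighbour
without replacement, no caliper — mirroring the defaults of the standard
matching tools). Cohorts can be flagged to skip matching (used when a
cohort has fewer controls than cases without covariate imbalance); their
subjects pass through whole. A degenerate (separating) propensity model
falls back to standardized covariate distance with a warning.

*Step one* regresses every feature on age, centered-age², sex and ICV
(ICV omitted for thickness features) separately within each training
cohort and averages coefficients arithmetically (unweighted — the natural
reading of "averaged") into one model per feature. Age is centered at the
pooled training mean before squaring purely for conditioning; residuals
are unchanged. ICV is then appended as a feature. *Step two* removes
scanner-vendor and field-strength effects with reference-coded dummy
regressions fit on the training cohorts only. Both models are applied
unchanged to held-out data; a vendor or field level seen only in test
data is predicted at the reference level with a warning — exactly the
situation a deployed model faces at a new site.

Step-one models are fit on matched cases *and* controls jointly (the
matched case-control data is the stated design); this is flagged as a
design point because a diagnosis-correlated covariate could absorb
signal — with 1:1 matching on age and sex the risk is minimal.

Two additional operations serve specific analysis modes:
`center_test_features()` sets the held-out cohort's feature means to
exactly zero (idempotent), quantifying how much of any cross-site
sensitivity/specificity imbalance is a pure mean-shift effect; and
`residualize_site_factor()` removes site and vendor factors jointly on
the pooled data for the whole-dataset (non-leave-site-out) analyses —
vendor is dropped automatically when aliased with site.

A *leakage guard* is built into the fitting functions: phenotype tables
can carry a declared set of test cohorts, and any attempt to include such
subjects in a design matrix raises an error. Every leave-site-out fold
records which subjects entered which fit; `verify_no_leakage()` replays
that audit log.

## Classifiers

The primary classifier is a random forest grown in a *site-stratified*
manner: each tree's bag contains exactly `s` subjects drawn without
replacement from every training site, so no site dominates any tree.
Trees are unpruned, split by Gini impurity, with
`mtry = floor(sqrt(p))` and 5000 trees by default; no parameter tuning.
The literal stratification rule "s equals the size of the smallest
cohort" leaves all smallest-site subjects in-bag for every tree, making
their out-of-bag (OOB) scores undefined; the default mode therefore uses
`s = ceiling(0.632 * n_min)` (the expected unique-draw fraction of a
bootstrap), which preserves the stratification intent while keeping OOB
evaluation defined everywhere. A strict mode reproduces the literal rule
and excludes always-in-bag subjects from OOB metrics.

A subject's OOB score is the fraction of its out-of-bag trees voting
case; prediction scores for new data are full-ensemble vote fractions
with classification cutoff 0.5 (conventional; the package reports
sensitivity, specificity and their mean at this fixed cutoff to expose
cross-site probability shifts that the rank-based AUC hides). The
comparison classifier is a linear SVM with the cost parameter tuned over
the 11-point log grid $10^{-5}...10^{5}$ by stratified 10-fold
cross-validation on training data only, ties broken toward stronger
regularization.

AUC is computed by the midrank Mann–Whitney formula (ties count one
half) and is tested against a brute-force all-pairs oracle. Within-site
significance uses label-permutation retraining with the empirical
p-value defined as the exact frequency of null statistics at least as
extreme (no +1 correction; a zero count should be read as $< 1/B$).

## Feature importance and cross-disorder overlap

Backward elimination drops the least important 20% of features per round
(importance re-computed after each refit), tracks the OOB error along the
path, and returns the smallest set whose error does not exceed the
minimum error plus one binomial standard error of that minimum — the
classical one-SD parsimony rule.

The cross-disorder overlap test asks whether the top-$m$ features of a
reference contrast are disproportionately important in a second contrast:
the observed statistic is the Wilcoxon rank-sum of the second task's
importances for the top set versus the rest; the null is built by
permuting the second task's labels and retraining its forest (the top set
stays fixed — permutations do not re-run the reference task's variable
selection, matching the described procedure). Permutation forests may use
fewer trees (default 500) than the observed forest for tractability; a
strict run sets them equal.

## Global-signal decomposition

The 22-member global set is assembled from 20 designated summary features
plus two per-subject medians (over ventricle features and over the active
family's regional features, computed *after* covariate adjustment,
consistent with the use of covariate-adjusted global features; the
density-mode and surface-mode sets differ only in the family median).
Regional features are residualized against all 22 globals simultaneously
by additive OLS — in leave-site-out mode fit on training sites only,
which the source procedure leaves unspecified but which preserves the
pipeline's leakage discipline. Two controls isolate the interpretation:
row-permuted globals (does residualizing against 22 covariates hurt per
se?) and within-cohort label permutation (the chance band; its mean can
exceed 0.5 in small samples because matching and training adapt to chance
associations). The permuted-global control permutes rows within each
fold's subject set, seeded identically across folds of one repetition.

Explained variance of individual features by the global set uses random
forest regression with OOB $R^2 = 1 - \text{MSE}_{oob}/\text{Var}$,
floored at zero, on the site-factor-corrected data path.

## Numerical choices and problem sizes

* All OLS fits use QR with pivoting; rank-deficient designs drop aliased
  columns with a warning rather than failing.
* Empirical p-values are exact frequencies; all Monte-Carlo procedures
  are seeded and reproducible, with seeds derived from a single master
  seed per run.
* The test suite and the acceptance script run the pipeline at desk
  scale, chosen as the package's own reference conditions: null
  calibration uses four 100-subject cohorts with the full 275-feature
  table over 10 seeds, and 200 scaled within-site replicates (40
  subjects, 13 features, B = 100); the decomposition experiment uses four
  80-subject cohorts with a 30 + 40 feature atlas, B = 100
  permuted-diagnosis repetitions and forests of 150–300 trees; selection
  recovery uses 400 subjects and 153 features over 10 seeds. Larger
  reference settings (5000 trees, B = 1000–5000) remain the function
  defaults.
* Permutation significance requires exchangeability between the observed
  and null statistics: calibration runs therefore use equal tree counts
  for the observed and permutation forests. The reduced
  `perm_n_trees` default trades a little conservatism for speed in the
  expensive overlap analyses. Monte-Carlo replicates use widely spaced
  seeds so their permutation streams stay disjoint.
* The overlap-test p-value is approximately uniform under a true null
  (labels independent of features). A second task with an *orthogonal*
  informative set yields p concentrated near 1, not uniform: its own
  signal depresses the reference top set's importance ranks relative to
  the permutation null. Both behaviours are asserted in the tests.
* Forest sizes in the experiments (150–600 trees) are far above the point
  where the OOB error of these problems stabilizes; 5000 trees is kept as
  the default for fidelity to standard practice.

## Known limitations

* The greedy matcher does not implement calipers, exact matching or
  optimal matching; with poor overlap it degrades gracefully (residual
  imbalance) rather than refusing to match.
* The equicorrelated factor model is a deliberate simplification; real
  global structure is hierarchical.
* `run_experiment()` orchestrates the standard flow but is not a general
  workflow engine; complex designs should call the stage functions
  directly.
* The between-dataset step models vendor and field strength additively
  with reference coding; interactions (vendor-specific field effects) are
  out of scope.
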