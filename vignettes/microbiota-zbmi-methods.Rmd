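---
title: "Methods: longitudinal gut microbiota and child zBMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal gut microbiota and child zBMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`microgrowth` implements a longitudinal analysis of the association between
gut microbiota composition and standardized child body mass index (zBMI):
compositional feature construction, multiple imputation, Bayesian multilevel
modelling, and permutation-calibrated random-forest inference, driven by a
synthetic-cohort generator with retained ground truth. This vignette explains
the statistical models, the defaults and their units, the numerical choices,
and what the synthetic cohorts do and do not establish about real data.

```{r setup}
library(microgrowth)
```

## The scientific setting

Children's BMI, standardized for age and sex (zBMI), develops alongside the
gut microbial community, which shifts from a Bifidobacterium-dominated
(Actinobacteria) profile in infancy to a Firmicutes-dominated profile in
childhood, with Bacteroidetes nearly absent in the first months of life. Two
microbiota summaries are of long-standing interest for obesity research: the
Firmicutes/Bacteroidetes (F/B) ratio, and the community's capacity to produce
short-chain fatty acids (SCFAs). Because SCFA concentrations are rarely
measured directly, the package uses a proxy: the summed counts of a curated
list of 17 SCFA-producing genera (`scfa_producers()`), aggregated into a
single feature and carried through a centered log-ratio transform.

## zBMI: the LMS method

Given a growth reference tabulating, per sex and age in days, the Box-Cox
power $L$, median BMI $M$ (kg/m²) and coefficient of variation $S$,

$$z = \frac{(\mathrm{BMI}/M)^L - 1}{L\,S}, \qquad
  z = \frac{\log(\mathrm{BMI}/M)}{S} \text{ if } L = 0,$$

with $L, M, S$ linearly interpolated at the child's exact age within sex and
no extrapolation beyond the tabulated span. A z-score of $+3$ corresponds to
the 99.865th percentile and $-3$ to the 0.135th; observations with
$|z| > 3$ are treated as measurement or entry errors and removed *per
observation* (a child keeps their remaining time points), with the bound
configurable in `flag_outliers()`. The package ships a synthetic LMS grid
(`synthetic_growth_reference()`) so the test-suite needs no external
download; real WHO-style tables in the same `sex,age_days,L,M,S` CSV layout
drop in unchanged. Only plain LMS is implemented — no special handling of
extreme z-scores beyond the removal rule, and no height-for-age or
weight-for-age scores.

## Compositional features

All features are computed from a genus-level count table with a
genus-to-phylum taxonomy:

* **Relative abundances** at genus or phylum level (`relative_abundance()`).
* **F/B ratio**: Firmicutes share divided by Bacteroidetes share. When a
  sample contains no Bacteroidetes the ratio is an infinity; it is reported
  as missing and excluded from ratio analyses rather than floored — matching
  how such samples must be handled in infancy cohorts, where most samples
  have zero Bacteroidetes counts.
* **CLR transform**: $x' = \log(x + c) - \overline{\log(x + c)}$, natural
  log. The pseudocount $c$ defaults to 0.5, added to every entry of the
  table being transformed. The base of the logarithm only rescales slopes;
  natural log is used throughout. CLR components sum to zero and the
  transform is invariant to scaling of the composition.
* **SCFA-producer sum score** (`scfa_sum_score()`): raw counts of all proxy
  genera are summed into one `SCFA_sum` feature which *replaces* them; the
  modified table (sum feature plus all non-proxy genera) is CLR-transformed
  and the sum feature's CLR value is the per-sample score. Genus names are
  matched exactly after whitespace/case normalization; Silva-style group
  names ("Eubacterium hallii group") are kept verbatim. Whether genus-level
  CLR features elsewhere in the pipeline should come from the proxy-modified
  or the full table is exposed as `clr_scope` in `composition_features()`
  (default: modified).
* **Observed richness**: the number of genera with nonzero count.
* **Abundance filter** (`abundance_filter()`): an optional input-side filter
  zeroing counts below a minimum within-sample relative abundance (e.g.
  0.1%). It is single-pass: proportions are evaluated against the original
  sample totals and survivors are not re-checked against the new total.

## The synthetic-cohort generator

`simulate_cohort()` emulates the longitudinal design the analyses assume:
five stool time points (1, 3, 4 months; 6, 10 years) and eight anthropometry
time points (adding 2, 7, 12 years) per subject.

* **Counts** are Dirichlet-multinomial per sample. Dirichlet concentration
  vectors per time point are calibrated so expected phylum shares track the
  descriptive course of a western birth cohort — Firmicutes rising from
  about 0.27 at 1 month to 0.72 at 10 years, Bacteroidetes from about 0.01
  to 0.11-0.18, Actinobacteria dominating infancy. Total concentration is
  small in infancy (6) and larger in childhood (25), giving realistic
  overdispersion and, in infancy, frequent structural zeros for
  Bacteroidetes: more than half of infant samples have none, so the F/B
  ratio is undefined for most infants, as in real infant cohorts.
  Dirichlet-multinomial was chosen over a logistic-normal model for exactly
  this zero-generating overdispersion.
* **Library size** is log-normal with configurable mean (default 20,000
  reads, log-scale SD 0.4, floor 100); sequencing depth is rarely reported
  for such cohorts, so this is an explicit stand-in exposed in the
  configuration.
* **zBMI trajectories** follow
  $z_T = \rho\, z_{T-1} + \textstyle\sum_g \beta_g\, \mathrm{clr}_g(T-1)
  + \beta_{bw}\, bw + u_{0j} + \varepsilon_T$,
  with autoregression $\rho = 0.45$, per-subject intercepts
  $u_{0j} \sim N(0, 0.3)$ (making the multilevel grouping non-trivial),
  birthweight slope 0.1 on standardized birthweight (drawn as
  $N(3613, 477)$ g), and residual SD 0.8 — jointly giving a marginal zBMI SD
  near 1, as a standardized score should have. The exposure term enters only
  at anthropometry time points whose immediate predecessor is a stool time
  point; `effect_timepoints` can restrict it further to plant a signal at a
  single exposure-outcome pair.
* **Generative CLR scale.** Planted effects act on the CLR of the *true*
  composition, expressed at the analysis's detection scale: CLR of expected
  counts at the mean library size with the analysis pseudocount. A CLR of
  raw proportions would let essentially-absent taxa (true share $10^{-30}$)
  drive zBMI through log magnitudes that no count table can resolve, making
  planted coefficients unrecoverable in principle rather than in practice.
  With the detection-scale definition, the measured CLR of an abundant genus
  tracks the generative CLR closely, and recovery error reflects genuine
  multinomial measurement noise. This is also why quantitative
  parameter-recovery studies plant effects on a consistently abundant genus
  (Bifidobacterium) or restrict fitting to childhood time points: for a rare
  genus in infancy, count-based CLR is a severely compressed version of the
  latent CLR and attenuates any slope — a real limitation of CLR regression
  on sparse compositions, not an artifact of the generator.
* **Weight and length** are produced by inverting the LMS reference at the
  latent z-score, with a smooth synthetic length-for-age curve; the
  anthropometry module's z-scores therefore round-trip to the latent truth.
* **Missingness**: anthropometry visits lose their weight/length/zBMI
  triplet; stool samples drop entirely. Under the default MAR mechanism the
  masking probability is logistic in the visit's true zBMI with the
  intercept calibrated so the mean rate matches the request (default 10%
  for both tables); MCAR is available. Complete tables and all latent
  quantities stay in `$truth` so imputation and recovery can be scored.

The generator does **not** simulate reads or ASVs, diet, delivery mode,
antibiotics, or any covariate structure linking composition to missingness
beyond zBMI. Passing tests therefore establish that the *statistical
machinery* is correct and calibrated under the stated generative model —
not that the biological effect sizes or the confounding structure of any
real cohort are captured.

## Multiple imputation: chained equations with PMM

`pmm_impute()` implements predictive mean matching from first principles.
Per stream (of `m`), missing cells are first filled by random draws from
their variable's observed values; then each sweep visits incomplete
variables in order of increasing missingness and, for each, fits a linear
regression on all other variables with a proper Bayesian draw of
coefficients (type-1 matching: the posterior draw predicts the missing
cases, the least-squares fit predicts the observed cases). Each missing
case copies the observed value of one of its `donors = 5` nearest predicted
neighbours, so imputed values always lie in the observed support. A small
ridge term ($10^{-5}$ on the diagonal) keeps the normal equations stable
under collinearity. Donor count and visit order are not canonical — five
donors is the conventional default — and both are recorded in the returned
object; chain means per sweep are kept for convergence inspection.

Desk-scale defaults are `m = 10`, `iterations = 10`; production-scale
`m = 100`, `iterations = 40` is a configuration change, not a code change.
For non-Bayesian downstream fits, `pool_estimates()` applies Rubin's rules
(total variance = within + $(1 + 1/m)\,$between). For the Bayesian
multilevel model, pooling instead mixes equal numbers of posterior draws
per completed dataset (`fit_across_imputations()`), which propagates
between-imputation uncertainty directly into the mixture quantiles.
Multilevel-aware imputation is out of scope.

## Spearman screening with BH control

`spearman_cor()` uses average ranks and the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on pairwise-complete cases, reporting
$(\rho, p, n)$ and a missing cell (never an exception) when $n < 3$.
`correlation_matrix()` builds the full predictor-time × zBMI-time grid and
applies Benjamini-Hochberg step-up adjustment *only over the hypothesised
cells*; the default mask marks same-time-point and next-time-point
(predictor earlier) cells, which are the a-priori directional questions, and
the mask is user-configurable because the exact a-priori cell set is a
design choice, not a statistical one.

## The Bayesian multilevel model

For outcome $z_{ij}$ (zBMI of subject $j$ at time point $T$) the model is

$$z_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + u_{0j} + u_{1j}\,e_{ij}
  + \varepsilon_{ij},\qquad
  \varepsilon_{ij}\sim N(0,\sigma^2),$$

with $\mathbf{x}$ containing an intercept, the exposure at $T-1$ (F/B
ratio, SCFA sum score, or genus CLR values), zBMI at $T-1$, and standardized
birthweight; $u_{0j}\sim N(0,\tau_0^2)$ and, for a single exposure,
$u_{1j}\sim N(0,\tau_1^2)$ on the exposure slope. Priors: $N(0, 0.5)$ on the
slopes of interest ($N(0, 0.25)$ recommended when many individual genera
enter jointly), $N(0,1)$ on the intercept, and exponential priors (rate 1 by
default, rate 15 as a stronger variant for hard-to-identify variance
components) on $\tau_0$, $\tau_1$ and $\sigma$. The intercept prior and the
residual-SD prior are this package's own defaults, declared here because a
complete prior set must be stated somewhere; both are configurable in
`model_spec()`.

Design choices:

* **Sampler.** Conjugate Gibbs updates for $\boldsymbol\beta$ and the
  subject effects; univariate slice sampling on the log scale for the three
  SDs under their exponential priors. Each SD update is followed by an
  ancillarity-sufficiency interweaving step (re-expressing $u_j/\tau$ as
  ancillary, under which the conditional for $\tau$ is a positive-truncated
  normal); without it, centered Gibbs mixes arbitrarily slowly when a
  variance component sits near zero. Chains start overdispersed;
  reproducibility comes from the seed.
* **Independent random effects.** The intercept and slope deviations are a
  priori independent; a correlation prior adds little at these data sizes
  and is deliberately omitted.
* **Vector exposures.** With many exposure columns, a varying slope per
  column would add ~17 weakly identified variance components; the package
  fits varying intercept + varying slope only for a single exposure and
  varying intercept only otherwise.
* **Scale.** Desk-scale defaults are 4 chains × 2,500 iterations (half
  warmup); larger runs are a configuration change. Split-$\hat R$ and an
  autocorrelation-based effective sample size are reported per parameter,
  and the shipped example configurations converge with $\hat R < 1.01$.
  For pooled mixtures across imputations the per-chain diagnostics are
  reported per dataset instead (between-imputation spread is intentional,
  so a mixture $\hat R$ would be misleading).
* **Degenerate inputs.** Zero-SD variables are an error in
  `standardize()`; rows missing any model variable are dropped by
  `fit_multilevel()` (imputation is the supported path for missingness);
  a non-finite likelihood is an error, not a warning.
* **Posterior predictive checks** simulate replicate outcomes with subject
  effects redrawn from their population distribution (a new-subjects
  replication), comparing mean, SD, min and max with Bayesian p-values.

zBMI itself is never re-standardized (it is already a standard-normal-scale
score); other exposures and covariates are standardized with the scaling
recorded for back-transformation.

## Random-forest inference

The forest regressor is `ranger`; everything inferential around it is
implemented in this package:

* **Tuning** (`tune_rf()`): randomized search over `mtry` (uniform on
  1..p) and `sample.fraction` (uniform on [0.3, 1]), scored by OOB mean
  squared error; 500 trees by default, subsampling without replacement.
* **Accuracy** (`repeated_cv()`): ten-times-repeated fourfold CV; per
  repeat, out-of-fold predictions for all samples are *pooled* and their
  Pearson correlation with the observed outcome computed; the median over
  repeats is the headline statistic (pooling rather than per-fold averaging
  was chosen for stability at small fold sizes). OOB-MSE of a full-data fit
  is reported on the outcome's own scale alongside.
* **Permutation null** (`permutation_null_test()`): the outcome is permuted
  `B` times and the full procedure — including re-tuning, by default — is
  re-run per permutation, so the null distribution carries the same
  optimistic selection as the observed statistic. Add-one p-values
  $p = (1 + \#\{\text{null} \geq \text{obs}\})/(B+1)$ for Pearson and
  $(1 + \#\{\text{null} \leq \text{obs}\})/(B+1)$ for OOB error (lower is
  better) are never exactly zero; `B ≥ 19` is enforced for resolution.
* **Family report** (`run_model_family()`): per stool time point, one
  cross-sectional and one next-time-point model; BH adjustment across the
  whole family of p-values; Altmann permutation-importance p-values
  (observed importance from the unpermuted fit, null importances from `B`
  fits on permuted outcomes) for models whose smaller p-value passes a
  configurable threshold (default 0.05). Constant features get importance 0
  and p = 1 by convention. Features are CLR genus abundances by default.
* **Desk scale.** Defaults of `B = 199` permutations and 20 tuning
  candidates keep a full family run tractable on one CPU; 1,000
  permutations is a configuration change. Validation studies in the test
  suite run smaller layouts (2-fold CV with one repeat, reduced tree
  counts) because permutation calibration is a property of the procedure,
  not of the forest size.

## Validation studies shipped with the package

The test suite computes, among others: exact LMS/CLR/BH identities;
type-I-error calibration of the permutation test (500 null replicates at
n = 100, B = 99); parameter recovery of a planted exposure slope of −0.3
(n = 300 subjects, 50 replicates) and credible-interval coverage under a
null exposure (50 replicates); PMM pooled-interval coverage of a known
regression slope under 20% MCAR (200 replicates, n = 200, m = 10); and
end-to-end detection of a single genus effect planted at the 10y→12y pair
(20 seeds, n = 150 subjects, planted slope −0.8 — chosen as a clearly
detectable signal — with B = 29 permutations and one CV repeat per model).
Problem sizes are the package's own desk-scale choices; every study
re-derives its expectations from the generator's retained truth rather than
from stored constants. `scripts/acceptance.R` re-runs condensed versions of
the same studies from scratch and writes their headline numbers to JSON.

## Known limitations

* CLR regression on sparse compositions attenuates slopes for rare taxa
  (see above); conclusions about low-abundance genera in infancy are
  intrinsically weaker than for abundant ones.
* The F/B ratio is undefined for most infant samples; analyses that need it
  in infancy will run on few observations, as reflected in the screening
  module's per-cell `n`.
* PMM imputes from the observed support only and is not multilevel-aware;
  strongly extrapolating missingness mechanisms are outside its comfort
  zone.
* The permutation framework calibrates p-values under exchangeability of
  the outcome; longitudinal dependence between *different models'* outcomes
  is handled only through the BH correction across the family.
* The sampler covers the specific varying-intercept/varying-slope Gaussian
  model described here; it is not a general-purpose MCMC engine, and no
  model-comparison criteria (LOO/WAIC) are provided.
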