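---
title: "Proteomic age gaps and case-cohort survival: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic age gaps and case-cohort survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

protage implements a complete analysis stack for proteomic aging studies:
linear "clock" predictors of chronological age from plasma protein
intensities, lowess-detrended age gaps as the exposure of interest, and
Prentice-weighted stratified Cox regression relating those gaps to mortality
and incident disease under a case-cohort design. Because individual-level
cohort proteomics data cannot be redistributed, the package ships a
synthetic cohort generator with a known latent ground truth, and every
inferential component is validated against it.

## The model

### Clocks and age gaps

A proteomic clock is an affine predictor

$$\hat a_i = \beta_0 + \sum_j \beta_j\, f_j(x_{ij}),$$

where $x_{ij}$ is the intensity of analyte $j$ in subject $i$ and $f_j$ is a
declared per-analyte preprocessing step (identity, $\log_{10}$, or
standardization with stored training mean/SD). `clock_spec()` carries the
weights, intercept and preprocessing together so a clock is self-contained
and portable (JSON). `train_clock()` fits clocks by cross-validated
elastic net (`glmnet`, mixing $\alpha = 0.5$ by default, $\lambda$ at the
CV minimum), storing training means/SDs as `zscore` preprocessing.
Missing analytes abort clock application rather than being imputed: silent
imputation changes the meaning of a published coefficient vector.

Clock predictions compress toward the training mean and can be non-linear
in age, so the raw difference $\hat a_i - a_i$ confounds prediction bias
with biology. The **age gap** is therefore defined against the cohort
trend: a locally weighted linear smoother (tricube kernel, span $2/3$,
no robustifying iterations) of predicted on chronological age is evaluated
at every observed age, and

$$\Delta_i = \hat a_i - \hat s(a_i).$$

By construction $\Delta$ is (close to) uncorrelated with age; a uniform
shift of all predictions is absorbed by $\hat s$ and leaves gaps unchanged —
gaps are *relative* quantities within the scoring population. Gaps are
z-scored per clock (sample SD, $n-1$ denominator) so clocks with different
variability can be compared on one scale; `per_year_effect()` converts a
per-z log hazard back to a per-year hazard ratio through the gap SD in
years. The robustness-iteration count of the smoother is configurable
(default 0) because published descriptions of the convention rarely state
it; with well-behaved predictions the difference is negligible.

The **Global** gap is the unweighted mean of the conventional clocks' gaps,
z-scored afterwards. If each clock's gap is a shared biological signal plus
independent error of similar size, averaging $K$ clocks multiplies the
error variance by $1/K$; with signal and noise SDs equal,
$\mathrm{cor}(\text{ensemble}, \text{signal}) = \sqrt{K/(K+1)}$ versus
$1/\sqrt 2$ for a single clock. Only conventional (all-protein) clocks
enter the ensemble; organ-specific clocks are deliberately excluded since
they are designed to diverge from each other.

**Organ-specific clocks** restrict training to analytes whose expression is
enriched in one organ. `select_organ_proteins()` applies an inclusive
fold-enrichment threshold (default 4, the usual convention in the
organ-clock literature); `"organismal"` selects the complement — analytes
below threshold for every organ — so the sets partition the analyte
universe.

### Quality control

`qc_outliers()` flags multivariate outlier samples: the log10-transformed,
column-standardized matrix is projected onto its top principal components
(default 10), each subject receives a local-outlier-factor score (LOF,
default 20 neighbours) in that projection, and Tukey's rule
($> Q_3 + 1.5\,\mathrm{IQR}$ of the scores) marks outliers. All three
parameters are configurable; the defaults are conventional values since the
procedure, not a parameterization, is the published method. LOF is
implemented in the package (blockwise distance computation to bound
memory); the test suite checks it against a brute-force double-loop
implementation.

### Case-cohort survival inference

The case-cohort design compares all incident cases of each endpoint with a
random subcohort drawn once from the full cohort. `sample_case_cohort()`
marks a Bernoulli subcohort, keeps every case, and drops non-subcohort
non-cases. Inference uses **Prentice weighting**: subcohort members are at
risk from study entry to exit; cases outside the subcohort enter the risk
set only just before their own failure ($t_i - \varepsilon$,
$\varepsilon = 10^{-6}$ yr), contributing their failure but standing in no
other risk set. Estimates are insensitive to $\varepsilon$ across
$10^{-4}$–$10^{-8}$ (tested).

The Cox model uses **age as the time scale** (delayed entry at recruitment
age) and is stratified by sex, study center and 5-year age band (bands
aligned to multiples of 5, configurable origin). The partial likelihood
with Breslow tie handling is maximized by Newton-Raphson with step-halving;
the convergence criterion is a score (gradient) norm below $10^{-9}$, and
every fit exposes its final gradient norm. Breslow rather than Efron ties:
the Prentice risk-set algebra stays exact under Breslow, simulated
continuous ages make ties measure-zero, and the tie-handling path is still
covered by a dedicated test against `survival::coxph(ties = "breslow")`.
The default variance is a robust sandwich grouped by subject — under the
Prentice risk-set modification the model-based (inverse-information)
variance is not consistent — with the model-based variance available by
flag. Eventless strata are dropped with a logged count. Collinear
covariates abort with the aliased column names.

Multiple testing uses Benjamini-Hochberg FDR (`stats::p.adjust`), computed
separately for the conventional-clock and organ-clock association families
within each model, mirroring how the two clock families form separate
hypothesis grids.

`harrell_c()` computes Harrell's concordance under left truncation: for
each event at age $t$, the comparable set is subjects at risk at $t$
(entered before, exited after); score ties count 1/2; tied event ages are
not comparable. `compare_models_concordance()` scores fixed fitted linear
predictors over subject-level bootstrap resamples (200 by default) for
percentile CIs; coefficients are not refit per resample, so the CIs
describe scoring uncertainty at the fitted model. Concordance models are
fitted on the Prentice-weighted case-cohort records and scored on the
sampled subjects' full risk intervals.

`lasso_cox_select()` performs L1-penalized selection among candidate gap
exposures (adjustment covariates enter unpenalized) on the stratified
(start, stop] partial likelihood via `glmnet`, with $\lambda$ at the 5-fold
CV minimum of partial-likelihood deviance, then refits the selected
exposures unpenalized with the full Prentice/stratification machinery. A
known property of the CV-minimum rule is mild overselection: with many
events it admits, on average, two to three null candidates alongside the
true ones in the package's recovery experiment. The CV-minimum rule is kept
because it is the stated tuning convention; users wanting parsimony can
pass `lambda.1se`-style paths through `...`.

`lag_sensitivity()` re-runs an association treating events within 2 or 5
years of entry as non-events. Subcohort members are censored at the event
age; non-subcohort early cases leave the sample entirely, since without
their case status they have no place in a case-cohort sample.

### Risk-factor models and the healthy lifestyle index

Cross-sectional associations between gap z-scores and lifestyle are
estimated by OLS within the subcohort (the representative sample), adjusted
for age, sex and center. Categorical factors use the least healthy category
as the reference (first factor level). The mutually adjusted variant fits
one regression per clock with all factors simultaneously and exports the
clock-by-factor coefficient matrix.

The healthy lifestyle index sums five 0–4 component scores (BMI, smoking,
alcohol, diet, physical activity; higher = healthier) to a 0–20 scale. The
component cutpoints are shipped as an editable YAML file
(`inst/extdata/hli_cutpoints.yaml`) rather than code, because such scores
are study conventions: the alcohol "light" boundary of 6 g ethanol/day
follows the common light-drinking convention, the remaining bounds are
round conventional values. Quintiles of the total use sample quantiles with
ties assigned to the lower quintile.

### Age-relatedness of endpoints

Each endpoint's age-relatedness is the slope $b$ of a Gompertz-Makeham
hazard $h(t) = c + a e^{bt}$ fitted to banded incidence by Poisson maximum
likelihood, $\text{events} \sim \text{Poisson}(\text{person-years} \cdot
(c + a e^{b m}))$ with $m$ the band midpoint (5-year bands by default —
band-level fitting replaces the individual-level data one rarely has).
Optimization runs on the $(\log c, \log a, b)$ scale, where the problem is
well conditioned, from 20 starts over a log-spaced $b$ grid in
$[10^{-3}, 0.3]$/yr (spanning reported human disease slopes), each start
with moment-matched $(c, a)$; Nelder-Mead is polished by BFGS. A Makeham
term collapsing to a negligible hazard share is refit with $c = 0$ and
flagged as a boundary solution, not an error. The SE of $b$ comes from the
observed information (numerical Hessian on the transformed scale).

`correlate_age_relatedness()` relates per-z log hazards to the $b$ slopes
across endpoints by Spearman rank correlation (exact p for $\le 10$ pairs,
normal approximation otherwise; matching is by endpoint label, with at
least 5 shared endpoints required). The raw slope is used, not a transform
of it — Spearman correlation is invariant to monotone transforms anyway
(tested). Association matrices are ordered by complete-linkage hierarchical
clustering on Euclidean distances, rows and columns independently.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure the
analysis assumes, with marginals typical of a large European cohort
recruited in midlife: recruitment ages uniform on
35–75, 62% female, four centers, 25% current smokers, BMI
$\mathcal N(26.9, 4.3^2)$, and conventional distributions for alcohol,
diet, activity and education (the joint lifestyle distribution of any real
cohort is unknown; these marginals are conventions, not estimates).

Each subject carries a latent **global acceleration** (years; SD default
3, matching typical Global-gap SDs) plus independent per-organ increments
(SD default 2). Lifestyle enters biology *only* through the global
acceleration, additively in years — the simplest structure that makes
risk-factor-adjusted attenuation testable. Default effect sizes emulate the
magnitudes reported for smoking (heavy smokers about a year older),
alcohol, and physical activity in large cohorts; BMI and diet default to
zero effect. Age-linked proteins are affine in biological age,
$x_{ij} = a_j + b_j (a_i + \text{accel}_i) + \varepsilon_{ij}$, with organ
blocks using the global plus their organ's acceleration; intercepts
$a_j \in [300, 600]$ and slopes $|b_j| \in [0.5, 1.5]$ keep intensities
positive at the default noise SD of 15. The generating organ blocks are
exported as an annotation table (enrichment 8 for block members, < 2
otherwise) so organ selection can be checked against ground truth.

Survival follows an additive Gompertz-Makeham hazard
$h(t) = c + a e^{bt + \gamma\,\text{accel}}$ with defaults
$c = 10^{-4}$/yr, $a = 10^{-5}$/yr, $b = 0.1$/yr — about a 1%/yr hazard at
age 70 and 15–20% mortality over the default 17-year follow-up, in line
with European cohort experience — and $\gamma = 0.1$ per year of
acceleration, i.e. a hazard ratio of about 1.35 per 3-year (one SD)
acceleration. Event ages are drawn by inverse-transform sampling; the
cumulative hazard has no closed-form inverse, so it is inverted by
vectorized bisection on the exact monotone cumulative hazard (60
iterations, machine precision) — chosen over a discretized-grid inversion
because it is exact and fully vectorized. Censoring is administrative at
`min(entry + follow_up_years, admin_censor_age)`; the `follow_up_years`
field (default 17) exists because a fixed censoring *age* alone would give
wildly unequal follow-up across a 40-year recruitment window.

What the generator does **not** emulate: plate/batch effects and assay
calibration, competing risks, covariate measurement error, informative
censoring, non-linear or interactive lifestyle effects, and clocks whose
error correlates across clocks. Passing tests therefore demonstrate that
the estimators recover the truth under the model's own assumptions — not
that those assumptions hold in any real cohort.

## The pipeline

`run_analysis()` executes simulate (or ingest) → QC → clock training →
age gaps → case-cohort associations (base and risk-factor-adjusted, with
per-family FDR) → risk factors → age-relatedness → concordance comparison,
writing TSV/JSON artifacts, a deterministic manifest and a timestamped log.
One master seed drives everything through a documented splitting map
(`derive_seed()`), so identical configurations reproduce byte-identical
tables. For simulated runs the generator draws a single cohort (one
protein-parameter draw) and splits it into a training part (default 800
subjects) and the analysis part, so clocks are always applied
out-of-sample; five "conventional" clocks are differentiated by training
each on a random 70% subset of analytes. Missing covariates (possible with
ingested data) receive a single mean/mode imputation with a logged count;
`impute = "none"` aborts instead. This single imputation replaces
multiple-imputation machinery deliberately: the pipeline's covariates are
complete by construction when simulated, and chained-equation imputation is
out of scope.

## Problem sizes and numerical tolerances

The test suite runs its recovery experiments at sizes chosen to make each
check sharp but fast: Cox-oracle equivalence at $n = 4$ and $n = 500$
(tolerance $10^{-6}$), case-cohort recovery over 20 cohorts of $n = 8000$
(subcohort fraction 0.3, true HR 1.4 per SD), lasso recovery over 20
cohorts of $n = 8000$ with 3 true among 11 candidate gaps, ensemble
dominance over 50 replicates of $n = 1000$, smoother-oracle agreement at
$n = 200$ ($10^{-6}$), gap-age decorrelation at $n = 5000$, and
Gompertz-slope recovery within 0.005/yr at $5 \times 10^5$ person-years
per band. Z-scores are exact to floating tolerance ($10^{-8}$); the Newton
solver's gradient norm at convergence is below $10^{-6}$ in all shipped
checks.

## Known limitations

- The Cox engine supports the Prentice scheme only (no Barlow or
  Self-Prentice weights), Breslow ties only, and no time-varying effects or
  competing risks.
- Concordance CIs hold coefficients fixed across bootstrap resamples;
  model-selection uncertainty is not propagated.
- The lasso CV-minimum rule overselects mildly by design (see above).
- Whether gap z-scores should be standardized on the full case-cohort
  sample or the subcohort alone is a genuine ambiguity of the design; the
  package defaults to the full analysis sample and exposes the scoring
  population as an argument (`zscore_gaps(population = ...)`).
- Real-data ingestion expects the documented TSV/CSV/JSON schemas; vendor
  normalization (hybridization/plate/ANML scaling) is upstream of this
  package and out of scope.
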