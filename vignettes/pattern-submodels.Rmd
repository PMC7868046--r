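---
title: "Pattern submodels: model, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern submodels: model, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternsub)
```

## The model

Let $Y$ be a fully observed response, $X$ an $n \times p$ predictor matrix
with arbitrarily missing cells, and $M$ the indicator matrix with $M_{ij} = 1$
when $X_{ij}$ is **missing** (this coding is deliberate and used everywhere in
the package; it is the reverse of the more common one, so it is worth stating
twice). A *pattern* is a distinct row of $M$, written as a bit string such as
`"10"`; patterns sort lexicographically, so the fully observed pattern comes
first in every table the package prints. At most $2^p$ patterns exist; in
practice only a few are observed.

A **pattern submodel (PS)** set fits, per observed pattern $m$, the model
$E[Y \mid X_M, M = m] = \gamma_{0,m} + \sum_{j \in \text{obs}(m)}
\gamma_{j,m} X_j$ on *exactly the records of pattern $m$*, using only that
pattern's observed columns. The all-missing pattern gets an intercept-only
model, the pattern's mean response. Because every submodel conditions on its
own pattern, nothing needs to be assumed about why the data are missing, and
prediction needs no imputation: a new record is dispatched to the submodel
matching its own pattern.

The supporting identity is the decomposition of the expected prediction error
over patterns,
$$
E\big[L(Y, \hat f(X))\big]
  = \sum_m P(M = m)\, E\big[L(Y, \hat f_m) \mid M = m\big],
$$
valid for any loss that scores records pattern by pattern (squared error,
Brier, log score — but *not* AUC, which compares records across patterns; the
package deliberately offers no AUC). Minimizing each pattern-specific expected
loss therefore minimizes the total, *within a fixed model class*: the same
family and variant must be used for every pattern, which
`pattern_model_set` enforces by construction.

Comparators implemented around PS:

* **CCS** (complete-case submodels): the same per-pattern column sets, but
  each submodel is fit on *all* records that observe those columns. Records
  are re-used across patterns and observed data outside the column set are
  discarded; predictions are trustworthy only under an MCAR-type assumption.
* **Complete-case model**: one full-column model on the complete records;
  forecasting an incomplete record requires an imputation engine.
* **Imputation strategies**: zero, unconditional mean, conditional mean
  (frequentist or Bayesian), and chained-equations PMM multiple imputation,
  all through a frozen in-sample engine (below), feeding the single
  full-column model.
* **MIMI**: the mean model augmented with indicator main effects and
  indicator-by-covariate interactions, fit on each completed data set and
  averaged at prediction time.
* **Hybrid PS/CCS** and **relaxed-lasso submodels** for sparse patterns and
  adaptive per-pattern selection.

## PS as the limit of the MIMI model

For $p = 2$ the full MIMI mean is
$$
E[Y \mid X, M] = \beta_0 + \beta_1 X_1 + \beta_2 X_2
  + \delta_1 M_1 + \delta_2 M_2
  + \delta_3 X_1 M_1 + \delta_4 X_2 M_2 + \delta_5 X_1 M_2 + \delta_6 X_2 M_1 ,
$$
and `build_mimi_design(scope = "full")` reproduces exactly this column layout.
Grouping terms shows the model is a per-pattern reparameterization: pattern
$(M_1 = 1, M_2 = 0)$ has intercept $\beta_0 + \delta_1$, $X_1$-coefficient
$\beta_1 + \delta_3$, $X_2$-coefficient $\beta_2 + \delta_6$. If the missing
$X_1$ is completed by its conditional mean $\alpha_0 + \alpha_2 X_2$, the
fitted surface in that pattern collapses to
$\gamma_0 + \gamma_2 X_2$ with
$\gamma_2 = \beta_2 + \delta_6 + (\beta_1 + \delta_3)\alpha_2$ — the PS
submodel. The test suite checks this equivalence to $10^{-8}$, prediction by
prediction and coefficient by coefficient.

Two numerical consequences are handled explicitly:

* **Aliasing is expected, not an error.** Under conditional-mean completion
  the design is rank-deficient *by construction* (the completed $X_1$ is an
  exact linear function of $X_2$ inside the missing pattern). All fits use
  pivoted least squares; aliased columns are recorded and act as zeros in
  prediction, which is precisely the projection the equivalence argument
  needs. The same policy applies inside sparse patterns of PS/CCS fits.
* **Interaction scope for $p > 2$.** The full pairwise set grows as $p^2$, so
  the default (`scope = "auto"`) is the full nine-term layout for $p \le 2$
  and "own" interactions ($M_j$ mains plus $X_j M_j$) for larger $p$;
  `scope = "full"` remains available. `scope = "none"` gives the plain design
  and is how the traditional-MI comparator is fit, sharing all the MIMI
  machinery. Indicator columns that are constant (covariates never missing in
  training) are dropped and recorded.

Unlike MIMI, which forces a single residual variance, PS stores a residual
variance per pattern; the model-set serialization keeps it.

## The missingness simulator

Predictors are multivariate normal, $X \sim N(\mu, \Sigma)$. Five mechanisms
govern $P(M_1 = 1)$ for the column subject to missingness (the first, by
default; only one column is missing in the two-covariate study, matching its
single target probability):

| kind  | drivers of the linear predictor            |
|-------|--------------------------------------------|
| MCAR  | none — constant probability                 |
| MAR   | $\nu_{x_{obs}} X_2$ (an observed column)    |
| MNAR  | $\nu_{x_{miss}} X_1$ (the missing column)   |
| MARY  | MAR's driver $+\ \nu_y Y$                   |
| MNARY | MNAR's driver $+\ \nu_y Y$                  |

The link is logistic: it is the standard selection-model form and makes the
mean missingness probability strictly monotone in the intercept $\nu_0$, so
`calibrate_intercept()` can solve
$\operatorname{mean}\{\text{logit}^{-1}(\nu_0 + \text{drivers}\,\nu)\} =
P(M_1 = 1)$ by bracketed root finding (`uniroot`, tolerance $10^{-10}$ on the
achieved probability). Calibration uses the *realized in-sample drivers*, and
the calibrated mechanism object is passed unchanged to the out-of-sample
generator, so the mechanism is identical in and out of sample.

Two outcome formulations are supported and must match the mechanism's:

* **selection**: $Y = \beta_0 + \beta^\top X + \varepsilon$ drawn *before*
  the indicators, so missingness may depend on $Y$ (MARY/MNARY exist only
  here);
* **pattern mixture**: the indicators are drawn first and
  $Y$ comes from the MIMI mean evaluated at the *true* covariates and the
  simulated indicators — patterns genuinely differ in their response model
  when $\delta \ne 0$.

Separate seeds are derived for the predictor, indicator and noise draws, so
changing the mechanism does not perturb the predictor draw.

**Study conditions.** `study_config()` defaults to the conditions the
simulation study is stated for: $n = 1000$ in- and out-of-sample,
$\mu = (3, 3)$, unit variances with correlation $\rho = 0.5$,
$\beta = (1, 3, 1)$, noise SD 1, $P(M_1 = 1) = 0.5$, driver coefficients
$\nu = 1$, and — under the pattern-mixture formulation —
$\delta_1 = \delta_3 = 1$ (an intercept and $X_1$-slope shift in the missing
pattern). Acceptance-scale runs use 200 repetitions, a deliberate scale-down
from the original thousands that still leaves Monte-Carlo standard errors an
order of magnitude below the effects being compared.

**What the generator does not emulate.** Real clinical tables have
non-Gaussian, bounded and discrete covariates, categorical predictors,
many-column missingness with dozens of sparse patterns, and measurement error.
`simulate_clinical_like()` narrows the gap on *pattern structure* (ten
covariates, overlapping MAR missingness, a dominant complete pattern, sparse
tails) but keeps Gaussian margins. Passing tests therefore demonstrate the
estimators' behavior under the stated generative conditions, not performance
guarantees on any particular registry.

## The frozen imputation engine

Real deployments impute a new record against the *training* state, not
against a refitted model. `fit_engine()` therefore captures everything at
training time — column means; per-(target column, pattern) conditional
regressions on the pattern's observed columns; PMM donor pools (observed
values with their fitted means, stored sorted); and any Bayesian coefficient
draws — and is immutable afterwards. Numerical choices:

* **PMM** is type-1: donors are ranked by fitted means under the frequentist
  coefficients, the target's predicted mean uses a per-set Bayesian draw, and
  one of the $k = 5$ nearest donors is sampled uniformly ($k$ configurable;
  5 is the conventional choice). The $k$ nearest donors in a pool sorted by
  fitted mean form a contiguous window, so selection is a two-pointer merge
  outward from the insertion point — exact, vectorized, with ties broken
  toward the smaller fitted mean. Imputed values are always members of the
  column's observed-value set.
* **Bayesian draws** use the standard noninformative-prior normal linear
  model: $\sigma^{2*} = \hat\sigma^2 \nu / \chi^2_\nu$, then
  $\alpha^* \sim N(\hat\alpha, \sigma^{2*}(D^\top D)^{-1})$.
* **Chained equations** (`multiply_impute_insample()`) visit incomplete
  columns in order of increasing missingness, defaulting to 10 sweeps per
  set. In the two-covariate study only one column is incomplete, so the chain
  is exact after a single sweep; the study driver uses 2 sweeps there.
* **Per-record seeds.** Out-of-sample records are imputed one by one; record
  $i$ under base seed $s$ uses seed $s + i$, so batch processing, processing
  order, and record-at-a-time imputation all agree bit for bit.
* **Unseen patterns** fall back to the unconditional mean with a warning;
  singular conditional fits error, naming the column.
* **The response as an imputation predictor** is off by default ($Y$ is
  unknown out of sample). It matters for *estimation*: with $Y$ excluded, the
  imputations are conditionally independent of $Y$ given the observed
  covariates, the within-pattern slope on the imputed column is attenuated,
  and the MIMI $\delta$'s pick up the artifact even under MCAR. With
  `include_response = TRUE` (the in-sample estimation setting) the pooled
  $\delta$'s are null under MCAR, which is how the delta-null check is run.
  The flip side, visible in the study output's imputation-error channel, is
  that response-aware engines cannot be used for out-of-sample forecasting.

A deliberate consequence of frozen-engine MI with finite $m$: averaged
predictions carry residual imputation noise of order
$\beta_1^2 \operatorname{Var}(X_1 \mid X_2)/m$, so traditional MI sits
measurably above the conditional-mean strategies even under MCAR. This is a
property of practical MI forecasting, not an implementation artifact, and the
tie checks among strategies exclude MI (and the structurally off-target zero
and unconditional-mean imputations) accordingly.

## Hybrid rule and relaxed lasso

Sparse patterns may not support a PS fit. `fit_hybrid()` uses the rule
"CCS when $n_m \le$ `ccs_threshold`", recording per pattern which route was
taken. The default threshold $2p - 1$ gives a PS whenever a pattern has at
least $2p$ records (the rule of thumb); `ccs_threshold = (p + 1) \cdot 2`
reproduces the clinical-example convention — for $p = 10$, CCS for patterns
with at most 22 records. The two conventions differ by one record at the
boundary; the argument makes either exact. `ccs_threshold = 0` is PS
everywhere, `Inf` is CCS everywhere.

Relaxed-lasso submodels run cross-validated lasso selection
(`glmnet`, `lambda.min`, fold assignment seeded per learner) followed by an
unpenalized refit on the selected support; unselected coefficients are exact
zeros, an empty support yields the intercept-only model, and patterns with
fewer than two observed columns fall back to the plain fit (the lasso stage
needs two). Covariates are standardized inside the lasso stage only;
coefficients are reported on the original scale. Two patterns may share a
predictor set yet select different supports — that is the point.

## Evaluation

`squared_error_decomposition()` reports per-pattern mean losses, empirical
pattern proportions as weights, and the weighted total, which equals the
pooled mean loss *exactly* (the empirical form of the EPE decomposition; the
tests assert it to $10^{-12}$). For binary outcomes, `binary_scores()` gives
the Brier score and the logarithmic score. The log-score formula is reported
as the *negative* mean Bernoulli log-likelihood so that smaller is better for
every score in the package, and probabilities are clipped to
$[10^{-15}, 1 - 10^{-15}]$: a certain-and-wrong prediction is grossly
penalized (about 34.5 per such record) but stays finite.

`cross_validate()` stratifies folds by pattern, because pattern-specific
losses are the unit of analysis and unstratified folds can leave a pattern
entirely out of training; patterns smaller than $k$ are spread without full
stratification. Engines and relaxed-lasso tuning are fit on training folds
only. `dichotomize_median()` splits at the sample median with ties to the
lower class.

`run_simulation_study()` reports per-strategy Monte-Carlo standard errors
alongside all means (ordering claims need uncertainty), shares one PMM engine
and one set of imputations between the MI and MIMI fits, isolates failed
repetitions, and records the squared imputation error of the missing
covariate as a side channel separating imputation bias from prediction bias.

## Problem sizes

The shipped checks run at: $n = 10^5$ for mechanism calibration (tolerance
0.02 on the achieved probability); $n = 5000$, 100 repetitions for the
MCAR PS–CCS coefficient agreement; $n = 5000$, $m = 10$ for the delta-null
check; $n = 1000$ in/out with 200 repetitions per mechanism for the
simulation study; and a 600-record, ten-covariate synthetic clinical table
for the hybrid/MNARY experiment. These sizes were chosen so every Monte-Carlo
comparison has standard errors well below the effects of interest.

## Known limitations

* Numeric covariates only; categorical predictors and missing responses are
  out of scope.
* MIMI standard errors come from Rubin's rules on per-set OLS fits; no
  shrinkage of the $\delta$'s is offered.
* Logistic fits use plain IRLS with an iteration cap; quasi-separation inside
  tiny patterns is best handled by the hybrid rule rather than penalized
  likelihood.
* The on-demand CCS fallback needs the stored training data, so a
  deserialized model set refuses unseen patterns instead.
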