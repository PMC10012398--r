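---
title: "Sample size methodology for multinomial prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size methodology for multinomial prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnlsampsize)
```

## The model and what "enough data" means here

A multinomial logistic regression for a nominal outcome with $K$
categories predicts all category probabilities through $K-1$ log-odds
sub-models against a reference category $r$,
$$\ln\frac{P(Y=k)}{P(Y=r)} = \beta_{0,k} + \sum_{q=1}^{Q}\beta_{q,k}X_q,$$
with the constraint that the probabilities sum to one. $Q$ counts
*candidate predictor parameters* per sub-model — every spline basis,
polynomial and interaction term considered before any selection, not the
number of clinical variables.

Development datasets that are too small produce overfitted models: the
fitted coefficients are too extreme, and validation calibration slopes
fall below 1. For binary outcomes a well-established framework sizes the
data so that (i) the expected shrinkage needed at validation stays above a
target $S$ (commonly 0.9), (ii) the optimism in the apparent Nagelkerke
$R^2$ stays below a tolerance $\delta$, and (iii) the overall outcome
proportion is estimated precisely. This package carries those three
criteria to the multinomial case. The subtlety is all in criterion (i).

## Criterion (i): why pairwise, not global

A single heuristic shrinkage factor for the whole multinomial model,
$S_{VH} = 1 - (K-1)Q/\mathrm{LR}$, can be targeted with the binary
formula, but it has no fixed relationship with the $K-1$ *sub-model*
shrinkage factors: a model can look fine globally while the sub-model
separating two rare categories is badly overfit. The package therefore
exposes that global calculation only as a diagnostic
(`heuristic_shrinkage_size()`, which always warns), and sizes instead on
the *distinct logistic regressions*: sub-model $\{k,r\}$ is parametrically
equivalent to the one-vs-one logistic model fitted on the subset with
$Y \in \{k,r\}$, so the binary shrinkage formula
$$m_{k,r} = \frac{Q}{(S-1)\,\ln\!\left(1 - R^2_{k,r}/S\right)}$$
applies per pair, with $R^2_{k,r}$ the pair's anticipated optimism-adjusted
Cox–Snell $R^2$. Because at validation any category may serve as the
reference, *every* unordered pair must be controlled, not only pairs with
the development reference; the whole-cohort requirement for a pair divides
by the pairwise prevalence, $n_{k,r} = m_{k,r}/p_{k,r}$, and the criterion
takes the maximum over the $K(K-1)/2$ pairs. Pairs are stored and reported
with $k>r$ only; the two orientations give the same model.

## Criterion (ii) and (iii)

Criterion (ii) bounds the difference between apparent and adjusted
Nagelkerke $R^2$ of the overall model by $\delta$ (default 0.05). The
implied lower bound on the heuristic shrinkage factor is
$S \ge R^2_{adj}/(R^2_{adj} + \delta\,\max R^2)$; substituting into the
shrinkage formula with $(K-1)Q$ parameters gives the smallest qualifying
$n$. A useful identity used in the tests: under the fallback assumption
$R^2_{adj} = 0.15\max R^2$ and $\delta = 0.05$, the bound is exactly
$0.15/0.20 = 0.75$ whatever $\max R^2$ is.

Criterion (iii) asks that *simultaneous* $(1-\alpha)$ confidence intervals
for all $K$ category proportions have absolute margin of error at most
$\delta$ (default 0.05). The Bonferroni/Goodman-type construction uses the
$\chi^2_1$ upper-tail quantile at $\alpha/K$:
$n_k = \chi^2_{1,\alpha/K}\, p_k(1-p_k)/\delta^2$, $n=\max_k n_k$. For
$K=5$, $\alpha=0.05$ the quantile is 6.635. For $K=2$ this is deliberately
more conservative than the pointwise $1.96^2$ convention used for binary
models; `pointwise = TRUE` restores that convention per category.

The final recommendation is the maximum of the three criteria. An
events-per-variable comparator (`epv_size()`, rarest category) is offered
for context only.

## Getting the pairwise R-squared values

Resolution precedence, applied per pair and logged in the report:

1. **Reported** adjusted Cox–Snell $R^2$ of the published one-vs-one model.
2. **Pairwise C-statistic**, converted by simulation: the linear predictor
   is taken normal within outcome groups with unit variance and mean
   separation $\sqrt{2}\,\Phi^{-1}(C)$ (location and common scale cancel
   in $R^2$); a replicate simulates `sim_size` individuals with event
   fraction $\varphi_{k,r}=E_k/(E_k+E_r)$, refits the logistic model, and
   computes $R^2 = 1-\exp(-\mathrm{LR}/n)$. Defaults: $10^6$ individuals
   $\times$ 10 replicates, fixed (non-Bernoulli) group allocation to
   suppress group-size noise, mean reported with its Monte-Carlo standard
   error. Because the induced log-odds is exactly linear in the predictor,
   the large-sample value is available in closed form by numerical
   integration; the test suite checks the simulation against that oracle
   (e.g. 0.18514 at $C=0.75$, $\varphi=0.5$).
3. **Fallback**: a conservative Nagelkerke $R^2$ of 0.15, rescaled per pair
   by the pair's maximum attainable Cox–Snell $R^2$,
   $\max R^2_{k,r} = 1-(\varphi^{\varphi}(1-\varphi)^{1-\varphi})^2$.

The overall maximum for criterion (ii) is
$\max R^2 = 1-(\prod_k p_k^{p_k})^2$, identical to the route through the
null log-likelihood $\sum_k E_k\ln(E_k/n)$ — both routes are implemented
and asserted equal to $10^{-10}$.

## Numerical and interface choices

* **Rounding.** Sizes are rounded *up* at the final step only
  (per-pair $n_{k,r}$, per-category $n_k$, the criterion (ii) bound), with
  unrounded intermediates carried internally; `rounding = "nearest"`
  exists for audit. Consequence: with the worked example's printed
  3-decimal inputs the criterion (ii) bound is 1477.08, reported as 1478,
  while the source publication prints the truncated 1477; the report logs
  this note. Similarly, published pairwise grids computed from unrounded
  simulated $R^2$ values are reproduced to within about 0.5% from their
  printed 3-decimal inputs (binding pair preserved), not digit-for-digit.
* **Degenerate inputs.** Empty outcome categories are a hard error in
  every likelihood-based quantity (the sizing question is ill-posed for an
  unobserved category) but contribute zero, with a warning, in criterion
  (iii). An anticipated $R^2 \ge S$ makes the shrinkage target
  unattainable at any $n$ and errors naming the pair.
* **Proportions input.** Published prevalences may be supplied instead of
  counts (with a nominal $n$); count-based quantities then use
  $\mathrm{round}(p_k n)$ and a warning is raised once. Printed rounding
  is tolerated up to 0.005 in $\sum p_k$.
* **Mitigations.** `merge_categories()` collapses categories (summing
  counts) and *invalidates* pairwise evidence touching a merged category —
  merging changes the one-vs-one models, so stale $R^2$ values are never
  silently reused. Per-pair `S_overrides` relax the shrinkage target for
  named pairs only; relaxing a pair never increases any requirement and
  strictly decreases the relaxed pair's.
* **Interface.** `mnl_sample_size()` is the programmatic entry point;
  `run_sizing()` drives it from a schema-validated YAML/JSON config
  (unknown keys rejected before any computation), `render_report()`
  produces the text or lossless-JSON view, and a thin Rscript wrapper
  lives in `inst/cli/`. All randomness (only the C-statistic route) hangs
  off one seed, with per-pair sub-seeds derived deterministically, so a
  config plus seed reproduces byte-identical JSON.

## The validation harness: what it simulates and what it shows

`run_shrinkage_experiment()` is the package's empirical check that
criterion (i) achieves what it promises. The data-generating process is a
multinomial logistic model with $Q$ independent standard-normal
covariates; intercepts are calibrated to hit target category proportions
(closed form when all coefficients are zero, otherwise a deterministic
marginal-matching iteration on a fixed calibration sample). The experiment

1. estimates "true" pairwise $R^2$ values from a single large pilot sample
   (one-vs-one fits; no analytic form exists for this quantity under a
   softmax DGP),
2. sizes the development set with criterion (i),
3. repeatedly develops a model at that size (`nnet::multinom`, tight
   tolerances) and estimates on an independent validation sample
   100$\times$ larger:
   * $S_{MN,k,r}$ — recalibration slopes of the multinomial sub-models
     under *every* reference category $r$: the $2(K-1)$-parameter model
     $\ln[P(Y=k)/P(Y=r)] = \alpha_k + S_k\,LP_k$ (each slope multiplying
     only its own developed linear predictor), maximized by BFGS with an
     analytic gradient — the recalibration likelihood is concave;
   * $S_{DL,k,r}$ — two-parameter logistic calibration slopes on the pair
     subsets;
   * the heuristic $S_{VH}$ from the development fit's LR.

Replicates flagged for separation (diverging coefficients) or
non-convergence are excluded and counted, never redrawn — redrawing would
bias the shrinkage summaries toward easy samples. All replicate seeds
derive from one master seed.

The default design used in the acceptance experiment is $K=3$, $Q=5$,
target proportions $(0.5, 0.3, 0.2)$, coefficient columns
$(0.6,0.5,0.4,0.3,0.2)$ and $(-0.4,0.4,-0.5,0.5,0.3)$ — chosen once to
give pairwise C-statistics of about 0.73–0.81, i.e. the moderate
discrimination typical of clinical models, and a criterion (i)
development size of roughly 420. At that size, over 200 replicates, the
median $S_{MN,k,r}$ lies within $0.9 \pm 0.05$ for every sub-model and
reference, and the median $|S_{DL}-S_{MN}|$ per pair stays below 0.05 —
the convergence of the two shrinkage notions that the criterion relies
on. Problem sizes in the routine tests (pilot $10^6$; validation sets of
$10^5$–$10^6$ for the truth-recovery checks, $2\times10^5$ for the
parametric-equivalence check) were picked as the package's own accuracy /
runtime trade-off; the tolerances quoted in the tests are matched to the
Monte-Carlo error at those sizes.

What passing does **not** show: the generator draws independent Gaussian
covariates with linear effects and no model misspecification, so the
experiment validates the sizing logic, not robustness to skewed or
correlated predictors, omitted non-linearities, or measurement error.
Real applications also hinge on the *quality* of the anticipated pairwise
$R^2$ values — optimistic inputs yield undersized studies regardless of
the formulas. The criteria target expected behaviour; individual
developments at the computed $n$ still vary around the target slope.

## Known limitations

* Anticipated $R^2$ can only be derived from Nagelkerke's statistic or a
  C-statistic; other pseudo-$R^2$ measures are out of scope.
* $Q$ is common to all sub-models; reducing $Q$ only in overfit-prone
  sub-models is attractive but its implications are not established, so it
  is deliberately not offered.
* No criterion for mean absolute prediction error, ordinal outcome
  structure, or external-validation sizing.
* The C-statistic conversion inherits its within-group-normal linear
  predictor assumption; strong departures (e.g. highly skewed predictor
  distributions) shift the implied $R^2$.
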