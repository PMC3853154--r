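---
title: "Boosting the concordance index: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosting the concordance index: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciboost)
```

## The estimation problem

For right-censored data $(t_i, \delta_i, x_i)$, $i = 1,\dots,n$ — observed
follow-up time, event indicator, covariates — ranking quality is measured on
the set $\mathcal{P}$ of *validly orderable* pairs: $(i, j) \in \mathcal{P}$
iff $\delta_i = 1$ and $t_i < t_j$ (strictly). A censored subject carries
ranking information only as the later member of a pair, and tied times are
excluded outright, because neither order can be asserted. With scores $F$
oriented as predicted survival time,

$$\mathrm{CI}(F) \;=\; \frac{1}{|\mathcal{P}|}
  \sum_{(i,j)\in\mathcal{P}} \mathbf{1}\{F(x_i) < F(x_j)\}.$$

`ciboost` maximizes this quantity directly through its differentiable
surrogate, the smoothed concordance index

$$\mathrm{SCI}_\alpha(F) \;=\; \frac{1}{|\mathcal{P}|}
  \sum_{(i,j)\in\mathcal{P}}
  \frac{1}{1 + e^{\alpha (F(x_i) - F(x_j))}},$$

which lies strictly in $(0,1)$, converges to the strict-indicator CI as
$\alpha \to \infty$ (absent tied scores) and flattens to $1/2$ as
$\alpha \to 0^+$. Its per-subject gradient is a signed sum of
$e^{\alpha d}/(1+e^{\alpha d})^2$ terms over the pairs containing that
subject, scaled by $\alpha/|\mathcal{P}|$; components sum to zero and
$|g_i| \le \alpha d_i / (4|\mathcal{P}|)$ with $d_i$ the subject's pair
degree, so both objective and gradient are bounded — one reason the
procedure tolerates an undamped step size (see below).

## The boosting loop

`fit_gbmci()` builds $F_m = F_{m-1} + \nu\,\rho_m f_m$ stage-wise:

1. **Initialization.** $F_0$ is the risk-score prediction
   $-\hat\theta^\top x$ of an internal linear Cox fit. SCI is neither convex
   nor concave, so the start point matters; a linear fit is a cheap,
   usually-sensible basin. If that fit is non-identifiable the start falls
   back to zero with a warning.
2. **Subsample.** A fraction `bag_fraction` of subjects is drawn *without
   replacement* (the stochastic-gradient-boosting convention; a bootstrap
   would duplicate subjects and manufacture tied times).
3. **Pseudo-response.** The SCI ascent gradient is evaluated over the pairs
   *internal to the subsample* — the stage's pseudo-responses exist only for
   the drawn subjects, and pairs that cross the bag boundary belong to no
   stage.
4. **Base learner.** A least-squares CART tree (depth `depth`, leaf minimum
   `min_obs`) is fitted to the gradient values.
5. **Stage weight.** $\rho_m$ maximizes the *full-data* SCI of
   $F_{m-1} + \rho f_m$ over $[0, \rho_{\max}]$. Searching the full data —
   even when the tree was fitted on a bag — preserves a guarantee: since
   $\rho = 0$ is always a candidate, full-bag training can never decrease
   the training objective.
6. **Update.** $F_m = F_{m-1} + \nu \rho_m f_m$ on all subjects; the
   full-data SCI is logged.

`fit_gbmcox()` shares the identical loop but minimizes the Breslow negative
log partial likelihood on the log-relative-hazard scale: stages fit the
martingale-type residual $\delta_i - e^{F_i} \hat\Lambda(t_i)$, terminal
nodes are refitted by one Newton step of the node-restricted objective
(denominators below $10^{-12}$ snap the node value to 0), $\rho_m \equiv 1$,
and predictions are negated back to the common survival-time orientation.

### Tunable parameters

| parameter | default | why |
|---|---|---|
| `alpha` | 1 | Sigmoid steepness (dimensionless, acts on score differences). Larger tracks CI more tightly but concentrates gradient mass on near-ties; 1 balances approximation against stability, and nearby values behave similarly. |
| `n_trees` | 1500 | Stage budget; the effective size is chosen by CV. |
| `depth` | 6 | Interaction depth of each tree. |
| `min_obs` | 10 | Minimum subjects per leaf; guards leaf means against noise. |
| `shrinkage` | 1 (sci), 0.002 (coxph) | For the SCI objective the bounded line-search range already damps stages (a local $\rho^*$ on $[0,100]$ rarely saturates the surrogate), so no extra shrinkage is applied; the partial-likelihood objective has unbounded Newton leaf values and needs a small $\nu$. |
| `bag_fraction` | 1 | Per-stage subsample fraction; 0.5 is the usual stochastic setting. |
| `rho_max` | 100 | Upper end of the stage-weight search; the lower end is pinned at 0 so "no move" is always searchable. |
| `cv_folds` | 5 | Folds for selecting the ensemble size; 0 disables. |

### The line search, numerically

The SCI profile along a stage direction is a sum of monotone sigmoids in
$\rho$ — smooth but potentially multimodal — so the search is a 201-point
uniform grid scan over $[0, \rho_{\max}]$ followed by Brent refinement
inside the best grid cell. Two implementation points matter:

* **Saturation.** Once scores separate well, $\mathrm{SCI}$ rounds to 1.0 in
  double precision and can no longer rank candidates. The scan therefore
  minimizes the *deficit* $1 - \mathrm{SCI}$ accumulated directly as a sum
  of sigmoid complements, which keeps resolving differences down to
  $e^{-745}$. Ties that survive even this (a zero direction) resolve to the
  smallest $\rho$.
* **Cost.** On the uniform grid the pairwise exponent advances by a constant
  per step, so $e^{z}$ follows a multiplicative recurrence: two `exp` calls
  per pair instead of one per grid point, with pairs saturated across the
  whole interval folded into a constant. Direct evaluation is used whenever
  the recurrence could over/underflow ($|z| > 700$) or the grid is
  non-uniform; agreement with naive evaluation is at the $10^{-15}$ level.

All sigmoids go through a branch that never exponentiates a positive large
argument, so $|\alpha\,\Delta|$ up to $10^4$ and beyond evaluates finitely
(saturating cleanly to 0 or 1 at the representable limit).

### Cross-validated size selection

`select_stages_cv()` partitions subjects into seeded folds, trains each fold
to `n_trees` stages, and records held-out CI after every stage; the selected
size is the argmax of the fold-averaged curve (ties to the smallest size).
Held-out concordance — not the training objective — is the selection metric,
since ranking is what the model is for. Fold $f$ runs with seed
`seed + f`, so any fold's curve is reproducible by a standalone refit; folds
whose validation part has no comparable pairs are dropped with a warning.

## The Cox baseline

`fit_coxph()` minimizes the Breslow negative log partial likelihood by
Newton–Raphson with step-halving, so the objective path is non-increasing by
construction; iteration stops when the decrease falls below `tol`
($10^{-8}$, `max_iter` 50). Breslow's tie handling (tied events share the
inclusive risk-set denominator) is the simplest construction consistent with
the risk-set sum and is also what the boosted partial-likelihood gradient
uses, keeping baseline and comparator consistent. Zero-variance covariates
are excluded from the update, a singular information matrix or diverging
coefficients ($\|\theta\|_\infty > 10^3$) stop iteration, and all three
cases yield a `converged = FALSE` fit rather than an error — the boosting
initializer then degrades gracefully to a zero start. No baseline hazard is
estimated: ranking needs only the linear predictor.

## What the simulators emulate — and what they do not

`simulate_ph()` draws standard-normal covariates, exponential event times
with rate $\lambda_0 e^{x^\top\beta}$, and independent exponential censoring
whose rate is calibrated by solving
$\mathrm{mean}_i\,[r_c / (r_c + r_i)] = c$ over the cohort's realized
subject hazards $r_i$ (the exponential-race closed form, exact conditional
on the drawn covariates; solved by `uniroot` to $10^{-12}$).
`simulate_nonlinear()` replaces the linear log-hazard with
$x_1 x_2 + \sin(\pi x_3)$ — an interaction plus a non-monotone effect,
deliberately orthogonal to any linear score (for standard-normal $x$,
$\mathrm{cor}(x_3, \sin \pi x_3)$ is nearly zero), so a linear PH fit ranks
near chance while trees can learn the structure. Both return the oracle
ranking `true_scores` $= -\log$ relative hazard.

The generators emulate the *statistical structure* the models assume —
multiplicative or non-multiplicative hazards with independent,
non-informative right censoring — and nothing else. Real cohorts bring
correlated and heavy-tailed covariates, non-exponential baselines,
informative censoring, tied recording of times, and $p \gg n$ feature
spaces; a passing suite here shows the algorithms are implemented correctly
and behave as designed under their own assumptions, not that they will win
on any particular clinical dataset.

## Degenerate inputs and tie-breaks

* Tied observed times: excluded from $\mathcal{P}$ (strict inequality).
  Tied *scores*: counted as failures under the default `strict` policy;
  `half` (0.5 credit, Harrell's convention) is available on
  `concordance_index()` for interoperability.
* Tree splits: candidates are midpoints between consecutive distinct sorted
  values; equal-error splits resolve to the lowest feature index, then the
  lowest threshold, making fits invariant to row order. A split must reduce
  the node SSE by more than a relative $10^{-12}$ floor, so constant or
  symmetric targets yield a single leaf rather than a noise-driven split.
* A subsample with no internal comparable pairs (or no events, for the
  partial-likelihood objective) is redrawn once, then the stage is skipped
  with a warning; a run in which every stage skips is an error.
* All simulation, bagging, and fold randomness is scoped: functions take a
  `seed`, restore the caller's RNG state, and identical inputs reproduce
  models bit-for-bit. Model JSON stores doubles at 17 significant digits,
  which round-trips IEEE doubles exactly.

## Problem sizes

The shipped tests and `scripts/acceptance.R` run cohorts of 120–500 subjects
(2000 for coefficient recovery), trees of depth 1–2, and 5–300 stages, with
5–10 replicate seeds for the comparative benchmarks; these sizes give stable
medians for the effects being measured while keeping the full suite fast
enough to run habitually. The implementation itself is sized for desk-scale
cohorts (thousands of subjects): pair sums are exact over the explicit pair
set, $O(|\mathcal{P}|)$ per evaluation, with no approximate or bucketed
variant.

## Known limitations

* Exact pair enumeration is quadratic in cohort size; very large cohorts
  would need a bucketed or sorted-sweep variant that this package
  deliberately omits.
* The SCI surface is non-concave: different seeds or initializations can
  reach different local optima. The Cox warm start and bounded line search
  are pragmatic, not optimal, choices.
* No missing-data handling, factor encoding, time-varying covariates, left
  truncation, or interval censoring; covariates must be numeric and
  complete.
* Concordance weighting is Harrell-style; inverse-probability-of-censoring
  (Uno) weighting and time-dependent AUC are out of scope.
* Training is single-threaded; stages are sequential by construction, and
  the per-stage pair sums, though parallelizable, are not parallelized.
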