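---
title: "Mixture design and response modeling for LNP formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture design and response modeling for LNP formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixformula)
```

## The problem

A lipid nanoparticle (LNP) formulation is a mixture: the four lipids —
ionizable lipid (SM-102), helper phospholipid (DSPC), cholesterol and
PEG-lipid (DMG-PEG2000) — are specified as molar fractions that sum to 1.
Changing one component necessarily changes the others, so factorial designs
and ordinary polynomial regression are the wrong tools: a four-factor,
four-level factorial would need `full_factorial_size(c(4, 4, 4, 4))` = 256
runs, and an intercept plus main effects would be aliased with the mixture
constraint. `mixformula` implements the standard mixture-experiment
workflow for this setting: optimal design on a bounded simplex, Scheffé
canonical polynomial models on power-transformed responses, BIC-based term
selection, adequacy screening, and multi-response desirability
optimization.

The built-in reference system is a Spikevax-type mRNA-LNP design space
(`lnp_bounds()`): DSPC 5–40%, SM-102 15–65%, cholesterol 15–65%,
DMG-PEG2000 1–10%. The packaged `builtin_design()` has 15 modeling runs
plus one hold-out composition ("MS", 10/50/38.5/1.5%) flagged
`is_validation` and excluded from every fit. The modeled responses are
encapsulation efficiency (%, the fraction of mRNA entrapped), particle
diameter (nm), and nMFI (median fluorescence intensity of transfected
cells normalized to the negative control, `normalize_mfi()`).

## Design construction

The feasible region is the intersection of the simplex with per-component
box bounds. Candidate points are the classical exchange geometry: extreme
vertices (each obtained by fixing all but one component at a bound
combination and solving the remaining "fill" component), edge centroids,
the overall centroid, and uniform interior points drawn by rejection from
the unconstrained simplex (`build_candidate_set()`). Rejection sampling is
exact but can starve on very tight bounds; the sampler fails loudly below
an acceptance rate of 1e-4 rather than silently biasing the region.

Two criteria are supported, both minimized (`design_criterion()`):

* **I-optimality**: the average prediction variance
  $\mathrm{tr}\{(X^\top X)^{-1} M\}$, where
  $M = \mathbb{E}[f(x)f(x)^\top]$ is the region moment matrix, estimated
  by Monte Carlo over uniform feasible points (`moment_matrix()`). The
  default Monte-Carlo size of 10^4 estimates the q = 2 closed-form moments
  to well under 2%; tests use 10^5 where the comparison is against
  analytic values.
* **D-optimality**: $-\log\det(X^\top X)$.

`exchange_design()` is a Fedorov-style point exchange: from each random
start, every design point is tested against every candidate and the best
improving swap is accepted until relative improvement falls below 1e-8.
Ties between equal swaps resolve to the lowest candidate index, so results
are reproducible given the seed. On candidate sets small enough to
enumerate, the exchange attains the brute-force optimum; at the reference
problem size (15 runs, 10-term quadratic) it beats essentially all random
15-run candidate subsets on the I-criterion. Point-for-point agreement
with any particular commercial design is *not* a goal — designs are judged
by criterion value and feasibility, and the packaged 15-run design is
shipped as data for the downstream stages.

`ratio_series()` covers the follow-up design pattern where optimization
fixes some components (SM-102 at 0.65, DMG-PEG2000 at 0.01) and the
remainder is split between DSPC and cholesterol at prescribed ratios
(5.8, 2.4, 1.27, 0.36, 0.13): with remainder $r$ and ratio $\rho$, the
pair receives $r\rho/(1+\rho)$ and $r/(1+\rho)$.

## Response models

Models are Scheffé canonical polynomials: no intercept, linear blending
terms $x_i$ and binary blending terms $x_i x_j$ (`scheffe_spec()`,
`scheffe_matrix()`). Because $\sum_i x_i = 1$, the full linear set spans
the constant; this motivates two conventions used throughout:

* $R^2$ statistics use the **mean-corrected** total sum of squares even
  though the model matrix has no intercept column — the linear terms
  already contain the constant, so the corrected definition is the
  meaningful one.
* All four linear terms are **mandatory** during model selection
  (mixture hierarchy); only interaction terms compete.

Responses are modeled on a plain power scale $t = y^\lambda$
(`power_transform()`; natural log at $\lambda = 0$). The exponent is
chosen by a Box–Cox profile scan (`boxcox_scan()`) using the
geometric-mean-normalized transform
$z(\lambda) = (y^\lambda - 1)/(\lambda g^{\lambda-1})$, whose constant
Jacobian makes profile log-likelihoods comparable across $\lambda$; the
~95% interval collects grid points within $\chi^2_{1,0.95}/2$ of the
maximum, and `choose_convenient_lambda()` rounds to the conventional
exponents $\{-2, -1.5, -1, -0.5, 0, 0.5, 1, 2\}$ inside the interval.
Model *fitting* then uses the plain power $y^\lambda$, matching how such
equations are conventionally reported; the normalized form appears only
inside the likelihood. Responses must be strictly positive wherever
$\lambda \le 0$ or fractional — zeros are rejected, not offset, to avoid
silent bias. Note that for $\lambda < 0$ the transform is decreasing:
*smaller* transformed values mean *larger* raw responses, which is why
optimization (below) always works on back-transformed raw-scale
predictions.

`fit_scheffe()` is ordinary least squares on the transformed scale with
validation rows excluded. `fit_statistics()` computes the conventional
response-surface summaries: residual SD, CV%, $R^2$, adjusted $R^2$,
PRESS via the leave-one-out shortcut $\sum(e_i/(1-h_{ii}))^2$ (verified in
the tests against explicit LOO refits), predicted
$R^2 = 1 - \mathrm{PRESS}/\mathrm{SST}$, and adequate precision
$(\max\hat{y} - \min\hat{y})/\sqrt{p\,\mathrm{MSE}/n}$ — the signal range
against the average prediction noise at the design points. The formula for
adequate precision is not universally standardized; this package uses the
definition above, stated explicitly so reported values are interpretable.
`adequacy_check()` applies the two conventional screens: adjusted minus
predicted $R^2$ below 0.2, adequate precision above 4.

## Term selection

`sequential_ss()` produces the type-I (sequential) ANOVA decomposition,
starting from the intercept-only model so the increments plus the residual
telescope exactly to the corrected SST; F-tests against the final MSE are
descriptive only (the entry-order screen's $\alpha$ affects ordering, not
selection). Selection itself is by BIC in its Gaussian profile form
$n\ln(\mathrm{SSE}/n) + k\ln n$ (`bic_score()`), via forward selection
from the mandatory terms and backward elimination from the full candidate
model (`forward_select()`, `backward_eliminate()`); when both run,
`stepwise_select()` keeps the lower-BIC result, exact ties favoring fewer
terms. `exhaustive_best_subset()` enumerates all hierarchy-valid subsets
as the reference the greedy searches are measured against. A residual sum
of squares below 1e-16 of the response's sum of squares is treated as an
exact fit (BIC $-\infty$), so that on noiseless data parsimony alone
decides among exactly-fitting subsets — without this, float-level residual
noise (~1e-28) would dominate the comparison.

Two honest caveats from simulation at the built-in noise levels, n = 15:
a null interaction term is added with probability
$P\{F(1,10) > 10(15^{1/15}-1)\} \approx 0.19$, so with six candidate
interactions the selected model contains at least one spurious term in
roughly two-thirds of null datasets; and exact recovery of a generating
term set by backward elimination is rare (the truly active interaction is
retained in a majority of refits, but spurious companions are common).
Fifteen runs buy prediction, not certain structure recovery — the tests
encode exactly these computed rates rather than optimistic ones.

## Desirability optimization

Each response gets a Derringer–Suich goal (`goal()`): maximize, minimize,
target, or in-range, with ramp exponent `weight` and integer `importance`
1–5. Per-goal desirabilities combine as the importance-weighted geometric
mean $D = (\prod d_i^{r_i})^{1/\sum r_i}$, so any fully unmet goal zeroes
$D$. The default analysis mirrors the reference study's objective
structure: encapsulation efficiency maximized from 40% toward 95% with
weight 2 (rewarding high values disproportionately) and importance 3, nMFI
maximized with importance 5; the diameter model is excluded from the
default objective because its predictions cluster too narrowly to
discriminate candidates, though it remains selectable. These defaults are
package choices — the exact weights used in the original analysis are not
published — and every one is a `goal()` argument.

`optimize_formulation()` evaluates desirability on raw-scale predictions,
seeds from the candidate geometry of the free components' rescaled
sub-simplex, refines the best seeds by Nelder–Mead (golden-section when
only two components are free), and repairs every iterate onto
$\{\sum s_i = 1,\ l_i \le s_i \le u_i\}$ by exact bisection on a common
shift, so returned candidates are feasible to 1e-9 rather than merely
penalized. Seeds themselves stay in the ranked pool, so the reported
optimum never falls below the best seed. `rank_candidates()` re-ranks by
any predicted response (e.g. highest predicted nMFI first), with ties
broken by overall desirability.

## Synthetic data: what it does and does not emulate

`simulate_responses()` generates response tables at any design from the
built-in (or user-supplied) ground-truth models: Gaussian noise with the
model's residual SD **on the transformed scale**, back-transformed to raw
units. Noise on the transformed scale is exactly the structure the fitted
models assume, which is what makes the generator a fair test-bed for the
estimators. Draws outside the valid window (encapsulation outside
(0, 100]; non-positive diameter, nMFI, or transformed values under a
negative exponent) are redrawn, so marginals are truncated normals; redraw
counts are recorded in the `"redraws"` attribute. At the built-in noise
levels truncation touches roughly 3% of encapsulation draws (fitted values
reach ~88% against the 100% cap) and essentially none elsewhere. Fixed
seeds give bit-identical tables.

What passing tests on this generator show: the estimators, statistics,
selection and optimization behave correctly under the assumed error model
at the study's size (single response value per run, n = 15). What they do
not show: robustness to replicate-level measurement error (flow-cytometry
and DLS noise are not Gaussian on these scales), storage-time drift,
between-batch variability, or model misspecification — real formulation
data carry all four. `n_rep` exposes replicate generation so both
single-value and replicate-mean workflows can be exercised.

## Numerical choices and degenerate inputs

* Row sums are classified as percent (~100) or proportion (~1) with a hard
  1% gate; inconsistent files are rejected by run id rather than guessed
  at (`read_design()`).
* Exchange convergence: relative improvement below 1e-8; singular
  candidate swaps score $+\infty$ rather than erroring mid-search; designs
  with fewer runs than terms error as under-determined.
* Leverage of exactly 1 makes PRESS undefined: flagged with a classed
  warning, other statistics still returned. Zero MSE reports adequate
  precision as $+\infty$.
* Problem sizes in the test suite: Monte-Carlo moment matrices at 10^4–10^5
  points, 200-seed transform-coverage and 200–500-seed refit simulations,
  100-instance selection-vs-oracle sweeps, 1000 random subsets against the
  exchange design — chosen so each estimate's Monte-Carlo error is small
  against the property being asserted.

## Known limitations

* No blocking, split-plot or mixture-process designs; no replicate/lack-of-
  fit augmentation heuristics.
* Selection is BIC-only by design (no AICc, cross-validation or
  shrinkage); sequential-SS p-values carry no multiplicity correction.
* The optimizer returns ranked local optima from a multistart, not a
  certified global optimum or Pareto front; on the toy problems where a
  dense grid is feasible it matches the grid to 1e-3 in desirability.
* One printed statistic of the reference analysis is reproduced as
  tabulated rather than as in its text, which prints a different
  $R^2$ for the diameter model (0.8172 vs the tabulated 0.8127); the
  package fixtures follow the table.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
design <- builtin_design()
responses <- simulate_responses(design, seed = 1)

# transform choice, fit, adequacy
X <- scheffe_matrix(design$x[!design$is_validation, ],
                    scheffe_spec(4, "linear", lnp_bounds()$names))
scan <- boxcox_scan(responses$nmfi[!design$is_validation], X)
lambda <- choose_convenient_lambda(scan)

sel <- stepwise_select(design, responses$nmfi,
                       candidate_terms = combn(4, 2, simplify = FALSE),
                       lambda = lambda)
fit <- fit_scheffe(design, responses$nmfi, sel$final_spec, lambda)
adequacy_check(fit_statistics(fit))

# hold-out check and optimization
holdout_validation(fit, mixture_design(design$x["MS", , drop = FALSE],
                                       run_ids = "MS"),
                   responses$nmfi[16])
res <- optimize_formulation(
  list(nmfi = fit),
  list(goal("nmfi", "maximize", low = 1, target = 3, importance = 5)),
  lnp_bounds(), fixed = c("SM-102" = 0.65, "DMG-PEG2000" = 0.01),
  seed = 1)
rank_candidates(res, "nmfi")
```
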