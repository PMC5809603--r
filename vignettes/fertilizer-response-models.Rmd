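---
title: "Fertilizer dose-response models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fertilizer dose-response models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertresp)
```

## The problem

A single-nutrient fertilizer trial measures mean grain yield $Y$ (kg/hm²) at
an ordered series of application rates $X$ (kg/hm²) of N, P₂O₅ or K₂O. Two
questions drive the analysis: which curve describes the dose-response, and
what rate should be recommended — the *agronomic maximum* $X_{max}$ that
maximizes yield, or the *economic optimum* $X_{eco}$ at which the marginal
yield equals the nutrient/product price ratio.

The classical tool is the quadratic polynomial model (QPFM)

$$Y = b_0 + b_1 X + b_2 X^2,$$

whose differential $dY/dX = b_1 + 2b_2X$ assumes the yield gain per kg of
nutrient falls *linearly* with the rate, symmetrically around the maximum.
Field data from modern high-yield, fertilizer-tolerant varieties often
contradict both assumptions: plotting the empirical marginal yield
$\Delta Y/\Delta X$ against the rate shows a fast early decline that
flattens at high rates — an exponential, not linear, shape. Quadratic fits
then turn "non-typical" (wrong coefficient signs, or maxima outside the
tested range) and over-recommend fertilizer because the parabola is flat
near its top.

## The non-structural response model

Writing $s_0$ for the indigenous soil nutrient supply expressed in
fertilizer-equivalent kg/hm² (so the total supply is $s_0 + X$), modifying
the linear marginal assumption by an exponential damping factor and
integrating gives the non-structural fertilizer response model (NSFM)

$$Y = A\,(s_0 + X)\,e^{-cX},$$

with marginal yield

$$\frac{dY}{dX} = A\,[1 - c(s_0 + X)]\,e^{-cX}.$$

The integration constant is fixed at zero because yield must vanish when
both the soil supply and the applied rate are zero. The three parameters
have direct agronomic meaning:

| parameter | units | meaning | plausible range (grain crops) |
|---|---|---|---|
| $A$ | kg yield per kg nutrient supply | soil-fertility-to-yield conversion; $A s_0$ is the unfertilized yield | 20–110 |
| $c$ | hm²/kg | yield-response (damping) coefficient | 0.002–0.008 |
| $s_0$ | kg/hm² | soil nutrient supply equivalent | 15–190 |

First-order Taylor expansion of $e^{-cX}$ maps the NSFM onto
$Y = As_0 + A(1 - cs_0)X - AcX^2$, i.e. the QPFM is the truncation of the
NSFM (`taylor_expand()`); the models agree when $cX$ stays small and
diverge otherwise. The NSFM has a unique interior maximum at
$X_{max} = 1/c - s_0$, and the economic optimum solves

$$X_{eco} = \frac{1}{c + \beta/Y_{eco}} - s_0, \qquad \beta = P_x / P_y,$$

which is implicit because $Y_{eco} = Y(X_{eco})$. `recommend()` resolves it
by fixed-point iteration started at $Y_{max}$; the fixed point satisfies
$dY/dX = \beta$ exactly (this is asserted to $10^{-6}\beta$ in the test
suite, alongside a brute-force profit-grid oracle). Three to five
iterations suffice in practice; the defaults (`tol = 0.01` kg/hm², far
below agronomic relevance, and `max_iter = 50`) are pure safety margin.

## Estimation

**QPFM.** Ordinary least squares on regressors $(1, X, X^2)$ via the QR
decomposition in `stats::lm()` (never the normal equations).

**NSFM and the exponential marginal model.** Both curves are linear in two
parameters once $c$ is fixed: $Y = (p + qX)e^{-cX}$ with $(p,q) = (As_0, A)$
for the yield curve, and $dY/dX = (u - vX)e^{-cX}$ with
$(u,v) = (A(1-cs_0), Ac)$ for the marginal curve. Estimation is therefore
separable (variable projection): for each $c$ the two-column OLS on basis
$(e^{-cX}, Xe^{-cX})$ gives the profiled SSE, which is scanned on a
400-point log-spaced grid over `c_bounds = c(1e-5, 5e-2)` hm²/kg — an
interval covering the plausible $c$ range with more than a decade of margin
on each side — and refined by Brent's method *on* $\log c$ with interval
tolerance $10^{-10}$. The refinement scale matters: Brent on the raw $c$
axis with the default tolerance is coarser than a grid cell and can stop
0.5% short of the optimum; on the log scale the profile optimum matches a
full 3-parameter Gauss-Newton solution (the `nls()` oracle in the test
suite) to six significant digits.

This strategy is deterministic, needs no starting values, and is global
over the searched interval — properties a small-n, strongly correlated
3-parameter exponential fit does not enjoy under generic descent. Guard
rails: a profiled optimum with $A \le 0$ is rejected (for the marginal
model this means the series is not decaying); an optimum at the edge of
`c_bounds` raises a `c_at_bound` flag; a Taylor-seeded check
$c_0 = -2b_2/b_1$ from a quadratic pre-fit warns when the quadratic fit
suggests a $c$ outside the searched interval; $s_0 < 0$ (a possible
outcome on very fertile soils) is flagged, not rejected. Monotone-increasing
trials fit fine but put $X_{max}$ beyond the tested range — a matter for
the typicality diagnostics, not a fitting error.

**Fit statistics.** For every fit: $R^2 = 1 - SSE/SST$,
$S = \sqrt{SSE/(n-p)}$, and $F = \frac{R^2}{1-R^2}\cdot\frac{n-p}{p-1}$ on
$(p-1, n-p)$ degrees of freedom, starred at the 0.05 (\*) and 0.01 (\*\*)
quantiles of the F distribution. This F definition (regression vs residual
mean squares) is the unique one consistent with every (F, R², n) triple in
the reference tables bundled with the package, and $n-p$ is the verified
denominator of $S$ — with one systematic exception noted below.

## Marginal-yield analysis

`marginal_series()` forms the exact difference quotients
$(Y_{i+1}-Y_i)/(X_{i+1}-X_i)$ and assigns each to the **upper** endpoint
$X_{i+1}$ of its interval. The convention is not innocuous: for equally
spaced rates the fitted slope is assignment-invariant but the intercept
shifts by $b\,\Delta X/2$ per half-interval, and only the upper-endpoint
convention reproduces the reference intercept (23.966 for the 8-level N
trial; midpoint and lower-endpoint assignments land 9% and 19% away). The
unequally spaced wheat series use the actual interval widths. No smoothing
and no SD weighting: the quotients are modelled as they stand.

## Typicality of quadratic fits

`classify_typicality()` evaluates the four classical conditions:
$b_1 > 0$; $b_2 < 0$; the fitted maximum inside the tested range; and the
derived recommended rates (maximum, plus economic when prices are given)
inside the design range. "Within the output range" in condition (3) is
interpreted as the *rate* interval $[\min X, \max X]$ rather than the yield
interval, consistent with condition (4)'s reference to the fertilization
design; conditions (3) and (4) then coincide unless prices are supplied.
A fit failing any condition is non-typical: its recommendations are
reported but should not be trusted.

## Bundled data and their quirks

`builtin_trials()` ships three 8-level rice trials (Fujian province; N,
P₂O₅, K₂O; replicate SDs, 3 replicates) and nine 5-to-8-level winter-wheat
trials (northern China, 1980s), with the published coefficient tables for
all of them in `builtin_coefficients()` — including 15 further rice
experiments whose raw yields were never published, so that the
recommended-rate comparisons can be reproduced from coefficients alone.
Transcription notes, all discovered through internal-consistency checks
(the F–R² identity above, and the fact that the two models fitted to the
same data must imply one common SST):

* wheat trial 9 prints yield 14550 at 450 kg/hm² amid neighbours 1208 and
  1733; the fixture stores 1455 (the published fit predicts an unfertilized
  yield of ≈449, incompatible with 14550) and keeps the printed value as
  metadata;
* the published coefficients for wheat trials 4 (urea) and 9 (calcium
  superphosphate) were estimated on rates converted to nutrient basis
  (×0.46 kg N per kg urea, ×0.12 kg P₂O₅ per kg superphosphate). Refitting
  the product-basis rates gives identical statistics — the fit is invariant
  under $(A,c,s_0,X) \to (A/k, c/k, ks_0, kX)$ — and the published
  parameters after the scale map. The coefficient table carries the basis
  in its `rate_factor` column;
* the 5-level wheat trials print rates 34/68/101 that are rounded from the
  quarter-steps 33.75/67.5/101.25 used in the original fits, which puts the
  refitted quadratic coefficients ~1% off the published ones;
* the published residual SDs of the exponential *marginal* fits use
  denominator $n-2$ rather than $n-3$ (verifiable from the refit SSE), and
  the residual SD of the 8-level K₂O NSFM row fails the common-SST
  cross-check by an order of magnitude (a misprint; the refit gives 95.9
  against the printed 30.3). These entries are excluded, with this
  reasoning, from the consistency sweeps and the `reproduce` report.

One reproduction is knowingly out of reach: the published
recommended-rate correlations (0.9868 over the 16 starred rice
experiments, 0.979 over the 9 wheat experiments) cannot be recovered from
the published *rounded* coefficients, which yield 0.967 and 0.989. The gap
traces mainly to one K₂O experiment whose printed $(b_1, b_2)$ put its
quadratic maximum rate 57% above its non-structural one; every printed
cross-check on that row (the $As_0 \approx b_0$ identity, the Taylor
$b_1$ map) confirms the transcription, so the published correlations were
evidently computed from unrounded internal values. The package reports the
honestly recomputed correlations; the corresponding acceptance assertions
are left failing by design, and every qualitative claim they support (all
16 non-structural maxima below their quadratic counterparts; per-nutrient
rate ratios of 84–91%) does hold.

The economic-rate correlation reported alongside (0.9910) depends on a
price ratio that was never published; economic-rate behaviour is therefore
covered only by property-based tests (monotonicity in $\beta$, exact
collapse at $\beta = 0$, optimality against the profit grid).

## Simulation and estimator validation

`simulate_trial()` draws plot yields i.i.d. $N(A(s_0+X)e^{-cX},\,
\sigma^2)$ with `n_reps` replicates per rate and stores the treatment mean
and sample SD — the structure of the real trials. Defaults are the study
conditions of the bundled 8-level trials: `n_reps = 3` and
$\sigma = 150$ kg/hm², the middle of the observed replicate SDs (33–379).
What the generator does *not* emulate: block and spatial effects,
heteroscedasticity, skewness, and year-to-year variation — so recovery
results speak to estimator behaviour under the assumed noise model, not to
field-scale forecasting accuracy. Seeding is explicit everywhere (the
`simulate` CLI command refuses to run without one); `recovery_experiment()`
derives per-replicate seeds as `seed + i - 1` so runs are reproducible and
trivially parallelizable.

The recovery experiments in the test suite use 60 simulations per
condition (200 in the acceptance script), enough to verify the qualitative
contracts — zero bias and RMSE at zero noise, RMSE shrinking with the noise
level, and the 8-level design beating a 4-level design of equal span for
$X_{max}$ recovery — in a few seconds on one CPU.

## Known limitations

No standard errors or confidence intervals are attached to NSFM parameters
(none exist in the reference analyses to validate against; the recovery
machinery is the intended substitute). Fits are unweighted even when
replicate SDs are available. Multi-nutrient (binary/tertiary) response
surfaces are out of scope, as are soil-assay data beyond free-text
metadata.
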