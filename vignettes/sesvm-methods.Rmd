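---
title: "Methods: eco-efficiency, LS-SVR sensitivity evaluation, and the synthetic panel"
author: "sesvm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eco-efficiency, LS-SVR sensitivity evaluation, and the synthetic panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesvm)
```

## The problem

Regional panels of health-care demand — yearly visits to hospitals (VTH),
outpatient/emergency treatments (OWT) and inpatient counts (NOI) per region —
co-move with climate (temperature, humidity, precipitation, sunshine hours)
and with the environmental footprint of economic activity. `sesvm`
implements a pipeline that (i) condenses each region-year's resource use and
pollution into a single eco-efficiency score, (ii) learns a flexible
nonparametric mapping from climate, eco-efficiency and socio-economic
controls to each health outcome, and (iii) reads quantitative sensitivities
off the fitted mapping by perturbing one predictor at a time by 1%.

The intended user fits the pipeline to a region × year CSV panel; because
such yearbook panels are rarely redistributable, the package also ships a
synthetic generator whose ground-truth sensitivities are known analytically,
and every stage is validated against it.

## Eco-efficiency: the slacks-based measure with undesirable outputs

Each region-year is a decision-making unit (DMU) with inputs
$x \in \mathbb{R}^m_{>0}$ (labor, capital, energy), desirable outputs
$y^g \in \mathbb{R}^{s_g}_{>0}$ (production) and undesirable outputs
$y^b \in \mathbb{R}^{s_b}_{>0}$ (waste gas, wastewater, ...). The
non-oriented slacks-based measure (SBM) of efficiency scores DMU $o$ by

$$\rho_o \;=\; \min_{\lambda, s^-, s^g, s^b \ge 0}
  \frac{1 - \frac{1}{m}\sum_i s^-_i / x_{io}}
       {1 + \frac{1}{s_g+s_b}\Bigl(\sum_r s^g_r/y^g_{ro} + \sum_r s^b_r/y^b_{ro}\Bigr)}$$

subject to $x_o = X\lambda + s^-$, $y^g_o = Y^g\lambda - s^g$,
$y^b_o = Y^b\lambda + s^b$. Scores lie in $(0,1]$; $\rho=1$ iff the DMU sits
on the frontier with zero slacks; the measure is invariant to the units of
every column because all slacks are normalized by the DMU's own observed
values. The fractional program is linearized by the Charnes–Cooper
transformation (multiply through by $t = 1/\text{denominator}$) and solved
as one LP per DMU.

Design choices:

* **Returns to scale.** Constant returns (`rts = "crs"`) is the default;
  variable returns adds the convexity row $\sum\lambda = t$ and is never
  below the CRS score (a property test asserts this).
* **Pooled frontier.** All region-years form one reference set, so scores
  are comparable across years; this is the natural reading when
  eco-efficiency is later used as a single predictor column.
* **LP engine.** The package carries a small dense two-phase simplex with
  Bland's anti-cycling rule (`R/simplex.R`). The linearized SBM program is
  heavily degenerate — every constraint except the normalization row has a
  zero right-hand side — and Bland's rule guarantees termination there. The
  solver is unit-tested against textbook LPs, a basic-solution enumeration
  oracle on random programs, and (through the SBM layer) a vertex-enumeration
  oracle of the fractional program itself.
* **Tolerances.** Slacks below $10^{-9}$ (relative) are reported as zero and
  scores within $10^{-9}$ of 1 snap to 1, so "efficient" is an exact
  statement in the output.

## LS-SVR: closed-form kernel regression

The regression engine is least-squares support-vector regression with the
Gaussian kernel $K(x,x') = \exp(-\lVert x-x'\rVert^2/2\sigma^2)$. With
$\Omega_{ij} = K(x_i, x_j)$ and $A = \Omega + \gamma^{-1} I$ (positive
definite for every $\gamma > 0$), the dual solution is

$$b = \frac{\mathbf{1}^\top A^{-1} y}{\mathbf{1}^\top A^{-1}\mathbf{1}},
\qquad \alpha = A^{-1}(y - b\,\mathbf{1}),
\qquad \hat y(x) = \sum_i \alpha_i K(x, x_i) + b.$$

There is no iterative training: `lssvr()` does one Cholesky factorization of
$A$. Larger $\gamma$ means weaker regularization; as $\gamma \to \infty$ the
fit interpolates distinct training points. Tests check the closed form
against the $(m{+}1)$-dimensional KKT saddle system on 50 random instances,
and predictions against a hand-looped kernel expansion.

**Conditioning.** The interpolation limit is only numerically reachable when
the Gram matrix is well conditioned. Fifteen random points in $[0,1]^2$ under
$\sigma = 0.8$ give $\lambda_{\min}(\Omega) \approx 3\times10^{-8}$, so
$\gamma = 10^8$ cannot drive the in-sample error to zero in double
precision; with separated design points and a local kernel
($\sigma = 0.15$ on a $4\times4$ grid) the limit holds to $10^{-16}$. The
interpolation tests use the well-conditioned design for this reason, and
`lssvr()` raises a clear error if $A$ is numerically singular.

## Hyperparameter tuning: random direct search

`direct_search()` minimizes the in-sample objective
$G(\sigma,\gamma) = \frac1m \sum_j (y_j - \hat y(x_j;\sigma,\gamma))^2$ by a
derivative-free accept/reject walk: propose
$(\sigma + \lambda_\sigma, \gamma + \lambda_\gamma)$ with uniform random
steps, accept iff $G$ does not increase, stop when $G \le \varepsilon$ or
after $N$ iterations. Defaults: start $(1,1)$ (sensible for predictors
normalized to $[0,1]$), $\varepsilon = 10^{-6}$, $N = 500$.

Two step conventions are provided. The literal convention draws both steps
from $U(0,1)$, so the walk can only ever increase both parameters from their
start; it is kept as `step_mode = "literal"` for fidelity to the procedure
it reproduces. The default `step_mode = "signed"` draws from $U(-1,1)$ and
rejects candidates that leave the positive quadrant, which lets the walk
move in any direction. The accepted-$G$ sequence is monotone non-increasing
under both conventions, and the whole trace is reproducible from the RNG
seed.

**Known limitations, stated plainly.** (1) $G$ is an in-sample objective and
decreases monotonically in $\gamma$, so given unlimited reach the optimum is
always noise interpolation; comparing any tuner against a log-grid that
includes a large-$\gamma$/small-$\sigma$ corner is then a comparison against
overfitting, and the grid wins. The grid-competitiveness test therefore uses
an instance with duplicated covariate rows and differing outcomes, where the
objective has an irreducible floor (the within-duplicate variance) and
"competitive" is well-posed; at the default budget the search lands within a
factor 1.5 of the 20×20 log-grid minimum across all 50 seeds tried during
development (median ratio 1.15). (2) Additive unit-scale steps explore
$\gamma$ only up to roughly $N$, so the tuner cannot reach the
near-interpolation regime ($\gamma \gtrsim 10^4$); fits it selects are
smoother than the data allow, which *shrinks elasticity estimates toward
zero* on short series. A leave-one-out or log-scale extension would remove
this, but is deliberately not the default because the shipped procedure is
the object of study.

## Forecast evaluation: MPE, MSE, SDE, and the five settings

For a series $y_t$ with in-sample forecasts $\hat y_t$:

$$\mathrm{MPE} = \frac1T\sum_t \frac{y_t - \hat y_t}{y_t},\qquad
  \mathrm{MSE} = \frac1T\sum_t (y_t - \hat y_t)^2,\qquad
  \mathrm{SDE} = \sqrt{\mathrm{MSE}}.$$

MPE is signed by default (over- and under-prediction cancel; an absolute
variant is a flag). SDE is defined as the square root of the MSE — the
published worked triples (MSE, SDE) = (0.005300, 0.072800),
(0.004053, 0.063664), (0.003812, 0.061742) satisfy exactly this relation at
four significant figures, and the test suite pins all three.

`compare_models()` evaluates five predictor settings per outcome and region:
each single climate variable plus eco-efficiency plus the six controls
(8 predictors), and all four climate variables together (11 predictors).
Metrics are averaged over regions (the national aggregate is excluded from
averages when regions are present). The four-indicator setting is flagged as
the basic model for elasticity analysis: all four climate factors act at
once in reality, so the comprehensive setting is preferred over whichever
single-factor setting happens to minimize in-sample error.

**Scales.** Predictors are min-max normalized per series before fitting (fit
globally across the rows entering the fit; the affine state is retained for
exact inversion and for mapping perturbed raw values). The outcome is
modeled on its raw, strictly positive scale: min-max or z-scoring the
outcome would create zero or near-zero $y_t$ and break MPE's division. All
reported metrics are therefore in the outcome's own units.

## Elasticity analysis

For the fitted four-indicator model, the elasticity of predictor $j$ is the
mean relative prediction change under a one-at-a-time 1% increase:

$$E_j = \frac1m \sum_i
  \frac{\hat y(x_i \text{ with } x_{ij} \cdot 1.01) - \hat y(x_i)}{\hat y(x_i)},$$

a dimensionless fraction: $E_j = 0.01$ means a 1% predictor increase moves
the outcome by 1% on average. Design choices where the procedure was open:

* **Aggregation** over the yearly rows is the plain mean of relative
  changes (mean-of-absolute or last-year-only are easy variants but not
  defaults); the mean matches the "percentage points per 1%" reading.
* **Scale independence.** The 1% change is applied on the *raw* predictor
  scale and mapped through the stored normalizer; predictions are on the raw
  outcome scale. $E_j$ is therefore invariant to how the pipeline normalizes.
* **One-at-a-time**, matching the per-variable table columns; a joint
  perturbation is a diagnostic variant, not the default.
* A guard errors when any base prediction is within $10^{-8}$ of zero.

`elasticity_table()` assembles the national row plus one row per region,
each with its own tuned $(\sigma^*,\gamma^*)$, over the 11 predictors. The
national series aggregates outcomes by sum and predictors by mean within
year — an explicit convention, since nation-level aggregation is not
otherwise defined.

## The synthetic panel generator

`simulate_panel()` emulates a ~30-region × 15-year panel (defaults:
30 regions, 2002–2016):

* **Climate** series are region-specific means times an AR(1) fluctuation
  with relative amplitude `climate_volatility` (default 0.08), so climate
  varies visibly year-to-year.
* **Controls and eco-efficiency proxy** follow smooth regional growth
  trends with ~1% noise; the outcome therefore fluctuates much less than
  climate, and a property test asserts exactly that ordering.
* **Outcomes** are a chosen response family (constant, linear, log-linear,
  or a smooth curved surface) of the predictors plus additive Gaussian noise
  (default SD 50, about half a percent of the default outcome level),
  floored at a small positive constant so relative errors are always
  defined.
* **Ground truth**: the analytic elasticity of the noiseless response at
  the panel mean, $0.01\, \bar x_j\, \partial f/\partial x_j(\bar x)/f(\bar x)$
  — exactly $0.01\beta_j$ for the log-linear family and exactly $0.01$ for a
  proportional response. The evaluation point (the panel mean) matches the
  averaging used by the elasticity estimator.

`simulate_dea()` generates positive lognormal inputs/outputs per region-year
and *plants* the first DMU on the efficient frontier (componentwise better
than every other DMU), so tests can assert that the SBM stage flags a known
frontier point; an exhaustive pairwise-dominance oracle confirms the plant
is undominated.

What the generator does **not** emulate: spatial autocorrelation between
regions, serial correlation in outcome noise, structural breaks, and any
distributional detail of real provincial yearbooks. Passing tests on this
generator show the pipeline's internal correctness (recovery of known
sensitivities, metric definitions, determinism), not fidelity to any real
panel.

## Problem sizes and determinism

The test suite runs the full pipeline at its default scale — 30 regions ×
15 years, three outcomes, five settings, national + 30 elasticity rows —
with a 150-iteration search per series, twice, and asserts byte-identical
output files; smaller unit fixtures use 2–10 regions and 15–500 search
iterations. All randomness flows through R's RNG: seeding once makes every
stage, and the whole `run_pipeline()` output directory, exactly
reproducible.

## Known limitations

* In-sample tuning rewards interpolation; see the direct-search section.
  Elasticities from short (15-row) per-region series are conservatively
  shrunk toward zero.
* SBM scores from a pooled frontier shift when DMUs are added or removed;
  they are relative, not absolute, measures.
* MPE's signed mean can mask large but offsetting relative errors; consult
  MSE/SDE alongside it.
* The simplex solver is dense and sized for a few hundred DMUs per LP; very
  large frontiers would want a sparse LP engine.
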