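---
title: "Methods: screening, response surfaces and fermentation kinetics in fermkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, response surfaces and fermentation kinetics in fermkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

fermkin implements the complete statistical chain of a fermentation
medium-optimization study: two-level screening, second-order response-surface
modelling and optimization, and batch kinetics of biomass and product. This
vignette documents the models, the estimation choices, the tunable
parameters, and what the synthetic-data generators do and do not emulate.

## Coded variables

Every design analysis runs on the coded scale
$x = (\mathrm{real} - \mathrm{center})/\mathrm{halfwidth}$, so that the
design levels sit at $-1, 0, +1$ and the intercept of any fitted model is
the predicted response at the design center. `factor_spec()` stores the
mapping; `read_design_csv()` applies it when a table is stored in real
units (as screening tables usually are) and snaps float fuzz onto the
declared levels. Decoding is exact by construction, which the tests assert
as a round-trip property.

## Plackett–Burman screening

For a balanced two-level orthogonal design the main effect of a factor is
the high-minus-low contrast of response means; it equals twice the OLS
coefficient of the main-effects model, a property tested against `lm()` as
an independent oracle. Error is estimated from the dummy columns, which
carry no real variable: $SE = \sqrt{\sum_d E_d^2 / n_d}$ with $n_d$ degrees
of freedom, here $n_d = 3$. The packaged screening table quotes a
significance threshold of $t > 2.36462$, which is the two-sided 5% Student
quantile at 7 df — more df than three dummy columns can supply. We take the
dummy-based error (the method the design names) as the default and leave
`t_limit` user-settable, so the quoted Pareto threshold can be reproduced
verbatim when desired; a residual-based error model is also exposed since
the original software's choice cannot be determined. On this table the two
coincide because the dummies are the only unassigned columns.

## Second-order response surface

`fit_quadratic()` fits
$Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
\sum_{i<j} \beta_{ij} x_i x_j$ by OLS on the coded model matrix — 15
coefficients for four factors — and refuses rank-deficient designs by
naming the collinear columns. The packaged 29-run table is a four-factor
Box–Behnken layout (24 edge midpoints + 5 center replicates), although its
source labels it a central composite design; the fitter is agnostic to the
design family and `bbd_design()` generates the Box–Behnken matrix that the
printed coded rows actually follow.

`anova_quadratic()` reports partial (drop-one) sums of squares per term,
which on the near-orthogonal Box–Behnken equal sequential SS for linear and
interaction terms and the extra-SS-given-all-others for the quadratic
terms — the convention commercial DOE software reports. Pure error is the
within-group squared deviation over replicate groups (runs with identical
coded rows); lack of fit is the remainder of the residual. The identities
$SS_{model} + SS_{resid} = SS_{total}$ and
$SS_{lof} + SS_{pe} = SS_{resid}$ hold exactly by construction, as do the
degree-of-freedom sums. On the packaged enzyme-activity response this
reproduces the published model SS (≈49,078 within 0.05%, the discrepancy
being the two-decimal rounding of the printed table) and the published
lack-of-fit p of 0.089. The published per-term *F* statistics are *not*
reproducible from their own SS and MS values; fermkin computes *F* and *p*
consistently from its own decomposition rather than matching those entries.

One published summary could not be reconciled: the biomass model's quoted
$R^2$ of 0.9700. The OLS refit of the printed biomass column gives
$R^2 = 0.9897$, which *agrees* with the published ANOVA decomposition
(model SS 0.054 of total 0.055); we report the computed value.

`optimize_quadratic()` writes the surface as $Y = b_0 + g'x + x'Hx$
(with $H_{ii} = \beta_{ii}$, $H_{ij} = \beta_{ij}/2$) and returns the
stationary point $-\tfrac12 H^{-1} g$ when the Hessian has the right
definiteness and the point is inside the box — the situation for both
packaged responses, whose optima land at ≈267.85 U/mL and ≈0.521 OD600,
matching the verification culture within 0.4% relative error. Otherwise a
deterministic multi-start bounded search ($3^k$ grid of starts plus the
clipped stationary point, L-BFGS-B) finds the boundary optimum and flags
`on_boundary`; determinism of the start ordering makes results repeatable.

## Batch kinetics

Biomass follows the logistic model
$dX/dt = \mu_m X (1 - X/X_m)$ with closed form evaluated as
$X_m / (1 + ((X_m - X_0)/X_0)e^{-\mu_m t})$, which cannot overflow at
large $\mu_m t$. Product follows Luedeking–Piret,
$dP/dt = \alpha\,dX/dt + \beta X$, whose integral along the logistic
trajectory is
$P(t) = \alpha X(t) + (\beta X_m/\mu_m)\log\big((X_m - X_0 +
X_0 e^{\mu_m t})/X_m\big) + P_0$, the log term computed in log-space. As
printed this form has $P(0) = \alpha X_0$; since the initial product level
of a real broth is rarely stated, an additive $P_0$ (default 0) is exposed
as an escape hatch. Both closed forms are tested against their rate
equations by finite differences and against `deSolve` quadrature at
relative tolerance $10^{-6}$.

Estimation is two-stage by design: the growth parameters come from a
Levenberg–Marquardt fit (`minpack.lm::nlsLM`) initialized by the standard
logit linearization, and with growth fixed the product curve is *linear*
in $(\alpha, \beta)$, so those are solved by least squares — deterministic,
and immune to the local minima of a joint five-parameter fit. A joint fit
was considered and rejected as the reference path for exactly that reason.
A flat biomass trajectory makes $\alpha$ unidentifiable; the fit errors
rather than returning arbitrary coefficients. Because the logistic/LP pair
does not represent the decline phase (both biomass and product fall late in
a real batch, typically after ~62 h here), `fit_logistic()` and `fit_lp()`
take a `cutoff` argument to truncate the series first.

Gaden classification applies $|\cdot| \le$ `tol` to each coefficient
independently; the default `tol = 0.005` (native units) treats a
coefficient reported as 0.000 at three decimals as zero, which classifies
the packaged 10 °C condition as type I and every other condition as type
II. Both coefficients below tolerance means no production: `NA` with a
warning rather than a spurious type.

### Parameter meta-models

The nine packaged operating conditions form a one-factor-at-a-time layout
(each of stirring speed, temperature, inoculum varied alone around a
center), which cannot identify a full three-variable quadratic with
interactions: 10 terms, 9 points, and rank deficiency besides.
`fit_param_surface()` therefore requires an explicit term list, reports the
achieved rank, and refuses underdetermined systems unless
`allow_underdetermined = TRUE` explicitly requests a minimum-norm solution
(flagged non-unique). For this reason the package deliberately does not
reproduce any published meta-model coefficient set over these nine points;
the machinery is instead validated by exact recovery of declared sparse
polynomials on a full 3×3×3 factorial grid.

## Assay arithmetic

DNS enzyme activity is
$(A \cdot 640.5 + 13.99)\,V n/(v T)$ U/mL (one unit = 1 µg d-galactose
per minute); the standard-curve constants are overridable defaults because
they derive from a galactose calibration not shipped with the package. The
total reaction volume $V$ is always a required input — the incubation
protocol alone does not pin it down. Viscosity is the rotor line
$\eta = k\,\alpha_{reading}$.

## Synthetic data

`simulate_fermentation()` adds homoscedastic Gaussian noise to the logistic
and LP curves on a 0–72 h grid sampled every 4 h, the cadence of a typical
shake-flask batch; default noise sd 0.01 OD600 (biomass) and 3 U/mL
(product) are on the scale of replicate spreads of such assays.
`simulate_doe()` evaluates a declared quadratic at each coded run and adds
Gaussian noise; its default sd of 5.9 U/mL equals the center-point
replicate standard deviation of the packaged enzyme-activity table, so
simulated designs carry a realistic pure-error structure. A seed is
mandatory for any stochastic call and the generators restore the caller's
RNG state.

What the generators do **not** emulate: heteroscedastic assay error
(larger spread at high activity), decline-phase curvature, autocorrelated
within-batch drift, or viscosity-mediated interactions between medium
composition and growth. Passing round-trip tests therefore demonstrates
the estimators' correctness under the models' own assumptions, not
robustness to those real-data features.

## Problem sizes and numerical choices

The test suite and analysis scripts run the designs at their natural sizes
(12 screening runs, 29 surface runs, 19-point time series); Monte-Carlo
checks use 200 refits for the bias check and 1000 replicates for the
law-of-large-numbers check, sizes at which the sampling error of the check
is an order of magnitude below its tolerance. Replicate groups are
detected by exact coded-row equality; responses are never pre-averaged —
replicates enter the fit individually and are pooled only inside the
pure-error computation. Stationary points are accepted as interior when
inside the box by $10^{-10}$; boundary contact is flagged at $10^{-6}$.
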