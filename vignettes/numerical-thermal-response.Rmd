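---
title: "Numerical and thermal response inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical and thermal response inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protistNR)
```

## The inference problem

A numerical-response campaign measures the specific growth rate of a
phagotrophic protist across a gradient of food concentrations at a fixed
temperature: one well per food level, no replicates, growth estimated
from initial and final counts under the exponential assumption
$r = \ln(N_t/N_0)/t$. Spreading singleton wells across the gradient —
with extra coverage at low food, where the curve bends — identifies
nonlinear parameters better than replicating a few standard levels, which
is why the design the package simulates and fits has 24 singleton wells
per temperature.

The growth–food relation is the threshold numerical response

$$ r(P) \;=\; \frac{r_{\max}\,(P - P')}{k + (P - P')}, $$

with $r_{\max}$ the satiated growth rate (d$^{-1}$), $P'$ the threshold
food level at which growth is zero, and $k$ a curvature constant in prey
units. Evaluating the fitted curve at zero food gives the maximum
physiological mortality rate
$\delta_{\max} = -r_{\max} P'/(k - P')$ — the starvation decline rate,
reported negative (multiply by $-1$ to compare with growth rates).

Two prey metrics are supported and must not be mixed within a fit:
initial bacterial abundance (fitted in units of $10^6$ cells mL$^{-1}$,
which keeps the parameters near unit scale), and depletion-averaged
carbon biomass (mg C L$^{-1}$). Because carbon conversion is linear in
abundance for a fixed morphotype split, the two fits are exact
reparameterisations of each other when food does not change during the
incubation — and then yield identical $\delta_{\max}$; they diverge only
through real prey dynamics or differing morphotype composition.

## Mean prey and carbon conversion

The depletion-averaged food level over an incubation is
$(P_t - P_0)/\ln(P_t/P_0)$, the logarithmic mean of the endpoints; it
lies strictly between them and tends to $P_0$ as $P_t \to P_0$ (we switch
to the limit when $|\ln(P_t/P_0)| < 10^{-12}$). An alternative printed
form $(P_t - P_0)/\ln(P_t - P_0)$ circulates in parts of the literature;
it is dimensionally inconsistent and undefined for declining prey, so the
logarithmic mean is the default and the alternative is kept only behind
`mode = "literal"` for transparency, with the choice recorded in output.

Carbon conversion multiplies abundance by a morphotype-weighted
biovolume — defaults 0.14 µm³ (cocci) and 1.25 µm³ (rods) — and
200 fg C µm$^{-3}$. The cocci fraction is rarely reported per well, so it
is an explicit input defaulting to 0.5; since rods are ~9× the volume of
cocci, biomass is monotone decreasing in that fraction, and sensitivity
to it is worth checking when the split is unknown.

## Fitting and uncertainty

`fit_nr()` minimises the unweighted residual sum of squares with bounded
Levenberg–Marquardt (analytic Jacobian; `k > 0`, `P' ≥ 0`, since a
negative threshold is uninterpretable; tolerances $10^{-8}$ on parameters
and cost, at most $10^4$ evaluations). Starting values are
$r_{\max}^0 = \max r_i$, $P'^0$ = the largest food level with
non-positive growth (half the smallest food level if growth is positive
everywhere), and $k^0$ = half the food range — robust for gradient
designs dense at low food. Wells with negative growth are retained: they
are precisely what pins down the threshold. Non-convergence is flagged,
never silently replaced. Standard errors come from
$s^2 (J^\top J)^{-1}$ and coefficient tests are two-sided $t$ with
$n - 3$ df, matching standard NLS reporting.

$\delta_{\max}$ is a ratio of correlated estimates, so its interval is
propagated by Monte Carlo: $10^5$ parameter draws (equal-tailed interval,
fixed seed). Draws are multivariate **t** with $n-3$ df — normal draws
scaled by $\sqrt{\mathrm{df}/\chi^2_{\mathrm{df}}}$ — rather than plain
multivariate normal. The scaling accounts for the uncertainty of the
residual variance itself, which matters at $n = 24$: in the package's own
recovery experiment (500 simulated campaigns, Gaussian rate noise
$\sigma = 0.1$ d$^{-1}$), plain normal draws covered the true
$\delta_{\max}$ slightly below the nominal 95%, while the t-scaled draws
sit within a couple of points of nominal — the acceptance suite reruns
this check. Draws violating $k > P' \ge 0$ (where the zero-food
evaluation crosses its pole) are discarded; if more than half are
invalid the interval is flagged unreliable, and if all are invalid it is
reported as missing rather than fabricated.

One honest caveat: bounded NLS on 24-well campaigns is not unbiased. In
the recovery simulations the mean estimates of all three parameters sit a
modest fraction (≈0.2–0.3) of their sampling SD away from truth, a
finite-sample nonlinearity effect that shrinks in absolute terms with the
noise but not relative to the spread. Tests therefore check bias against
spread, not against the Monte-Carlo error of the mean.

## Thermal performance and traits

The Lactin-2 family
$\mathrm{rate}(T) = e^{aT} - e^{a\,t_{\max} - (t_{\max}-T)/\Delta} + b$
suits left-skewed curves with a sharp supraoptimal collapse. One naming
convention (`a`, `b`, `t_max`, `delta_t`) is fixed throughout to avoid
the $\rho/\lambda$ symbol drift across the literature; note `t_max` is a
curve parameter, not the critical limit. At $T = t_{\max}$ the two
exponentials cancel and the rate equals `b` exactly — a free algebraic
test point.

`fit_lactin2()` is multistart least squares: 25 uniform random starts
over $a \in [0.01, 0.3]$, $b \in [-2, 0]$,
$t_{\max} \in [\max T_i, \max T_i + 10]$, $\Delta \in [1, 10]$, keeping
the lowest converged RSS (ties resolved to the first best under the
seeded start order, so fits are seed-reproducible). With only four
distinct temperatures the likelihood has a genuine ridge: distinct
parameter vectors can attain the same RSS while agreeing on the curve
inside the data range and disagreeing in cold-end extrapolation. The
extracted warm-side traits are stable across the ridge; `CT_min` is not,
which is one more reason it is reported only when a sign change actually
brackets it.

Traits are extracted numerically: a 2000-point coarse grid over
$[-20, t_{\max} + 30]$ °C locates the optimum, refined by bounded scalar
maximisation; `CT_max` and `CT_min` come from sign-change bracketing and
bisection (to $10^{-6}$ °C) above and below the optimum, searching
outward from the optimum so the nearest crossing wins; each is undefined
— not an error — when the curve never crosses zero on that side, the
typical behaviour of shallow cold limbs that approach the axis only
asymptotically. If the rate at the optimum is not positive the trait set
is flagged degenerate. The machinery is validated against a closed-form
parabola oracle in the tests.

Which rates feed the TPC is a design choice. The satiating-rates rule
takes the measured rates at the 3–5 highest food levels per temperature;
the fitted-r_max rule takes the per-temperature NR estimates. For the
packaged reference reproduction the TPC is fitted to all eight published
r_max values (abundance- and biomass-based jointly) at 5/15/19/21 °C:
the reference analysis pooled both metrics, the 10 °C treatment is
excluded because its food levels never reached satiation, and the choice
is exposed as configuration rather than hard-coded.

## Mortality trend and ecological arithmetic

The temperature trend of $\delta_{\max}$ is ordinary least squares with a
two-sided $t$ test on the slope and a pointwise confidence band. Outlier
exclusions are input data, with mandatory reasons — no automatic rule
reproduces the reference study's two exclusions (one of its unflagged
fits has a weaker r_max significance than a flagged one), so pretending
to derive them would be false precision. The reproduction default pools
abundance- and biomass-based records (8 points after exclusions), the
only composition consistent with the published slope; the table reports
`n_used` so users can judge the pseudo-replication of using both metrics
of the same wells. The printed "± 0.06" on the reference median matches
no construction we checked (not the MAD, not $1.2533\,s/\sqrt{n}$) and is
deliberately not reproduced.

Scenario arithmetic is deliberately transparent: community grazing rate
= grazer density × clearance rate × $10^{-3}$; required grazer density
is its inverse at a given growth rate; starvation projections apply
$N_0 e^{rt}$. In the packaged reproduction the projection uses the
regression prediction rounded to the 2-dp precision at which the source
reports it, so the arithmetic chain matches the published one; litre
quantities are converted at the interface, never by changing the
package's internal per-mL units.

## What the generator does and does not emulate

`generate_campaign()` reproduces the reference design: treatments at 5,
10, 15, 19, 21 °C; 24 singleton wells per treatment; initial food drawn
from a biased log-spacing $P_0 = \mathrm{lo}\,(\mathrm{hi}/\mathrm{lo})^{u^{1.5}}$
(the exponent 1.5 concentrates wells at low food, echoing the design's
denser low-food coverage; any exponent > 1 biases low); inocula uniform
on 20–40 cells mL$^{-1}$ (the range most experiments used); 24-h
incubations; truth parameters defaulting to the published
abundance-based triples. Prey may decay passively (first-order, default
0 — settling of heat-killed food, not consumption: the study provides no
ingestion rates to couple to). The true rate is the response evaluated at
the depletion-averaged prey; counting error is Poisson on the cells
actually counted in a 3-mL subsample (the default, matching Lugol's
subsample counting; applied to ciliate counts only, since cytometric
prey counts tally ~10⁶ cells and their counting error is negligible), or
additive Gaussian rate noise with $\sigma = 0.1$ d$^{-1}$ — a magnitude
chosen once as visually consistent with the scatter of published response
plots, and flagged as a convention, not an estimate.

Passing recovery tests on this generator shows the estimators invert the
model they assume. It does not validate the exponential-growth
assumption itself, density-dependent feeding, wall growth, prey quality
shifts, acclimation, or non-Poisson counting artefacts (clumping,
fixation losses). Conclusions about real campaigns inherit those
assumptions.

## Problem sizes

The shipped tests run campaigns of 24–60 wells, 100–500 replicate
campaigns for coverage and recovery, $10^4$–$10^5$ Monte-Carlo draws per
interval, and 10–25 multistarts per TPC fit — sizes chosen so the whole
suite exercises every stochastic path in well under a minute while
keeping Monte-Carlo error small against the tolerances tested.

## Known limitations

* `k` is weakly identified when no treatment reaches satiation; its SE
  can exceed the estimate (visible in the packaged reference table) and
  its finite-sample bias is the largest of the three parameters.
* $\delta_{\max}$ inherits a pole at $k = P'$; fits landing in the
  $k < P'$ regime produce positive zero-food "mortality" and an
  unreliable interval — both are surfaced, not masked.
* The Lactin-2 cold limb is an extrapolation; `CT_min` should be trusted
  only when data bracket it.
* With four temperatures the TPC fit is ridge-prone (see above);
  reported uncertainty for traits would require propagating across the
  ridge and is intentionally not reported for the reference reproduction.
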