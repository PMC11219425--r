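# protistNR

Trait inference for bacterivorous protists from microcosm growth
experiments: threshold numerical-response curves, starvation mortality,
and Lactin-2 thermal performance.

## The problem

How fast can a bacterivorous ciliate grow when food is plentiful, how fast
does it die when food is gone, and how close does it live to its thermal
limits? Numerical-response (NR) experiments answer the food side: wells
spanning a gradient of bacterial concentrations are incubated for a day at
a fixed temperature, and the specific growth rate in each well,

    r = ln(Nt / N0) / t,

is regressed on the food level `P` with the threshold numerical response

    r(P) = r_max (P − P′) / [k + (P − P′)],

a rectangular hyperbola shifted so growth crosses zero at the threshold
food concentration `P′` (`k` is a curvature constant, *not* a
Michaelis–Menten half-saturation, because of the shift). Two derived
quantities carry most of the ecology:

* **δ_max = r(0) = −r_max P′ / (k − P′)** — the maximum physiological
  (starvation) mortality rate, the zero-food counterpart of `r_max`;
* the temperature profile of `r_max`, summarised by a **thermal
  performance curve (TPC)**. The package uses the Lactin-2 family,

      rate(T) = exp(aT) − exp(a·t_max − (t_max − T)/Δ) + b,

  and extracts the optimum `T_opt`, the critical limits `CT_max` /
  `CT_min` (zero crossings), and the thermal safety margin
  `TSM = CT_max − T_opt`.

The package is for experimentalists running such campaigns: it fits the
curves with bounded Levenberg–Marquardt least squares, propagates
parameter uncertainty into δ_max by Monte-Carlo draws, regresses δ_max on
temperature, and evaluates simple grazing-pressure scenarios (community
grazing rate = grazer density × clearance rate). A synthetic campaign
generator with the same design as the reference study (24 wells per
temperature, food 0.1–10 × 10⁶ bacteria mL⁻¹ biased toward low food, no
replicates, Poisson subsample counting noise) makes every stage testable
without raw data.

## Worked example

The packaged reference analysis recomputes every desk-scale number of the
*Colpidium kleini* study from its published parameter table:

```r
library(protistNR)
ref <- reproduce_reference(seed = 1)
ref
#> Reference C. kleini analysis, recomputed from published constants
#>   delta_max table: 10 values, max |recomputed - printed| = 0.000
#> Mortality trend: slope -0.0194 +/- 0.0068 d^-1 degC^-1 (t = -2.85, df = 6, p = 0.0291)
#>   intercept -0.272 d^-1; n = 8 used, 2 excluded
#>   mortality summary (positive): mean 0.55 +/- 0.17, median 0.53
#>   at 8 degC: -0.43 d^-1; 1000 cells/L -> 2.4 cells/L after 14 d
#>   grazing: community 0.0054 d^-1; required density 27.0 ind/L
#> Thermal traits: Topt = 16.47 degC (rate 1.200 d^-1), CTmax = 22.48 degC, CTmin = undefined, TSM = 6.01 degC
#>   TSM identities: 4.6 degC (TPC1), 6.0 degC (TPC2)
```

Reading the output: evaluating each published (r_max, P′, k) triple at
zero food reproduces all ten printed δ_max values; mortality steepens by
≈0.019 d⁻¹ per °C (significant at the 5% level after the study's two
outlier exclusions); a starving population at the 8 °C habitat
temperature declines at 0.43 d⁻¹, so 1000 cells L⁻¹ shrink to ~2 cells
L⁻¹ in two weeks; the sparse alpine copepod community grazes at only
0.005 d⁻¹, ~80-fold below δ_max, while ~27 grazers L⁻¹ would be needed to
offset satiated growth; and the Lactin-2 fit to the eight published r_max
estimates puts the optimum at 16.5 °C with a 6 °C safety margin.

A synthetic campaign runs through the same pipeline:

```r
wells  <- generate_campaign(campaign_config(seed = 11))
bundle <- run_pipeline(wells, analysis_config(prey_metric = "abundance",
                                              interval_draws = 1e4, seed = 11))
bundle$nr_fits$abundance[["15"]]
#> Threshold numerical-response fit at 15 degC (abundance)
#>   n = 24, converged: TRUE, RSS = 0.2295
#>         estimate     se p
#> r_max     0.7721 0.1203 0
#> p_prime   0.8228 0.0704 0
#> k         1.6393 0.2875 0
#>   delta_max = -0.778 d^-1 [-1.185, -0.670] (95% MC)
```

(Abundance-based fits are reported in units of 10⁶ cells mL⁻¹; with the
default Poisson counting noise, single-campaign estimates scatter around
the generator truth — `recovery_experiment()` quantifies how much.)

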