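# co2pause

Diagnostics of the atmospheric CO2 growth rate and the terrestrial carbon
sink, for carbon-cycle scientists who want a transparent, fully testable
implementation of a satellite-driven photosynthesis–respiration (PR)
diagnostic and the accompanying growth-rate statistics — runnable end to end
on synthetic forcing with known truth, or on real annual carbon-budget
series supplied as CSV.

## What the package computes

**Photosynthesis.** A first-principles light-use-efficiency model of gross
primary production. Under the coordination hypothesis (Rubisco- and electron
transport-limited rates co-limiting under typical field conditions), GPP
follows the electron-transport form

GPP = M_C φ₀ I (χc_a − Γ\*) / (χc_a + 2Γ\*),

with absorbed light I = I₀ × fAPAR, quantum efficiency φ₀, compensation
point Γ\*(T) and the ratio χ = c_i/c_a predicted by the least-cost
hypothesis,

χ = ξ / (ξ + √D),  ξ = √(β K(T) / (1.6 η\*(T))),

where D is the vapour pressure deficit (Pa), K the effective
Michaelis–Menten coefficient of Rubisco and η\* the relative viscosity of
water (β = 356.51 at the χ₂₅ = 0.8 calibration).

**CO2 sensitivity.** The closed-form relative sensitivity
β_CO2 = (∂GPP/∂c_a)(c_a/GPP) = 3χc_aΓ\* / ((χc_a − Γ\*)(χc_a + 2Γ\*)),
which evaluates to 37% at 400 ppm and declines to 19% at 800 ppm
(χ = 0.8, Γ\* = 43 ppm), with its analytic derivative showing the decline
itself flattens as c_a rises.

**Respiration and NEP.** Ecosystem respiration
R_eco = (R₀ + k·GPP) f(T) α with the Lloyd–Taylor temperature scalar f(T)
(E₀ and k per plant functional type), moisture index α, and the reference
rate R₀ solved analytically per grid cell so that preindustrial net
ecosystem production (NEP = GPP − R_eco) is exactly zero.

**Growth-rate diagnostics.** The one-box linear sink model
G = F_anthro + F₀ − B·M (B an inverse residence time for excess atmospheric
carbon), fit by OLS on a chosen window; a t-test for structural change in
the post-window residuals; the annual airborne fraction G/F_anthro; and
Mann–Kendall/Sen trend tests.

**SSA + IAAFT.** Singular spectrum analysis with exact-completeness
reconstruction, extraction of the low-frequency (period ≥ 5 yr) subsignal,
and extraction uncertainty from 100 IAAFT surrogates that preserve the
residual's amplitude distribution exactly and its power spectrum to within
a few percent.

**Attribution.** Factorial single-driver experiments: remove the long-term
trend from every forcing driver except one (CO2, climate = T and D, fAPAR,
or α), rerun the PR model, and difference the fluxes between two periods,
globally and by latitude band.

## Worked example

```r
library(co2pause)

# How sensitive is photosynthesis to CO2?
sensitivity_curve(c(280, 400, 560, 800))
#>      ca   chi gamma_star beta_co2 d_beta_d_ca
#> 1   280   0.8         43    0.515   -0.00177
#> 2   400   0.8         43    0.367   -0.000866
#> 3   560   0.8         43    0.267   -0.000451
#> 4   800   0.8         43    0.190   -0.000227
```

A 37% relative sensitivity at today's 400 ppm, falling to 19% at doubled
CO2: CO2 fertilization keeps strengthening the sink, but at a declining
rate.

```r
# A synthetic 1959-2014 budget whose sink rate strengthens 30% from 2002
b <- make_budget_series(break_spec = list(year = 2002, B = 0.039), seed = 1)
fit <- fit_sink_model(b, window = c(1959, 1988))
fit
#> Linear sink model of the CO2 growth rate
#>   fit window : 1959-1988
#>   B  = 0.0309 yr^-1  (se 0.0013)
#>   F0 = 19.11 PgC yr^-1 (se 0.93, composite intercept B*M0)

residual_break_test(fit, 2002)
#>   candidate_year n_post mean_residual statistic    df  p_value
#> 1           2002     13         -1.71     -36.7    12 1.09e-13
```

The fit window recovers the generator's true B = 0.03 yr⁻¹ within one
standard error, and the post-2002 residuals sit significantly below zero:
observed growth rates fall short of the linear model's prediction, the
signature of a strengthening sink. The airborne fraction shows the same
change (`airborne_fraction()` + `mann_kendall_sen()`), and
`subsignal_uncertainty(b$G)` extracts the underlying ≥ 5-year dynamic of
the growth rate with a surrogate-based uncertainty band.

For the gridded side, `make_forcing()` generates a century of monthly
synthetic forcing, and

```r
f <- make_forcing(1900:2013, nlat = 9, nlon = 18, noise = noise_spec(0,0,0,0,0,0))
d <- period_delta(run_experiment(f, keep = "ca"), cell_areas(f),
                  c(1901, 1915), c(1995, 2010))
```

isolates the CO2-fertilization contribution to the change in GPP, R_eco
and NEP between the early and late periods (positive ΔGPP and ΔNEP, as
theory requires). `run_pipeline()` chains all stages and writes CSV/JSON
outputs reproducibly from one seed.

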