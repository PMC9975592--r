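---
title: "Methods: photothermal growth, nitrogen dilution and demand budgeting in pakchoi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photothermal growth, nitrogen dilution and demand budgeting in pakchoi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pakchoiN)
```

## Scope and model structure

pakchoiN implements a nitrogen (N) demand pipeline for greenhouse pakchoi
built from four linked components: (1) a photothermal driver that collapses
hourly weather into a daily growth-suitability product and its running sum
(LTF); (2) exponential growth and N-uptake models driven by LTF, with a
quadratic response of the rate parameter to the N application rate; (3) the
critical N dilution curve with maximum/critical/minimum envelopes, the
nitrogen nutrition index (NNI) and a status classification; and (4) a
demand/supply budget converting the concentration gap into grams of N per
plant. A synthetic-trial generator and a Monte-Carlo recovery harness close
the loop so every stage can be verified end to end.

## Photothermal driver

The temperature response `fT` is piecewise linear in the cardinal
temperatures: 0 at or below Tb = 7 °C and at or above Tm = 35 °C, 1 at
T0 = 24 °C, linear between. The light response is
`fI = 1 − exp(−α·I)` with α = 0.001 per mmol m⁻² d⁻¹ and `I` the daily PAR
integral in mmol m⁻² d⁻¹.

Two unit/aggregation choices deserve explanation because they are the
largest practical hazards in this model class:

* **Hourly-to-daily aggregation.** `fT` is defined on hourly mean
  temperatures, but the LTF sum runs over days. We take the daily `f_t` to
  be the arithmetic mean of the 24 hourly `fT` values, which preserves the
  hourly evaluation while producing one factor per day. Days must be
  complete (hours 0–23); partial first or last days are rejected rather
  than padded, and within-day gaps longer than one hour are reported as
  malformed input, because silently padding would bias `f_t` toward
  whatever part of the diurnal cycle survives.
* **Units of `I`.** The curvature α = 0.001 only makes sense if `I` is in
  mmol m⁻² d⁻¹: daily integrals of 5.3–9.5 mol m⁻² then give
  `fI ≈ 0.995–0.9999`, i.e. light nearly saturates and temperature
  dominates day-to-day variation. Reading `I` in mol would make
  `fI ≈ 0.005–0.009` and LTF virtually zero. The package therefore works in
  mmol internally and converts the weather table's mol column by 1000. The
  daily-cumulative (rather than instantaneous) reading of `I` is a design
  choice; nothing in the model's provenance pins it down, but only the
  cumulative reading produces saturation at realistic greenhouse radiation.

`cumulative_ltf` sums `f_t · f_i` over an inclusive day range; the empty
range is 0 by convention, and over n days the value is bounded by n.

## Growth and uptake models

All three responses (fresh biomass FW and dry biomass DW in g/plant, N
uptake in mg/plant) follow `Y = a·e^(b·LTF)`. `fit_growth` estimates
(a, b) by Levenberg–Marquardt nonlinear least squares **on the natural
scale**, initialized from the log-linear OLS solution; the log-scale
estimates are retained in the fit object for comparison. Natural-scale
fitting weights the late, large observations more heavily; whether the
original calibration used the log or natural scale is not determinable, so
we expose both and verify that they agree exactly on noiseless
model-generated data. Convergence tolerances are 1e−12 on the objective
and parameters with a 200-iteration cap; the log-linear start makes the
problem benign, and non-convergence is reported with the start values in
the diagnostic.

Fit quality is summarized by R² about the mean on the natural scale, its
adjusted version with n − 2 residual degrees of freedom, and an F statistic
formed as regression mean square over residual mean square with 1 and n − 2
degrees of freedom — the one-slope ANOVA decomposition, which matches the
magnitude and df structure customarily reported for such fits. On an exact
fit the F statistic is infinite and is serialized as absent in JSON
reports.

The rate parameter responds to the N application rate F (g N/kg) as
`b(F) = c0 + c1·F + c2·F²` with `c2 < 0`. The calibrated coefficient sets
are bundled in `pakchoi_b_quadratics()` (FW: 0.0665, 0.4749, −1.0323; DW:
0.0729, 0.2052, −0.3986; N uptake: 0.0599, 0.4114, −0.8141).
`optimal_n_rate` returns the unconstrained vertex `−c1/(2c2)` and its value
`c0 − c1²/(4c2)`; because the vertex can fall outside the experimentally
tested range (the DW vertex sits near 0.26 g/kg, beyond the usual 0–0.2
range), the function also reports the maximum over a user-supplied closed
interval. The unconstrained vertex is the quantity whose three-decimal
roundings (0.121, 0.099, 0.112) the test suite asserts.

Unit conversions: `FW = 25.64·DW` (fresh-to-dry ratio, exposed as a
parameter), and per-plant to areal biomass via an explicit plant density
(t/ha = g/plant × plants/ha × 10⁻⁶). **There is deliberately no default
density**: pot trials rarely justify one, and the areal dilution curve is
sensitive to it, so any areal computation fails loudly until the user
supplies a density.

## Dilution envelope, NNI and status

With Nmax = 6.83 % of DW (the mean of cotyledon-stage N contents 6.52,
6.93, 6.96, 6.90 %) and exponent b = 0.33, the three envelope curves are

* `Nmax(DW) = min(6.83, 6.83·2^b · DW^−b)` — plateau joins the power law
  at 2 t/ha;
* `Nc(DW)` — plateau `0.7·Nmax = 4.78 %` up to 1.5 t/ha, power law beyond;
* `Nmin(DW) = min(0.4·Nmax, 0.4·Nmax·0.5^b · DW^−b)` — join at 0.5 t/ha.

The plateau fractions 0.7 and 0.4 are parameters, not constants, so the
envelope generalizes to other leafy crops.

The critical curve is implemented in two modes. `"as_printed"` (default)
uses the curve exactly as usually quoted — coefficient 4.78 above the
breakpoint — which implies a downward step of factor `1.5^−0.33 ≈ 0.875` at
1.5 t/ha. `"continuous"` derives the coefficient from the plateau-matching
recipe `a_c = 0.7·Nmax·1.5^b ≈ 5.47`, removing the step. The discontinuity
is a genuine property of the headline calibration, not an implementation
artifact; defaulting to it keeps the package faithful to the published
curve while the continuous mode is available (and is the one under which
the envelope-ordering invariant `Nmin ≤ Nc ≤ Nmax` is asserted everywhere).
The boundary DW = 1.5 t/ha belongs to the plateau in both modes. In the
fresh-weight domain the breakpoint is derived from the configured ratio and
breakpoint (25.64 × 1.5 = 38.46 t/ha) rather than hard-coded, since
independently printed restatements of this threshold disagree in their
second decimal.

`NNI = Na/Nc` with the standard directionality: below 1 is deficient, above
1 is luxury/excess. (Some descriptions of the index state the reverse
mapping; the convention used throughout the dilution-curve literature is
implemented.) Because measured pipelines never produce exactly 1,
`classify_status` takes a tolerance (default 0.05) and labels the crop
optimal when `1 − tol ≤ NNI ≤ 1 + tol`, with the band edges inclusive.

`fit_dilution` estimates (a, b) by OLS of `ln(N%)` on `ln(DW)` using only
samples above the breakpoint — plateau points carry no information about
the power law — and requires at least three usable points.

## Demand and supply

`N_demand = k·FW·(Nc − Na)/100` with crop coefficient k = 0.39. The
concentrations are percentages and **enter as fractions**: this is the only
reading under which a realistic plant (tens of grams fresh weight, a
concentration gap of a point or two) yields a demand of tens to hundreds of
mg — the scale on which such budgets are validated. The division by 100 is
explicit in the code and documented prominently. When the plant is in
excess the raw value is negative; fertilizer advice cannot be negative, so
the demand is clamped to zero and the overshoot is reported separately as
`surplus_g`. Supply divides demand by the N use efficiency, defaulting by
cultivation system to the calibrated 0.38 (substrate) and 0.17 (soil); the
crop coefficient is treated as an opaque calibrated constant.

## Synthetic trials

`generate_weather` emulates a greenhouse season: a diurnal sinusoid with
pre-dawn minimum (03:00) and mid-afternoon maximum (15:00) around the
regime mean, plus AR(1) noise (lag-1 correlation 0.8) whose stationary SD
is 5 % of the amplitude — tying the noise to the amplitude makes a
zero-amplitude regime exactly periodic, which the determinism tests
exploit. Daily PAR totals are drawn from a normal distribution truncated at
zero (via the inverse CDF, so the draw count is seed-stable) and spread
over the daylight window as a half-sine, zero at night. The two presets
encode the study conditions the package targets: `exp13` (mean 19 °C,
half-range 5 °C, PAR 5.3 mol m⁻² d⁻¹, 11 h daylight) and `exp2` (26.3 °C,
half-range 6 °C, 9.5 mol m⁻² d⁻¹, 10 h). The PAR standard deviations (1.2
and 2.0 mol m⁻² d⁻¹) are our own choice, set so a season's range of daily
totals spans roughly what greenhouse records of this kind show (about
9–15 mol m⁻² between darkest and brightest days).

`generate_trial` forward-simulates the package's own model: per N rate the
b values come from the calibrated quadratics; FW starts at 0.2816 g, DW at
0.2816/25.64 g, and N uptake at the DW intercept times Nmax (only the FW
intercept is part of the calibration; the other two are derived, flagged
assumptions). The N concentration implied by uptake/DW is clipped into the
[Nmin, Nmax] envelope evaluated at the areal biomass, which produces the
plateau-then-decline concentration trajectory characteristic of real
seasons. The generator's default conversion uses a nominal density of
2×10⁷ plants/ha — an explicit structural choice that maps the default
trial's final per-plant DW a few-fold past the 1.5 t/ha breakpoint so both
the plateau and the dilution phase are exercised; it is a scaling device
for pot-scale trajectories, not a recommendation of a field density.
Between-plant noise is multiplicative lognormal (destructive samples are
distinct individuals; biomass errors scale with size), mean-corrected so
the expectation equals the trajectory, with CV 0.08 by default and
independent draws per response. All draws flow from one generator per
trial, so a trial is a pure function of its design.

What the generator does **not** emulate: measurement error structure beyond
a single CV, within-canopy light competition, treatment-by-time interaction
beyond the b(F) quadratic, or the measured values of any real experiment —
the real data are not publicly deposited. Passing tests therefore
demonstrate internal consistency and recoverability under the model's own
assumptions, not agreement with field measurements.

## Validation machinery

`agreement` reports the Pearson r of the measured/simulated pairs and its
square (the 1:1 framing, not regression through the origin), the RMSE of
the paired differences, the OLS slope of simulated on measured, and a
relative standard error of prediction: the residual standard deviation of
that regression as a percentage of the mean measured value. That reading of
"standard error of the regression estimate" is the one that yields
double-digit percentages on growth data of this scale; the regression
direction is fixed (simulated on measured), so RE and slope are
direction-sensitive while r and RMSE are not. The slope's standard t test
is available from the retained lm fit for users who want a significance
statement; we do not attach a bespoke test to R².

`recovery_study` is the property-based substitute for real-data
validation: it repeatedly generates trials at a given noise CV, refits the
growth models on per-day treatment means and the dilution curve on
critical-curve points carrying the same noise, and reports bias and RMSE
against the injected truth. With zero noise every parameter is recovered
exactly — the strongest end-to-end check the pipeline admits. The N-uptake
rate is not among the tracked parameters because envelope clipping
legitimately decouples the realized uptake trajectory from the injected
exponential at high N; uptake is instead checked by internal-consistency
tests (`uptake = DW × N% × 10` mg).

Problem sizes used by the shipped tests — 42-day trials, four N rates,
weekly sampling, 12 plants per harvest, 200 Monte-Carlo replicates for the
CV = 0.08 recovery check — mirror a realistic single-season greenhouse
trial while keeping the full suite under ten seconds on one core.

## Known limitations

* The photothermal model ignores humidity, CO₂, and canopy light
  interception; `fI` uses the daily PAR integral, not an interception
  model.
* The dilution envelope is whole-plant; no leaf/stem partitioning.
* The demand equation is a static budget: no soil mineralization,
  leaching, or split-dose scheduling.
* Areal quantities inherit the uncertainty of the user-supplied plant
  density; with pot data the t/ha scale is nominal.
* The machine-learning N-demand predictor that complements this model in
  some workflows (random-forest fusion of phenotype features) is out of
  scope: its feature set is not reproducible from public information. The
  demand interface is deliberately small so such a predictor can be
  plugged in upstream of `demand_report`.
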