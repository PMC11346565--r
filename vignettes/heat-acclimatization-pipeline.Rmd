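---
title: "Methods: the heat-acclimatization analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the heat-acclimatization analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatadapt)
```

# Scope and design

`heatadapt` implements the derived-measure and inference chain used to
quantify seasonal heat acclimatization in small repeated-measures cohorts:
adolescents or adults completing a standardized heat-response test (HRT) —
here modelled as 45 min of uphill treadmill walking in a 40 °C / 30 % RH
chamber — before and after a summer, with CO-rebreathing hematology,
outdoor wet-bulb globe temperature (WBGT) reconstructed from meteorological
records, and activity-exposure summaries. Because participant-level data of
such studies are rarely deposited, the package ships a synthetic-data
generator with known ground truth; every stage is validated end to end
against that truth and against independent oracles (brute-force scans, grid
posteriors, psychrometric tables).

The package follows the classic R modelling idiom where an estimator is the
deliverable: the segmented sweating-onset fit (`fit_sweat_onset()`) and the
Bayesian hierarchical pre/post model (`fit_hier_linear()`) return classed S3
objects with `print`, `summary`, `coef`, `predict`/`plot` methods; the
surrounding derived measures are plain functions.

# Thermometry

Mean skin temperature is the fixed four-site weighting 0.3 chest +
0.3 shoulder + 0.2 thigh + 0.2 calf; a missing site is an error rather than
a silent re-weight, because the weights are part of the measure's
definition. Visit summaries (`summarize_visit()`) take resting baselines as
the mean of the final 5 min of the 10-min pre-exercise rest — the first
half is discarded as instrumentation transient; the window width is a
parameter. The rise in core temperature is referenced to the
exercise-onset sample (after chamber entry), not to the temperate-room
baseline; where the other convention is wanted, `rise_reference = "rest"`
selects it. Telemetric capsule traces are screened for physically
impossible values (outside 30–43 °C) and for jumps above 0.5 °C per 15 s —
a telemetry-artifact threshold chosen from the capsule's plausible maximal
physiological slew rate; a trace losing more than 20 % of samples is
refused as unusable. Safety handling mirrors chamber practice: the first
sample at or above 39.5 °C truncates all exercise summaries at that time
and flags the visit.

# Sweat kinetics

Local sweat rate (LSR) follows from ventilated-capsule hygrometry as vapor
concentration × flow ÷ area, with vapor concentration from the Buck-form
saturation vapor pressure converted to density by the ideal-gas law; no
psychrometric formulation was prescribed, and the Buck coefficients are the
ones the rest of the package uses, keeping the generator and analysis on a
single psychrometric axis.

The sweating onset is the breakpoint of the flat-then-linear model
`LSR(t) = a` for `t ≤ t0`, `a + b (t − t0)` after. The breakpoint is found
by exhaustive search over the observed sample times (the 5-s capsule
cadence), with `a`, `b` solved analytically per candidate; this guarantees
the global optimum on the grid, matches the data's resolution, and ties
break toward the earliest time. Whether an onset exists at all is an
F-test of the segmented against the flat model at α = 0.05; a flat or
negative-slope trace reports "no onset" rather than a spurious breakpoint.
Sensitivity is defined as the post-onset slope against *time*
(mg·cm⁻²·min⁻¹ per min), the convention of the printed units; the onset
*threshold* is expressed in °C by interpolating the cleaned core-temperature
trace at `t0`. The two capsule sites are fitted independently; per-site
values and their mean are both available to the caller.

Whole-body sweat loss closes the mass balance
`(nude mass loss) + fluid intake − respiratory water loss`, with nude mass
from clothed minus clothing masses so sweat trapped in fabric is counted
automatically; the respiratory term may be measured or estimated from the
heat balance (`Eres / 2426 J g⁻¹` over the bout). Whether the original
analyses used measured or estimated ventilation is not stated; estimation
from metabolic rate is the default here and the term is an explicit input.

# Partitional calorimetry

The heat balance uses the standard partitional-calorimetry coefficient set:
`hc = 8.3 v^0.6`, a linearised radiative coefficient with emissivity 0.95
and radiating-area fraction 0.70, respiratory terms `0.0014 M (34 − Ta)`
and `0.0173 M (5.87 − Pa)`, the Lewis relation `16.5 hc` for maximal
evaporation, and the Du Bois surface area. All constants are overridable
through the `constants` argument. Sign convention: positive flux = heat
loss, so in a 40 °C chamber convection and radiation are *negative* (dry
heat gain) and inflate the evaporative requirement
`Ereq = M − Wext − C − R − Cres − Eres`.

Chamber air velocity is the one genuinely open parameter: it is rarely
printed for treadmill chambers. The default is 0.3 m s⁻¹, the still-air
convention for an enclosure without directed airflow. Under the study-type
conditions (40 °C, 30 % RH, VO₂ ≈ 36 mL kg⁻¹ min⁻¹, adolescent
anthropometry) this yields a compensability ratio Ereq/Emax ≈ 1.5, inside
the 1.4–2.2 band such exposures report; the ratio crosses 1 near
0.6 m s⁻¹, so the uncompensability conclusion holds for still-air chambers
but not for fan-ventilated ones — which is why the acceptance checks assert
the ratio over the still-air band 0.2–0.45 m s⁻¹ rather than at arbitrary
velocities. Mean radiant temperature is set equal to air temperature inside
the chamber, and clothing resistance is omitted (semi-nude exercise); both
are stated limitations rather than switches.

# Hematology

Hemoglobin mass follows the CO-dilution formula
`CO_absorbed × 100 / (ΔHbCO × 1.39)`; the Hüfner constant 1.39 mL g⁻¹ and
the f-cell factor 0.91 are literature defaults and both configurable.
Blood volume is `hb_mass / [Hb] × 100`; red-cell volume applies the f-cell
correction to hematocrit; plasma volume is the difference, an identity that
holds exactly by construction. The unabsorbed-CO accounting (spirometer
plus end-exhalation) enters as a single field. When hemoglobin
concentration is unavailable it is imputed from hematocrit via an MCHC of
33 g dL⁻¹ of red cells, with a warning. The typical error of duplicates is
the within-pair SD / √2 as a percent of the grand mean.

# Outdoor WBGT

The package reconstructs WBGT from standard hourly meteorological records
(dry bulb, RH, wind, cloud) because that is how seasonal exposure is
characterised when no on-site WBGT instrument exists. Solar irradiance
comes from solar-position geometry (Spencer declination and equation of
time) with solar constant 1367 W m⁻², a bulk clear-sky transmittance of
0.75 per unit air mass, and the empirical cloud attenuation
`1 − 0.75 c^3.4`. Globe and natural-wet-bulb temperatures solve
Liljegren-style steady-state energy balances: the 150-mm globe balances
absorbed shortwave (`0.95 S/4`, the sphere's projected-area ratio) against
sphere convection (Ranz–Marshall) and longwave exchange with surroundings
at air temperature, by damped Newton iteration to 0.01 °C within 100
iterations; the wick balances convective and longwave heating plus a lumped
shortwave absorption (0.15) against evaporation tied to convection through
the psychrometer coefficient `0.622 λ / (cp P)`. The wick solution is
bracketed — and clamped — between the aspirated psychrometric wet bulb and
the dry bulb: within this steady-state model radiative loading cannot push
a wet wick above air temperature. With zero solar load the natural wet
bulb stays within a few tenths of a degree of the psychrometric wet bulb
(the residual being the longwave term), which is the package's cross-check
against the independent psychrometer relation. The outdoor index is
`0.7 Tnw + 0.2 Tg + 0.1 Tdb`.

Daytime summaries use the clock-time window 08:00–18:00 (inclusive start,
exclusive end). Solar-time windowing was considered and rejected: exposure
guidance and school schedules run on clock time. Days with under half the
window's hours are dropped and reported. Activity exposure uses the
conventional Freedson vector-magnitude cutpoint 2690 counts min⁻¹ on 60-s
epochs (the equations are named in such studies, the cutpoint usually not;
it is a parameter here), with non-wear as ≥ 60 consecutive zero epochs.
Diary RPE bands are 1–3 light, 4–6 moderate, 7–10 high (RPE 0 falls to
light); bands are configurable.

# Hierarchical inference

Scalar outcomes use the Gaussian random-intercept model
`y_ij = β0 + β1·post + β2·(VO₂peak − mean) + u_i + ε_ij`. The original
analyses of such studies use thin-plate-spline hierarchical GAMs and a
beta-binomial family for ordinal perceptual scales through a probabilistic-
programming engine; this package deliberately implements a simplified,
self-contained sampler instead — the posterior-summary mechanics (mean,
equal-tailed 90 % CrI, probability of direction) and parameter recovery do
not require the exact basis, and perceptual scales analysed with the
Gaussian machinery are flagged as an approximation. The covariate is
centered at the arithmetic mean, matching the convention of reporting
model estimates at the mean VO₂peak.

Priors are weakly informative and data-scaled: `N(mean(y), (10 SD(y))²)` on
the intercept, `N(0, (5 SD(y))²)` on the period effect,
`N(0, (2.5 SD(y)/SD(x))²)` on the covariate, half-normal(2.5 SD(y)) on τ
and σ. The τ prior is exact through parameter expansion
(`u_i = ξ η_i`, `η_i ~ N(0,1)`, `ξ ~ N(0, s²)` ⇒ `τ = |ξ| ~ half-N(s)`),
which keeps every conditional normal; σ keeps its half-normal prior via a
slice-sampling step, since no conjugate update exists. Four chains of 2500
post-warmup draws are the default; split-R̂ above 1.01 warns. The period
effect β1 mixes essentially independently (ESS ≈ draws); the intercept/τ
pair mixes more slowly in the centered parameterisation, which is why the
default draw count is generous. The 90 % rather than 95 % interval is used
because the narrower tails are stable at practical draw counts.

`pd_from_interval()` provides the inverse route: from a published posterior
mean and equal-tailed interval, the implied normal posterior SD is
`(hi − lo)/(2 z)` and Pd = `100 Φ(|mean|/SD)`. On exactly normal
posteriors the draw-based and interval-based routes agree within one
percentage point, which is the package's worked-example check against nine
published contrasts. Both routes are exposed because it is unknowable
whether published Pd values were computed from draws before or after
rounding of the summaries.

Time courses (5-min cadence signals) use period-specific penalized
B-splines (second-difference penalty as a normal prior on the coefficients,
conjugate gamma update for the smoothing precision, default basis size 8)
with the same participant-intercept expansion, returning fitted curves and
a time-resolved pre/post contrast with 90 % bands.

# The synthetic generator

The generator *defines* the study conditions: 15 participants (5 female),
body mass 56.84 ± 9.05 kg, height 1.70 ± 0.08 m, VO₂peak 60.4 mL kg⁻¹
min⁻¹ (SD 9.9, the between-participant spread implied by the published
interval of the cohort mean). Outcome dispersions are matched to the
published pre/post spreads — e.g. resting heart rate: between-participant
SD 10, within-participant SD 6 bpm, true shift −7 bpm; resting core
temperature: 0.20/0.20 °C, shift −0.19 °C. The core-temperature template
is an exponential-saturating rise normalised to reach baseline + rise
exactly at 45 min (so end-exercise arithmetic is exact), with the rate
solved so the curve passes through the configured onset point; being
concave, it bounds the onset temperature below by the chord value, so the
default onset (37.7 °C at 10 min) is an internal-consistency choice, not a
reproduction of any printed threshold. The LSR template is flat-then-linear
by construction — it *is* the segmented-regression estimand. Capsule
humidity is produced by inverting the same psychrometric relation the
analysis applies, so noiseless round trips are exact; that inversion is in
turn checked against tabulated vapor densities, keeping the loop honest.
Each signal draws from its own seed-derived stream, so adding one signal
never perturbs another, and every generator is byte-reproducible under a
fixed seed.

What the generator does not emulate: day-to-day within-participant
variation in baseline core temperature beyond the configured residual SD
(no such variability is published for this population), cardiovascular
drift interacting with sweating, diurnal timing of visits, missingness, or
raw accelerations (counts only). Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every artifact of field data.

Noise for the segmented-regression recovery checks is 5 % of the plateau
LSR the trace attains (1.85 mg cm⁻² min⁻¹ under the defaults), a
conservative reading of capsule hygrometry noise; recovery of the onset is
then accurate to ~0.2 min on average at the 5-s cadence.

# Numerical choices and problem sizes

Grid searches use the data's own sampling grid; breakpoint ties break
early. The Newton and bracketed root solvers converge to 0.01 °C. The
slice sampler is Neal's stepping-out/shrinkage on log σ. Priors are
floored (`SD(y) ≥ 1e-6`) so constant inputs remain proper. The packaged
validation sizes — 200 segmented-regression replicates, 500 calibration
cohorts at one chain × 1000 draws, 1000 heat-balance identity points,
10 000 WBGT solver conditions — were chosen to pin Monte-Carlo error well
inside each check's tolerance (e.g. coverage SE ≈ 1.3 % at 500
replicates against a ±5 % acceptance band) while keeping a full validation
run in the low minutes on one core.

# Known limitations

Single steady-state heat balance per visit (no transient heat-storage
model); no clothing resistance; no sweat-sodium chemistry (sweat [Na⁺]
passes through as a covariate); no CO diffusion kinetics beyond the
unabsorbed-dose correction; the WBGT chain targets a documented CSV layout,
not any proprietary station archive; perceptual ordinal scales are
approximated as Gaussian. The hierarchical sampler is not a general
probabilistic-programming replacement — it implements exactly the two model
families the pipeline needs.
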