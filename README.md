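# heatadapt

Analysis pipeline for **seasonal heat-acclimatization studies** built around
laboratory heat-response tests (HRT): repeated-measures cohorts (think 15
active adolescents, 5 female, tested before and after summer) walking 45 min
at ~60 % V̇O₂peak in a 40 °C / 30 % RH chamber, with core and skin
temperature, heart rate, ventilated-capsule local sweat rate, whole-body
sweat loss, CO-rebreathing hematology, outdoor WBGT exposure and activity
records. The package turns those raw signals into the derived measures the
field reports and carries them through Bayesian hierarchical pre/post
inference.

What it computes:

- **Thermometry** — weighted mean skin temperature
  (T̄sk = 0.3 chest + 0.3 shoulder + 0.2 thigh + 0.2 calf), telemetric-capsule
  trace cleaning, resting baselines, exercise rise/end values, 39.5 °C
  safety-stop handling.
- **Sweat kinetics** — local sweat rate from capsule hygrometry
  (LSR = ρᵥ(RH, T) · flow / area), the sweating-onset threshold and
  thermosensitivity by segmented regression
  (LSR(t) = a for t ≤ t₀, a + b(t − t₀) after; exhaustive breakpoint grid,
  F-test against the flat model), and whole-body sweat loss by mass balance
  with clothing-trapped sweat and respiratory water corrections.
- **Partitional calorimetry** — M, Wext, C, R, Cres, Eres,
  Ereq = M − Wext − C − R − Cres − Eres, Emax = 16.5 hc A (Psat(Tsk) − Pa),
  and the compensability ratio Ereq/Emax (> 1 ⇒ uncompensable).
- **Hematology** — hemoglobin mass from CO rebreathing
  (hbmass = CO_abs · 100 / (ΔHbCO · 1.39)), intravascular volumes, typical
  error of duplicates.
- **Environment** — outdoor WBGT (0.7 Tnw + 0.2 Tg + 0.1 Tdb) reconstructed
  from hourly meteorological records via solar-position geometry and
  Liljegren-style globe/wick energy balances; daytime (08:00–18:00)
  summaries; Freedson-type MVPA from 60-s accelerometer epochs; diary
  summaries by RPE band.
- **Inference** — Gibbs sampler for the hierarchical model
  y_ij = β₀ + β₁·post + β₂·(V̇O₂peak − mean) + u_i + ε_ij with
  participant intercepts, reporting posterior means, equal-tailed 90 %
  credible intervals and the probability of direction (Pd); penalized
  B-spline time courses with a time-resolved pre/post contrast; and
  `pd_from_interval()`, the normal-approximation identity recovering Pd
  from a published mean + CrI.
- **Synthetic data** — generators for cohorts, HRT signal sets, CO
  records, meteorological years and activity weeks with known ground
  truth, so the whole chain is testable without any participant data.

See the methods vignette
(`vignettes/heat-acclimatization-pipeline.Rmd`) for the models,
assumptions, priors and numerical choices.

## Worked example

```r
library(heatadapt)

## simulate a 15-participant cohort with a true -7 bpm resting-HR shift
coh <- generate_cohort(cohort_config(seed = 11))
tab <- simulate_outcome_table(coh, "resting_hr")
fit <- fit_hier_linear(tab, seed = 11)
fit
#> Hierarchical pre/post model (Gibbs sampler)
#>   30 observations, 15 participants; 4 chains x 2500 draws
#>   parameter       mean     ci_low    ci_high     pd     rhat      ess
#> 1        b0 80.1342082 76.1856087 84.1297814 100.00 1.000475 1921.957
#> 2        b1 -4.7265134 -8.4903053 -0.9439710  97.58 1.000408 9363.389
#> 3        b2 -0.1273126 -0.3799753  0.1314455  80.71 1.001562 1671.479
#> 4       tau  6.3282068  2.4163138 10.3103933 100.00 1.002164 1323.116
#> 5     sigma  6.1941899  4.3603996  8.6711750 100.00 1.000995 1764.862
```

`b1` is the pre→post contrast: this replicate estimates −4.7 bpm
[90 % CrI −8.5, −0.9], Pd ≈ 98 % — a single-cohort draw around the true
−7 bpm with n = 15 and ±6 bpm residual noise.

```r
## one synthetic heat-response test, summarized and fitted
s <- generate_hrt_series(hrt_ground_truth(noise_sd = list(lsr = 0.05)), seed = 11)
summarize_visit(s)
#> Heat-response-test visit summary
#>   resting: Tgi 37.28 degC, Tsk 32.15 degC, HR 90 bpm
#>   exercise: rise in Tgi 1.78 degC, end Tgi 39.06 degC, mean Tsk 35.80 degC
#>   heart rate: mean 157, end 187 bpm

cap <- s$capsules$back
lsr <- lsr_from_hygrometry(cap$rh_pct, cap$temp_c, s$capsule)
fit_sweat_onset(cap$t_min, lsr)
#> Segmented sweating-onset fit (flat baseline, then linear rise)
#>   onset at t0 = 10.08 min; baseline 0.103, sensitivity 0.0499 mg cm^-2 min^-1 per min
#>   n = 541 samples, SSE = 1.396
```

The true onset is 10 min at sensitivity 0.05; the noisy trace recovers
10.08 min and 0.0499.

```r
## chamber heat balance at the study's printed conditions
heat_balance(56.84, 1.70, ta_c = 40, rh_pct = 30, tsk_c = 36.3,
             m_w = metabolic_rate(36.2 * 56.84 / 1000, 0.9),
             wext_w = external_work(56.84, 6.1, 10.2))
#> Partitional calorimetry heat balance (positive flux = heat loss)
#>   M  =   707.5 W   Wext =   96.4 W   BSA = 1.66 m^2
#>   C  =   -24.7 W   R    =  -27.9 W   Cres =  -5.9 W   Eres =  44.7 W
#>   Ereq =  624.9 W   Emax =  421.7 W   Ereq/Emax = 1.48 (uncompensable)
#>   assumed air velocity 0.30 m/s, emissivity 0.95, Tr = Ta

## published-summary consistency: Pd from a printed mean and 90% CrI
pd_from_interval(-0.22, -0.48, 0.04)
#> [1] 91.80084   # prints as 92%
```

Negative C and R mean the hot chamber adds dry heat, and the evaporative
requirement exceeds the environmental maximum (ratio 1.48): the exposure
is uncompensable, as such chamber protocols are designed to be.

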