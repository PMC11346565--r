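test_that("hygrometric LSR matches the psychrometric oracle and scaling laws", {
  # dry effluent carries no sweat
  expect_equal(lsr_from_hygrometry(0, 35), 0)
  # tabulated saturation vapor density at 35 degC is ~39.6 g/m^3; at RH 50%
  # and the default 500 mL/min over 4 cm^2 the oracle value is
  # 0.5 * 39.6 * 0.5 / 4 mg/cm^2/min
  oracle <- 0.5 * 39.6 * 500 * 1e-3 / 4
  got <- lsr_from_hygrometry(50, 35)
  expect_lt(abs(got - oracle) / oracle, 0.01)
  # doubling the capsule area halves LSR; doubling flow doubles it
  expect_equal(lsr_from_hygrometry(50, 35, capsule_config(area_cm2 = 8)),
               got / 2)
  expect_equal(lsr_from_hygrometry(50, 35, capsule_config(flow_ml_min = 1000)),
               got * 2)
  expect_error(lsr_from_hygrometry(101, 35), "\\[0, 100\\]")
  expect_error(capsule_config(area_cm2 = -1), "positive")
})

test_that("segmented regression recovers a noiseless onset exactly", {
  t <- seq(0, 45, by = 1 / 12)
  y <- lsr_template_oracle(t)
  f <- fit_sweat_onset(t, y)
  expect_true(f$converged)
  expect_equal(f$breakpoint, 10)
  expect_equal(f$sensitivity, 0.05, tolerance = 1e-10)
  expect_equal(f$baseline, 0.1, tolerance = 1e-10)
  # a constant trace has no onset
  fc <- fit_sweat_onset(t, rep(0.3, length(t)))
  expect_false(fc$converged)
  expect_true(is.na(fc$breakpoint))
  expect_error(fit_sweat_onset(1:5, 1:5), "at least 10")
})

test_that("segmented fit equals the brute-force QR oracle on noisy traces", {
  t <- seq(0, 45, by = 1 / 12)
  set.seed(77)
  for (r in 1:20) {
    y <- lsr_template_oracle(t, onset = runif(1, 6, 25),
                             slope = runif(1, 0.02, 0.08)) +
      rnorm(length(t), 0, 0.08)
    f <- fit_sweat_onset(t, y)
    o <- seg_oracle(t, y)
    expect_equal(f$breakpoint, o$t0)
    expect_equal(f$sensitivity, unname(o$b), tolerance = 1e-8)
    expect_equal(f$sse, o$sse, tolerance = 1e-8)
  }
})

test_that("onset threshold is referenced against the core-temperature trace", {
  t <- seq(0, 45, by = 1 / 12)
  f <- fit_sweat_onset(t, lsr_template_oracle(t, onset = 9))
  # Tgi linear 37 -> 38 over 0-45: interpolation at 9 min gives 37.2
  tg_t <- seq(0, 45, by = 0.25)
  tg <- 37 + tg_t / 45
  expect_equal(onset_tgi(f, tg_t, tg), 37.2)
  # breakpoint at a sample time returns that sample
  expect_equal(onset_tgi(f, c(0, 9, 45), c(37, 37.5, 38)), 37.5)
  # unconverged fit and uncovered breakpoint are contract errors
  fc <- fit_sweat_onset(t, rep(0.3, length(t)))
  expect_error(onset_tgi(fc, tg_t, tg), "converge")
  expect_error(onset_tgi(f, seq(20, 45), seq(37, 38, length.out = 26)),
               "outside")
})

test_that("whole-body sweat loss closes the mass balance", {
  # no change anywhere: zero sweat
  expect_equal(wbsl(57, 57, 1, 1, resp_loss_kg = 0)$wbsl_l, 0)
  # 0.80 kg nude loss, 0.02 kg respiratory water: 0.78 L of sweat
  expect_equal(wbsl(58.0, 57.2, 1.0, 1.0, resp_loss_kg = 0.02)$wbsl_l, 0.78)
  # sweat trapped in clothing with unchanged clothed mass still counts
  m <- wbsl(58.0, 58.0, 1.0, 1.1, resp_loss_kg = 0)
  expect_equal(m$wbsl_l, 0.1)
  expect_equal(m$trapped_in_clothing_kg, 0.1)
  # invariance to redistribution between evaporated and trapped sweat:
  # moving d kg of sweat into the clothing raises both clothed and clothing
  # post masses by d and leaves WBSL unchanged
  base <- wbsl(58.0, 57.2, 1.0, 1.0, fluid_intake_kg = 0.2,
               resp_loss_kg = 0.02)
  for (d in c(0.05, 0.1, 0.3)) {
    moved <- wbsl(58.0, 57.2 + d, 1.0, 1.0 + d, fluid_intake_kg = 0.2,
                  resp_loss_kg = 0.02)
    expect_equal(moved$wbsl_l, base$wbsl_l)
  }
  # respiratory term can come from the heat balance
  hb <- heat_balance(56.84, 1.70, 40, 30, 0.3, 36.3,
                     m_w = metabolic_rate(2.06, 0.9), wext_w = 96.4)
  m2 <- wbsl(58.0, 57.2, 1.0, 1.0, heat_balance = hb, duration_min = 45)
  expect_equal(m2$resp_loss_kg, hb$resp_mass_loss_g_s * 60 * 45 / 1000)
  # contract violations
  expect_error(wbsl(58, 57.2, 1.0, 0.9, resp_loss_kg = 0), "clothing")
  expect_warning(wbsl(57.0, 57.2, 1.0, 1.0, resp_loss_kg = 0), "negative")
})
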