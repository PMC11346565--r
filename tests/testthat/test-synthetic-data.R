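test_that("cohort generation is deterministic and respects the effect structure", {
  cfg <- cohort_config(seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  # zero between-participant dispersion: every participant sits on the
  # population mean and the pre/post shift is exact
  cfg0 <- cohort_config(seed = 2,
                        between_participant_sd = c(resting_hr = 0),
                        true_effects = c(resting_hr = -7))
  coh <- generate_cohort(cfg0)
  tr <- coh$truth[coh$truth$outcome == "resting_hr", ]
  expect_equal(tr$true_post - tr$true_pre, rep(-7, 15))
  expect_equal(tr$true_pre, rep(80, 15))

  # pre/post shift is exact for every outcome even with dispersion
  d <- c1$truth$true_post - c1$truth$true_pre
  eff <- cfg$outcomes$effect[match(c1$truth$outcome, cfg$outcomes$outcome)]
  expect_equal(d, eff)
})

test_that("cohort anthropometry matches the configured distribution", {
  # Monte-Carlo: grand mean body mass over 1000 cohorts within 3 SE of the
  # configured 56.84 kg
  masses <- vapply(1:1000, function(s) {
    mean(generate_cohort(cohort_config(seed = s))$participants$mass_kg)
  }, numeric(1))
  se <- 9.05 / sqrt(1000 * 15)
  expect_lt(abs(mean(masses) - 56.84), 3 * se)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_female = 20), "n_female")
  expect_error(cohort_config(between_participant_sd = c(resting_hr = -1)),
               ">= 0")
  expect_error(cohort_config(true_effects = c(not_an_outcome = 1)), "named")
  expect_error(hrt_ground_truth(onset_time = 50), "onset_time")
  expect_error(hrt_ground_truth(onset_tgi = 30), "onset_tgi")
  expect_error(hrt_ground_truth(sweat_sensitivity = -1), "sensitivity")
})

test_that("heat-response-test series follow the deterministic templates", {
  s <- generate_hrt_series(hrt_ground_truth(), seed = 1)
  # noiseless: final Tgi is baseline + total rise exactly
  expect_equal(s$tgi$tgi_c[s$tgi$t_min == 45], 37.28 + 1.78)
  # Tgi passes through the onset point
  expect_equal(s$tgi$tgi_c[s$tgi$t_min == 10], 37.7)
  # rest is flat at baseline
  expect_true(all(s$tgi$tgi_c[s$tgi$t_min < 0] == 37.28))
  # determinism of the noisy trace
  tr <- hrt_ground_truth(noise_sd = list(tgi = 0.05, lsr = 0.03))
  expect_identical(generate_hrt_series(tr, seed = 9),
                   generate_hrt_series(tr, seed = 9))
  # physical ranges with realistic noise
  sn <- generate_hrt_series(hrt_ground_truth(noise_sd = list(
    tgi = 0.05, tsk = 0.1, hr = 2, lsr = 0.05)), seed = 3)
  expect_true(all(sn$tgi$tgi_c > 35 & sn$tgi$tgi_c < 41))
  expect_true(all(sn$hr$hr_bpm > 40 & sn$hr$hr_bpm < 220))
  expect_true(all(sn$capsules$back$rh_pct >= 0 & sn$capsules$back$rh_pct <= 100))
})

test_that("adding a signal's noise does not perturb the other signals", {
  quiet <- generate_hrt_series(hrt_ground_truth(), seed = 5)
  noisy_hr <- generate_hrt_series(hrt_ground_truth(noise_sd = list(hr = 5)),
                                  seed = 5)
  expect_identical(quiet$tgi, noisy_hr$tgi)
  expect_identical(quiet$capsules, noisy_hr$capsules)
  expect_false(identical(quiet$hr, noisy_hr$hr))
})

test_that("synthetic met years have the requested shape, ranges and season", {
  m1 <- generate_met_year(n_days = 1, seed = 1)
  expect_equal(nrow(m1), 24)
  m0 <- generate_met_year(n_days = 2, seed = 1,
                          config = list(annual_amp_c = 0, diurnal_amp_c = 0,
                                        noise_sd = 0))
  expect_equal(m0$dry_bulb_c, rep(13.5, 48))

  m <- generate_met_year(n_days = 365, seed = 7)
  expect_identical(m, generate_met_year(n_days = 365, seed = 7))
  expect_true(all(m$rh_pct >= 0 & m$rh_pct <= 100))
  expect_true(all(m$wind_ms >= 0))
  expect_true(all(m$cloud >= 0 & m$cloud <= 1))
  # austral seasonal phase: January daily maxima exceed June daily maxima
  mon <- as.POSIXlt(m$timestamp)$mon + 1
  day <- as.Date(m$timestamp)
  dmax <- tapply(m$dry_bulb_c, day, max)
  dmon <- as.POSIXlt(as.Date(names(dmax)))$mon + 1
  expect_gt(mean(dmax[dmon == 1]), mean(dmax[dmon == 6]))
})

test_that("CO-rebreathing forward model inverts exactly and doses correctly", {
  rec <- generate_co_rebreathe(690, 5000, 56.84)
  expect_equal(rec$co_admin_ml, 0.8 * 56.84)  # 45.5 mL
  expect_equal(as.numeric(hb_mass_from_rebreathe(rec)), 690)
  # duplicate noisy records reproduce the configured typical error
  pairs <- vapply(1:1000, function(s) {
    r1 <- generate_co_rebreathe(690, 5000, 56.84, seed = 2 * s, noise_cv = 0.017)
    r2 <- generate_co_rebreathe(690, 5000, 56.84, seed = 2 * s + 1,
                                noise_cv = 0.017)
    c(hb_mass_from_rebreathe(r1), hb_mass_from_rebreathe(r2))
  }, numeric(2))
  te <- typical_error(pairs[1, ], pairs[2, ])
  expect_lt(abs(te - 1.7), 0.2)
})

test_that("activity weeks hit the requested outdoor volume and timing", {
  wk <- generate_activity_week(7, seed = 1)
  expect_equal(sum(wk$diary$duration_h), 7)
  expect_true(all(wk$diary$rpe >= 0 & wk$diary$rpe <= 10))
  # 60-s epochs, 7 days
  expect_equal(nrow(wk$epochs), 7 * 1440)
  expect_equal(unique(diff(as.numeric(wk$epochs$timestamp))), 60)

  # all-sedentary week: nothing reaches the MVPA cutpoint
  sed <- generate_activity_week(6, intensity_mix = c(light = 1, moderate = 0,
                                                     high = 0), seed = 2)
  expect_equal(mvpa_from_counts(sed$epochs)$mvpa_h_per_day, 0)

  # afternoon placement: with 49% of bouts at 15:00-18:00 that bin is the
  # histogram mode
  big <- generate_activity_week(20, seed = 3)
  hs <- diary_summary(big$diary)$tod_hist
  expect_equal(names(which.max(hs)), "15:00-18:00")
})
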