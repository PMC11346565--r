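test_that("solar irradiance obeys geometry and cloud attenuation", {
  noon <- as.POSIXct("2023-03-21 12:00:00", tz = "UTC")
  # overhead sun at the equator on the equinox: ~1367 * 0.75
  expect_equal(solar_irradiance(noon, 0, 0, 0, tz_offset_hours = 0),
               1367 * 0.75, tolerance = 0.01)
  midnight <- as.POSIXct("2023-03-21 00:00:00", tz = "UTC")
  expect_equal(solar_irradiance(midnight, 0, 0, 0, tz_offset_hours = 0), 0)
  # clouds only attenuate
  expect_lt(solar_irradiance(noon, 0, 0, 1, 0),
            solar_irradiance(noon, 0, 0, 0, 0))
  expect_equal(solar_irradiance(noon, 0, 0, 1, 0) /
                 solar_irradiance(noon, 0, 0, 0, 0), 0.25)
  # symmetric about solar noon (date chosen with ~zero equation of time)
  d <- as.POSIXct("2023-09-01 12:00:00", tz = "UTC")
  for (h in c(1, 3, 5)) {
    expect_equal(solar_irradiance(d - h * 3600, 0, 0, 0, 0),
                 solar_irradiance(d + h * 3600, 0, 0, 0, 0), tolerance = 0.05)
  }
  expect_error(solar_irradiance(noon, 0, 0, 2), "cloud")
})

test_that("globe temperature solves its energy balance", {
  # no radiative load, strong wind: globe sits at air temperature
  expect_equal(globe_temp(30, 5, 0), 30, tolerance = 0.2)
  # any solar load heats the globe above air temperature
  expect_gt(globe_temp(30, 1, 800), 30)
  # independent root-finder on the same balance agrees within 0.5 degC
  oracle_tg <- function(ta, v, s) {
    sigma <- 5.67e-8
    re <- max(v, 0.1) * 0.15 / 1.5e-5
    h <- (2 + 0.6 * sqrt(re) * 0.71^(1 / 3)) * 0.026 / 0.15
    ta_k <- ta + 273.15
    f <- function(tg) 0.95 * s / 4 - h * (tg - ta_k) -
      0.95 * sigma * (tg^4 - ta_k^4)
    uniroot(f, c(ta_k - 1, ta_k + 60), tol = 1e-6)$root - 273.15
  }
  for (case in list(c(30, 1, 800), c(22, 0.5, 400), c(38, 2, 1000))) {
    expect_equal(globe_temp(case[1], case[2], case[3]),
                 oracle_tg(case[1], case[2], case[3]), tolerance = 0.5)
  }
})

test_that("natural wet bulb respects its physical limits", {
  # saturated air without sun: wick sits at the dry bulb
  expect_equal(natural_wet_bulb(25, 100, 1, 0), 25, tolerance = 0.1)
  # without sun the wick stays close to the aspirated psychrometric wet bulb
  for (case in list(c(25, 50, 1), c(30, 40, 2), c(20, 70, 1.5))) {
    expect_equal(natural_wet_bulb(case[1], case[2], case[3], 0),
                 psychrometric_wet_bulb(case[1], case[2]), tolerance = 0.5)
  }
  # more humidity, warmer wick
  tnw <- natural_wet_bulb(rep(30, 5), c(20, 40, 60, 80, 100), 1, 300)
  expect_true(all(diff(tnw) > -1e-9))
  # always between the psychrometric wet bulb and the dry bulb
  set.seed(31)
  ta <- runif(200, 0, 45); rh <- runif(200, 5, 100)
  v <- runif(200, 0.1, 8); s <- runif(200, 0, 1100)
  x <- natural_wet_bulb(ta, rh, v, s)
  expect_true(all(x <= ta + 1e-6))
  expect_true(all(x >= psychrometric_wet_bulb(ta, rh) - 1e-6))
})

test_that("the WBGT index is the 0.7/0.2/0.1 weighting", {
  expect_equal(wbgt(25, 25, 25), 25)
  expect_equal(wbgt(18, 34, 24), 21.8)
  # weights sum to one: shift equivariance
  expect_equal(wbgt(18 + 1, 34 + 1, 24 + 1), wbgt(18, 34, 24) + 1)
})

test_that("daytime summaries window, average and drop days correctly", {
  ts <- seq(as.POSIXct("2023-01-01 00:00", tz = "UTC"),
            by = "hour", length.out = 72)
  # constant series
  ds <- daytime_summary(ts, rep(21.2, 72))
  expect_equal(ds$period_mean, 21.2)
  expect_equal(ds$period_sd, 0)
  # sinusoidal series: daytime mean equals the discrete average of the
  # sinusoid over hours 08..17, computed independently here
  hr <- as.POSIXlt(ts)$hour
  v <- 25 + 5 * cos(2 * pi * (hr - 14) / 24)
  ds2 <- daytime_summary(ts, v)
  expect_equal(ds2$period_mean, mean(25 + 5 * cos(2 * pi * (8:17 - 14) / 24)),
               tolerance = 1e-10)
  expect_equal(ds2$period_max_mean, max(25 + 5 * cos(2 * pi * (8:17 - 14) / 24)))
  # a day with only 4 daytime hours is dropped and reported
  v3 <- rep(20, 72)
  v3[hr >= 12 & seq_along(v3) <= 24] <- NA  # first day keeps 08:00-11:00 only
  ds3 <- daytime_summary(ts, v3)
  expect_equal(length(ds3$dropped_days), 1)
  expect_equal(nrow(ds3$daily), 2)
  expect_error(daytime_summary(ts, rep(NA_real_, 72)), "window")
})

test_that("MVPA classification counts epochs above the cutpoint on wear days", {
  day0 <- as.POSIXct("2023-01-02 00:00", tz = "UTC")
  ts <- day0 + 60 * (0:(1440 - 1))
  vm <- rep(0, 1440)
  vm[300:419] <- 3000  # 120 epochs of MVPA, rest zero
  ep <- data.frame(timestamp = ts, vm = vm)
  res <- mvpa_from_counts(ep)
  expect_equal(res$mvpa_h_per_day, 2)
  # a fully zero day is non-wear and contributes no wear day
  ep0 <- data.frame(timestamp = ts, vm = 0)
  res0 <- mvpa_from_counts(ep0)
  expect_true(res0$daily$nonwear_day)
  expect_equal(res0$mvpa_h_per_day, 0)
  # raising the cutpoint never increases MVPA
  set.seed(41)
  ep2 <- data.frame(timestamp = ts, vm = pmax(rnorm(1440, 2500, 1500), 0))
  h <- vapply(c(1952, 2690, 3500), function(cp) {
    mvpa_from_counts(ep2, cutpoint_cpm = cp)$mvpa_h_per_day
  }, numeric(1))
  expect_true(all(diff(h) <= 0))
  # triaxial input uses the vector magnitude
  ep3 <- data.frame(timestamp = ts[1:120], axis1 = 3000, axis2 = 0, axis3 = 0)
  expect_equal(mvpa_from_counts(ep3)$daily$mvpa_min, 120L)
  expect_error(mvpa_from_counts(data.frame(timestamp = ts[c(1, 3)], vm = 0)),
               "60-s")
})

test_that("diary summaries categorize by RPE band and histogram by start time", {
  day0 <- as.POSIXct("2023-01-02 00:00", tz = "UTC")
  d <- data.frame(
    start_time = day0 + c(16, 6, 16, 10) * 3600,
    duration_h = c(2, 1, 3, 1.4),
    location = c("outdoor", "outdoor", "outdoor", "indoor"),
    rpe = c(5, 2, 8, 3))
  s <- diary_summary(d)
  expect_equal(as.numeric(s$by_intensity),
               c(1, 2, 3))  # light, moderate, high outdoor hours
  expect_equal(unname(s$by_location["outdoor"]), 6)
  expect_equal(s$total_h, 7.4)
  expect_equal(unname(s$tod_hist[["15:00-18:00"]]), 5)
  # out-of-range RPE rows are rejected, not silently kept
  d_bad <- rbind(d, data.frame(start_time = day0, duration_h = 1,
                               location = "outdoor", rpe = 12))
  s2 <- diary_summary(d_bad)
  expect_equal(s2$rejected, 5L)
  expect_equal(s2$total_h, 7.4)
  expect_error(diary_summary(transform(d, duration_h = -1)), "negative")
})
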