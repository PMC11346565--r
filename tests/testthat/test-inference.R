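test_that("the hierarchical model recovers a noiseless period effect", {
  coh <- generate_cohort(cohort_config(
    seed = 3, within_participant_sd = c(resting_hr = 0.01),
    true_effects = c(resting_hr = -7)))
  tab <- simulate_outcome_table(coh, "resting_hr")
  fit <- suppressWarnings(
    fit_hier_linear(tab, chains = 2, iter = 800, warmup = 300, seed = 1))
  expect_lt(abs(mean(fit$draws[, "b1"]) - (-7)), 0.05)
})

test_that("row order does not affect the posterior under a fixed seed", {
  coh <- generate_cohort(cohort_config(seed = 4))
  tab <- simulate_outcome_table(coh, "resting_tgi")
  f1 <- suppressWarnings(
    fit_hier_linear(tab, chains = 2, iter = 400, warmup = 200, seed = 2))
  set.seed(123)
  f2 <- suppressWarnings(
    fit_hier_linear(tab[sample(nrow(tab)), ], chains = 2, iter = 400,
                    warmup = 200, seed = 2))
  expect_identical(f1$draws, f2$draws)
})

test_that("non-identifiable designs are rejected", {
  coh <- generate_cohort(cohort_config(seed = 5))
  tab <- simulate_outcome_table(coh, "resting_hr")
  expect_error(fit_hier_linear(tab[tab$period == "pre", ]), "both periods")
  tiny <- tab[tab$participant == "P01", ]
  expect_error(fit_hier_linear(tiny), "2 participants")
  expect_error(fit_hier_linear(data.frame(participant = 1, period = "mid",
                                          y = 1)), "pre")
})

test_that("the Gibbs sampler matches a brute-force grid posterior", {
  yp <- c(80.5, 77.9, 83.0)
  yq <- c(73.2, 71.5, 76.8)
  dat <- data.frame(participant = rep(c("A", "B", "C"), 2),
                    period = rep(c("pre", "post"), each = 3),
                    y = c(yp, yq))
  fit <- suppressWarnings(
    fit_hier_linear(dat, chains = 4, iter = 2500, warmup = 500, seed = 5))
  b1_gibbs <- mean(fit$draws[, "b1"])
  b1_grid <- grid_posterior_b1(yp, yq)
  expect_lt(abs(b1_gibbs - b1_grid) / abs(b1_grid), 0.01)
})

test_that("posterior summaries report mean, equal-tailed CrI and Pd", {
  # degenerate: all draws equal
  s <- summarize_posterior(rep(2.5, 2000))
  expect_equal(s$mean, 2.5)
  expect_equal(c(s$ci_low, s$ci_high), c(2.5, 2.5))
  expect_equal(s$pd, 100)
  # standard normal draws: CrI ~ [-1.645, 1.645], Pd ~ 50
  set.seed(7)
  z <- rnorm(1e6)
  s2 <- summarize_posterior(z)
  expect_equal(s2$ci_low, qnorm(0.05), tolerance = 0.01)
  expect_equal(s2$ci_high, qnorm(0.95), tolerance = 0.01)
  expect_lt(abs(s2$pd - 50), 0.5)
  # shifted normal mirroring a published rise-in-core-temperature posterior
  d <- rnorm(1e6, -0.22, 0.158)
  expect_equal(summarize_posterior(d)$pd, 100 * pnorm(0.22 / 0.158),
               tolerance = 0.1)
  expect_error(summarize_posterior(rnorm(100)), "1000")
})

test_that("draw-based and interval-based Pd agree on normal posteriors", {
  set.seed(8)
  for (m in c(-0.22, 0.1, 1.5)) {
    d <- rnorm(2e5, m, 0.3)
    s <- summarize_posterior(d)
    pd_i <- pd_from_interval(s$mean, s$ci_low, s$ci_high)
    expect_lt(abs(s$pd - pd_i), 1)
  }
})

test_that("credible intervals nest across levels", {
  set.seed(9)
  d <- rnorm(5e4, 1, 2)
  s90 <- summarize_posterior(d, level = 0.90)
  s95 <- summarize_posterior(d, level = 0.95)
  expect_lt(s95$ci_low, s90$ci_low)
  expect_gt(s95$ci_high, s90$ci_high)
})

test_that("interval-based Pd reproduces published worked examples", {
  expect_equal(round(pd_from_interval(-0.22, -0.48, 0.04)), 92)
  expect_equal(round(pd_from_interval(-0.2, -0.5, 0.1)), 86)
  expect_equal(round(pd_from_interval(-0.01, -0.02, 0.00)), 95)
  expect_error(pd_from_interval(0, 1, 1), "degenerate")
})

test_that("penalized-spline time courses recover known curves", {
  set.seed(10)
  tt <- seq(0, 45, by = 5)
  dat <- expand.grid(participant = sprintf("P%02d", 1:10), period = "pre",
                     time = tt, stringsAsFactors = FALSE)
  f_true <- function(t) 37 + 0.002 * t^2
  dat$y <- f_true(dat$time) + rnorm(nrow(dat), 0, 0.1)
  dat2 <- rbind(dat, transform(dat, period = "post"))
  fit <- fit_timecourse(dat2, k = 6, chains = 2, iter = 800, warmup = 250,
                        seed = 2)
  # fitted curve within 2 posterior SDs of the truth everywhere
  pre <- fit$curves[fit$curves$period == "pre", ]
  sd_hat <- (pre$ci_high - pre$ci_low) / (2 * qnorm(0.95))
  expect_true(all(abs(pre$mean - f_true(pre$time)) < 2 * sd_hat + 0.05))
  # identical pre and post data: the contrast band covers 0 everywhere
  expect_true(all(fit$contrast$ci_low <= 0 & fit$contrast$ci_high >= 0))
  # constant data: flat fit
  dat3 <- dat2
  dat3$y <- 37
  fit3 <- fit_timecourse(dat3, k = 6, chains = 1, iter = 400, warmup = 150,
                         seed = 3)
  expect_lt(diff(range(fit3$curves$mean)), 1e-6)
  # a basis larger than the number of distinct times is rejected
  expect_error(fit_timecourse(dat2, k = 30), "basis size")
  expect_error(fit_timecourse(dat2[dat2$time < 20, ], k = 4), "5 distinct")
})

test_that("a genuine pre/post difference shows in the timecourse contrast", {
  set.seed(11)
  tt <- seq(0, 45, by = 5)
  dat <- expand.grid(participant = sprintf("P%02d", 1:10),
                     period = c("pre", "post"), time = tt,
                     stringsAsFactors = FALSE)
  shift <- ifelse(dat$period == "post", -0.4, 0)
  dat$y <- 37 + 1.8 * (1 - exp(-dat$time / 15)) + shift +
    rnorm(nrow(dat), 0, 0.15)
  fit <- fit_timecourse(dat, k = 6, chains = 2, iter = 800, warmup = 250,
                        seed = 4)
  mid <- fit$contrast[fit$contrast$time > 10, ]
  expect_true(mean(mid$ci_high < 0) > 0.8)  # clearly negative contrast
  expect_lt(abs(mean(mid$mean) - (-0.4)), 0.15)
})
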