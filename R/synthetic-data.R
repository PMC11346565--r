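# Synthetic-data generators with known ground truth. These define the study
# conditions every downstream stage is tested against: a 15-participant
# (5 female) cohort measured pre and post summer, 45-min uncompensable
# heat-response-test bouts, CO-rebreathing records, an austral-summer
# meteorological year, and activity diaries with accelerometer epochs.

# deterministic per-signal seed derivation (Lehmer step plus offset) so that
# adding one signal never perturbs the draws of another
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx) %% 2147483647)
}

#' Cohort configuration for the synthetic study
#'
#' Defaults parameterise a cohort of 15 active adolescents (5 female) with
#' the anthropometry and outcome structure of a seasonal heat-acclimatization
#' study: body mass 56.84 +/- 9.05 kg, height 1.70 +/- 0.08 m, VO2peak
#' 60.4 mL/kg/min. Each outcome has a pre-summer population mean, a true
#' pre-to-post shift, a between-participant SD (participant intercepts) and a
#' within-participant residual SD.
#'
#' @param n_participants Cohort size (default 15).
#' @param n_female Number of female participants (default 5).
#' @param seed Integer seed; fully determines all generated data.
#' @param true_effects Named numeric overrides of the per-outcome pre/post
#'   shifts, in the outcome's units.
#' @param between_participant_sd,within_participant_sd Named numeric
#'   overrides of the per-outcome dispersions (must be >= 0).
#' @param vo2peak_mean,vo2peak_sd VO2peak distribution, mL/kg/min.
#' @param mass_mean,mass_sd,height_mean,height_sd Anthropometry.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 15, n_female = 5, seed = 1,
                          true_effects = NULL, between_participant_sd = NULL,
                          within_participant_sd = NULL,
                          vo2peak_mean = 60.4, vo2peak_sd = 9.9,
                          mass_mean = 56.84, mass_sd = 9.05,
                          height_mean = 1.70, height_sd = 0.08) {
  if (n_participants < 2 || n_female < 0 || n_female > n_participants) {
    stop("need n_participants >= 2 and 0 <= n_female <= n_participants",
         call. = FALSE)
  }
  outcomes <- data.frame(
    outcome = c("resting_tgi", "resting_hr", "rise_tgi", "end_tgi",
                "wbsl", "hb_mass_g_kg"),
    baseline_mean = c(37.28, 80, 1.78, 38.95, 0.78, 11.6),
    effect = c(-0.19, -7, -0.22, -0.35, 0.03, 0.3),
    between_sd = c(0.20, 10, 0.35, 0.40, 0.20, 1.2),
    within_sd = c(0.20, 6, 0.43, 0.47, 0.15, 1.5),
    stringsAsFactors = FALSE)
  apply_override <- function(col, ov, nonneg = FALSE) {
    if (is.null(ov)) return()
    if (is.null(names(ov)) || !all(names(ov) %in% outcomes$outcome)) {
      stop("overrides must be named after known outcomes", call. = FALSE)
    }
    if (nonneg && any(ov < 0)) stop("dispersions must be >= 0", call. = FALSE)
    outcomes[match(names(ov), outcomes$outcome), col] <<- unname(ov)
  }
  apply_override("effect", true_effects)
  apply_override("between_sd", between_participant_sd, nonneg = TRUE)
  apply_override("within_sd", within_participant_sd, nonneg = TRUE)
  if (any(c(vo2peak_sd, mass_sd, height_sd) < 0)) {
    stop("dispersions must be >= 0", call. = FALSE)
  }
  structure(list(n_participants = n_participants, n_female = n_female,
                 seed = as.integer(seed), outcomes = outcomes,
                 vo2peak_mean = vo2peak_mean, vo2peak_sd = vo2peak_sd,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 height_mean = height_mean, height_sd = height_sd),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a participant roster (sex, mass, height, VO2peak) and, per outcome,
#' the true pre and post values: participant intercept (population mean plus
#' a between-participant normal deviate) plus the period shift for post.
#' No within-participant noise is included here; observed measurements are
#' drawn by [simulate_outcome_table()].
#'
#' @param config A [cohort_config()].
#' @return List of class `cohort`: `participants` data frame (id, sex,
#'   mass_kg, height_m, vo2peak), `truth` long data frame (id, outcome,
#'   true_pre, true_post) and the config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config",
                                               call. = FALSE)
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_participants
  participants <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    sex = c(rep("F", config$n_female), rep("M", n - config$n_female)),
    mass_kg = stats::rnorm(n, config$mass_mean, config$mass_sd),
    height_m = stats::rnorm(n, config$height_mean, config$height_sd),
    vo2peak = stats::rnorm(n, config$vo2peak_mean, config$vo2peak_sd),
    stringsAsFactors = FALSE)
  oc <- config$outcomes
  truth <- do.call(rbind, lapply(seq_len(nrow(oc)), function(j) {
    set.seed(derive_seed(config$seed, 100 + j))
    u <- stats::rnorm(n, 0, oc$between_sd[j])
    data.frame(id = participants$id, outcome = oc$outcome[j],
               true_pre = oc$baseline_mean[j] + u,
               true_post = oc$baseline_mean[j] + u + oc$effect[j],
               stringsAsFactors = FALSE)
  }))
  structure(list(participants = participants, truth = truth, config = config),
            class = "cohort")
}

#' Observed pre/post measurements for one outcome
#'
#' Adds within-participant residual noise to the cohort's true values,
#' yielding the tidy outcome table the hierarchical model consumes.
#'
#' @param cohort A [generate_cohort()] result.
#' @param outcome Outcome name (one of the config's outcomes).
#' @param seed Optional seed; defaults to one derived from the cohort seed
#'   and the outcome.
#' @return Data frame (participant, period, y, vo2peak) with one row per
#'   participant and period.
#' @export
simulate_outcome_table <- function(cohort, outcome, seed = NULL) {
  oc <- cohort$config$outcomes
  j <- match(outcome, oc$outcome)
  if (is.na(j)) stop("unknown outcome: ", outcome, call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(cohort$config$seed, 200 + j)
  set.seed(seed)
  tr <- cohort$truth[cohort$truth$outcome == outcome, ]
  n <- nrow(tr)
  sw <- oc$within_sd[j]
  data.frame(
    participant = rep(tr$id, 2),
    period = rep(c("pre", "post"), each = n),
    y = c(tr$true_pre + stats::rnorm(n, 0, sw),
          tr$true_post + stats::rnorm(n, 0, sw)),
    vo2peak = rep(cohort$participants$vo2peak, 2),
    stringsAsFactors = FALSE)
}

#' Ground truth for one synthetic heat-response-test visit
#'
#' The deterministic templates: core temperature rests at `tgi_baseline`,
#' then rises along an exponential-saturating curve normalised to reach
#' `tgi_baseline + tgi_rise_total` exactly at 45 min, with the rate solved
#' so the curve passes through `onset_tgi` at `onset_time`. Local sweat rate
#' is flat at `lsr_baseline` until `onset_time`, then linear with slope
#' `sweat_sensitivity`, capped at `lsr_plateau`. Skin temperature saturates
#' toward `tsk_plateau`; heart rate toward `hr_baseline + hr_rise`.
#'
#' @param tgi_baseline,tgi_rise_total Core temperature start (degC) and
#'   total 45-min rise (degC).
#' @param tsk_plateau Exercising mean skin temperature plateau, degC.
#' @param hr_baseline,hr_rise Heart-rate start and rise, bpm.
#' @param onset_time Sweating onset, min; must lie in (0, 45).
#' @param onset_tgi Core temperature at the sweating onset, degC; must be
#'   reachable by the concave template (at least the chord value
#'   `tgi_baseline + tgi_rise_total * onset_time / 45`).
#' @param sweat_sensitivity Post-onset LSR slope, mg cm^-2 min^-1 per min.
#' @param lsr_baseline,lsr_plateau LSR before onset and cap, mg cm^-2 min^-1.
#' @param noise_sd Named list of per-signal noise SDs:
#'   `tgi` (degC), `tsk` (degC), `hr` (bpm), `lsr` (mg cm^-2 min^-1).
#' @return List of class `hrt_ground_truth`.
#' @export
hrt_ground_truth <- function(tgi_baseline = 37.28, tgi_rise_total = 1.78,
                             tsk_plateau = 36.3, hr_baseline = 90,
                             hr_rise = 97, onset_time = 10, onset_tgi = 37.7,
                             sweat_sensitivity = 0.05, lsr_baseline = 0.10,
                             lsr_plateau = 2.0,
                             noise_sd = list(tgi = 0, tsk = 0, hr = 0, lsr = 0)) {
  if (onset_time <= 0 || onset_time >= 45) {
    stop("onset_time must lie in (0, 45) min", call. = FALSE)
  }
  if (sweat_sensitivity < 0) stop("sweat_sensitivity must be >= 0", call. = FALSE)
  ns <- list(tgi = 0, tsk = 0, hr = 0, lsr = 0)
  ns[names(noise_sd)] <- noise_sd
  if (any(unlist(ns) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  chord <- tgi_baseline + tgi_rise_total * onset_time / 45
  if (onset_tgi < chord - 1e-9 || onset_tgi >= tgi_baseline + tgi_rise_total) {
    stop(sprintf("onset_tgi must lie in [%.3f, %.3f) for a saturating template",
                 chord, tgi_baseline + tgi_rise_total), call. = FALSE)
  }
  structure(list(tgi_baseline = tgi_baseline, tgi_rise_total = tgi_rise_total,
                 tsk_plateau = tsk_plateau, hr_baseline = hr_baseline,
                 hr_rise = hr_rise, onset_time = onset_time,
                 onset_tgi = onset_tgi, sweat_sensitivity = sweat_sensitivity,
                 lsr_baseline = lsr_baseline, lsr_plateau = lsr_plateau,
                 noise_sd = ns),
            class = "hrt_ground_truth")
}

# saturating rise fraction f(t) = (1 - exp(-k t)) / (1 - exp(-k * 45)),
# with k solved so the curve passes through the onset point
tgi_template <- function(truth) {
  target <- (truth$onset_tgi - truth$tgi_baseline) / truth$tgi_rise_total
  frac <- function(k, t) (1 - exp(-k * t)) / (1 - exp(-k * 45))
  f <- function(k) frac(k, truth$onset_time) - target
  k <- if (abs(f(1e-8)) < 1e-9) 1e-8 else {
    stats::uniroot(f, lower = 1e-8, upper = 5, tol = 1e-10)$root
  }
  function(t) {
    ifelse(t < 0, truth$tgi_baseline,
           truth$tgi_baseline + truth$tgi_rise_total * frac(k, pmin(t, 45)))
  }
}

lsr_template <- function(truth) {
  function(t) {
    pmin(truth$lsr_baseline +
           truth$sweat_sensitivity * pmax(t - truth$onset_time, 0),
         truth$lsr_plateau)
  }
}

#' Generate one synthetic heat-response-test series
#'
#' Produces the synchronized signals of one participant-visit: core
#' temperature at 15-s cadence (10 min rest, 45 min exercise), four-site
#' skin temperatures at 1 min, heart rate at 5 min, and two ventilated
#' capsules' effluent humidity/temperature at 5 s. Capsule humidity is
#' written so that [lsr_from_hygrometry()] recovers the LSR template (plus
#' any injected noise) exactly: the generator inverts the same psychrometric
#' relation the analysis applies. Each signal draws from its own seeded
#' stream, so adding a signal does not perturb the others.
#'
#' @param truth A [hrt_ground_truth()].
#' @param seed Integer seed.
#' @param capsule A [capsule_config()] shared by both sites.
#' @param effluent_temp_c Capsule effluent air temperature, degC.
#' @return List of class `hrt_series` with data frames `tgi` (t_min, tgi_c),
#'   `tsk` (t_min plus four site columns), `hr` (t_min, hr_bpm), a
#'   `capsules` list (per site: t_min, rh_pct, temp_c), the `truth`, the
#'   capsule config, and chamber conditions.
#' @export
generate_hrt_series <- function(truth = hrt_ground_truth(), seed = 1,
                                capsule = capsule_config(),
                                effluent_temp_c = 34.5) {
  if (!inherits(truth, "hrt_ground_truth")) {
    stop("truth must be an hrt_ground_truth", call. = FALSE)
  }
  tgi_f <- tgi_template(truth)
  lsr_f <- lsr_template(truth)

  t_tgi <- seq(-10, 45, by = 0.25)
  set.seed(derive_seed(seed, 11))
  tgi <- data.frame(t_min = t_tgi,
                    tgi_c = tgi_f(t_tgi) +
                      stats::rnorm(length(t_tgi), 0, truth$noise_sd$tgi))

  t_tsk <- seq(-10, 45, by = 1)
  offs <- c(chest = 0.5, shoulder = 0.3, thigh = -0.6, calf = -0.6)
  tsk_rest <- 32.15
  base_curve <- ifelse(t_tsk < 0, tsk_rest,
                       tsk_rest + (truth$tsk_plateau - tsk_rest) *
                         (1 - exp(-t_tsk / 5)))
  set.seed(derive_seed(seed, 12))
  tsk <- data.frame(t_min = t_tsk)
  for (s in names(offs)) {
    tsk[[paste0("tsk_", s, "_c")]] <- base_curve + offs[[s]] +
      stats::rnorm(length(t_tsk), 0, truth$noise_sd$tsk)
  }

  t_hr <- seq(-10, 45, by = 5)
  hr_curve <- ifelse(t_hr < 0, truth$hr_baseline,
                     truth$hr_baseline + truth$hr_rise *
                       (1 - exp(-t_hr / 15)) / (1 - exp(-45 / 15)))
  set.seed(derive_seed(seed, 13))
  hr <- data.frame(t_min = t_hr,
                   hr_bpm = hr_curve +
                     stats::rnorm(length(t_hr), 0, truth$noise_sd$hr))

  t_cap <- seq(0, 45, by = 1 / (60 * capsule$sample_hz) ) # min between samples
  capsules <- list()
  for (i in seq_along(c("back", "forearm"))) {
    site <- c("back", "forearm")[i]
    set.seed(derive_seed(seed, 20 + i))
    lsr <- pmax(lsr_f(t_cap) +
                  stats::rnorm(length(t_cap), 0, truth$noise_sd$lsr), 0)
    rh <- pmin(pmax(rh_for_lsr(lsr, effluent_temp_c, capsule), 0), 100)
    capsules[[site]] <- data.frame(t_min = t_cap, rh_pct = rh,
                                   temp_c = effluent_temp_c)
  }

  structure(list(tgi = tgi, tsk = tsk, hr = hr, capsules = capsules,
                 truth = truth, capsule = capsule,
                 chamber = list(ta_c = 40, rh_pct = 30)),
            class = "hrt_series")
}

#' Generate an hourly synthetic meteorological year
#'
#' Sinusoidal seasonal and diurnal structure plus AR(1) noise, with relative
#' humidity anti-correlated with the temperature anomaly, non-negative wind,
#' and beta-distributed daily cloud fraction. Defaults emulate a temperate
#' austral site (Canberra-like: warmest mid-January, diurnal peak 15:00).
#'
#' @param lat,lon Site coordinates, decimal degrees (defaults -35.31, 149.12).
#' @param start_date Date (or string) of the first day.
#' @param n_days Number of days (>= 1).
#' @param seed Integer seed.
#' @param config Named overrides: `mean_c` (13.5), `annual_amp_c` (8.5),
#'   `diurnal_amp_c` (6.0), `noise_sd` (2.0), `ar1` (0.8), `peak_doy` (15),
#'   `peak_hour` (15), `rh_mean` (65), `rh_slope` (-2.2 %/degC anomaly),
#'   `wind_shape` (2), `wind_scale` (1.25), `cloud_a` (0.9), `cloud_b` (1.1).
#' @return Data frame with 24 * n_days rows: `timestamp` (local standard
#'   time), `dry_bulb_c`, `rh_pct`, `wind_ms`, `cloud`, `lat`, `lon`.
#' @export
generate_met_year <- function(lat = -35.31, lon = 149.12,
                              start_date = "2022-10-01", n_days = 365,
                              seed = 1, config = list()) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  k <- list(mean_c = 13.5, annual_amp_c = 8.5, diurnal_amp_c = 6.0,
            noise_sd = 2.0, ar1 = 0.8, peak_doy = 15, peak_hour = 15,
            rh_mean = 65, rh_slope = -2.2, wind_shape = 2, wind_scale = 1.25,
            cloud_a = 0.9, cloud_b = 1.1)
  k[names(config)] <- config
  n <- 24 * n_days
  ts <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n) - 1)
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1
  hour <- lt$hour

  seasonal <- k$annual_amp_c * cos(2 * pi * (doy - k$peak_doy) / 365.25)
  diurnal <- k$diurnal_amp_c * cos(2 * pi * (hour - k$peak_hour) / 24)
  set.seed(derive_seed(seed, 31))
  eps <- stats::rnorm(n, 0, k$noise_sd * sqrt(1 - k$ar1^2))
  noise <- as.numeric(stats::filter(eps, k$ar1, method = "recursive"))
  anomaly <- diurnal + noise
  tdb <- k$mean_c + seasonal + anomaly

  set.seed(derive_seed(seed, 32))
  rh <- pmin(pmax(k$rh_mean + k$rh_slope * anomaly + stats::rnorm(n, 0, 6),
                  5), 100)
  set.seed(derive_seed(seed, 33))
  wind <- stats::rgamma(n, shape = k$wind_shape, scale = k$wind_scale)
  set.seed(derive_seed(seed, 34))
  cloud_day <- stats::rbeta(n_days, k$cloud_a, k$cloud_b)
  cloud <- pmin(pmax(rep(cloud_day, each = 24) + stats::rnorm(n, 0, 0.05),
                     0), 1)

  data.frame(timestamp = ts, dry_bulb_c = tdb, rh_pct = rh, wind_ms = wind,
             cloud = cloud, lat = lat, lon = lon)
}

#' Generate a CO-rebreathing record with known truth
#'
#' Forward model of the CO-rebreathing procedure, constructed as the exact
#' inverse of [hb_mass_from_rebreathe()] in the noiseless limit: the
#' administered dose is 0.8 mL CO per kg body mass, a fixed fraction goes
#' unabsorbed, and the carboxyhemoglobin rise is the absorbed dose diluted
#' into the true hemoglobin mass. `noise_cv` perturbs the measured HbCO
#' rise multiplicatively, emulating analyser error.
#'
#' @param hb_mass_true_g True hemoglobin mass, g.
#' @param blood_volume_true_ml True blood volume, mL (sets the hemoglobin
#'   concentration on the record).
#' @param body_mass_kg Body mass, kg.
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @param hbco_pre_pct Baseline carboxyhemoglobin, percent.
#' @param unabsorbed_frac Fraction of the administered dose exhaled or left
#'   unabsorbed (default 0.03).
#' @param hct Hematocrit fraction on the record.
#' @param noise_cv Coefficient of variation of the measured HbCO rise
#'   (0 = noiseless).
#' @param huefner CO binding capacity used by the forward model, mL/g.
#' @return List (a rebreathing record) with fields `hbco_pre_pct`,
#'   `hbco_post_pct`, `hct`, `co_admin_ml`, `co_unabsorbed_ml`,
#'   `body_mass_kg`, `hb_conc_g_dl`.
#' @export
generate_co_rebreathe <- function(hb_mass_true_g, blood_volume_true_ml,
                                  body_mass_kg, seed = 1, hbco_pre_pct = 0.8,
                                  unabsorbed_frac = 0.03, hct = 0.42,
                                  noise_cv = 0, huefner = 1.39) {
  if (any(c(hb_mass_true_g, blood_volume_true_ml, body_mass_kg) <= 0)) {
    stop("physiological inputs must be positive", call. = FALSE)
  }
  co_admin <- 0.8 * body_mass_kg
  co_unabs <- unabsorbed_frac * co_admin
  d_hbco <- (co_admin - co_unabs) * 100 / (hb_mass_true_g * huefner)
  if (noise_cv > 0) {
    set.seed(derive_seed(seed, 41))
    d_hbco <- d_hbco * (1 + stats::rnorm(1, 0, noise_cv))
  }
  list(hbco_pre_pct = hbco_pre_pct, hbco_post_pct = hbco_pre_pct + d_hbco,
       hct = hct, co_admin_ml = co_admin, co_unabsorbed_ml = co_unabs,
       body_mass_kg = body_mass_kg,
       hb_conc_g_dl = hb_mass_true_g / blood_volume_true_ml * 100)
}

#' Generate one week of activity diary and accelerometer epochs
#'
#' Builds outdoor activity bouts whose durations are rescaled to total
#' exactly `hours_outdoor_per_wk`, with start times placed so that 49% of
#' bouts begin between 15:00 and 18:00 and 28% between 05:00 and 08:00 (the
#' canonical after-school and early-morning windows), RPE drawn within the
#' band of each bout's intensity category, and a parallel 60-s triaxial
#' accelerometer record: low sub-cutpoint counts while awake and worn,
#' zeros overnight (non-wear), and intensity-dependent counts during bouts.
#'
#' @param hours_outdoor_per_wk Target outdoor activity, h/wk (>= 0).
#' @param intensity_mix Probabilities for (light, moderate, high) bouts;
#'   must sum to 1.
#' @param seed Integer seed.
#' @param start_date First day of the week.
#' @param afternoon_frac,morning_frac Fractions of bouts starting 15:00-18:00
#'   and 05:00-08:00.
#' @return List with `diary` (start_time, duration_h, location, rpe,
#'   intensity) and `epochs` (timestamp, axis1, axis2, axis3).
#' @export
generate_activity_week <- function(hours_outdoor_per_wk = 7.4,
                                   intensity_mix = c(light = 0.24,
                                                     moderate = 0.30,
                                                     high = 0.46),
                                   seed = 1, start_date = "2022-11-07",
                                   afternoon_frac = 0.49,
                                   morning_frac = 0.28) {
  if (hours_outdoor_per_wk < 0) stop("hours must be >= 0", call. = FALSE)
  if (abs(sum(intensity_mix) - 1) > 1e-8) {
    stop("intensity_mix must sum to 1", call. = FALSE)
  }
  set.seed(derive_seed(seed, 51))
  day0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")

  diary <- data.frame(start_time = day0[0], duration_h = numeric(0),
                      location = character(0), rpe = numeric(0),
                      intensity = character(0), stringsAsFactors = FALSE)
  if (hours_outdoor_per_wk > 0) {
    dur <- numeric(0)
    while (sum(dur) < hours_outdoor_per_wk) {
      dur <- c(dur, stats::rgamma(1, shape = 2, scale = 0.5))
    }
    dur <- dur * hours_outdoor_per_wk / sum(dur)  # exact weekly total
    nb <- length(dur)
    cat_lv <- c("light", "moderate", "high")
    category <- sample(cat_lv, nb, replace = TRUE, prob = intensity_mix)
    rpe_lo <- c(light = 1, moderate = 4, high = 7)
    rpe_hi <- c(light = 3, moderate = 6, high = 10)
    rpe <- mapply(function(cc) sample(rpe_lo[[cc]]:rpe_hi[[cc]], 1), category)
    slot <- sample(c("pm", "am", "other"), nb, replace = TRUE,
                   prob = c(afternoon_frac, morning_frac,
                            1 - afternoon_frac - morning_frac))
    start_hour <- ifelse(slot == "pm", stats::runif(nb, 15, 18 - 1e-3),
                  ifelse(slot == "am", stats::runif(nb, 5, 8 - 1e-3),
                         stats::runif(nb, 9, 14)))
    day <- sample(0:6, nb, replace = TRUE)
    diary <- data.frame(
      start_time = day0 + day * 86400 + round(start_hour * 3600),
      duration_h = dur, location = "outdoor", rpe = as.numeric(rpe),
      intensity = category, stringsAsFactors = FALSE)
    diary <- diary[order(diary$start_time), ]
    rownames(diary) <- NULL
  }

  # accelerometer: 7 days of 60-s epochs
  n_ep <- 7 * 1440
  ts <- day0 + 60 * (seq_len(n_ep) - 1)
  hour <- as.POSIXlt(ts)$hour
  awake <- hour >= 7 & hour < 22
  set.seed(derive_seed(seed, 52))
  base <- ifelse(awake, pmax(stats::rnorm(n_ep, 150, 80), 0), 0)
  vm_target <- base
  if (nrow(diary)) {
    lvl_mean <- c(light = 1000, moderate = 4000, high = 7000)
    lvl_sd <- c(light = 200, moderate = 500, high = 800)
    for (b in seq_len(nrow(diary))) {
      i0 <- as.integer(difftime(diary$start_time[b], day0, units = "mins")) + 1
      len <- max(1L, round(diary$duration_h[b] * 60))
      idx <- i0:min(i0 + len - 1, n_ep)
      cc <- diary$intensity[b]
      vm_target[idx] <- pmax(stats::rnorm(length(idx), lvl_mean[[cc]],
                                          lvl_sd[[cc]]), 0)
    }
  }
  # split the vector magnitude over three axes with fixed direction cosines
  w <- c(0.65, 0.55, 0.52); w <- w / sqrt(sum(w^2))
  epochs <- data.frame(timestamp = ts,
                       axis1 = vm_target * w[1],
                       axis2 = vm_target * w[2],
                       axis3 = vm_target * w[3])
  list(diary = diary, epochs = epochs)
}
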