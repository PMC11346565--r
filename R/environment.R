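# Outdoor WBGT reconstruction from standard meteorological records, plus
# activity-exposure summaries (accelerometer counts, activity diaries).

# solar geometry: fractional day angle, declination and equation of time
# (Spencer series), zenith angle from local standard time + longitude offset
solar_position <- function(timestamp, lat, lon, tz_offset_hours) {
  lt <- as.POSIXlt(timestamp)
  n <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi * (n - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot_min <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                       0.014615 * cos(2 * g) - 0.04089 * sin(2 * g))
  solar_hour <- hour + (lon - 15 * tz_offset_hours) * 4 / 60 + eot_min / 60
  ha <- (solar_hour - 12) * 15 * pi / 180
  phi <- lat * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  list(cos_zenith = cosz, declination = decl)
}

#' Solar irradiance on a horizontal surface
#'
#' Clear-sky global irradiance from solar-position geometry (solar constant
#' 1367 W/m^2, bulk atmospheric transmittance 0.75 per unit air mass,
#' air mass approximated by 1/cos(zenith)), attenuated by cloud cover with
#' the empirical factor `1 - 0.75 * cloud^3.4`. Zero when the sun is below
#' the horizon.
#'
#' @param timestamp POSIXct timestamps in local standard time; vectorised.
#' @param lat,lon Latitude/longitude in decimal degrees (south/west negative).
#' @param cloud Cloud fraction in \[0, 1\]; scalar or per-timestamp.
#' @param tz_offset_hours UTC offset of the local standard time the
#'   timestamps are expressed in; defaults to the longitude's nominal zone.
#' @return Global horizontal irradiance, W/m^2.
#' @export
solar_irradiance <- function(timestamp, lat, lon, cloud = 0,
                             tz_offset_hours = round(lon / 15)) {
  if (any(cloud < 0 | cloud > 1)) stop("cloud must lie in [0, 1]", call. = FALSE)
  sp <- solar_position(timestamp, lat, lon, tz_offset_hours)
  cz <- sp$cos_zenith
  s <- ifelse(cz > 0, 1367 * 0.75^(1 / pmax(cz, 1e-6)) * cz, 0)
  s * (1 - 0.75 * cloud^3.4)
}

#' Psychrometric (aspirated) wet-bulb temperature
#'
#' Thermodynamic wet-bulb from the psychrometer relation
#' `e = es(Tw) - A * P * (Ta - Tw)` with psychrometer coefficient
#' `A = 0.000662 K^-1`, solved by bisection. Used as the lower bound and
#' cross-check for the natural (unaspirated) wet bulb.
#'
#' @param ta_c Dry-bulb temperature, degC.
#' @param rh_pct Relative humidity, percent.
#' @param pressure_kpa Barometric pressure, kPa (default 101.325).
#' @return Wet-bulb temperature, degC; vectorised.
#' @export
psychrometric_wet_bulb <- function(ta_c, rh_pct, pressure_kpa = 101.325) {
  if (any(rh_pct < 0 | rh_pct > 100)) stop("rh_pct must lie in [0, 100]", call. = FALSE)
  e <- rh_pct / 100 * saturation_vapor_pressure(ta_c)
  mapply(function(ta, ea) {
    stats::uniroot(function(tw) {
      saturation_vapor_pressure(tw) - 0.000662 * pressure_kpa * (ta - tw) - ea
    }, lower = -20, upper = ta + 1e-9, tol = 1e-6)$root
  }, ta_c, e)
}

# transfer constants for the globe and wick energy balances; everything is
# overridable through the `constants` argument of the solvers
wbgt_constants <- function(overrides = list()) {
  k <- list(globe_diam_m = 0.150, globe_emissivity = 0.95,
            globe_absorptivity = 0.95,
            wick_diam_m = 0.007, wick_emissivity = 0.95,
            wick_solar_absorption = 0.15,  # absorptivity * geometry, lumped
            air_conductivity = 0.026, air_viscosity = 1.5e-5, prandtl = 0.71,
            pressure_kpa = 101.325, lambda_j_kg = 2.43e6, cp_air = 1005,
            min_wind = 0.1, tol_c = 0.01, max_iter = 100)
  k[names(overrides)] <- overrides
  k
}

# sphere convective coefficient (Ranz-Marshall) and cylinder coefficient
h_sphere <- function(wind, k) {
  re <- max(wind, k$min_wind) * k$globe_diam_m / k$air_viscosity
  nu <- 2 + 0.6 * sqrt(re) * k$prandtl^(1 / 3)
  nu * k$air_conductivity / k$globe_diam_m
}
h_cylinder <- function(wind, k) {
  re <- max(wind, k$min_wind) * k$wick_diam_m / k$air_viscosity
  nu <- 0.281 * re^0.6 * k$prandtl^0.44
  nu * k$air_conductivity / k$wick_diam_m
}

#' Black-globe temperature from meteorological inputs
#'
#' Solves the 150-mm black-globe energy balance - absorbed shortwave equals
#' convective plus longwave loss to surroundings at air temperature -
#' by damped Newton iteration to within `tol_c` (default 0.01 degC).
#' Absorbed shortwave is `absorptivity * S / 4` (the sphere's projected to
#' total area ratio); the convective coefficient uses the Ranz-Marshall
#' sphere correlation.
#'
#' @param ta_c Air temperature, degC.
#' @param wind_ms Wind speed, m/s (floored at 0.1 for free convection).
#' @param solar_wm2 Global horizontal irradiance, W/m^2.
#' @param constants Named overrides of [wbgt_constants()].
#' @return Globe temperature, degC; vectorised over inputs.
#' @export
globe_temp <- function(ta_c, wind_ms, solar_wm2, constants = list()) {
  k <- wbgt_constants(constants)
  sigma <- 5.67e-8
  mapply(function(ta, v, s) {
    h <- h_sphere(v, k)
    ta_k <- ta + 273.15
    absorbed <- k$globe_absorptivity * s / 4
    tg <- ta_k + absorbed / (h + 4 * k$globe_emissivity * sigma * ta_k^3)
    for (i in seq_len(k$max_iter)) {
      f <- absorbed - h * (tg - ta_k) - k$globe_emissivity * sigma * (tg^4 - ta_k^4)
      df <- -h - 4 * k$globe_emissivity * sigma * tg^3
      step <- f / df
      tg_new <- tg - step
      if (abs(tg_new - tg) < k$tol_c) return(tg_new - 273.15)
      tg <- tg_new
    }
    stop(sprintf("globe_temp did not converge (Ta=%.1f, v=%.2f, S=%.0f, last Tg=%.2f)",
                 ta, v, s, tg - 273.15), call. = FALSE)
  }, ta_c, wind_ms, solar_wm2)
}

#' Natural (unaspirated) wet-bulb temperature
#'
#' Solves the wetted-wick energy balance: convective and longwave heating
#' plus absorbed shortwave equal evaporative cooling, with the evaporative
#' term tied to convection through the psychrometer relation
#' `0.622 * lambda / (cp * P)`. The root is bracketed between the
#' psychrometric wet bulb and the dry bulb, to which the result is also
#' clamped (radiative loading cannot push a wet wick above air temperature
#' in this steady-state model, nor evaporation below the aspirated limit).
#'
#' @inheritParams globe_temp
#' @param rh_pct Relative humidity, percent.
#' @return Natural wet-bulb temperature, degC; vectorised.
#' @export
natural_wet_bulb <- function(ta_c, rh_pct, wind_ms, solar_wm2,
                             constants = list()) {
  k <- wbgt_constants(constants)
  sigma <- 5.67e-8
  k_psy <- 0.622 * k$lambda_j_kg / (k$cp_air * k$pressure_kpa * 1000)  # K/Pa
  tw_psy <- psychrometric_wet_bulb(ta_c, rh_pct, k$pressure_kpa)
  mapply(function(ta, rh, v, s, twp) {
    h <- h_cylinder(v, k)
    e <- rh / 100 * saturation_vapor_pressure(ta) * 1000  # Pa
    bal <- function(tnw) {
      evap <- h * k_psy * (saturation_vapor_pressure(tnw) * 1000 - e)
      h * (ta - tnw) +
        k$wick_emissivity * sigma * ((ta + 273.15)^4 - (tnw + 273.15)^4) +
        k$wick_solar_absorption * s - evap
    }
    lo <- twp; hi <- ta
    if (hi - lo < 1e-9) return(ta)          # saturated air: wick at dry bulb
    f_lo <- bal(lo); f_hi <- bal(hi)
    if (f_lo <= 0) return(twp)               # clamp at the aspirated limit
    if (f_hi >= 0) return(ta)                # clamp at the dry bulb
    r <- stats::uniroot(bal, lower = lo, upper = hi, tol = k$tol_c / 10,
                        maxiter = k$max_iter)
    if (abs(bal(r$root)) > 1e3) {
      stop("natural_wet_bulb did not converge", call. = FALSE)
    }
    r$root
  }, ta_c, rh_pct, wind_ms, solar_wm2, tw_psy)
}

#' Outdoor wet-bulb globe temperature
#'
#' The outdoor WBGT index `0.7 * Tnw + 0.2 * Tg + 0.1 * Tdb`.
#'
#' @param tnw_c Natural wet-bulb temperature, degC.
#' @param tg_c Black-globe temperature, degC.
#' @param tdb_c Dry-bulb (air) temperature, degC.
#' @return WBGT, degC; vectorised.
#' @examples
#' wbgt(18, 34, 24)  # 21.8
#' @export
wbgt <- function(tnw_c, tg_c, tdb_c) {
  0.7 * tnw_c + 0.2 * tg_c + 0.1 * tdb_c
}

#' Reconstruct hourly WBGT from a meteorological table
#'
#' Runs the full chain solar irradiance -> globe temperature -> natural wet
#' bulb -> WBGT for each row of an hourly meteorological table.
#'
#' @param met Data frame with columns `timestamp` (POSIXct, local standard
#'   time), `dry_bulb_c`, `rh_pct`, `wind_ms`, `cloud` (fraction 0-1).
#' @param lat,lon Site coordinates, decimal degrees.
#' @param tz_offset_hours UTC offset of the timestamps.
#' @param constants Named overrides of [wbgt_constants()].
#' @return `met` with added columns `solar_wm2`, `globe_temp_c`,
#'   `nat_wet_bulb_c`, `wbgt_c`.
#' @export
wbgt_from_met <- function(met, lat, lon, tz_offset_hours = round(lon / 15),
                          constants = list()) {
  need <- c("timestamp", "dry_bulb_c", "rh_pct", "wind_ms", "cloud")
  if (!all(need %in% names(met))) {
    stop("met must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  met$solar_wm2 <- solar_irradiance(met$timestamp, lat, lon, met$cloud,
                                    tz_offset_hours)
  met$globe_temp_c <- globe_temp(met$dry_bulb_c, met$wind_ms, met$solar_wm2,
                                 constants)
  met$nat_wet_bulb_c <- natural_wet_bulb(met$dry_bulb_c, met$rh_pct,
                                         met$wind_ms, met$solar_wm2, constants)
  met$wbgt_c <- wbgt(met$nat_wet_bulb_c, met$globe_temp_c, met$dry_bulb_c)
  met
}

#' Daytime summary of an hourly series
#'
#' Per-day daytime (clock-time window, inclusive of the start hour and
#' exclusive of the end hour) means and maxima, and their period-level
#' mean and SD. Days with less than `min_coverage` of the window's hours
#' are dropped and reported.
#'
#' @param timestamp Hourly POSIXct timestamps (local standard time).
#' @param value Hourly values (e.g. WBGT or dry-bulb).
#' @param window Daytime window in hours, default `c(8, 18)` (08:00-18:00).
#' @param min_coverage Minimum fraction of window hours a day must have,
#'   default 0.5.
#' @return List with `daily` (date, n_hours, mean, max), `period_mean`,
#'   `period_sd` (of daily daytime means), `period_max_mean`,
#'   `period_max_sd` (of daily maxima) and `dropped_days`.
#' @export
daytime_summary <- function(timestamp, value, window = c(8, 18),
                            min_coverage = 0.5) {
  lt <- as.POSIXlt(timestamp)
  hour <- lt$hour + lt$min / 60
  keep <- hour >= window[1] & hour < window[2] & is.finite(value)
  if (!any(keep)) stop("no samples inside the daytime window", call. = FALSE)
  date <- as.Date(trunc(as.POSIXct(timestamp), "days"))[keep]
  v <- value[keep]
  agg <- data.frame(date = sort(unique(date)))
  agg$n_hours <- as.integer(tapply(v, date, length))
  agg$mean <- as.numeric(tapply(v, date, mean))
  agg$max <- as.numeric(tapply(v, date, max))
  need_hours <- min_coverage * (window[2] - window[1])
  ok <- agg$n_hours >= need_hours
  dropped <- agg$date[!ok]
  agg <- agg[ok, , drop = FALSE]
  if (!nrow(agg)) stop("all days dropped for insufficient coverage", call. = FALSE)
  list(daily = agg,
       period_mean = mean(agg$mean), period_sd = stats::sd(agg$mean),
       period_max_mean = mean(agg$max), period_max_sd = stats::sd(agg$max),
       dropped_days = dropped)
}

#' Moderate-to-vigorous physical activity from accelerometer counts
#'
#' Classifies 60-s triaxial epochs by vector-magnitude counts against a
#' Freedson-type cutpoint, excludes non-wear time (runs of at least
#' `nonwear_run` consecutive zero epochs) and returns average MVPA hours per
#' wear day.
#'
#' @param epochs Data frame with `timestamp` (POSIXct at 60-s spacing) and
#'   either `vm` (vector-magnitude counts/min) or `axis1`, `axis2`, `axis3`.
#' @param cutpoint_cpm MVPA vector-magnitude cutpoint, counts/min
#'   (default 2690).
#' @param nonwear_run Epochs of consecutive zeros marking non-wear
#'   (default 60, i.e. one hour).
#' @return List with `daily` (date, wear_min, mvpa_min, nonwear flag),
#'   `mvpa_h_per_day` (mean over wear days; 0 if none) and `wear_days`.
#' @export
mvpa_from_counts <- function(epochs, cutpoint_cpm = 2690, nonwear_run = 60) {
  if (!"vm" %in% names(epochs)) {
    if (!all(c("axis1", "axis2", "axis3") %in% names(epochs))) {
      stop("epochs need vm or axis1..axis3 columns", call. = FALSE)
    }
    epochs$vm <- sqrt(epochs$axis1^2 + epochs$axis2^2 + epochs$axis3^2)
  }
  dt <- diff(as.numeric(epochs$timestamp))
  if (length(dt) && any(abs(dt - 60) > 1e-6)) {
    stop("epochs must be contiguous 60-s epochs", call. = FALSE)
  }
  zero <- epochs$vm == 0
  r <- rle(zero)
  nonwear <- inverse.rle(list(lengths = r$lengths,
                              values = r$values & r$lengths >= nonwear_run))
  wear <- !nonwear
  date <- as.Date(trunc(as.POSIXct(epochs$timestamp), "days"))
  daily <- data.frame(date = sort(unique(date)))
  daily$wear_min <- as.integer(tapply(wear, date, sum))
  daily$mvpa_min <- as.integer(tapply(wear & epochs$vm >= cutpoint_cpm,
                                      date, sum))
  daily$nonwear_day <- daily$wear_min == 0
  wear_days <- daily$date[!daily$nonwear_day]
  mvpa <- if (length(wear_days)) {
    mean(daily$mvpa_min[!daily$nonwear_day]) / 60
  } else 0
  list(daily = daily, mvpa_h_per_day = mvpa, wear_days = wear_days)
}

#' Weekly summary of a physical-activity diary
#'
#' Totals diary bouts by location and by RPE intensity category and builds a
#' time-of-day histogram of outdoor activity in 3-h bins. Rows with RPE
#' outside \[0, 10\] are rejected and reported.
#'
#' @param diary Data frame with `start_time` (POSIXct), `duration_h`,
#'   `location` (`"outdoor"`/`"indoor"`) and `rpe` (0-10).
#' @param bands RPE band upper bounds for light and moderate intensity:
#'   light is `rpe <= bands[1]`, moderate `<= bands[2]`, high above.
#'   Default `c(3, 6)`.
#' @return List with `total_h`, `by_location` (h/wk), `by_intensity`
#'   (outdoor h/wk: light/moderate/high), `tod_hist` (outdoor h per 3-h bin)
#'   and `rejected` (row indices).
#' @export
diary_summary <- function(diary, bands = c(3, 6)) {
  if (any(diary$duration_h < 0)) stop("negative durations", call. = FALSE)
  bad <- !is.finite(diary$rpe) | diary$rpe < 0 | diary$rpe > 10
  rejected <- which(bad)
  d <- diary[!bad, , drop = FALSE]
  cat_of <- function(rpe) {
    ifelse(rpe <= bands[1], "light", ifelse(rpe <= bands[2], "moderate", "high"))
  }
  d$category <- cat_of(d$rpe)
  out_rows <- d$location == "outdoor"
  by_loc <- tapply(d$duration_h, d$location, sum)
  by_int <- tapply(d$duration_h[out_rows], factor(d$category[out_rows],
                   levels = c("light", "moderate", "high")), sum)
  by_int[is.na(by_int)] <- 0
  hr <- as.POSIXlt(d$start_time)$hour
  bin <- (hr %/% 3) * 3
  hist <- tapply(d$duration_h[out_rows],
                 factor(bin[out_rows], levels = seq(0, 21, by = 3)), sum)
  hist[is.na(hist)] <- 0
  names(hist) <- sprintf("%02d:00-%02d:00", seq(0, 21, 3), seq(3, 24, 3))
  list(total_h = sum(d$duration_h), by_location = by_loc,
       by_intensity = by_int, tod_hist = hist, rejected = rejected)
}
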