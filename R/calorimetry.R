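#' Saturation vapor pressure of water
#'
#' Buck/Antoine-form saturation vapor pressure over liquid water,
#' `0.61121 * exp(17.502 * T / (240.97 + T))` kPa. Used throughout the
#' package: evaporative terms of the heat balance, capsule hygrometry,
#' and the wet-bulb solvers.
#'
#' @param temp_c Air (or surface) temperature in degrees Celsius; vectorised.
#'   Must lie in \[-20, 60\] degC, the range over which the coefficient fit
#'   is intended.
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vapor_pressure(35)  # ~5.63 kPa
#' @export
saturation_vapor_pressure <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c < -20) || any(temp_c > 60)) {
    stop("temp_c must be finite and within [-20, 60] degC", call. = FALSE)
  }
  0.61121 * exp(17.502 * temp_c / (240.97 + temp_c))
}

#' Body surface area (Du Bois)
#'
#' @param mass_kg Body mass in kg.
#' @param height_m Height in m.
#' @return Body surface area in m^2: `0.007184 * height_cm^0.725 * mass_kg^0.425`.
#' @export
body_surface_area <- function(mass_kg, height_m) {
  if (any(mass_kg <= 0) || any(height_m <= 0)) {
    stop("mass and height must be positive", call. = FALSE)
  }
  0.007184 * (height_m * 100)^0.725 * mass_kg^0.425
}

#' Metabolic rate from oxygen uptake
#'
#' Converts oxygen uptake and the respiratory exchange ratio to metabolic
#' heat production using the linear interpolation between the energy
#' equivalents of pure fat (19630 J per L O2 at RER 0.7) and pure
#' carbohydrate (21130 J per L O2 at RER 1.0) oxidation.
#'
#' @param vo2_l_min Oxygen uptake in L/min (STPD). Must be > 0.
#' @param rer Respiratory exchange ratio; accepted in \[0.7, 1.3\] and clamped
#'   to \[0.7, 1.0\] for the energy equivalent (values above 1 reflect
#'   non-metabolic CO2 during heavy exercise).
#' @return Metabolic rate in W.
#' @examples
#' metabolic_rate(1, 1.0)  # 352.2 W
#' @export
metabolic_rate <- function(vo2_l_min, rer) {
  if (any(vo2_l_min <= 0)) stop("vo2_l_min must be positive", call. = FALSE)
  if (any(rer < 0.7) || any(rer > 1.3)) {
    stop("rer must lie in [0.7, 1.3]", call. = FALSE)
  }
  r <- pmin(rer, 1.0)
  ee <- (r - 0.7) / 0.3 * 21130 + (1.0 - r) / 0.3 * 19630  # J per L O2
  vo2_l_min * ee / 60
}

#' External work rate on a graded treadmill
#'
#' Rate of mechanical work against gravity while walking up a grade:
#' `mass * g * vertical velocity`.
#'
#' @param mass_kg Body mass in kg.
#' @param speed_kmh Treadmill belt speed in km/h.
#' @param grade_pct Treadmill grade in percent (rise over run * 100); >= 0.
#' @return External work rate in W.
#' @examples
#' external_work(56.84, 6.1, 10.2)  # ~96.4 W
#' @export
external_work <- function(mass_kg, speed_kmh, grade_pct) {
  if (any(grade_pct < 0)) stop("grade_pct must be >= 0", call. = FALSE)
  mass_kg * 9.81 * (speed_kmh / 3.6) * grade_pct / 100
}

#' Partitional calorimetry heat balance for one heat-response-test visit
#'
#' Steady-state partitional calorimetry in the convention where a positive
#' flux is heat *loss* from the body. Convective and radiative exchanges use
#' `hc = 8.3 * v^0.6` and a linearised radiative coefficient
#' (emissivity 0.95, effective radiating area fraction 0.70, mean radiant
#' temperature equal to air temperature inside the chamber). Respiratory
#' exchanges follow the conventional `0.0014 * M * (34 - Ta)` (convective)
#' and `0.0173 * M * (5.87 - Pa)` (evaporative) forms. The evaporative
#' requirement is the residual
#' `Ereq = M - Wext - C - R - Cres - Eres`, the environmental maximum is
#' `Emax = 16.5 * hc * BSA * (Psat(Tsk) - Pa)` (Lewis relation), and their
#' ratio is the compensability index: ratio > 1 marks an uncompensable
#' exposure. In a 40 degC chamber with skin cooler than air, C and R are
#' negative (dry heat gain), which inflates Ereq.
#'
#' @param mass_kg,height_m Anthropometry; body surface area by Du Bois.
#' @param ta_c Chamber air temperature, degC.
#' @param rh_pct Chamber relative humidity, percent.
#' @param air_velocity Effective air speed over the skin, m/s. The default
#'   0.3 m/s is the still-air convention for an environmental chamber without
#'   directed airflow; under the study-type conditions it yields
#'   compensability ratios in the mid-1 range.
#' @param tsk_c Mean skin temperature, degC.
#' @param m_w Metabolic rate, W (e.g. from [metabolic_rate()]).
#' @param wext_w External work rate, W (e.g. from [external_work()]).
#' @param constants Optional list overriding any of the transfer constants:
#'   `hc_coef` (8.3), `hc_exp` (0.6), `emissivity` (0.95), `ar_ad` (0.70),
#'   `lewis` (16.5 W m^-2 kPa^-1 per unit hc), `cres_coef` (0.0014),
#'   `eres_coef` (0.0173), `lambda_j_g` (2426 J/g latent heat of sweat).
#' @return An object of class `heat_balance`: list with components `M`,
#'   `Wext`, `C`, `R`, `Cres`, `Eres`, `Ereq`, `Emax`, `ratio`, `bsa`,
#'   `resp_mass_loss_g_s` (evaporative respiratory water loss rate, for the
#'   whole-body sweat-loss mass balance) and an `assumptions` record.
#' @examples
#' hb <- heat_balance(56.84, 1.70, ta_c = 40, rh_pct = 30, tsk_c = 36.3,
#'                    m_w = metabolic_rate(2.06, 0.9),
#'                    wext_w = external_work(56.84, 6.1, 10.2))
#' hb$ratio
#' @export
heat_balance <- function(mass_kg, height_m, ta_c, rh_pct, air_velocity = 0.3,
                         tsk_c, m_w, wext_w, constants = list()) {
  if (rh_pct < 0 || rh_pct > 100) stop("rh_pct must be in [0, 100]", call. = FALSE)
  if (air_velocity <= 0) stop("air_velocity must be positive", call. = FALSE)
  if (m_w <= 0) stop("metabolic rate must be positive", call. = FALSE)
  k <- list(hc_coef = 8.3, hc_exp = 0.6, emissivity = 0.95, ar_ad = 0.70,
            lewis = 16.5, cres_coef = 0.0014, eres_coef = 0.0173,
            lambda_j_g = 2426)
  k[names(constants)] <- constants

  bsa <- body_surface_area(mass_kg, height_m)
  hc <- k$hc_coef * air_velocity^k$hc_exp
  C <- hc * bsa * (tsk_c - ta_c)
  tr_c <- ta_c  # mean radiant temperature = air temperature in the chamber
  sigma <- 5.67e-8
  hr <- 4 * k$emissivity * sigma * k$ar_ad * ((tsk_c + tr_c) / 2 + 273.15)^3
  R <- hr * bsa * (tsk_c - tr_c)
  pa <- rh_pct / 100 * saturation_vapor_pressure(ta_c)
  cres <- k$cres_coef * m_w * (34 - ta_c)
  eres <- k$eres_coef * m_w * (5.87 - pa)
  ereq <- m_w - wext_w - C - R - cres - eres
  evap_grad <- saturation_vapor_pressure(tsk_c) - pa
  if (evap_grad <= 0) stop("no evaporative gradient: Psat(Tsk) <= Pa", call. = FALSE)
  emax <- k$lewis * hc * bsa * evap_grad

  out <- list(M = m_w, Wext = wext_w, C = C, R = R, Cres = cres, Eres = eres,
              Ereq = ereq, Emax = emax, ratio = ereq / emax, bsa = bsa,
              hc = hc, hr = hr,
              resp_mass_loss_g_s = eres / k$lambda_j_g,
              assumptions = list(air_velocity = air_velocity,
                                 emissivity = k$emissivity,
                                 tr_equals_ta = TRUE, clothing = "none"))
  class(out) <- "heat_balance"
  out
}

#' @export
print.heat_balance <- function(x, ...) {
  cat("Partitional calorimetry heat balance (positive flux = heat loss)\n")
  cat(sprintf("  M  = %7.1f W   Wext = %6.1f W   BSA = %.2f m^2\n",
              x$M, x$Wext, x$bsa))
  cat(sprintf("  C  = %7.1f W   R    = %6.1f W   Cres = %5.1f W   Eres = %5.1f W\n",
              x$C, x$R, x$Cres, x$Eres))
  cat(sprintf("  Ereq = %6.1f W   Emax = %6.1f W   Ereq/Emax = %.2f (%s)\n",
              x$Ereq, x$Emax, x$ratio,
              if (x$ratio > 1) "uncompensable" else "compensable"))
  cat(sprintf("  assumed air velocity %.2f m/s, emissivity %.2f, Tr = Ta\n",
              x$assumptions$air_velocity, x$assumptions$emissivity))
  invisible(x)
}
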