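#' Ventilated-capsule configuration
#'
#' @param area_cm2 Capsule skin area, cm^2 (default 4.0).
#' @param flow_ml_min Dry-air flow through the capsule, mL/min (default 500).
#' @param sample_hz Effluent sampling rate, Hz (default 0.2, i.e. one sample
#'   per 5 s).
#' @param site Site label, `"back"` or `"forearm"`.
#' @return List of class `capsule_config`.
#' @export
capsule_config <- function(area_cm2 = 4.0, flow_ml_min = 500,
                           sample_hz = 0.2, site = c("back", "forearm")) {
  site <- match.arg(site)
  if (area_cm2 <= 0 || flow_ml_min <= 0 || sample_hz <= 0) {
    stop("capsule area, flow and sampling rate must be positive", call. = FALSE)
  }
  structure(list(area_cm2 = area_cm2, flow_ml_min = flow_ml_min,
                 sample_hz = sample_hz, site = site),
            class = "capsule_config")
}

#' Local sweat rate from effluent-air hygrometry
#'
#' Converts the humidity and temperature of capsule effluent air to local
#' sweat rate. Inlet air is anhydrous, so all effluent water vapor is
#' evaporated sweat: LSR is the product of the effluent vapor concentration
#' and the flow rate, per unit capsule area. Vapor concentration is the
#' ideal-gas water-vapor density at the effluent temperature scaled by
#' relative humidity: `rho_v = RH/100 * Psat(T) * Mw / (R * T_K)`.
#'
#' @param rh_pct Effluent relative humidity, percent, in \[0, 100\].
#' @param temp_c Effluent air temperature, degC.
#' @param config A [capsule_config()].
#' @return Local sweat rate in mg cm^-2 min^-1, vectorised over samples.
#' @export
lsr_from_hygrometry <- function(rh_pct, temp_c, config = capsule_config()) {
  if (any(rh_pct < 0) || any(rh_pct > 100)) {
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  }
  rho_v <- vapor_density(rh_pct, temp_c)                 # g/m^3
  # g/m^3 * mL/min = g/m^3 * 1e-6 m^3/min -> g/min; *1000 -> mg/min; / cm^2
  rho_v * config$flow_ml_min * 1e-3 / config$area_cm2
}

# ideal-gas water-vapor density, g/m^3
vapor_density <- function(rh_pct, temp_c) {
  p_kpa <- rh_pct / 100 * saturation_vapor_pressure(temp_c)
  p_kpa * 1000 * 18.015 / (8.314 * (temp_c + 273.15))
}

# inverse of lsr_from_hygrometry at a known effluent temperature: the RH that
# yields a target LSR (used by the synthetic generator)
rh_for_lsr <- function(lsr, temp_c, config = capsule_config()) {
  rho_v <- lsr * config$area_cm2 / (config$flow_ml_min * 1e-3)
  rho_sat <- vapor_density(100, temp_c)
  100 * rho_v / rho_sat
}

#' Segmented (flat-then-linear) fit of a local-sweat-rate trace
#'
#' Least-squares fit of the sweating-onset model
#' `LSR(t) = a` for `t <= t0` and `a + b (t - t0)` for `t > t0`.
#' The breakpoint is found by exhaustive search over the observed sample
#' times (the data's own resolution), with the intercept and slope solved
#' analytically for each candidate; the global SSE minimiser is returned and
#' ties break toward the earliest breakpoint. Whether a sweating onset is
#' detectable at all is decided by an F-test of the segmented model against
#' the flat (constant) model; if not significant at `alpha`, the fit is
#' returned with `converged = FALSE` and no onset.
#'
#' @param time_min Sample times, min.
#' @param lsr Local sweat rate, mg cm^-2 min^-1.
#' @param alpha Significance level of the segmented-vs-flat F-test
#'   (default 0.05).
#' @param min_tail Minimum number of samples required on each side of a
#'   candidate breakpoint (default 3).
#' @return Object of class `sweat_onset`: `breakpoint` (t0, min),
#'   `baseline` (a), `sensitivity` (b, mg cm^-2 min^-1 per min), `sse`,
#'   `f_stat`, `p_value`, `converged`, `n`, and the data.
#' @examples
#' t <- seq(0, 45, by = 1 / 12)
#' y <- 0.1 + 0.05 * pmax(t - 10, 0)
#' fit_sweat_onset(t, y)
#' @export
fit_sweat_onset <- function(time_min, lsr, alpha = 0.05, min_tail = 3) {
  n <- length(lsr)
  if (n < 10) stop("need at least 10 samples to fit a breakpoint", call. = FALSE)
  if (length(time_min) != n) stop("time and lsr lengths differ", call. = FALSE)
  o <- order(time_min)
  t <- time_min[o]; y <- lsr[o]

  # candidate breakpoints: observed times with >= min_tail points strictly
  # after and >= min_tail at or before
  cand_idx <- seq(min_tail, n - min_tail)
  cand <- t[cand_idx]

  # suffix sums over points strictly after each candidate time; since
  # candidates are observed times, "strictly after" = indices > cand_idx
  rcum <- function(x) rev(cumsum(rev(x)))
  st <- c(rcum(t), 0); sy <- c(rcum(y), 0)
  st2 <- c(rcum(t^2), 0); sty <- c(rcum(t * y), 0)
  i1 <- cand_idx + 1                       # first index strictly after cand
  m <- n - cand_idx                        # points after breakpoint
  Sh <- st[i1] - cand * m                  # sum (t - t0)+
  Sh2 <- st2[i1] - 2 * cand * st[i1] + cand^2 * m
  Shy <- sty[i1] - cand * sy[i1]
  Sy <- sum(y)

  # normal equations for y ~ a + b*h, h = (t - t0)+, over all n points
  det <- n * Sh2 - Sh^2
  b <- (n * Shy - Sh * Sy) / det
  a <- (Sy - b * Sh) / n
  # at the LS solution the residuals are orthogonal to both regressors,
  # so SSE = sum y^2 - a*Sy - b*Shy
  sse <- pmax(sum(y^2) - a * Sy - b * Shy, 0)
  best <- which(sse <= min(sse) + 1e-12)[1]  # ties -> earliest t0

  t0 <- cand[best]; a0 <- a[best]; b0 <- b[best]; sse0 <- sse[best]
  sse_flat <- sum((y - mean(y))^2)
  df2 <- n - 3
  f <- ((sse_flat - sse0) / 2) / (sse0 / df2)
  p <- if (sse0 <= 1e-12 * max(sse_flat, 1e-300)) {
    f <- Inf
    0  # perfect segmented fit of a non-flat trace
  } else if (is.finite(f) && f > 0) {
    stats::pf(f, 2, df2, lower.tail = FALSE)
  } else 1
  converged <- p < alpha && b0 > 0

  out <- list(breakpoint = if (converged) t0 else NA_real_,
              baseline = a0, sensitivity = b0, sse = sse0,
              f_stat = f, p_value = p, converged = converged, n = n,
              time_min = t, lsr = y, alpha = alpha)
  class(out) <- "sweat_onset"
  out
}

#' @export
print.sweat_onset <- function(x, ...) {
  cat("Segmented sweating-onset fit (flat baseline, then linear rise)\n")
  if (x$converged) {
    cat(sprintf("  onset at t0 = %.2f min; baseline %.3f, sensitivity %.4f mg cm^-2 min^-1 per min\n",
                x$breakpoint, x$baseline, x$sensitivity))
  } else {
    cat("  no detectable onset (segmented model not better than flat; ")
    cat(sprintf("F = %.2f, p = %.3f)\n", x$f_stat, x$p_value))
  }
  cat(sprintf("  n = %d samples, SSE = %.4g\n", x$n, x$sse))
  invisible(x)
}

#' @export
coef.sweat_onset <- function(object, ...) {
  c(breakpoint = object$breakpoint, baseline = object$baseline,
    sensitivity = object$sensitivity)
}

#' @export
predict.sweat_onset <- function(object, newtime = object$time_min, ...) {
  t0 <- if (object$converged) object$breakpoint else Inf
  object$baseline + object$sensitivity * pmax(newtime - t0, 0)
}

#' @export
fitted.sweat_onset <- function(object, ...) predict(object)

#' @export
residuals.sweat_onset <- function(object, ...) object$lsr - fitted(object)

#' @export
plot.sweat_onset <- function(x, ...) {
  graphics::plot(x$time_min, x$lsr, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "time (min)", ylab = expression(LSR~(mg~cm^-2~min^-1)),
                 ...)
  graphics::lines(x$time_min, fitted(x), col = "firebrick", lwd = 2)
  if (x$converged) graphics::abline(v = x$breakpoint, lty = 2)
  invisible(x)
}

#' Core temperature at the sweating onset
#'
#' Interpolates the (cleaned) core-temperature trace at the fitted
#' sweating-onset time, expressing the onset threshold in degC.
#'
#' @param fit A converged [fit_sweat_onset()] object.
#' @param tgi_time_min,tgi_c Core-temperature trace covering the breakpoint.
#' @return Onset core temperature, degC.
#' @export
onset_tgi <- function(fit, tgi_time_min, tgi_c) {
  if (!inherits(fit, "sweat_onset")) stop("fit must be a sweat_onset", call. = FALSE)
  if (!fit$converged) stop("no onset: segmented fit did not converge", call. = FALSE)
  t0 <- fit$breakpoint
  if (t0 < min(tgi_time_min) || t0 > max(tgi_time_min)) {
    stop("breakpoint outside the core-temperature trace", call. = FALSE)
  }
  stats::approx(tgi_time_min, tgi_c, xout = t0)$y
}

#' Whole-body sweat loss by mass balance
#'
#' Whole-body sweat loss over an exercise bout from pre/post clothed and
#' clothing masses, corrected for fluid intake and respiratory water loss.
#' Sweat trapped in clothing is captured automatically: the nude mass change
#' `(pre_clothed - pre_clothing) - (post_clothed - post_clothing)` counts
#' sweat whether it evaporated or soaked into the clothing, so WBSL is
#' invariant to redistribution of sweat between skin, air and fabric.
#' 1 kg of water is reported as 1 L.
#'
#' @param pre_clothed_kg,post_clothed_kg Clothed body mass before/after, kg.
#' @param pre_clothing_kg,post_clothing_kg Clothing mass before/after, kg
#'   (post >= pre: clothing can only gain trapped sweat).
#' @param fluid_intake_kg Mass of fluid ingested during the bout, kg.
#' @param resp_loss_kg Respiratory water loss over the bout, kg. Either give
#'   it directly or supply `heat_balance` + `duration_min` and it is taken as
#'   `resp_mass_loss_g_s * 60 * duration_min / 1000`.
#' @param heat_balance Optional [heat_balance()] object used to estimate the
#'   respiratory term.
#' @param duration_min Exercise duration, min (required with `heat_balance`).
#' @return List of class `mass_balance` with `nude_mass_change_kg`,
#'   `trapped_in_clothing_kg`, `resp_loss_kg`, `wbsl_l` and `flag`
#'   (non-NULL when WBSL is negative).
#' @examples
#' wbsl(58.0, 57.2, 1.0, 1.0, resp_loss_kg = 0.02)  # 0.78 L
#' @export
wbsl <- function(pre_clothed_kg, post_clothed_kg, pre_clothing_kg,
                 post_clothing_kg, fluid_intake_kg = 0, resp_loss_kg = NULL,
                 heat_balance = NULL, duration_min = NULL) {
  masses <- c(pre_clothed_kg, post_clothed_kg, pre_clothing_kg, post_clothing_kg)
  if (any(masses <= 0)) stop("all masses must be positive", call. = FALSE)
  if (post_clothing_kg < pre_clothing_kg - 1e-9) {
    stop("post clothing mass below pre: clothing cannot lose mass", call. = FALSE)
  }
  if (is.null(resp_loss_kg)) {
    if (is.null(heat_balance) || is.null(duration_min)) {
      stop("give resp_loss_kg, or heat_balance plus duration_min", call. = FALSE)
    }
    resp_loss_kg <- heat_balance$resp_mass_loss_g_s * 60 * duration_min / 1000
  }
  nude_pre <- pre_clothed_kg - pre_clothing_kg
  nude_post <- post_clothed_kg - post_clothing_kg
  d_nude <- nude_pre - nude_post
  wbsl_l <- d_nude + fluid_intake_kg - resp_loss_kg
  flag <- NULL
  if (wbsl_l < 0) {
    flag <- "negative WBSL: check masses and corrections"
    warning(flag, call. = FALSE)
  }
  structure(list(nude_mass_change_kg = d_nude,
                 trapped_in_clothing_kg = post_clothing_kg - pre_clothing_kg,
                 fluid_intake_kg = fluid_intake_kg,
                 resp_loss_kg = resp_loss_kg,
                 wbsl_l = wbsl_l, flag = flag),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("WBSL %.2f L (nude mass change %.2f kg, trapped in clothing %.2f kg,\n",
              x$wbsl_l, x$nude_mass_change_kg, x$trapped_in_clothing_kg))
  cat(sprintf("      intake %.2f kg, respiratory loss %.3f kg)\n",
              x$fluid_intake_kg, x$resp_loss_kg))
  if (!is.null(x$flag)) cat("  FLAG:", x$flag, "\n")
  invisible(x)
}
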