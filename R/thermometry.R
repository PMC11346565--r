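#' Weighted mean skin temperature
#'
#' Four-site weighted mean skin temperature with the chest 30%,
#' shoulder 30%, thigh 20%, calf 20% weighting. All sites are required;
#' there is no silent re-weighting around a missing sensor.
#'
#' @param chest,shoulder,thigh,calf Site temperatures in degC; vectorised.
#'   Each must be finite and within 10-45 degC.
#' @param weights Numeric length-4 weights (chest, shoulder, thigh, calf);
#'   must sum to 1.
#' @return Mean skin temperature, degC.
#' @examples
#' mean_skin_temp(35, 35, 34, 34)  # 34.6
#' @export
mean_skin_temp <- function(chest, shoulder, thigh, calf,
                           weights = c(0.3, 0.3, 0.2, 0.2)) {
  if (length(weights) != 4 || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be 4 values summing to 1", call. = FALSE)
  }
  sites <- cbind(chest, shoulder, thigh, calf)
  if (any(!is.finite(sites)) || any(sites < 10) || any(sites > 45)) {
    stop("all four sites are required and must lie in 10-45 degC", call. = FALSE)
  }
  drop(sites %*% weights)
}

#' Clean a telemetric core-temperature trace
#'
#' Removes physiologically impossible samples from a gastro-intestinal
#' temperature trace - values outside `range_c` or isolated jumps larger
#' than `max_jump_c` per 15 s relative to the last retained sample - and
#' fills the gaps by linear interpolation. Cleaning is idempotent: a
#' cleaned trace passes through unchanged.
#'
#' @param time_min Sample times in minutes, strictly increasing.
#' @param tgi_c Core temperature samples, degC.
#' @param range_c Plausible physiological range, default c(30, 43) degC.
#' @param max_jump_c Largest plausible change per 15 s, default 0.5 degC.
#' @param max_removed_frac If more than this fraction of samples is removed
#'   the trace is deemed unusable and an error is thrown (default 0.2).
#' @return List with `time_min`, `tgi_c` (cleaned), and `removed` (integer
#'   indices of replaced samples).
#' @export
clean_tgi_trace <- function(time_min, tgi_c, range_c = c(30, 43),
                            max_jump_c = 0.5, max_removed_frac = 0.2) {
  n <- length(tgi_c)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(time_min) != n) stop("time and value lengths differ", call. = FALSE)
  if (any(diff(time_min) <= 0)) stop("time must be strictly increasing", call. = FALSE)

  bad <- !is.finite(tgi_c) | tgi_c < range_c[1] | tgi_c > range_c[2]
  # jump screen against the last retained sample, threshold scaled to the gap
  last_good <- NA_integer_
  for (i in seq_len(n)) {
    if (bad[i]) next
    if (!is.na(last_good)) {
      dt <- time_min[i] - time_min[last_good]
      thr <- max_jump_c * max(dt / 0.25, 1)
      if (abs(tgi_c[i] - tgi_c[last_good]) > thr) {
        bad[i] <- TRUE
        next
      }
    }
    last_good <- i
  }
  removed <- which(bad)
  if (length(removed) / n > max_removed_frac) {
    stop(sprintf("unusable trace: %d of %d samples (%.0f%%) removed",
                 length(removed), n, 100 * length(removed) / n), call. = FALSE)
  }
  out <- tgi_c
  if (length(removed)) {
    good <- which(!bad)
    out[removed] <- stats::approx(time_min[good], tgi_c[good],
                                  xout = time_min[removed], rule = 2)$y
  }
  list(time_min = time_min, tgi_c = out, removed = removed)
}

#' Safety-cutoff decision for a core-temperature trace
#'
#' @param time_min,tgi_c Cleaned core-temperature trace.
#' @param cutoff_c Stop criterion, default 39.5 degC.
#' @return Time (min) of the earliest sample at or above the cutoff, or
#'   `NA_real_` if never reached.
#' @export
safety_flag <- function(time_min, tgi_c, cutoff_c = 39.5) {
  hit <- which(tgi_c >= cutoff_c)
  if (!length(hit)) return(NA_real_)
  time_min[min(hit)]
}

#' Summarize one heat-response-test visit
#'
#' Computes the visit-level quantities used for pre/post contrasts: resting
#' baselines (mean over the final `rest_window_min` minutes before exercise
#' onset at t = 0), end-exercise values (last exercising sample), the rise in
#' core temperature referenced to the exercise-onset sample, and exercise-mean
#' skin temperature and heart rate. If the trace crosses the safety cutoff,
#' summaries run to the stop time and the visit is flagged.
#'
#' @param series A heat-response-test series as produced by
#'   [generate_hrt_series()]: a list with data frames `tgi` (t_min, tgi_c),
#'   `tsk` (t_min, tsk_chest_c, tsk_shoulder_c, tsk_thigh_c, tsk_calf_c) and
#'   `hr` (t_min, hr_bpm). Negative times are rest.
#' @param rest_window_min Width of the pre-exercise averaging window,
#'   default 5 min (the final half of a 10-min rest, discarding
#'   instrumentation transients).
#' @param exercise_end_min Nominal end of exercise, default 45 min.
#' @param cutoff_c Safety cutoff passed to [safety_flag()].
#' @param rise_reference Either `"exercise_onset"` (default; rise referenced
#'   to the sample at t = 0, i.e. after chamber entry) or `"rest"` (rise
#'   referenced to the resting baseline).
#' @return List of class `visit_summary` with fields `resting_tgi`,
#'   `resting_tsk`, `resting_hr`, `onset_tgi_t0`, `rise_tgi`, `end_tgi`,
#'   `mean_tsk_exercise`, `end_hr`, `mean_hr_exercise`, `safety_stop`,
#'   `stop_time`.
#' @export
summarize_visit <- function(series, rest_window_min = 5, exercise_end_min = 45,
                            cutoff_c = 39.5, rise_reference = "exercise_onset") {
  tg <- series$tgi
  rest <- tg$t_min < 0
  if (!any(rest) || -min(tg$t_min) < rest_window_min) {
    stop("rest window of at least ", rest_window_min, " min required", call. = FALSE)
  }
  if (!any(tg$t_min >= 0)) stop("exercise window absent", call. = FALSE)

  in_rest_win <- tg$t_min >= -rest_window_min & tg$t_min < 0
  resting_tgi <- mean(tg$tgi_c[in_rest_win])

  stop_time <- safety_flag(tg$t_min[tg$t_min >= 0], tg$tgi_c[tg$t_min >= 0],
                           cutoff_c)
  t_end <- if (is.na(stop_time)) exercise_end_min else stop_time
  ex <- tg$t_min >= 0 & tg$t_min <= t_end
  end_idx <- which(ex)[sum(ex)]
  end_tgi <- tg$tgi_c[end_idx]
  tgi_t0 <- tg$tgi_c[which.min(abs(tg$t_min))]
  ref <- if (identical(rise_reference, "rest")) resting_tgi else tgi_t0
  rise_tgi <- end_tgi - ref

  ts <- series$tsk
  tsk_all <- mean_skin_temp(ts$tsk_chest_c, ts$tsk_shoulder_c,
                            ts$tsk_thigh_c, ts$tsk_calf_c)
  resting_tsk <- mean(tsk_all[ts$t_min >= -rest_window_min & ts$t_min < 0])
  mean_tsk_exercise <- mean(tsk_all[ts$t_min >= 0 & ts$t_min <= t_end])

  hr <- series$hr
  hr_rest <- hr$hr_bpm[hr$t_min >= -rest_window_min & hr$t_min < 0]
  resting_hr <- if (length(hr_rest)) mean(hr_rest) else NA_real_
  hr_ex <- hr$t_min >= 0 & hr$t_min <= t_end
  mean_hr_exercise <- mean(hr$hr_bpm[hr_ex])
  end_hr <- hr$hr_bpm[which(hr_ex)[sum(hr_ex)]]

  out <- list(resting_tgi = resting_tgi, resting_tsk = resting_tsk,
              resting_hr = resting_hr, onset_tgi_t0 = tgi_t0,
              rise_tgi = rise_tgi, end_tgi = end_tgi,
              mean_tsk_exercise = mean_tsk_exercise, end_hr = end_hr,
              mean_hr_exercise = mean_hr_exercise,
              safety_stop = !is.na(stop_time), stop_time = stop_time)
  class(out) <- "visit_summary"
  out
}

#' @export
print.visit_summary <- function(x, ...) {
  cat("Heat-response-test visit summary\n")
  cat(sprintf("  resting: Tgi %.2f degC, Tsk %.2f degC, HR %.0f bpm\n",
              x$resting_tgi, x$resting_tsk, x$resting_hr))
  cat(sprintf("  exercise: rise in Tgi %.2f degC, end Tgi %.2f degC, mean Tsk %.2f degC\n",
              x$rise_tgi, x$end_tgi, x$mean_tsk_exercise))
  cat(sprintf("  heart rate: mean %.0f, end %.0f bpm\n",
              x$mean_hr_exercise, x$end_hr))
  if (x$safety_stop) {
    cat(sprintf("  SAFETY STOP at %.1f min\n", x$stop_time))
  }
  invisible(x)
}
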