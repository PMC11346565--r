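# Plain-CSV interchange (UTF-8, "." decimal, ISO-8601 timestamps) for the
# pipeline's documented layouts.

#' Write / read a heat-response-test series as CSV
#'
#' The HRT CSV holds all slow signals merged on time: columns `t_min`,
#' `tgi_c`, `tsk_chest_c`, `tsk_shoulder_c`, `tsk_thigh_c`, `tsk_calf_c`,
#' `hr_bpm`; rows where a signal has no sample hold NA. Capsule traces are
#' written separately (see [write_capsule_csv()]).
#'
#' @param series An `hrt_series` (see [generate_hrt_series()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hrt_csv <- function(series, path) {
  tsk_cols <- setdiff(names(series$tsk), "t_min")
  df <- merge(series$tgi, series$tsk, by = "t_min", all = TRUE)
  df <- merge(df, series$hr, by = "t_min", all = TRUE)
  df <- df[order(df$t_min), c("t_min", "tgi_c", tsk_cols, "hr_bpm")]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hrt_csv
#' @return `read_hrt_csv`: a list with data frames `tgi`, `tsk`, `hr`
#'   (NA rows of each signal dropped), usable by [summarize_visit()].
#' @export
read_hrt_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  tsk_cols <- grep("^tsk_", names(df), value = TRUE)
  list(
    tgi = df[!is.na(df$tgi_c), c("t_min", "tgi_c")],
    tsk = df[stats::complete.cases(df[, tsk_cols]), c("t_min", tsk_cols)],
    hr = df[!is.na(df$hr_bpm), c("t_min", "hr_bpm")]
  )
}

#' Write / read a ventilated-capsule trace as CSV
#'
#' Columns `t_s` (seconds from exercise onset), `rh_pct`, `temp_c`.
#'
#' @param capsule One site's trace (`t_min`, `rh_pct`, `temp_c`).
#' @param path Output file.
#' @export
write_capsule_csv <- function(capsule, path) {
  df <- data.frame(t_s = capsule$t_min * 60, rh_pct = capsule$rh_pct,
                   temp_c = capsule$temp_c)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_capsule_csv
#' @export
read_capsule_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  data.frame(t_min = df$t_s / 60, rh_pct = df$rh_pct, temp_c = df$temp_c)
}

#' Read an hourly meteorological CSV
#'
#' Reads a station export into the canonical meteorological layout used by
#' [wbgt_from_met()]. `column_map` maps canonical names to the file's
#' column names; timestamps must be ISO-8601 local standard time.
#'
#' @param path CSV file.
#' @param column_map Named character vector: canonical name ->
#'   file column name. Canonical names: `timestamp`, `dry_bulb_c`,
#'   `rh_pct`, `wind_ms`, `cloud`.
#' @param tz Timezone of the timestamps (default "UTC", i.e. treat them as
#'   local standard time without conversion).
#' @return Data frame with the canonical columns.
#' @export
read_met_csv <- function(path,
                         column_map = c(timestamp = "timestamp",
                                        dry_bulb_c = "dry_bulb_c",
                                        rh_pct = "rh_pct",
                                        wind_ms = "wind_ms",
                                        cloud = "cloud"),
                         tz = "UTC") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols)) {
    stop("met CSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    timestamp = as.POSIXct(df[[column_map[["timestamp"]]]], tz = tz,
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%d %H:%M",
                                          "%Y-%m-%d")),
    dry_bulb_c = df[[column_map[["dry_bulb_c"]]]],
    rh_pct = df[[column_map[["rh_pct"]]]],
    wind_ms = df[[column_map[["wind_ms"]]]],
    cloud = df[[column_map[["cloud"]]]])
  if (any(out$rh_pct < 0 | out$rh_pct > 100, na.rm = TRUE) ||
      any(out$wind_ms < 0, na.rm = TRUE) ||
      any(out$cloud < 0 | out$cloud > 1, na.rm = TRUE)) {
    stop("met values outside physical ranges", call. = FALSE)
  }
  out
}

#' Published pre/post posterior summaries used as worked examples
#'
#' Reference table of published posterior summaries (posterior mean,
#' equal-tailed 90% credible interval, printed probability of direction)
#' from a seasonal heat-acclimatization study of 15 active adolescents.
#' Used to validate [pd_from_interval()]: the printed Pd values should be
#' recoverable from the printed mean and interval under a normal
#' approximation to the posterior.
#'
#' @return Data frame with columns `outcome`, `mean`, `ci_low`, `ci_high`,
#'   `pd_printed`, `units`.
#' @export
adolescent_summer_contrasts <- function() {
  data.frame(
    outcome = c("rise_tgi", "end_exercise_tgi", "exercising_tsk",
                "vo2peak", "sweat_sensitivity", "max_hr", "resting_hr",
                "rpe_25min", "rpe_5min", "resting_tgi", "wbsl"),
    mean = c(-0.22, -0.35, -0.2, 1.2, -0.01, -4, -7, -1.0, -1.8, -0.19, 0.03),
    ci_low = c(-0.48, -0.63, -0.5, -0.5, -0.02, -6, -10, -1.8, -2.9, -0.31,
               -0.06),
    ci_high = c(0.04, -0.07, 0.1, 2.8, 0.00, -2, -3, -0.2, -0.7, -0.07, 0.12),
    pd_printed = c(92, 98, 86, 88, 95, 100, 100, 98, 99, 99, 73),
    units = c("degC", "degC", "degC", "mL/kg/min",
              "mg.cm-2.min-1 per min", "bpm", "bpm", "0-10", "0-10",
              "degC", "L"),
    stringsAsFactors = FALSE)
}
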