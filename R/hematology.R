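#' Hemoglobin mass from a CO-rebreathing record
#'
#' CO-dilution calculation of total hemoglobin mass. The absorbed CO dose
#' (administered minus unabsorbed/exhaled) is divided by the rise in
#' carboxyhemoglobin it produced and by the CO binding capacity of
#' hemoglobin (Huefner constant, 1.39 mL CO per g Hb by default):
#' `hb_mass = CO_absorbed * 100 / (dHbCO * huefner)`.
#'
#' @param rec A rebreathing record: list or one-row data frame with at least
#'   `hbco_pre_pct`, `hbco_post_pct`, `co_admin_ml`, `co_unabsorbed_ml`, and
#'   optionally `body_mass_kg`.
#' @param huefner CO binding capacity, mL CO per g Hb (default 1.39).
#' @return Hemoglobin mass in g; if `body_mass_kg` is present the result
#'   carries an attribute `per_kg` in g/kg.
#' @examples
#' rec <- list(hbco_pre_pct = 1, hbco_post_pct = 6,
#'             co_admin_ml = 49, co_unabsorbed_ml = 1)
#' hb_mass_from_rebreathe(rec)  # 690.6 g
#' @export
hb_mass_from_rebreathe <- function(rec, huefner = 1.39) {
  d_hbco <- rec$hbco_post_pct - rec$hbco_pre_pct
  if (!is.finite(d_hbco) || d_hbco <= 0) {
    stop("HbCO must rise during rebreathing (dHbCO > 0)", call. = FALSE)
  }
  if (rec$hbco_pre_pct < 0 || rec$hbco_post_pct > 15) {
    stop("HbCO%% outside the plausible 0-15%% band", call. = FALSE)
  }
  co_abs <- rec$co_admin_ml - rec$co_unabsorbed_ml
  if (co_abs <= 0) stop("absorbed CO must be positive", call. = FALSE)
  hb <- co_abs * 100 / (d_hbco * huefner)
  if (!is.null(rec$body_mass_kg)) attr(hb, "per_kg") <- hb / rec$body_mass_kg
  hb
}

#' Intravascular volumes from hemoglobin mass
#'
#' Blood volume from hemoglobin mass and hemoglobin concentration, red-cell
#' volume via hematocrit corrected by the whole-body/venous hematocrit ratio
#' (f-cell factor), and plasma volume as their difference.
#'
#' @param hb_mass_g Total hemoglobin mass, g.
#' @param hct Hematocrit as a fraction (0.2-0.6).
#' @param hb_conc_g_dl Hemoglobin concentration, g/dL. If `NA`, it is
#'   imputed from the hematocrit assuming a mean corpuscular hemoglobin
#'   concentration of `mchc` g/dL of red cells, with a warning.
#' @param body_mass_kg Optional body mass for per-kg outputs.
#' @param f_cell f-cell factor (default 0.91).
#' @param mchc MCHC used only when `hb_conc_g_dl` is missing (default 33).
#' @return List of class `hematology_result`: `hb_mass_g`, `blood_volume_ml`,
#'   `red_cell_volume_ml`, `plasma_volume_ml`, and when body mass is given
#'   `hb_mass_g_kg`, `blood_volume_ml_kg`, `plasma_volume_ml_kg`.
#' @examples
#' intravascular_volumes(660, hct = 0.42, hb_conc_g_dl = 14.5,
#'                       body_mass_kg = 56.84)
#' @export
intravascular_volumes <- function(hb_mass_g, hct, hb_conc_g_dl = NA,
                                  body_mass_kg = NULL, f_cell = 0.91,
                                  mchc = 33) {
  if (hb_mass_g <= 0) stop("hb_mass_g must be positive", call. = FALSE)
  if (hct < 0 || hct > 0.6) stop("hct must lie in [0, 0.6]", call. = FALSE)
  if (is.na(hb_conc_g_dl)) {
    hb_conc_g_dl <- mchc * hct * f_cell
    warning("hb_conc imputed from hematocrit via MCHC assumption", call. = FALSE)
  }
  if (hb_conc_g_dl <= 0) stop("hb_conc_g_dl must be positive", call. = FALSE)
  bv <- hb_mass_g / hb_conc_g_dl * 100   # g / (g/dL) -> dL -> *100 mL
  rcv <- bv * hct * f_cell
  pv <- bv - rcv
  out <- list(hb_mass_g = hb_mass_g, blood_volume_ml = bv,
              red_cell_volume_ml = rcv, plasma_volume_ml = pv)
  if (!is.null(body_mass_kg)) {
    out$hb_mass_g_kg <- hb_mass_g / body_mass_kg
    out$blood_volume_ml_kg <- bv / body_mass_kg
    out$plasma_volume_ml_kg <- pv / body_mass_kg
  }
  class(out) <- "hematology_result"
  out
}

#' @export
print.hematology_result <- function(x, ...) {
  cat(sprintf("Hb mass %.0f g; blood volume %.0f mL; red cell %.0f mL; plasma %.0f mL\n",
              x$hb_mass_g, x$blood_volume_ml, x$red_cell_volume_ml,
              x$plasma_volume_ml))
  if (!is.null(x$blood_volume_ml_kg)) {
    cat(sprintf("per kg: Hb %.1f g/kg, blood %.1f mL/kg, plasma %.1f mL/kg\n",
                x$hb_mass_g_kg, x$blood_volume_ml_kg, x$plasma_volume_ml_kg))
  }
  invisible(x)
}

#' Typical error of duplicate measurements
#'
#' Within-pair typical error of measurement expressed as a coefficient of
#' variation: the standard deviation of the pairwise differences divided by
#' sqrt(2), as a percentage of the grand mean.
#'
#' @param first,second Paired duplicate measurements (equal length >= 2).
#' @return Typical error, percent CV.
#' @export
typical_error <- function(first, second) {
  if (length(first) != length(second)) {
    stop("duplicates must be paired (equal lengths)", call. = FALSE)
  }
  if (length(first) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- first - second
  te <- stats::sd(d) / sqrt(2)
  100 * te / mean(c(first, second))
}
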