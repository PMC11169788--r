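#' Mean arterial pressure
#'
#' One-third pulse-pressure rule: `dbp + (sbp - dbp) / 3`.
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param dbp Diastolic blood pressure, mmHg; must not exceed `sbp`.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp < dbp)) {
    stop("require sbp >= dbp > 0", call. = FALSE)
  }
  dbp + (sbp - dbp) / 3
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv Stroke volume, ml.
#' @param hr Heart rate, beats/min.
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(sv, hr) {
  if (any(sv <= 0) || any(hr <= 0)) stop("sv and hr must be positive", call. = FALSE)
  sv * hr / 1000
}

#' External cardiac work
#'
#' Product of cardiac output and mean arterial pressure.
#'
#' @param co Cardiac output, L/min.
#' @param map Mean arterial pressure, mmHg.
#' @return External work, mmHg·L/min.
#' @export
external_work <- function(co, map) {
  if (any(co <= 0) || any(map <= 0)) stop("co and map must be positive", call. = FALSE)
  co * map
}

#' Surrogate myocardial work efficiency
#'
#' External work divided by LV mass; a mass-normalised surrogate for
#' myocardial external efficiency (units mmHg·L·min^-1·g^-1).
#'
#' @param ew External work, mmHg·L/min.
#' @param lv_mass LV mass, g.
#' @return MWE, mmHg·L/min/g.
#' @export
mwe <- function(ew, lv_mass) {
  if (any(lv_mass <= 0)) stop("lv_mass must be positive", call. = FALSE)
  ew / lv_mass
}

#' Rate-pressure product index
#'
#' `sbp * hr / 1e4`, a dimensionless index of cardiac workload.
#'
#' @inheritParams mean_arterial_pressure
#' @param hr Heart rate, beats/min.
#' @return RPP index.
#' @export
rpp_index <- function(sbp, hr) {
  if (any(sbp <= 0) || any(hr <= 0)) stop("sbp and hr must be positive", call. = FALSE)
  sbp * hr / 1e4
}

#' RPP-normalised myocardial blood flow
#'
#' Per-subject ratio of rest MBF to the RPP index.
#'
#' @param mbf Rest MBF, ml/min/g.
#' @param rpp RPP index (see [rpp_index()]), positive.
#' @return Normalised MBF, ml/min/g.
#' @export
rpp_normalized_mbf <- function(mbf, rpp) {
  if (any(rpp <= 0)) stop("rpp index must be positive", call. = FALSE)
  mbf / rpp
}

#' Index a quantity by body surface area
#'
#' @param value Quantity to index (e.g. LV mass in g, volume in ml).
#' @param bsa Body surface area, m^2; missing values are an error (no
#'   imputation).
#' @return `value / bsa`.
#' @export
index_by_bsa <- function(value, bsa) {
  if (any(is.na(bsa)) || any(bsa <= 0)) {
    stop("`bsa` must be present and positive for every subject", call. = FALSE)
  }
  value / bsa
}

#' Du Bois body surface area
#'
#' Fallback when BSA is not tabulated but height and weight are:
#' `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BSA in m^2.
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Append derived hemodynamic columns to a cohort table
#'
#' Computes MAP, cardiac output, external work, surrogate MWE, the RPP index
#' and RPP-normalised MBF for every row of a subject-level cohort table with
#' columns `sbp`, `dbp`, `hr`, `sv`, `lv_mass` (and `rest_mbf` for the
#' normalised flow).
#'
#' @param cohort Data frame of subject records (see [read_cohort()]).
#' @return The cohort with columns `map_mmHg`, `co_l_min`, `ew`, `mwe`,
#'   `rpp_index`, `mbf_rpp_norm` appended.
#' @export
derive_hemodynamics <- function(cohort) {
  need <- c("sbp", "dbp", "hr", "sv", "lv_mass")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort$map_mmHg <- mean_arterial_pressure(cohort$sbp, cohort$dbp)
  cohort$co_l_min <- cardiac_output(cohort$sv, cohort$hr)
  cohort$ew <- external_work(cohort$co_l_min, cohort$map_mmHg)
  cohort$mwe <- mwe(cohort$ew, cohort$lv_mass)
  cohort$rpp_index <- rpp_index(cohort$sbp, cohort$hr)
  cohort$mbf_rpp_norm <- if ("rest_mbf" %in% names(cohort)) {
    rpp_normalized_mbf(cohort$rest_mbf, cohort$rpp_index)
  } else NA_real_
  cohort
}
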