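#' AHA 16-segment map
#'
#' Segment-to-slice and segment-to-wall-class lookup for the modified AHA
#' model without the apical cap: segments 1-6 basal, 7-12 mid, 13-16 apical;
#' the septal segments are 2-3 (basal), 8-9 (mid) and 14 (apical).
#'
#' @return Data frame with columns `segment` (`seg_01` ... `seg_16`), `aha`
#'   (1-16), `slice` and `wall_class`.
#' @export
aha_segment_map <- function() {
  aha <- 1:16
  data.frame(
    segment = sprintf("seg_%02d", aha),
    aha = aha,
    slice = c(rep("basal", 6), rep("mid", 6), rep("apical", 4)),
    wall_class = ifelse(aha %in% c(2, 3, 8, 9, 14), "septal", "free_wall"),
    stringsAsFactors = FALSE)
}

#' Segmental first-pass curve set
#'
#' Container for the arterial input and the 16 segmental curves sharing one
#' uniform time grid; all curves are either raw signal or \eqn{\Delta R1}.
#'
#' @param times Frame times, seconds, strictly increasing.
#' @param aif Arterial-input values.
#' @param segments Numeric matrix, one column per segment, named
#'   `seg_01` ... `seg_16`.
#' @param kind `"signal"` or `"delta_r1"`.
#' @return Object of class `curve_set`.
#' @export
curve_set <- function(times, aif, segments, kind = c("signal", "delta_r1")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  segments <- as.matrix(segments)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (length(aif) != length(times) || nrow(segments) != length(times)) {
    stop("aif and segments must match the time grid length", call. = FALSE)
  }
  if (is.null(colnames(segments))) {
    colnames(segments) <- sprintf("seg_%02d", seq_len(ncol(segments)))
  }
  if (any(!is.finite(times)) || any(!is.finite(aif)) || any(!is.finite(segments))) {
    stop("curve set contains non-finite values", call. = FALSE)
  }
  structure(list(times = times, aif = as.numeric(aif), segments = segments,
                 kind = kind, map = aha_segment_map()),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set: %s, %d frames x %d segments + AIF>\n",
              x$kind, length(x$times), ncol(x$segments)))
  invisible(x)
}

#' Read a segmental curve set from CSV
#'
#' Dialect: header `time_s,aif,seg_01,...,seg_16`, one row per frame, no
#' missing frames.  Schema violations (missing columns, non-monotone time,
#' missing values) are reported with the offending lines before any
#' computation runs.
#'
#' @param path Path to the CSV file.
#' @param kind Interpretation of the values (`"signal"` default).
#' @return A [curve_set()].
#' @export
read_curves <- function(path, kind = "signal") {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "aif", sprintf("seg_%02d", 1:16))
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("curve file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(d[need])) {
    bad <- which(rowSums(is.na(d[need])) > 0)
    stop("curve file has missing values at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono) > 0L) {
    stop("time_s not strictly increasing at data line(s) ",
         paste(utils::head(nonmono + 1L, 5), collapse = ", "), call. = FALSE)
  }
  curve_set(d$time_s, d$aif, as.matrix(d[sprintf("seg_%02d", 1:16)]),
            kind = kind)
}

#' Write a segmental curve set to CSV
#'
#' @param curves A [curve_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "curve_set"))
  d <- data.frame(time_s = curves$times, aif = curves$aif,
                  curves$segments, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write T1 R1-triplet tables
#'
#' Dialect: `segment,timepoint,r1_blood_per_s,r1_tissue_per_s`.
#'
#' @param path Path to the CSV file.
#' @return Data frame in the dialect above.
#' @export
read_t1_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "timepoint", "r1_blood_per_s", "r1_tissue_per_s")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("T1 sample file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(d[need])) stop("T1 sample file contains missing values", call. = FALSE)
  d
}

#' @rdname read_t1_samples
#' @param samples Data frame of R1 triplets.
#' @export
write_t1_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a subject-level cohort table
#'
#' @param path Path to the CSV file.
#' @param required Columns that must be present (default `id`).
#' @return Data frame of subject records.
#' @export
read_cohort <- function(path, required = "id") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L) {
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_cohort
#' @param cohort Data frame of subject records.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a curve onto a new time grid
#'
#' Linear interpolation; the target grid must lie within the observed span
#' (no extrapolation).
#'
#' @param curve A [ts_curve()].
#' @param target_times New sample times, seconds.
#' @return A [ts_curve()] on `target_times`.
#' @export
resample_to_grid <- function(curve, target_times) {
  stopifnot(inherits(curve, "ts_curve"))
  if (min(target_times) < curve$times[1] - 1e-12 ||
      max(target_times) > curve$times[length(curve$times)] + 1e-12) {
    stop("target grid extends beyond the observed span (no extrapolation)",
         call. = FALSE)
  }
  v <- stats::approx(curve$times, curve$values, xout = target_times,
                     rule = 1)$y
  ts_curve(target_times, v, kind = curve$kind)
}

#' Run configuration
#'
#' Bundles the seed and per-stage settings of a full simulate -> quantify ->
#' analyze run.  Round-trips losslessly through JSON/YAML (see
#' [read_run_config()]).
#'
#' @param seed Integer seed (mandatory; drives every stochastic stage).
#' @param n_subjects Cohort size.
#' @param n_boot Bootstrap replicates of the mediation stage.
#' @param out_dir Output directory.
#' @param sr Named list of [sr_params()] overrides.
#' @param deconv Named list of [deconv_config()] overrides.
#' @param cohort Named list of [cohort_truth()] overrides.
#' @param perfusion_mbf True MBF (scalar or 16-vector) of the simulated
#'   perfusion subject.
#' @param perfusion_snr SNR of the simulated perfusion signal.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed, n_subjects = 92L, n_boot = 500L,
                       out_dir = tempfile("myoflow_run_"),
                       sr = list(), deconv = list(), cohort = list(),
                       perfusion_mbf = 0.9, perfusion_snr = 40) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for a reproducible run", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_boot = as.integer(n_boot), out_dir = out_dir,
                 sr = sr, deconv = deconv, cohort = cohort,
                 perfusion_mbf = perfusion_mbf,
                 perfusion_snr = perfusion_snr),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json or .yaml/.yml", call. = FALSE))
  do.call(run_config, lst)
}

#' Write a run configuration
#'
#' @param config A [run_config()].
#' @param path Output file (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE),
         yaml = ,
         yml = yaml::write_yaml(x, path),
         stop("config must be .json or .yaml/.yml", call. = FALSE))
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, a T1 triplet set and a first-pass perfusion subject,
#' quantifies MBF and ECV, derives the hemodynamic columns, runs the cohort
#' inference layer (tertile trends, correlations, mediation with bootstrap,
#' segmental and base-to-apex mixed models, logistic LGE), writes every
#' output as CSV/JSON under `config$out_dir`, and records a manifest with
#' package version, seed and per-file MD5 hashes.  Re-running with the same
#' configuration reproduces the deterministic outputs bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  sr <- do.call(sr_params, config$sr)
  dc <- do.call(deconv_config, config$deconv)

  # --- simulate -------------------------------------------------------------
  coh <- stage("simulate-cohort", {
    tr <- do.call(cohort_truth, c(config$cohort, list(n = config$n_subjects)))
    gen_cohort(tr, seed = config$seed)
  })
  if (!"hct" %in% names(coh$subjects)) {
    stop("[stage simulate-cohort] cohort lacks the 'hct' column needed for ECV",
         call. = FALSE)
  }
  perf <- stage("simulate-perfusion",
                gen_perfusion_dataset(
                  perfusion_truth(mbf = config$perfusion_mbf,
                                  snr = config$perfusion_snr,
                                  seed = config$seed),
                  params = sr))
  lam <- coh$subjects$global_ecv[1] / (1 - coh$subjects$hct[1])
  t1 <- stage("simulate-t1",
              gen_t1_dataset(true_lambda = lam, hct = coh$subjects$hct[1],
                             noise_sd = 0.01, seed = config$seed))

  # --- quantify -------------------------------------------------------------
  mbf <- stage("quantify-mbf", quantify_segmental_mbf(perf$curves, sr, dc))
  ecv <- stage("quantify-ecv", quantify_ecv(t1$samples, t1$truth$hct))

  # --- derive + analyze -----------------------------------------------------
  subjects <- stage("compute-mwe", derive_hemodynamics(coh$subjects))
  subjects$ecv_pct <- 100 * subjects$global_ecv
  tert <- stage("analyze-tertiles", tertile_stratify(subjects$ecv_pct))
  trend <- stage("analyze-trends", list(
    mbf = linear_trend_test(subjects$rest_mbf, tert),
    mwe = linear_trend_test(subjects$mwe, tert)))
  corr <- stage("analyze-correlations",
                pearson_matrix(subjects, c("rest_mbf", "mwe", "ecv_pct",
                                           "lvef", "lv_mass", "map_mmHg")))
  med <- stage("analyze-mediation",
               fit_mediation(subjects$ecv_pct, subjects$rest_mbf,
                             subjects$mwe, n_boot = config$n_boot,
                             seed = config$seed))
  lmm <- stage("analyze-lmm",
               fit_lmm_random_intercept(coh$segments, "mbf_seg",
                                        c("ecv_seg_pct", "rpp_index"),
                                        "subject_id"))
  b2a <- stage("analyze-base-to-apex", base_to_apex_analysis(coh$segments))
  lge <- stage("analyze-lge",
               logistic_lge(subjects$ecv_pct, subjects$lge_present))

  # --- write ----------------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  write_cohort(subjects, out("cohort_derived.csv"))
  utils::write.csv(rbind(mbf$table,
                         data.frame(segment = "GLOBAL",
                                    mbf_ml_min_g = mbf$global_mbf,
                                    lambda = NA, resid_norm = NA)),
                   out("mbf.csv"), row.names = FALSE)
  utils::write.csv(ecv, out("ecv.csv"), row.names = FALSE)
  utils::write.csv(b2a$contrasts, out("base_to_apex_contrasts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    trend = trend,
    mediation = list(estimates = as.list(med$estimates),
                     standardized = as.list(med$standardized),
                     per5 = as.list(med$per5),
                     boot_se = as.list(med$boot_se),
                     share_indirect = med$share_indirect,
                     share_direct = med$share_direct,
                     rmsea = rmsea(med)),
    lmm = list(fixed = lmm$fixed, varcomp = as.list(lmm$varcomp),
               grouping = lmm$grouping),
    lge = lge[c("or", "ci", "slope", "se", "p", "n")],
    correlations = list(r = corr$r, p = corr$p)),
    out("analysis.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, out("config.json"))

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- list(
    package = "myoflow",
    version = as.character(utils::packageVersion("myoflow")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(out("config.json"))),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(subjects = subjects, segments = coh$segments, mbf = mbf,
                 ecv = ecv, tertiles = tert, trend = trend, corr = corr,
                 mediation = med, lmm = lmm, base_to_apex = b2a, lge = lge,
                 manifest = manifest))
}
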