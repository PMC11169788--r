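#' Time-series curve for one region
#'
#' Lightweight container for a sampled curve of either raw signal intensity
#' (arbitrary units) or change in longitudinal relaxation rate (\eqn{\Delta R1},
#' 1/s) versus time, for a single region (arterial input or one AHA segment).
#'
#' @param times Numeric vector of sample times in seconds, strictly increasing.
#' @param values Numeric vector of the same length; signal (a.u.) or
#'   \eqn{\Delta R1} (1/s) depending on `kind`.
#' @param kind Either `"signal"` or `"delta_r1"`.
#' @return An object of class `ts_curve`: a list with elements `times`,
#'   `values`, `kind`.
#' @export
ts_curve <- function(times, values, kind = c("signal", "delta_r1")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a curve needs at least two samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, values = values, kind = kind),
            class = "ts_curve")
}

#' @export
print.ts_curve <- function(x, ...) {
  cat(sprintf("<ts_curve: %s, %d frames, t = [%.3g, %.3g] s>\n",
              x$kind, length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Saturation-recovery acquisition parameters
#'
#' Parameters of the idealised saturation-recovery gradient-echo signal model
#' \eqn{S = S_0 (1 - e^{-T_S R_1})}.  All sequence-specific readout effects are
#' collapsed into a single effective saturation delay `ts`.
#'
#' @param ts Effective saturation delay in seconds (> 0).
#' @param n_baseline Number of pre-contrast baseline frames used for the
#'   per-region signal-scale calibration (>= 1).
#' @param t1_native_tissue Native (pre-contrast) tissue T1 in milliseconds.
#' @param t1_native_blood Native blood T1 in milliseconds.
#' @return A list of class `sr_params`.
#' @export
sr_params <- function(ts = 0.1, n_baseline = 5L,
                      t1_native_tissue = 1232, t1_native_blood = 1650) {
  if (!is.numeric(ts) || length(ts) != 1L || !is.finite(ts) || ts <= 0) {
    stop("`ts` must be a single positive number (seconds)", call. = FALSE)
  }
  n_baseline <- as.integer(n_baseline)
  if (is.na(n_baseline) || n_baseline < 1L) {
    stop("`n_baseline` must be >= 1", call. = FALSE)
  }
  if (t1_native_tissue <= 0 || t1_native_blood <= 0) {
    stop("native T1 values must be positive (ms)", call. = FALSE)
  }
  structure(list(ts = ts, n_baseline = n_baseline,
                 t1_native_tissue = t1_native_tissue,
                 t1_native_blood = t1_native_blood),
            class = "sr_params")
}

# native R1 in 1/s from a T1 in ms
.r1_native <- function(t1_ms) 1000 / t1_ms

#' Saturation-recovery signal from a relaxation rate
#'
#' Forward signal model: `s0 * (1 - exp(-ts * r1))`.  Strictly monotone
#' increasing in `r1` and bounded above by `s0`.
#'
#' @param r1 Longitudinal relaxation rate(s), 1/s, non-negative.
#' @param s0 Fully recovered signal scale, a.u., positive scalar.
#' @param params An [sr_params()] object (only `ts` is used).
#' @return Signal intensity values, a.u.
#' @export
signal_from_r1 <- function(r1, s0, params) {
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0) {
    stop("`s0` must be a single positive number", call. = FALSE)
  }
  if (any(r1 < 0)) stop("`r1` must be non-negative", call. = FALSE)
  s0 * (1 - exp(-params$ts * r1))
}

#' Relaxation rate from a saturation-recovery signal
#'
#' Exact inverse of [signal_from_r1()].  Signals at or above `s0` are outside
#' the model's range (the recovery curve saturates at `s0`) and raise an error
#' naming the offending frame.
#'
#' @inheritParams signal_from_r1
#' @param signal Signal intensity values, a.u., in `[0, s0)`.
#' @return Relaxation rate(s), 1/s.
#' @export
r1_from_signal <- function(signal, s0, params) {
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0) {
    stop("`s0` must be a single positive number", call. = FALSE)
  }
  bad <- which(signal >= s0)
  if (length(bad) > 0L) {
    stop(sprintf("signal at frame(s) %s reaches or exceeds the calibrated scale s0 = %.6g (saturation clipping)",
                 paste(bad, collapse = ", "), s0), call. = FALSE)
  }
  if (any(signal < 0)) stop("`signal` must be non-negative", call. = FALSE)
  -log(1 - signal / s0) / params$ts
}

#' Calibrate the signal scale from pre-contrast baseline frames
#'
#' Fixes the unknown per-region scale `s0` by equating the mean pre-contrast
#' signal with the model prediction at the native relaxation rate:
#' `s0 = mean(baseline) / (1 - exp(-ts * 1000 / t1_native_ms))`.
#'
#' @param baseline_values Numeric vector of pre-contrast signal values (a.u.).
#' @param t1_native Native T1 of the region in milliseconds.
#' @param ts Effective saturation delay in seconds.
#' @return The calibrated scale `s0` (a.u.).
#' @export
calibrate_s0 <- function(baseline_values, t1_native, ts) {
  if (length(baseline_values) == 0L) {
    stop("`baseline_values` must be non-empty", call. = FALSE)
  }
  if (t1_native <= 0 || ts <= 0) {
    stop("`t1_native` and `ts` must be positive", call. = FALSE)
  }
  denom <- 1 - exp(-ts * .r1_native(t1_native))
  if (denom <= .Machine$double.eps) {
    stop("degenerate saturation-recovery factor; check `ts` and `t1_native` units",
         call. = FALSE)
  }
  mean(baseline_values) / denom
}

#' Convert a signal curve to a \eqn{\Delta R1} curve
#'
#' Per-frame inversion of the saturation-recovery model followed by
#' subtraction of the native relaxation rate of the region, so that
#' pre-contrast frames average approximately zero.
#'
#' @param curve A [ts_curve()] with `kind = "signal"`.
#' @param s0 Calibrated signal scale for this region (see [calibrate_s0()]).
#' @param params An [sr_params()] object.
#' @param region `"tissue"` or `"blood"`; selects which native T1 to subtract.
#' @return A [ts_curve()] with `kind = "delta_r1"` (units 1/s).
#' @export
delta_r1_curve <- function(curve, s0, params, region = c("tissue", "blood")) {
  region <- match.arg(region)
  if (!inherits(curve, "ts_curve") || curve$kind != "signal") {
    stop("`curve` must be a ts_curve of kind 'signal'", call. = FALSE)
  }
  t1 <- if (region == "tissue") params$t1_native_tissue else params$t1_native_blood
  r1 <- r1_from_signal(curve$values, s0, params)
  ts_curve(curve$times, r1 - .r1_native(t1), kind = "delta_r1")
}
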