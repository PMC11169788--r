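#' Gamma-variate arterial input function
#'
#' \eqn{\Delta R1(t) = A\,((t-t_0)/(\alpha\beta))^{\alpha}
#' e^{\alpha-(t-t_0)/\beta}} for \eqn{t > t_0} (zero before bolus arrival),
#' parameterised by its peak value `peak` attained at `t0 + alpha*beta`; an
#' optional recirculation bump re-enters a fraction of the bolus with a
#' broadened shape.
#'
#' @param n_frames Number of frames.
#' @param dt Frame spacing in seconds (one heartbeat, default 0.8 s).
#' @param peak Peak \eqn{\Delta R1} of the first pass, 1/s (may be 0).
#' @param t0 Bolus arrival time, s.
#' @param alpha,beta Gamma-variate shape and scale.
#' @param recirc_frac Peak fraction of the recirculation bump (default 0).
#' @param recirc_delay Delay of the recirculation bump, s.
#' @param times Optional explicit time grid (overrides `n_frames`/`dt`).
#' @return A [ts_curve()] of kind `delta_r1`.
#' @export
gen_aif <- function(n_frames = 60L, dt = 0.8, peak = 4, t0 = 5,
                    alpha = 2.5, beta = 1.5, recirc_frac = 0,
                    recirc_delay = 12, times = NULL) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive", call. = FALSE)
  if (peak < 0) stop("`peak` must be non-negative", call. = FALSE)
  if (is.null(times)) times <- seq(0, by = dt, length.out = n_frames)
  if (max(times) < t0 + 30) {
    stop("time grid must cover bolus onset plus 30 s", call. = FALSE)
  }
  v <- .gamma_variate(times, peak, t0, alpha, beta)
  if (recirc_frac > 0) {
    v <- v + .gamma_variate(times, recirc_frac * peak, t0 + recirc_delay,
                            alpha, 2 * beta)
  }
  ts_curve(times, v, kind = "delta_r1")
}

# peak-normalised gamma variate (peak value `peak` at t0 + alpha*beta)
.gamma_variate <- function(t, peak, t0, alpha, beta) {
  u <- pmax(t - t0, 0)
  ifelse(u > 0, peak * (u / (alpha * beta))^alpha * exp(alpha - u / beta), 0)
}

#' Ground truth for a synthetic first-pass dataset
#'
#' @param mbf True MBF per segment, ml/min/g; a scalar is recycled to the 16
#'   AHA segments.
#' @param residue Residue (impulse-retention) model: `"exponential"` (rate
#'   `F / lambda_p`) or `"fermi"`.
#' @param aif List of [gen_aif()] parameters (`peak`, `t0`, `alpha`, `beta`).
#' @param snr Signal-to-noise ratio of the tissue curves: peak myocardial
#'   signal enhancement divided by the image noise SD.  The same absolute
#'   noise SD is applied to every curve (image noise is spatially uniform),
#'   so the arterial input -- whose enhancement is several-fold larger --
#'   carries proportionally less relative noise.  `Inf` for noiseless data.
#' @param lambda_p Tissue distribution volume of the exponential residue
#'   (ml/ml).
#' @param fermi_tau0,fermi_k Fermi residue shoulder position and width, s.
#' @param density_g_per_ml Myocardial density, g/ml.
#' @param seed Seed used when noise is generated.
#' @return List of class `perfusion_truth`.
#' @export
perfusion_truth <- function(mbf = 0.9, residue = c("exponential", "fermi"),
                            aif = list(peak = 4, t0 = 5, alpha = 2.5, beta = 1.5),
                            snr = Inf, lambda_p = 0.1,
                            fermi_tau0 = 4, fermi_k = 1,
                            density_g_per_ml = 1.05, seed = 1L) {
  residue <- match.arg(residue)
  if (length(mbf) == 1L) mbf <- rep(mbf, 16L)
  if (length(mbf) != 16L) stop("`mbf` must have length 1 or 16", call. = FALSE)
  if (any(mbf < 0)) stop("`mbf` must be non-negative", call. = FALSE)
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  structure(list(mbf = mbf, residue = residue, aif = aif, snr = snr,
                 lambda_p = lambda_p, fermi_tau0 = fermi_tau0,
                 fermi_k = fermi_k, density_g_per_ml = density_g_per_ml,
                 seed = as.integer(seed)),
            class = "perfusion_truth")
}

.residue_fn <- function(truth) {
  switch(truth$residue,
         exponential = function(t, F) exp(-t * F / truth$lambda_p),
         fermi = function(t, F) {
           (1 + exp(-truth$fermi_tau0 / truth$fermi_k)) /
             (1 + exp((t - truth$fermi_tau0) / truth$fermi_k))
         })
}

#' Generate a synthetic first-pass perfusion curve set
#'
#' Forward model on a heavily oversampled grid: tissue \eqn{\Delta R1} is the
#' convolution (trapezoidal rule) of the gamma-variate arterial input with
#' the flow-scaled residue (impulse response `h(t) = F * R(t)` with
#' `F = mbf * density / 60` in 1/s), sampled back to the frame grid, pushed
#' through the saturation-recovery signal model with a per-region scale, and
#' degraded with Gaussian image noise at the configured SNR.  The truth
#' record is returned alongside.
#'
#' @param truth A [perfusion_truth()].
#' @param params An [sr_params()].
#' @param n_frames,dt Frame grid (defaults 60 frames at 0.8 s).
#' @param s0_tissue,s0_blood True per-region signal scales, a.u.
#' @param oversample Oversampling factor of the internal convolution grid.
#' @param seed Noise seed; defaults to `truth$seed`.
#' @return List with `curves` (a [curve_set()] of signal curves) and `truth`.
#' @export
gen_perfusion_dataset <- function(truth = perfusion_truth(),
                                  params = sr_params(),
                                  n_frames = 60L, dt = 0.8,
                                  s0_tissue = 500, s0_blood = 500,
                                  oversample = 20L, seed = truth$seed) {
  times <- seq(0, by = dt, length.out = n_frames)
  dtf <- dt / oversample
  tf <- seq(0, max(times), by = dtf)
  aif_f <- .gamma_variate(tf, truth$aif$peak, truth$aif$t0,
                          truth$aif$alpha, truth$aif$beta)
  idx <- match(round(times / dtf), round(tf / dtf))
  Rfn <- .residue_fn(truth)

  seg_dr1 <- vapply(truth$mbf, function(m) {
    F <- m * truth$density_g_per_ml / 60
    if (F == 0) return(rep(0, n_frames))
    h <- F * Rfn(tf, F)
    conv <- stats::convolve(aif_f, rev(h), type = "open")[seq_along(tf)] * dtf
    # trapezoidal endpoint correction of the rectangle-rule convolution
    conv <- conv - 0.5 * dtf * (aif_f * h[1] + aif_f[1] * h)
    conv[idx]
  }, numeric(n_frames))
  colnames(seg_dr1) <- sprintf("seg_%02d", 1:16)
  aif_dr1 <- aif_f[idx]

  r1n_t <- .r1_native(params$t1_native_tissue)
  r1n_b <- .r1_native(params$t1_native_blood)
  sig_seg <- s0_tissue * (1 - exp(-params$ts * (r1n_t + seg_dr1)))
  sig_aif <- s0_blood * (1 - exp(-params$ts * (r1n_b + aif_dr1)))

  if (is.finite(truth$snr)) {
    baseline <- colMeans(sig_seg[seq_len(min(5L, n_frames)), , drop = FALSE])
    enhance <- max(apply(sig_seg, 2, max) - baseline)
    if (enhance <= 0) enhance <- max(sig_aif) - sig_aif[1]
    sd_img <- enhance / truth$snr
    noise <- withr::with_seed(seed, {
      list(seg = matrix(stats::rnorm(length(sig_seg), 0, sd_img),
                        nrow = n_frames),
           aif = stats::rnorm(n_frames, 0, sd_img))
    })
    sig_seg <- sig_seg + noise$seg
    sig_aif <- sig_aif + noise$aif
    if (any(sig_seg >= s0_tissue) || any(sig_aif >= s0_blood)) {
      stop("generated signal reaches the saturation ceiling; increase s0 or lower the AIF peak",
           call. = FALSE)
    }
    sig_seg[sig_seg < 0] <- 0
    sig_aif[sig_aif < 0] <- 0
  }
  list(curves = curve_set(times, sig_aif, sig_seg, kind = "signal"),
       truth = truth)
}

#' Generate synthetic T1-mapping R1 triplets
#'
#' Blood R1 follows a contrast-washout schedule over the timepoints (pre,
#' 10 min, 20 min); tissue R1 is `intercept + lambda * r1_blood` plus
#' Gaussian noise, so [partition_coefficient()] recovers `lambda` exactly at
#' `noise_sd = 0`.
#'
#' @param true_lambda True partition coefficient per segment (scalar recycled
#'   to 16 segments).
#' @param hct Hematocrit fraction.
#' @param noise_sd SD of the tissue-R1 noise, 1/s.
#' @param seed Noise seed.
#' @param r1_blood Named blood R1 schedule (1/s) at `pre`, `post10`,
#'   `post20`.
#' @param t1_native_tissue Native tissue T1 (ms), anchoring the pre-contrast
#'   tissue R1 (and hence the intercept).
#' @return List with `samples` (long data frame `segment`, `timepoint`,
#'   `r1_blood_per_s`, `r1_tissue_per_s`) and `truth`.
#' @export
gen_t1_dataset <- function(true_lambda = 0.5, hct = 0.40, noise_sd = 0,
                           seed = 1L,
                           r1_blood = c(pre = 0.6, post10 = 2.0, post20 = 1.4),
                           t1_native_tissue = 1232) {
  if (any(true_lambda <= 0)) stop("`true_lambda` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(true_lambda) == 1L) true_lambda <- rep(true_lambda, 16L)
  if (length(true_lambda) != 16L) stop("`true_lambda` must have length 1 or 16", call. = FALSE)
  segs <- sprintf("seg_%02d", 1:16)
  intercept <- .r1_native(t1_native_tissue) - true_lambda * r1_blood[["pre"]]
  grid <- expand.grid(segment = segs, timepoint = names(r1_blood),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lam <- true_lambda[match(grid$segment, segs)]
  icpt <- intercept[match(grid$segment, segs)]
  rb <- r1_blood[grid$timepoint]
  rt <- icpt + lam * rb
  if (noise_sd > 0) {
    rt <- rt + withr::with_seed(seed, stats::rnorm(length(rt), 0, noise_sd))
  }
  samples <- data.frame(segment = grid$segment, timepoint = grid$timepoint,
                        r1_blood_per_s = unname(rb),
                        r1_tissue_per_s = unname(rt),
                        stringsAsFactors = FALSE)
  list(samples = samples,
       truth = list(lambda = stats::setNames(true_lambda, segs), hct = hct,
                    intercept = stats::setNames(intercept, segs),
                    noise_sd = noise_sd, seed = as.integer(seed),
                    ecv = stats::setNames((1 - hct) * true_lambda, segs)))
}

#' Structural cohort ground truth
#'
#' Defaults are calibrated once to the marginal summaries a cohort of this
#' kind exhibits (ECV 46 +/- 10 %, rest MBF 0.87 +/- 0.21 ml/min/g, MWE
#' 3.61 +/- 1.68 mmHg·L/min/g, and the tertile and correlation structure
#' among them); they live in `inst/extdata/cohort_defaults.json`.
#' Path coefficients are standardized: `path_a` (ECV -> MBF), `path_b`
#' (MBF -> MWE), `path_c_prime` (direct ECV -> MWE), `path_rpp`
#' (RPP -> MBF).
#'
#' @param ... Named overrides of any default (see the JSON file for the full
#'   list).
#' @return List of class `cohort_truth`.
#' @export
cohort_truth <- function(...) {
  defaults <- jsonlite::read_json(
    system.file("extdata", "cohort_defaults.json", package = "myoflow",
                mustWork = TRUE),
    simplifyVector = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown cohort_truth field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  if (defaults$n < 3L) stop("`n` must be >= 3", call. = FALSE)
  structure(defaults, class = "cohort_truth")
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a structural synthetic cohort
#'
#' Draws a subject table and a 16-segment table with a known causal
#' structure: ECV (truncated normal) affects rest MBF directly
#' (`path_a`), MBF affects surrogate MWE (`path_b`), and ECV retains a
#' direct effect on MWE (`path_c_prime`); the RPP contributes to MBF
#' (`path_rpp`).  Hemodynamic columns are back-solved so that
#' `mwe = co * map / lv_mass` holds row-wise exactly; LGE follows a logistic
#' dependence on ECV; segmental tables carry a within-subject ECV effect and
#' a base-to-apex MBF increment in the upper two ECV tertiles.
#'
#' @param truth A [cohort_truth()].
#' @param seed Integer seed (mandatory; the generator is a pure function of
#'   `(truth, seed)`).
#' @return List with `subjects`, `segments` and `truth` (the input truth
#'   augmented with the derived raw-scale paths and residual SDs under
#'   `$derived`).
#' @export
gen_cohort <- function(truth = cohort_truth(), seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  tr <- truth
  n <- tr$n
  a_raw <- tr$path_a * tr$mbf_sd / tr$ecv_sd
  g_raw <- tr$path_rpp * tr$mbf_sd /
    (sqrt(tr$sbp_sd^2 * tr$hr_sd^2 + tr$sbp_sd^2 * tr$hr_mean^2 +
            tr$hr_sd^2 * tr$sbp_mean^2) / 1e4)
  b_raw <- tr$path_b * tr$mwe_sd / tr$mbf_sd
  c_raw <- tr$path_c_prime * tr$mwe_sd / tr$ecv_sd
  sd_m <- tr$mbf_sd * sqrt(max(0, 1 - tr$path_a^2 - tr$path_rpp^2))
  expl_y <- tr$path_c_prime^2 + tr$path_b^2 +
    2 * tr$path_a * tr$path_b * tr$path_c_prime
  sd_y <- tr$mwe_sd * sqrt(max(0, 1 - expl_y))

  out <- withr::with_seed(seed, {
    sbp <- .rnorm_trunc(n, tr$sbp_mean, tr$sbp_sd, 80, 200)
    dbp <- pmin(.rnorm_trunc(n, tr$dbp_mean, tr$dbp_sd, 40, 130), sbp - 10)
    hr <- .rnorm_trunc(n, tr$hr_mean, tr$hr_sd, 45, 130)
    rpp <- sbp * hr / 1e4
    ecv <- .rnorm_trunc(n, tr$ecv_mean, tr$ecv_sd, tr$ecv_min, tr$ecv_max)
    mbf <- pmax(0.05, tr$mbf_mean + a_raw * (ecv - tr$ecv_mean) +
                  g_raw * (rpp - tr$sbp_mean * tr$hr_mean / 1e4) +
                  stats::rnorm(n, 0, sd_m))
    mwe_v <- tr$mwe_mean + c_raw * (ecv - tr$ecv_mean) +
      b_raw * (mbf - tr$mbf_mean) + stats::rnorm(n, 0, sd_y)
    n_resampled <- 0L
    bad <- which(mwe_v <= tr$mwe_min)
    while (length(bad) > 0L) {
      n_resampled <- n_resampled + length(bad)
      mwe_v[bad] <- tr$mwe_mean + c_raw * (ecv[bad] - tr$ecv_mean) +
        b_raw * (mbf[bad] - tr$mbf_mean) +
        stats::rnorm(length(bad), 0, sd_y)
      bad <- which(mwe_v <= tr$mwe_min)
    }

    bsa <- .rnorm_trunc(n, tr$bsa_mean, tr$bsa_sd, 1.3, 2.6)
    ci <- .rnorm_trunc(n, tr$cardiac_index_mean, tr$cardiac_index_sd, 1.5, 5.5)
    co <- ci * bsa
    sv <- 1000 * co / hr
    lvef <- pmin(pmax(tr$lvef_ref + tr$lvef_slope * (ecv - tr$lvef_ref_ecv) +
                        stats::rnorm(n, 0, tr$lvef_sd), 15), 80)
    edv <- sv / (lvef / 100)
    esv <- edv - sv
    map <- dbp + (sbp - dbp) / 3
    lv_mass <- co * map / mwe_v  # back-solve: mwe == co * map / mass
    hct <- .rnorm_trunc(n, tr$hct_mean, tr$hct_sd, 0.25, 0.55)

    lge <- stats::rbinom(n, 1, stats::plogis(log(tr$lge_or_per_pct) *
                                               (ecv - tr$lge_midpoint_ecv)))
    u <- -(mwe_v - mean(mwe_v)) / stats::sd(mwe_v) +
      stats::rnorm(n, 0, tr$nyha_noise_sd)
    cp <- stats::quantile(u, cumsum(tr$nyha_probs) / sum(tr$nyha_probs),
                          names = FALSE)
    nyha <- 1L + findInterval(u, cp[1:3])
    nt_probnp <- exp(log(tr$ntprobnp_median) +
                       tr$ntprobnp_logslope * (ecv - tr$ecv_mean) +
                       stats::rnorm(n, 0, tr$ntprobnp_logsd))
    troponin <- exp(log(tr$troponin_median) +
                      tr$troponin_logslope * (ecv - tr$ecv_mean) +
                      stats::rnorm(n, 0, tr$troponin_logsd))
    dflc <- exp(log(tr$dflc_median) + stats::rnorm(n, 0, tr$dflc_logsd))
    gls <- tr$gls_ref + tr$gls_slope * (ecv - tr$lvef_ref_ecv) +
      stats::rnorm(n, 0, tr$gls_sd)
    la_volume <- pmax(15, tr$la_index_ref +
                        tr$la_index_slope * (ecv - tr$lvef_ref_ecv) +
                        stats::rnorm(n, 0, tr$la_index_sd)) * bsa
    al_status <- ifelse(stats::runif(n) < tr$remission_frac,
                        "remission", "recent")

    subjects <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      sbp = sbp, dbp = dbp, hr = hr, edv = edv, esv = esv, sv = sv,
      lv_mass = lv_mass, bsa = bsa, hct = hct,
      global_ecv = ecv / 100, rest_mbf = mbf, nyha = nyha,
      lge_present = lge, nt_probnp = nt_probnp, troponin_t = troponin,
      dflc = dflc, al_status = al_status, lvef = lvef,
      la_volume = la_volume, gls = gls,
      stringsAsFactors = FALSE)

    # segmental table: within-subject ECV scatter (centred so the subject
    # mean matches the global value), base-to-apex increments in the upper
    # two ECV tertiles, segment-level noise
    map16 <- aha_segment_map()
    tert <- tertile_stratify(ecv)$labels
    seg_rows <- lapply(seq_len(n), function(i) {
      e <- stats::rnorm(16, 0, tr$seg_ecv_sd)
      ecv_seg <- ecv[i] + e - mean(e)
      inc <- rep(0, 16)
      if (tert[i] %in% c("middle", "upper")) {
        inc[map16$slice == "mid"] <- tr$base_apex_mid
        inc[map16$slice == "apical"] <- tr$base_apex_apex
      }
      mbf_seg <- mbf[i] + tr$seg_ecv_slope * (ecv_seg - ecv[i]) + inc +
        stats::rnorm(16, 0, tr$seg_mbf_sd)
      data.frame(subject_id = subjects$id[i], segment = map16$segment,
                 slice = map16$slice, wall_class = map16$wall_class,
                 ecv_seg_pct = ecv_seg, mbf_seg = mbf_seg,
                 rpp_index = rpp[i], ecv_tertile = as.character(tert[i]),
                 stringsAsFactors = FALSE)
    })
    list(subjects = subjects, segments = do.call(rbind, seg_rows),
         n_resampled = n_resampled)
  })

  tr$derived <- list(a_raw = a_raw, b_raw = b_raw, c_prime_raw = c_raw,
                     rpp_raw = g_raw, resid_sd_mbf = sd_m,
                     resid_sd_mwe = sd_y, n_resampled = out$n_resampled,
                     seed = as.integer(seed))
  list(subjects = out$subjects, segments = out$segments, truth = tr)
}
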