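#' Gadolinium partition coefficient of one segment
#'
#' Ordinary least-squares regression of segmental tissue R1 on blood R1 across
#' the contrast timepoints (typically pre-contrast, 10 min and 20 min
#' post-contrast).  The slope is the partition coefficient \eqn{\lambda_{Gd}};
#' using all three timepoints rather than a single pre/post pair lowers the
#' variance of the resulting ECV estimate.
#'
#' @param r1_blood Blood relaxation rates (1/s), one per timepoint.
#' @param r1_tissue Tissue relaxation rates (1/s), same length.
#' @return A list with `lambda_gd` (dimensionless slope) and `intercept`
#'   (1/s).
#' @export
partition_coefficient <- function(r1_blood, r1_tissue) {
  if (length(r1_blood) != length(r1_tissue) || length(r1_blood) < 2L) {
    stop("need >= 2 paired (blood, tissue) R1 samples", call. = FALSE)
  }
  if (any(r1_blood <= 0) || any(r1_tissue <= 0)) {
    stop("R1 values must be positive", call. = FALSE)
  }
  sxx <- sum((r1_blood - mean(r1_blood))^2)
  if (sxx <= .Machine$double.eps) {
    stop("degenerate design: all blood R1 values are equal", call. = FALSE)
  }
  slope <- sum((r1_blood - mean(r1_blood)) * (r1_tissue - mean(r1_tissue))) / sxx
  list(lambda_gd = slope, intercept = mean(r1_tissue) - slope * mean(r1_blood))
}

#' Extracellular volume fraction from the partition coefficient
#'
#' `ecv = (1 - hct) * lambda_gd`, with the hematocrit as a fraction in
#' `[0, 1)`.  Returned as a fraction; reports render it as percent.
#'
#' @param lambda_gd Partition coefficient (dimensionless).
#' @param hct Hematocrit fraction, `0 <= hct < 1`.
#' @return ECV fraction.
#' @export
ecv_from_lambda <- function(lambda_gd, hct) {
  if (any(hct < 0) || any(hct >= 1)) {
    stop("`hct` must be a fraction in [0, 1)", call. = FALSE)
  }
  (1 - hct) * lambda_gd
}

#' Global ECV as the unweighted mean over valid segments
#'
#' @param segment_ecvs Numeric vector of per-segment ECV fractions; `NA`s
#'   (non-diagnostic segments) are dropped with a warning.
#' @return Global ECV fraction.
#' @export
global_ecv <- function(segment_ecvs) {
  ok <- !is.na(segment_ecvs)
  if (!any(ok)) stop("no valid segmental ECV values", call. = FALSE)
  if (any(!ok)) {
    warning(sprintf("global ECV averaged over %d of %d segments (%d missing)",
                    sum(ok), length(segment_ecvs), sum(!ok)), call. = FALSE)
  }
  mean(segment_ecvs[ok])
}

#' Per-segment ECV table from R1 triplets
#'
#' Runs [partition_coefficient()] and [ecv_from_lambda()] for every segment in
#' a long-format R1 table and appends a `GLOBAL` row with the unweighted mean.
#'
#' @param t1_table Data frame with columns `segment`, `timepoint`,
#'   `r1_blood_per_s`, `r1_tissue_per_s` (the on-disk dialect of
#'   [read_t1_samples()]).
#' @param hct Subject hematocrit fraction.
#' @return Data frame `segment`, `lambda_gd`, `intercept`, `ecv_pct` with a
#'   final `GLOBAL` row (ECV in percent).
#' @export
quantify_ecv <- function(t1_table, hct) {
  need <- c("segment", "timepoint", "r1_blood_per_s", "r1_tissue_per_s")
  if (!all(need %in% names(t1_table))) {
    stop("t1_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  segs <- unique(t1_table$segment)
  rows <- lapply(segs, function(s) {
    d <- t1_table[t1_table$segment == s, ]
    fit <- partition_coefficient(d$r1_blood_per_s, d$r1_tissue_per_s)
    data.frame(segment = s, lambda_gd = fit$lambda_gd,
               intercept = fit$intercept,
               ecv_pct = 100 * ecv_from_lambda(fit$lambda_gd, hct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(segment = "GLOBAL",
                        lambda_gd = mean(out$lambda_gd),
                        intercept = mean(out$intercept),
                        ecv_pct = 100 * global_ecv(out$ecv_pct / 100)))
}
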