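#' Tertile stratification
#'
#' Cuts at the 1/3 and 2/3 type-7 sample quantiles with left-open
#' right-closed intervals.  Missing values are excluded and counted.
#'
#' @param values Numeric vector; at least 3 non-missing values required.
#' @return Object of class `tertiles`: list with `boundaries` (two cuts),
#'   `labels` (factor `lower`/`middle`/`upper`, `NA` where `values` was
#'   missing) and `n_missing`.
#' @export
tertile_stratify <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  cuts <- stats::quantile(values[ok], probs = c(1, 2) / 3, type = 7,
                          names = FALSE)
  if (diff(cuts) <= .Machine$double.eps * max(1, abs(cuts[2]))) {
    stop("degenerate ties: tertile boundaries coincide", call. = FALSE)
  }
  labels <- cut(values, breaks = c(-Inf, cuts, Inf),
                labels = c("lower", "middle", "upper"), right = TRUE)
  structure(list(boundaries = cuts, labels = labels,
                 n_missing = sum(!ok)),
            class = "tertiles")
}

#' Linear trend test across ordered groups
#'
#' Regresses the outcome on the ordinal group score (1, 2, 3) and tests the
#' slope with a two-sided t-test.
#'
#' @param outcome Numeric outcome, one value per subject.
#' @param groups A `tertiles` object or a factor of ordered group labels.
#' @return List with `slope`, `se`, `p`, `n`.
#' @export
linear_trend_test <- function(outcome, groups) {
  if (inherits(groups, "tertiles")) groups <- groups$labels
  score <- as.integer(groups)
  ok <- !is.na(outcome) & !is.na(score)
  if (length(unique(score[ok])) < 2L) {
    stop("need at least 2 populated groups for a trend test", call. = FALSE)
  }
  fit <- stats::lm(outcome[ok] ~ score[ok])
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co[2, 1]
  se <- co[2, 2]
  p <- co[2, 4]
  # degenerate zero-residual designs: constant outcome -> no trend (p = 1),
  # exact nonzero trend -> p = 0
  rss <- sum(stats::residuals(fit)^2)
  if (!is.finite(p) || rss < 1e-16 * max(1, sum(outcome[ok]^2))) {
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  list(slope = slope, se = se, p = p, n = sum(ok))
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations with t-distributed p-values; cells
#' with fewer than 3 complete pairs are left missing.
#'
#' @param table Data frame.
#' @param variables Character vector of column names to correlate.
#' @return List of class `pearson_matrix` with matrices `r`, `p`, `n`.
#' @export
pearson_matrix <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- table[[variables[i]]]
      y <- table[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      nmat[i, j] <- sum(ok)
      if (sum(ok) < 3L) next
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r[i, j] <- unname(ct$estimate)
        p[i, j] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "pearson_matrix")
}

#' Stepwise-AIC multivariable model with forced covariates
#'
#' Bidirectional stepwise selection minimising AIC over the candidate terms,
#' with the forced terms (typically age and sex) present in every visited
#' model.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns (may be
#'   empty, in which case the forced-terms model is returned).
#' @param forced Character vector of columns always kept in the model.
#' @return List with `model` (the final `lm`), `coefficients` (summary
#'   table), `selected` (candidate terms retained) and `trace` (the stepwise
#'   `anova` component, `NULL` when no selection ran).
#' @export
stepwise_aic <- function(data, outcome, candidates, forced = character(0)) {
  stopifnot(outcome %in% names(data),
            all(candidates %in% names(data)),
            all(forced %in% names(data)))
  data <- data[stats::complete.cases(data[, c(outcome, candidates, forced)]), ]
  if (nrow(data) <= length(candidates) + 2L) {
    stop("too few complete cases for the candidate pool", call. = FALSE)
  }
  rhs_low <- if (length(forced) > 0L) paste(forced, collapse = " + ") else "1"
  if (length(candidates) == 0L) {
    fit <- stats::lm(stats::reformulate(rhs_low, response = outcome), data = data)
    return(list(model = fit, coefficients = summary(fit)$coefficients,
                selected = character(0), trace = NULL))
  }
  rhs_full <- paste(c(forced, candidates), collapse = " + ")
  full <- stats::lm(stats::reformulate(rhs_full, response = outcome), data = data)
  lower <- stats::reformulate(rhs_low)
  upper <- stats::reformulate(rhs_full)
  step <- MASS::stepAIC(full, scope = list(lower = lower, upper = upper),
                        direction = "both", trace = 0)
  kept <- attr(stats::terms(step), "term.labels")
  list(model = step, coefficients = summary(step)$coefficients,
       selected = intersect(candidates, kept), trace = step$anova)
}

# mediation path estimates by closed-form OLS: a from m ~ x, (c', b) from
# y ~ x + m; all on centred data, intercepts dropped
.med_paths <- function(x, m, y) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc * xc); sxm <- sum(xc * mc); smm <- sum(mc * mc)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  a <- sxm / sxx
  det <- sxx * smm - sxm * sxm
  c_prime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c(a = a, b = b, c_prime = c_prime, indirect = a * b,
    total = c_prime + a * b)
}

#' Bootstrap mediation of an exposure on an outcome through a mediator
#'
#' Linear mediation model for the decomposition of the effect of ECV
#' (exposure `x`) on surrogate MWE (outcome `y`) into a direct path and an
#' indirect path through rest MBF (mediator `m`): path `a` from the OLS of
#' `m` on `x`, paths `b` and `c'` from the OLS of `y` on `x` and `m`;
#' `indirect = a * b`, `total = c' + a * b` (exact linear identity).
#' Percentile confidence intervals come from nonparametric case-resampling
#' bootstrap; standardized coefficients are the same fits on z-scored
#' variables; effects are additionally rescaled per 5-unit change of the
#' exposure (a 5-percentage-point ECV increment when `x` is ECV in percent).
#'
#' @param x Exposure (e.g. ECV in percent).
#' @param m Mediator (e.g. rest MBF, ml/min/g).
#' @param y Outcome (e.g. surrogate MWE, mmHg·L/min/g).
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling (mandatory).
#' @param conf_level Confidence level for the percentile intervals.
#' @param include_direct If `FALSE`, fit the restricted model without the
#'   direct path (`c' = 0`); the model then has one degree of freedom and a
#'   non-trivial RMSEA (see [rmsea()]).
#' @return Object of class `mediation_fit`: estimates (raw, standardized and
#'   per-5-unit), bootstrap SEs and percentile CIs, effect shares, `n`, `df`
#'   and the likelihood-ratio discrepancy `chisq` of the fitted structure.
#' @export
fit_mediation <- function(x, m, y, n_boot = 2000L, seed = 1L,
                          conf_level = 0.95, include_direct = TRUE) {
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 complete cases", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance in x, m or y", call. = FALSE)
  }

  point <- if (include_direct) .med_paths(x, m, y) else .med_paths_nodirect(x, m, y)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  std <- if (include_direct) .med_paths(zs(x), zs(m), zs(y)) else
    .med_paths_nodirect(zs(x), zs(m), zs(y))

  boot <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (include_direct) .med_paths(x[idx], m[idx], y[idx]) else
        .med_paths_nodirect(x[idx], m[idx], y[idx])
    }, numeric(5)))
  })
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  se <- apply(boot, 2, stats::sd)

  # model degrees of freedom and ML discrepancy of the fitted covariance
  # structure; the model with a direct path is just-identified (df = 0)
  if (include_direct) {
    df <- 0L; chisq <- 0
  } else {
    df <- 1L
    chisq <- .med_chisq_nodirect(x, m, y)
  }

  structure(list(
    estimates = point,
    standardized = std,
    per5 = point * 5,  # x-scale effects per 5-unit exposure change
    boot_se = se,
    boot_ci = ci,
    per5_ci = ci[, c("a", "c_prime", "indirect", "total")] * 5,
    share_indirect = unname(point["indirect"] / point["total"]),
    share_direct = unname(point["c_prime"] / point["total"]),
    n = n, n_boot = n_boot, df = df, chisq = chisq,
    conf_level = conf_level, include_direct = include_direct),
    class = "mediation_fit")
}

.med_paths_nodirect <- function(x, m, y) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  a <- sum(xc * mc) / sum(xc * xc)
  b <- sum(mc * yc) / sum(mc * mc)
  c(a = a, b = b, c_prime = 0, indirect = a * b, total = a * b)
}

# ML chi-square of the x -> m -> y chain without a direct path: the only
# unreproduced moment is cov(x, y)
.med_chisq_nodirect <- function(x, m, y) {
  n <- length(x)
  S <- stats::cov(cbind(x, m, y)) * (n - 1) / n
  a <- S["x", "m"] / S["x", "x"]
  b <- S["m", "y"] / S["m", "m"]
  Sigma <- S
  Sigma["x", "y"] <- Sigma["y", "x"] <- a * b * S["x", "x"]
  f_ml <- log(det(Sigma)) - log(det(S)) +
    sum(diag(S %*% solve(Sigma))) - 3
  (n - 1) * max(0, f_ml)
}

#' @export
print.mediation_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<mediation_fit: n = %d, a = %.4g, b = %.4g, c' = %.4g>\n",
              x$n, e["a"], e["b"], e["c_prime"]))
  cat(sprintf("  indirect = %.4g, total = %.4g; shares: %.0f%% indirect / %.0f%% direct\n",
              e["indirect"], e["total"], 100 * x$share_indirect,
              100 * x$share_direct))
  invisible(x)
}

#' Direct/indirect effect shares
#'
#' Decomposes a total effect into percentage shares of its direct and
#' indirect components (linear mediation: `total = direct + indirect`).
#'
#' @param direct Direct effect (any consistent scale, e.g. per 5% ECV).
#' @param indirect Indirect effect on the same scale.
#' @return List with `share_direct_pct` and `share_indirect_pct` (summing to
#'   100).
#' @export
mediation_shares <- function(direct, indirect) {
  total <- direct + indirect
  if (total == 0) stop("total effect is zero; shares undefined", call. = FALSE)
  list(share_direct_pct = 100 * direct / total,
       share_indirect_pct = 100 * indirect / total)
}

#' RMSEA of a fitted mediation structure
#'
#' Root mean square error of approximation,
#' `sqrt(max(0, (chisq - df) / (df * (n - 1))))`.  The mediation model with a
#' direct path is just-identified (df = 0) and has RMSEA 0 by construction;
#' the restricted model without the direct path has df = 1.
#'
#' @param fit A [fit_mediation()] result.
#' @return List with `rmsea`, `df`, `chisq`.
#' @export
rmsea <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  val <- if (fit$df == 0L) 0 else
    sqrt(max(0, (fit$chisq - fit$df) / (fit$df * (fit$n - 1))))
  list(rmsea = val, df = fit$df, chisq = fit$chisq)
}

#' Random-intercept linear mixed model
#'
#' REML fit (via `lme4`) of a response on fixed-effect predictors with random
#' intercepts for one or more grouping factors, nested (default, e.g. slice
#' within patient) or crossed.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect predictor columns.
#' @param grouping Character vector of grouping columns, outermost first.
#' @param nested If `TRUE` (default) successive grouping factors are nested
#'   inside the previous ones; if `FALSE` they are crossed.
#' @return Object of class `lmm_fit`: list with `fixed` (estimate, SE, t, and
#'   Wald p per fixed effect), `varcomp` (between-group variance components
#'   and the residual variance), `reml_loglik`, `grouping` descriptor and the
#'   underlying `merMod` object as `model`.
#' @export
fit_lmm_random_intercept <- function(data, response, fixed, grouping,
                                     nested = TRUE) {
  stopifnot(response %in% names(data), all(fixed %in% names(data)),
            all(grouping %in% names(data)))
  if (length(grouping) < 1L) stop("need at least one grouping factor", call. = FALSE)
  g1 <- data[[grouping[1]]]
  if (length(unique(g1)) < 2L) {
    stop("random intercept unidentifiable: fewer than 2 groups in '",
         grouping[1], "'", call. = FALSE)
  }
  terms <- if (nested) {
    vapply(seq_along(grouping), function(k) {
      paste0("(1 | ", paste(grouping[seq_len(k)], collapse = ":"), ")")
    }, character(1))
  } else {
    paste0("(1 | ", grouping, ")")
  }
  rhs <- paste(c(if (length(fixed) > 0L) fixed else "1", terms), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressMessages(suppressWarnings(tryCatch({
    model <- lme4::lmer(form, data = data, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
    co <- as.data.frame(summary(model)$coefficients)
    vc <- as.data.frame(lme4::VarCorr(model))
    list(co = co, varcomp = stats::setNames(vc$vcov, vc$grp),
         loglik = as.numeric(stats::logLik(model)), model = model)
  }, error = function(e) NULL)))
  if (is.null(fit)) {
    # degenerate response (e.g. exactly constant): fall back to the fixed-
    # effects OLS fit with zero variance components
    ols <- stats::lm(stats::reformulate(
      if (length(fixed) > 0L) fixed else "1", response = response),
      data = data)
    co <- as.data.frame(
      suppressWarnings(summary(ols))$coefficients[, 1:3, drop = FALSE])
    fit <- list(co = co,
                varcomp = stats::setNames(rep(0, length(grouping) + 1L),
                                          c(grouping, "Residual")),
                loglik = NA_real_, model = ols)
  }
  co <- fit$co
  names(co) <- c("estimate", "se", "t")[seq_len(ncol(co))]
  co$p_wald <- 2 * stats::pnorm(-abs(co$t))
  # zero-residual designs: a zero slope is no evidence, an exact one is
  deg <- !is.finite(co$p_wald)
  co$p_wald[deg] <- ifelse(abs(co$estimate[deg]) < 1e-12, 1, 0)
  co$t[!is.finite(co$t)] <- 0
  structure(list(fixed = co, varcomp = fit$varcomp,
                 reml_loglik = fit$loglik,
                 grouping = paste(grouping,
                                  collapse = if (nested) " / " else " x "),
                 model = fit$model),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit: grouping %s, REML logLik %.2f>\n", x$grouping,
              x$reml_loglik))
  print(round(x$fixed, 5))
  invisible(x)
}

#' Base-to-apex gradient analysis of segmental flow
#'
#' Per-subject slice-level means are modelled with slice location (basal
#' reference) as a fixed effect and a per-subject random intercept; slice
#' levels are additionally compared with paired t-tests, Holm-adjusted.
#'
#' @param segment_table Data frame with columns `subject_id`, `slice`
#'   (`basal`/`mid`/`apical`) and `mbf_seg`.
#' @param value Name of the value column (default `"mbf_seg"`).
#' @return List with `lmm` (an `lmm_fit` on slice-level means), `contrasts`
#'   (data frame `pair`, `estimate`, `p_raw`, `p_holm`) and `slice_means`.
#' @export
base_to_apex_analysis <- function(segment_table, value = "mbf_seg") {
  need <- c("subject_id", "slice", value)
  stopifnot(all(need %in% names(segment_table)))
  if (length(unique(segment_table$subject_id)) < 2L) {
    stop("random intercept unidentifiable with a single subject", call. = FALSE)
  }
  agg <- stats::aggregate(segment_table[[value]],
                          by = list(subject_id = segment_table$subject_id,
                                    slice = segment_table$slice),
                          FUN = mean)
  names(agg)[3] <- "value"
  lev <- intersect(c("basal", "mid", "apical"), unique(as.character(agg$slice)))
  if (length(lev) < 2L) stop("need at least 2 slice levels", call. = FALSE)
  agg$slice <- factor(agg$slice, levels = lev)
  lmm <- fit_lmm_random_intercept(agg, "value", "slice", "subject_id")

  wide <- stats::reshape(agg, idvar = "subject_id", timevar = "slice",
                         direction = "wide")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    v1 <- wide[[paste0("value.", pr[1])]]
    v2 <- wide[[paste0("value.", pr[2])]]
    ok <- stats::complete.cases(v1, v2)
    d <- v2[ok] - v1[ok]
    if (stats::sd(d) == 0) {
      est <- mean(d); p <- if (abs(est) < 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(d)
      est <- mean(d); p <- tt$p.value
    }
    data.frame(pair = paste(pr[2], "vs", pr[1]), estimate = est, p_raw = p,
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  contrasts$p_holm <- holm_adjust(contrasts$p_raw)
  slice_means <- stats::aggregate(agg$value, by = list(slice = agg$slice),
                                  FUN = mean)
  names(slice_means)[2] <- "mean"
  list(lmm = lmm, contrasts = contrasts, slice_means = slice_means)
}

#' Holm step-down multiple-comparison adjustment
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Logistic model of late gadolinium enhancement on ECV
#'
#' Maximum-likelihood logistic regression of the binary LGE flag on global
#' ECV (percent); reports the odds ratio per 1% ECV with a Wald confidence
#' interval.  Complete separation is detected and reported as an error.
#'
#' @param ecv_pct Global ECV in percent.
#' @param lge Binary LGE indicator (0/1 or logical).
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `or` (odds ratio per 1% ECV), `ci` (length-2), `slope`,
#'   `se`, `p`, `n` and the fitted `glm` as `model`.
#' @export
logistic_lge <- function(ecv_pct, lge, conf_level = 0.95) {
  lge <- as.integer(lge)
  ok <- stats::complete.cases(ecv_pct, lge)
  ecv_pct <- ecv_pct[ok]; lge <- lge[ok]
  if (length(unique(lge)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (max(ecv_pct[lge == 0]) < min(ecv_pct[lge == 1]) ||
      max(ecv_pct[lge == 1]) < min(ecv_pct[lge == 0])) {
    stop("complete separation: ECV perfectly predicts LGE; odds ratio unbounded",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(lge ~ ecv_pct, family = stats::binomial()))
  co <- summary(fit)$coefficients
  slope <- co["ecv_pct", "Estimate"]
  se <- co["ecv_pct", "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(slope), ci = exp(slope + c(-1, 1) * z * se),
       slope = slope, se = se, p = co["ecv_pct", "Pr(>|z|)"],
       n = length(lge), model = fit)
}

#' Exact power of the two-sample t-test
#'
#' Exact two-sided power from the noncentral t distribution.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param delta True difference of means.
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(n_per_group, delta, sd, alpha = 0.05) {
  if (n_per_group < 2L || sd <= 0) stop("need n >= 2 and sd > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (delta == 0) return(alpha)
  stats::power.t.test(n = n_per_group, delta = delta, sd = sd,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided")$power
}
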