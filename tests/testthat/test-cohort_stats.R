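test_that("tertile stratification uses type-7 cuts and handles missing", {
  t9 <- tertile_stratify(1:9)
  expect_equal(unname(t9$boundaries), c(11, 19) / 3, tolerance = 1e-12)
  expect_equal(as.character(t9$labels),
               rep(c("lower", "middle", "upper"), each = 3))
  expect_error(tertile_stratify(rep(5, 10)), "degenerate")
  expect_error(tertile_stratify(c(1, 2, NA, NA)), "3 non-missing")

  x <- withr::with_seed(5, c(rnorm(89, 46, 10), NA, NA, NA))
  tt <- tertile_stratify(x)
  expect_identical(tt$n_missing, 3L)
  expect_true(all(is.na(tt$labels[90:92])))
  expect_true(all(abs(table(tt$labels) - 89 / 3) <= 2))
})

test_that("linear trend test behaves on degenerate and perfect trends", {
  g <- factor(rep(c("lower", "middle", "upper"), each = 30),
              levels = c("lower", "middle", "upper"))
  same <- rep(1.3, 90)
  r <- linear_trend_test(same, g)
  expect_equal(r$slope, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  perfect <- as.integer(g)
  r <- linear_trend_test(as.numeric(perfect), g)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)
  expect_error(linear_trend_test(rnorm(3), factor(rep("lower", 3))),
               "2 populated groups")
})

test_that("a decline at the study's scale is detectable across tertiles", {
  # group means 0.97 / 0.85 / 0.81, sd 0.2, n = 27/32/30
  ps <- withr::with_seed(21, vapply(1:400, function(i) {
    y <- c(rnorm(27, 0.97, 0.2), rnorm(32, 0.85, 0.2), rnorm(30, 0.81, 0.2))
    g <- factor(rep(c("lower", "middle", "upper"), times = c(27, 32, 30)),
                levels = c("lower", "middle", "upper"))
    linear_trend_test(y, g)$p
  }, numeric(1)))
  expect_lt(median(ps), 0.05)
})

test_that("pearson matrix handles trivial and missing-pair cases", {
  d <- data.frame(x = c(1, 2, 3, 4, 5))
  d$y <- -d$x
  d$z <- c(2, NA, NA, NA, 3)
  pm <- pearson_matrix(d, c("x", "y", "z"))
  expect_equal(pm$r["x", "x"], 1)
  expect_equal(pm$r["x", "y"], -1, tolerance = 1e-12)
  expect_true(is.na(pm$r["x", "z"]))  # only 2 complete pairs
  expect_identical(unname(pm$n["x", "z"]), 2)
})

test_that("generated correlation structure is estimated without bias", {
  rho <- 0.42
  rs <- withr::with_seed(31, vapply(1:300, function(i) {
    x <- rnorm(92)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(92)
    pearson_matrix(data.frame(a = x, b = y), c("a", "b"))$r["a", "b"]
  }, numeric(1)))
  expect_lt(abs(mean(rs) - rho), 0.03)
})

test_that("stepwise AIC keeps forced terms and finds the true predictor", {
  # a real predictor among noise candidates
  hits <- withr::with_seed(41, vapply(1:40, function(i) {
    n <- 200
    d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
    d$y <- 1.0 * d$x3 + rnorm(n)
    fit <- stepwise_aic(d, "y", paste0("x", 1:5), forced = c("age", "sex"))
    expect_true(all(c("age", "sex") %in% rownames(fit$coefficients)))
    "x3" %in% fit$selected
  }, logical(1)))
  expect_gte(mean(hits), 0.95)

  # empty candidate set returns the forced-terms model
  d <- data.frame(y = rnorm(50), age = rnorm(50), sex = rbinom(50, 1, 0.5))
  fit <- stepwise_aic(d, "y", character(0), forced = c("age", "sex"))
  expect_identical(fit$selected, character(0))
  expect_null(fit$trace)
})

test_that("pure-noise candidates are admitted at AIC's known liberal rate", {
  sel <- withr::with_seed(43, vapply(1:40, function(i) {
    n <- 500
    d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                    x1 = rnorm(n), x2 = rnorm(n))
    d$y <- rnorm(n)
    fit <- stepwise_aic(d, "y", c("x1", "x2"), forced = c("age", "sex"))
    length(fit$selected) / 2
  }, numeric(1)))
  expect_lte(mean(sel), 0.20)
})

test_that("mediation paths match the OLS closed form exactly", {
  n <- 40
  x <- as.numeric(scale(1:n, scale = FALSE))
  e <- withr::with_seed(8, rnorm(n))
  e <- residuals(lm(e ~ x))           # exactly orthogonal mediator noise
  m <- -0.5 * x + e
  y <- -0.4 * x + 0.3 * m             # no outcome noise
  fit <- fit_mediation(x, m, y, n_boot = 200, seed = 1)
  expect_equal(unname(fit$estimates["a"]), -0.5, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["b"]), 0.3, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["c_prime"]), -0.4, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["indirect"]), -0.15, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["total"]), -0.55, tolerance = 1e-10)
})

test_that("a null mediator path yields an indirect CI covering zero", {
  d <- withr::with_seed(9, {
    x <- rnorm(100); m <- 0.5 * x + rnorm(100); y <- -0.4 * x + rnorm(100)
    list(x = x, m = m, y = y)
  })
  fit <- fit_mediation(d$x, d$m, d$y, n_boot = 500, seed = 2)
  ci <- fit$boot_ci[, "indirect"]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("the mediation identity holds to machine precision on random fits", {
  withr::with_seed(10, {
    for (i in 1:20) {
      x <- rnorm(30); m <- rnorm(30, 0.3 * x); y <- rnorm(30, x + m)
      fit <- fit_mediation(x, m, y, n_boot = 50, seed = i)
      e <- fit$estimates
      expect_equal(unname(e["total"]),
                   unname(e["c_prime"] + e["a"] * e["b"]), tolerance = 1e-12)
      expect_equal(fit$share_direct + fit$share_indirect, 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("bootstrap intervals tighten with sample size", {
  widths <- withr::with_seed(12, {
    vapply(c(100, 400), function(n) {
      mean(vapply(1:20, function(i) {
        x <- rnorm(n); m <- -0.3 * x + rnorm(n); y <- -0.4 * x + 0.35 * m + rnorm(n)
        ci <- fit_mediation(x, m, y, n_boot = 300, seed = i)$boot_ci[, "indirect"]
        diff(ci)
      }, numeric(1)))
    }, numeric(1))
  })
  expect_lt(widths[2], widths[1])
})

test_that("effect shares reproduce the printed decomposition", {
  s <- mediation_shares(direct = -0.366, indirect = -0.068)
  expect_identical(round(s$share_indirect_pct), 16)
  expect_identical(round(s$share_direct_pct), 84)
  expect_error(mediation_shares(1, -1), "zero")
})

test_that("RMSEA is zero for the saturated model and small for a true chain", {
  d <- withr::with_seed(13, {
    x <- rnorm(80); m <- -0.5 * x + rnorm(80); y <- 0.4 * m + rnorm(80)
    list(x = x, m = m, y = y)
  })
  sat <- fit_mediation(d$x, d$m, d$y, n_boot = 50, seed = 1)
  r <- rmsea(sat)
  expect_identical(r$df, 0L)
  expect_identical(r$rmsea, 0)

  # dropping the direct path on data generated with c' = 0: df = 1 and the
  # fit is good in the vast majority of replicates (n large enough that the
  # chi-square sampling noise sits below the 0.05 approximation cut)
  ok <- withr::with_seed(14, vapply(1:100, function(i) {
    n <- 1500
    x <- rnorm(n); m <- -0.5 * x + rnorm(n); y <- 0.4 * m + rnorm(n)
    fit <- fit_mediation(x, m, y, n_boot = 10, seed = i,
                         include_direct = FALSE)
    rmsea(fit)$rmsea < 0.05
  }, logical(1)))
  expect_gte(mean(ok), 0.95)
})

test_that("the random-intercept LMM reduces to OLS at zero group variance", {
  # residuals orthogonalised against the grouping, so the in-sample
  # between-group variance is exactly zero and REML sits on the boundary
  d <- withr::with_seed(15, {
    n <- 200
    d0 <- data.frame(g = rep(letters[1:20], each = 10), x = rnorm(n))
    e <- residuals(lm(rnorm(n) ~ g, data = d0))
    d0$y <- 2 + 0.5 * d0$x + e
    d0
  })
  fit <- fit_lmm_random_intercept(d, "y", "x", "g")
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$fixed$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  expect_lt(fit$varcomp[["g"]] / fit$varcomp[["Residual"]], 1e-6)
})

test_that("balanced-design REML matches the ANOVA method of moments", {
  d <- withr::with_seed(17, {
    g <- rep(1:20, each = 10)
    b <- rnorm(20, 0, 1)[g]
    data.frame(g = factor(g), y = 3 + b + rnorm(200, 0, 1))
  })
  fit <- fit_lmm_random_intercept(d, "y", character(0), "g")
  a <- anova(lm(y ~ g, data = d))
  msb <- a["g", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
  expect_equal(fit$varcomp[["g"]], max(0, (msb - msw) / 10),
               tolerance = 1e-6)
  expect_equal(fit$varcomp[["Residual"]], msw, tolerance = 1e-6)
})

test_that("LMM input validation", {
  d <- data.frame(g = rep("a", 10), y = rnorm(10), x = rnorm(10))
  expect_error(fit_lmm_random_intercept(d, "y", "x", "g"), "fewer than 2")
})

test_that("base-to-apex analysis recovers a synthetic gradient", {
  seg <- withr::with_seed(18, {
    n <- 60
    base <- rnorm(n, 0.85, 0.15)
    do.call(rbind, lapply(1:n, function(i) {
      data.frame(subject_id = sprintf("S%02d", i),
                 slice = c("basal", "mid", "apical"),
                 mbf_seg = base[i] + c(0, 0.05, 0.10) + rnorm(3, 0, 0.1))
    }))
  })
  r <- base_to_apex_analysis(seg)
  est <- r$lmm$fixed
  expect_true(all(est$estimate[grep("slice", rownames(est))] > 0))
  expect_gt(est["slicemid", "estimate"], 0)
  expect_gt(est["sliceapical", "estimate"], est["slicemid", "estimate"])
  expect_true(all(c("mid vs basal", "apical vs basal", "apical vs mid")
                  %in% r$contrasts$pair))

  # identical values at all slices: zero effects, p = 1
  segc <- seg; segc$mbf_seg <- 1
  rc <- base_to_apex_analysis(segc)
  expect_lt(max(abs(rc$lmm$fixed$estimate[-1])), 1e-10)
  expect_true(all(rc$contrasts$p_holm == 1))

  expect_error(base_to_apex_analysis(seg[seg$subject_id == "S01", ]),
               "single subject")
})

test_that("Holm adjustment matches the step-down hand computation", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.05, 0.05)), c(0.10, 0.10))
  p <- withr::with_seed(19, runif(10))
  adj <- holm_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) > -1e-12))
  expect_error(holm_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("logistic LGE model recovers a known odds ratio", {
  ors <- withr::with_seed(20, vapply(1:100, function(i) {
    ecv <- rnorm(89, 46, 10)
    p <- plogis(log(1.55) * (ecv - 40))
    lge <- rbinom(89, 1, p)
    if (length(unique(lge)) < 2) return(NA_real_)
    tryCatch(logistic_lge(ecv, lge)$or, error = function(e) NA_real_)
  }, numeric(1)))
  expect_lt(abs(median(ors, na.rm = TRUE) - 1.55) / 1.55, 0.10)
})

test_that("logistic LGE null coverage and separation detection", {
  cover <- withr::with_seed(22, vapply(1:100, function(i) {
    ecv <- rnorm(500, 46, 10)
    lge <- rbinom(500, 1, 0.5)
    ci <- logistic_lge(ecv, lge)$ci
    ci[1] <= 1 && ci[2] >= 1
  }, logical(1)))
  expect_gte(mean(cover), 0.90)

  expect_error(logistic_lge(c(30, 35, 55, 60), c(0, 0, 1, 1)), "separation")
  expect_error(logistic_lge(c(30, 40), c(1, 1)), "both outcome classes")
})

test_that("exact two-sample power reproduces the design claim", {
  expect_equal(power_two_sample_t(30, 0, 0.2, 0.05), 0.05)
  expect_gt(power_two_sample_t(30, 0.2, 0.2, 0.05), 0.9)
  # monotone in n, delta and alpha
  p_n <- vapply(c(10, 20, 40, 80), power_two_sample_t,
                numeric(1), delta = 0.1, sd = 0.2)
  expect_true(all(diff(p_n) > 0))
  p_d <- vapply(c(0.05, 0.1, 0.2, 0.4), function(d)
    power_two_sample_t(30, d, 0.2), numeric(1))
  expect_true(all(diff(p_d) > 0))
  p_a <- vapply(c(0.01, 0.05, 0.1), function(a)
    power_two_sample_t(30, 0.1, 0.2, a), numeric(1))
  expect_true(all(diff(p_a) > 0))
  expect_error(power_two_sample_t(30, 0.2, 0.2, 1.5), "alpha")
})
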