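test_that("gamma-variate AIF has the analytic peak location and linearity", {
  times <- seq(0, 47.2, by = 0.1)
  a <- gen_aif(times = times, peak = 4, t0 = 5, alpha = 2.5, beta = 1.5)
  # analytic argmax t0 + alpha*beta
  expect_lt(abs(a$times[which.max(a$values)] - (5 + 2.5 * 1.5)), 0.1 + 1e-9)
  expect_equal(max(a$values), 4, tolerance = 1e-3)
  # zero amplitude -> zero curve; integral linear in the amplitude
  expect_true(all(gen_aif(times = times, peak = 0)$values == 0))
  a2 <- gen_aif(times = times, peak = 8, t0 = 5, alpha = 2.5, beta = 1.5)
  expect_equal(sum(a2$values), 2 * sum(a$values), tolerance = 1e-10)
  expect_error(gen_aif(alpha = -1), "alpha")
  expect_error(gen_aif(n_frames = 10, dt = 0.8), "30 s")
})

test_that("perfusion generator is a pure function of (parameters, seed)", {
  tr <- perfusion_truth(mbf = 1, snr = 25, seed = 99)
  d1 <- gen_perfusion_dataset(tr)
  d2 <- gen_perfusion_dataset(tr)
  expect_identical(d1$curves$segments, d2$curves$segments)
  expect_identical(d1$curves$aif, d2$curves$aif)
  # different seed: different noise, identical truth record
  d3 <- gen_perfusion_dataset(tr, seed = 100)
  expect_false(identical(d1$curves$segments, d3$curves$segments))
  expect_identical(d1$truth, d3$truth)
})

test_that("zero-flow segments produce flat tissue curves", {
  d <- gen_perfusion_dataset(perfusion_truth(mbf = c(0, rep(0.9, 15)),
                                             snr = Inf))
  seg1 <- d$curves$segments[, 1]
  expect_lt(diff(range(seg1)), 1e-9)  # baseline only
  expect_gt(diff(range(d$curves$segments[, 2])), 1)
})

test_that("T1 generator recovers lambda and composes with the ECV chain", {
  d0 <- gen_t1_dataset(true_lambda = 0.65, hct = 0.42, noise_sd = 0)
  fit <- partition_coefficient(
    d0$samples$r1_blood_per_s[d0$samples$segment == "seg_01"],
    d0$samples$r1_tissue_per_s[d0$samples$segment == "seg_01"])
  expect_equal(fit$lambda_gd, 0.65, tolerance = 1e-12)

  # lambda chosen so the pipeline lands at ECV 46% for hct 0.40
  lam <- 0.46 / (1 - 0.40)
  d <- gen_t1_dataset(true_lambda = lam, hct = 0.40, noise_sd = 0)
  tab <- quantify_ecv(d$samples, 0.40)
  expect_equal(tab$ecv_pct[tab$segment == "GLOBAL"], 46, tolerance = 1e-9)

  # noisy replicates: unbiased within Monte-Carlo error
  lams <- vapply(1:300, function(s) {
    dn <- gen_t1_dataset(true_lambda = 0.7, hct = 0.4, noise_sd = 0.05,
                         seed = s)
    one <- dn$samples[dn$samples$segment == "seg_01", ]
    partition_coefficient(one$r1_blood_per_s, one$r1_tissue_per_s)$lambda_gd
  }, numeric(1))
  expect_lt(abs(mean(lams) - 0.7), 4 * sd(lams) / sqrt(300))
})

test_that("cohort generator enforces its structural identities", {
  g <- gen_cohort(quick_truth(n = 92), seed = 5)
  s <- derive_hemodynamics(g$subjects)
  # back-solved hemodynamics: mwe = co * map / mass holds row-wise
  expect_equal(s$mwe, s$co_l_min * s$map_mmHg / s$lv_mass, tolerance = 1e-12)
  expect_identical(nrow(g$subjects), 92L)
  expect_identical(nrow(g$segments), 92L * 16L)
  expect_true(all(g$subjects$sbp > g$subjects$dbp))
  expect_true(all(g$subjects$global_ecv > 0.19 & g$subjects$global_ecv < 0.71))
  # segment-mean ECV equals the subject's global value by construction
  seg_means <- tapply(g$segments$ecv_seg_pct, g$segments$subject_id, mean)
  expect_equal(as.numeric(seg_means[g$subjects$id]),
               100 * g$subjects$global_ecv, tolerance = 1e-9)
  # determinism
  g2 <- gen_cohort(quick_truth(n = 92), seed = 5)
  expect_identical(g, g2)
})

test_that("a null ECV->MBF path yields near-zero correlation over seeds", {
  rs <- vapply(1:20, function(s) {
    g <- gen_cohort(quick_truth(n = 92, path_a = 0), seed = s)
    cor(g$subjects$global_ecv, g$subjects$rest_mbf)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("generated marginals land near their configured targets", {
  g <- do.call(rbind, lapply(1:10, function(s)
    gen_cohort(quick_truth(n = 92), seed = s)$subjects))
  expect_lt(abs(mean(100 * g$global_ecv) - 46), 1.5)
  expect_lt(abs(sd(100 * g$global_ecv) - 10) / 10, 0.15)  # truncation shrinks slightly
  expect_lt(abs(mean(g$rest_mbf) - 0.87), 0.03)
  d <- derive_hemodynamics(g)
  expect_lt(abs(mean(d$mwe) - 3.61), 0.25)
  expect_lt(abs(mean(g$lge_present) - 0.80), 0.12)
  expect_lt(abs(mean(g$al_status == "remission") - 0.23), 0.08)
})

test_that("truth records round-trip through JSON serialisation", {
  tr <- perfusion_truth(mbf = 1.2, residue = "fermi", snr = 30, seed = 4)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(tr), f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$mbf, tr$mbf)
  expect_equal(back$aif$peak, tr$aif$peak)
  expect_identical(back$residue, tr$residue)
  ct <- quick_truth(n = 92)
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(ct), f2, auto_unbox = TRUE, digits = NA)
  back2 <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(back2[order(names(back2))],
               unclass(ct)[order(names(unclass(ct)))], tolerance = 1e-12)
})

test_that("truth constructors validate their inputs", {
  expect_error(perfusion_truth(mbf = rep(1, 5)), "length 1 or 16")
  expect_error(perfusion_truth(snr = 0), "snr")
  expect_error(gen_t1_dataset(true_lambda = -1), "positive")
  expect_error(cohort_truth(bogus_field = 1), "unknown")
  expect_error(cohort_truth(n = 2), "n")
})
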