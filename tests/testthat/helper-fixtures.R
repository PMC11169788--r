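# Shared fixture builders; everything is generated in code at test time.

default_sr <- function() sr_params()

# signal-space synthetic first-pass dataset converted to per-region dR1
# curves, for tests that exercise deconvolve() directly
dr1_pair <- function(mbf = 1, residue = "exponential", snr = Inf, seed = 1,
                     segment = 1L) {
  sr <- default_sr()
  d <- gen_perfusion_dataset(perfusion_truth(mbf = mbf, residue = residue,
                                             snr = snr, seed = seed), sr)
  cs <- d$curves
  nb <- seq_len(sr$n_baseline)
  s0a <- calibrate_s0(cs$aif[nb], sr$t1_native_blood, sr$ts)
  aif <- delta_r1_curve(ts_curve(cs$times, cs$aif, "signal"), s0a, sr, "blood")
  s0t <- calibrate_s0(cs$segments[nb, segment], sr$t1_native_tissue, sr$ts)
  tis <- delta_r1_curve(ts_curve(cs$times, cs$segments[, segment], "signal"),
                        s0t, sr, "tissue")
  list(tissue = tis, aif = aif, curves = cs, truth = d$truth)
}

# small cohort truth for quick statistical tests
quick_truth <- function(...) cohort_truth(...)
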