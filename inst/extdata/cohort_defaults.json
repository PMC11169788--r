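{
  "n": 92,
  "ecv_mean": 46, "ecv_sd": 10, "ecv_min": 20, "ecv_max": 70,
  "path_a": -0.35, "path_b": 0.26, "path_c_prime": -0.45, "path_rpp": 0.36,
  "mbf_mean": 0.87, "mbf_sd": 0.21,
  "mwe_mean": 3.61, "mwe_sd": 1.68, "mwe_min": 0.2,
  "sbp_mean": 117, "sbp_sd": 18,
  "dbp_mean": 69, "dbp_sd": 12,
  "hr_mean": 77, "hr_sd": 12,
  "bsa_mean": 1.87, "bsa_sd": 0.22,
  "cardiac_index_mean": 2.99, "cardiac_index_sd": 0.60,
  "hct_mean": 0.40, "hct_sd": 0.04,
  "lvef_ref": 61, "lvef_ref_ecv": 35, "lvef_slope": -0.30, "lvef_sd": 7,
  "remission_frac": 0.23,
  "lge_or_per_pct": 1.55, "lge_midpoint_ecv": 40,
  "seg_ecv_sd": 3, "seg_mbf_sd": 0.12, "seg_ecv_slope": -0.003,
  "base_apex_mid": 0.05, "base_apex_apex": 0.10,
  "la_index_ref": 38, "la_index_slope": 0.73, "la_index_sd": 10,
  "gls_ref": -20.4, "gls_slope": 0.29, "gls_sd": 3.5,
  "ntprobnp_median": 1530, "ntprobnp_logslope": 0.10, "ntprobnp_logsd": 1.0,
  "troponin_median": 0.03, "troponin_logslope": 0.06, "troponin_logsd": 1.0,
  "dflc_median": 50, "dflc_logsd": 1.0,
  "nyha_probs": [0.22, 0.43, 0.29, 0.06], "nyha_noise_sd": 0.8
}
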