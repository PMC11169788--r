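# myoflow

Quantitative myocardial perfusion, extracellular volume, and work efficiency
from contrast-enhanced cardiac MRI.

## The problem

In infiltrative cardiomyopathies such as light-chain (AL) amyloidosis,
misfolded protein deposits expand the myocardial interstitium. Three
CMR-derived quantities track the consequences:

* **ECV** (extracellular volume fraction) — a surrogate for amyloid burden,
  computed as `(1 − Hct) · λ_Gd`, where the partition coefficient `λ_Gd` is
  the slope of segmental tissue R1 regressed on blood R1 across contrast
  timepoints (pre-contrast, 10 min, 20 min);
* **MBF** (rest myocardial blood flow, ml/min/g) — from first-pass
  perfusion: segmental signal curves are converted to ΔR1 via the
  saturation-recovery model `S = S0·(1 − exp(−TS·R1))` and deconvolved with
  the arterial input; by the central volume principle the amplitude of the
  tissue impulse response is flow, `MBF = 60·max(h)/ρ`;
* **MWE** (surrogate myocardial work efficiency, mmHg·L·min⁻¹·g⁻¹) —
  external work (cardiac output × mean arterial pressure) divided by LV
  mass.

The package implements this full chain plus the inference layer that
connects the three quantities at cohort level: ECV-tertile stratification
with linear trend tests, Pearson correlation matrices, stepwise-AIC
multivariable models, bootstrap mediation decomposing the ECV→MWE effect
into a direct path and an indirect path through MBF, random-intercept mixed
models for segmental flow and the base-to-apex gradient, Holm adjustment,
logistic models for late gadolinium enhancement, and exact noncentral-t
power. A first-class synthetic-data module generates perfusion curve sets,
R1 triplets and structural cohorts with known ground truth, so every stage
is verifiable end to end.

The deconvolution core is model-independent: the impulse response is
expanded on a cubic B-spline basis with early-dense knots and estimated by
penalised least squares with a first-order difference penalty, the
regularisation weight chosen by GCV, and the solution refined under the
physiological shape constraint that a residue function is non-increasing.
The arterial input is continued between frames by a fitted gamma-variate.
See `vignettes/myoflow-methods.Rmd` for the full account of the models and
the design decisions.

## Worked example

Simulate a first-pass dataset with true MBF 0.9 ml/min/g at curve SNR 30,
quantify it, and run the cohort analysis on a synthetic 92-subject cohort:

```r
library(myoflow)
sr <- sr_params()                          # TS = 0.1 s, native T1s 1232/1650 ms

d <- gen_perfusion_dataset(perfusion_truth(mbf = 0.9, snr = 30, seed = 42), sr)
q <- quantify_segmental_mbf(d$curves, sr)
q
#> <segmental_mbf: global 0.848 ml/min/g over 16 segments>

t1  <- gen_t1_dataset(true_lambda = 0.767, hct = 0.40, noise_sd = 0.01, seed = 42)
ecv <- quantify_ecv(t1$samples, hct = 0.40)
tail(ecv, 2)
#>    segment lambda_gd intercept  ecv_pct
#> 16  seg_16 0.7680115 0.3594226 46.08069
#> 17  GLOBAL 0.7611328 0.3588930 45.66797

coh  <- gen_cohort(cohort_truth(), seed = 42)
subj <- derive_hemodynamics(coh$subjects)   # appends map, co, ew, mwe, rpp...
med  <- fit_mediation(100 * subj$global_ecv, subj$rest_mbf, subj$mwe,
                      n_boot = 2000, seed = 42)
med
#> <mediation_fit: n = 92, a = -0.00952, b = 1.793, c' = -0.09193>
#>   indirect = -0.01707, total = -0.109; shares: 16% indirect / 84% direct

tert <- tertile_stratify(100 * subj$global_ecv)
linear_trend_test(subj$rest_mbf, tert)$p
#> [1] 0.0105
```

Reading the output: the perfusion pipeline recovers the simulated flow
within a few percent (0.848 vs 0.9 at SNR 30); the ECV chain lands on the
configured 46% at `λ_Gd = 0.767`, Hct 0.40; and in the structural cohort a
5-percentage-point ECV increase lowers MWE both directly and through reduced
MBF, with about 16% of the total effect mediated by flow — the mediation
identity `total = direct + indirect` holds exactly on every fit. The
declining MBF trend across ECV tertiles is detected at p ≈ 0.01.

`run_pipeline(run_config(seed = 1))` wires simulate → quantify → analyze
into one run that writes CSV/JSON outputs plus a manifest with per-file MD5
hashes; rerunning the same configuration reproduces the outputs
bit-identically.

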