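# nirmilk

Chemometric calibration and evaluation of near-infrared (NIR) milk
analyzers in R.

Compact MEMS spectrometers make at-line and in-line raw-milk analysis on the
farm affordable, but only if their narrow-window NIR spectra can be turned
into fat, protein and lactose predictions (% w/w) accurate enough for the
ICAR limits (RMSEP ≤ 0.25 in-line, ≤ 0.20 at-line, ≤ 0.10 laboratory).
`nirmilk` implements the full calibration procedure such an evaluation
needs, end to end and reproducibly, for chemometricians and dairy-sensor
developers:

* **Instrument-side corrections** — white/dark standard referencing
  `(S − D)/(W − D)`, replicate-scan averaging, wavelength-window
  restriction.
* **A 420-combination preprocessing grid** — {Raw, Log₁₀(1/T)} ×
  {none, baseline offset, detrend, SNV, MSC} × {none, Savitzky–Golay
  derivatives SGxDyy: orders 1–2, ten odd windows 3–21, quadratic filter} ×
  {none, one-component orthogonal signal correction} + mean centering, with
  strict calibration/application state separation.
* **Cow-blocked duplex splitting** — Snee's duplex on cow-mean autoscaled
  compositions assigns whole cows 2:1 to calibration and validation, so a
  71-cow herd yields 48 + 23 cows and no animal leaks across sets.
* **PLSR with statistically parsimonious selection** — single-response
  NIPALS up to 20 latent variables; 10-group cow-blocked cross-validation;
  the number of latent variables A, the preprocessing chain, and the
  wavelength-selection method are each chosen as the most parsimonious
  candidate whose cross-validated absolute residuals are not significantly
  worse than the best candidate's (one-sided paired t-test, α = 0.05).
* **Four wavelength selectors** — VIP (threshold 1), Martens jack-knife,
  and backward/forward interval PLS (RiPLS/FiPLS).
* **Evaluation** — RMSECV/RMSEP, R²cv/R²p, Williams quality classes
  (approximate quantitative 0.66–0.81, good 0.82–0.90, excellent > 0.91),
  ICAR compliance flags, and a two-way ANOVA (spectrometer + sample block)
  with Tukey HSD and compact-letter display for comparing instruments.
* **A synthetic raw-milk generator** — Beer–Lambert absorbance
  `A(λ) = ℓ·(Σᵢ cᵢ εᵢ(λ) + c_w ε_w(λ))` over instrument windows, herd-level
  composition moments with within-cow clustering, per-sample
  multiplicative/additive scatter and detector noise — so every stage is
  testable against known ground truth without any data download.

The prediction model is affine in the processed spectrum,
ŷ = ȳ + (x − x̄)ᵀb, with b assembled from the NIPALS weights W, loadings P
and response loadings q as b = W(PᵀW)⁻¹q.

## Worked example

Simulate a 50-cow herd (200 samples) on the 1550–1950 nm transmittance
window, split it, run the fast preprocessing grid, select wavelengths and
evaluate on the held-out third:

```r
library(nirmilk)

cfg <- pipeline_config(
  synthetic  = synthetic_config(n_cows = 50, samples_per_cow = 4, seed = 5),
  components = c("fat_pct", "protein_pct", "lactose_pct"),
  grid = "fast", seed = 6
)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 3 model(s)
#> # A tibble: 3 × 9
#>   spectrometer component chain selection n_latent n_retained rmsecv  rmsep   r2p
#>   <chr>        <chr>     <chr> <chr>        <int>      <int>  <dbl>  <dbl> <dbl>
#> 1 nirone_2.0_T fat_pct   Log|… JK               3         58 0.0302 0.0314 0.999
#> 2 nirone_2.0_T protein_… Log|… FiPLS            3         72 0.0633 0.0675 0.975
#> 3 nirone_2.0_T lactose_… Log|… JK               3         43 0.0710 0.0918 0.673
```

Each row is one calibrated model: the selected preprocessing chain, the
wavelength-selection method and retained-wavelength count, the number of
latent variables, the cross-validated error on the calibration cows and the
prediction error on the 64 never-touched validation samples.  Fat is
predicted almost perfectly on this synthetic herd (RMSEP 0.031 % w/w versus
a herd SD of 1.107); lactose, whose natural variation is only 0.154 % w/w,
ends at RMSEP 0.092 — under the ICAR laboratory limit yet with a modest
R²p of 0.67, the familiar situation in which low lactose variance depresses
R² while the absolute error is excellent:

```r
glance(res$artifacts[["nirone_2.0_T.lactose_pct"]]$eval)
#> # A tibble: 1 × 11
#>   component   spectrometer n_val  rmsep   r2p rmsecv  r2cv williams icar_in_line …
#> 1 lactose_pct nirone_2.0_T    64 0.0918 0.673 0.0710 0.809 approxi… TRUE
```

`autoplot()` methods draw RMSECV-versus-latent-count curves and
predicted-versus-reference scatter plots; `tidy()` on a fitted `plsr_model`
returns per-wavelength coefficients and VIP scores.

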