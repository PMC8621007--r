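---
title: "Calibration methodology: preprocessing grid, parsimonious PLSR and synthetic milk spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmilk)
```

This vignette is the package's account of its own methodology: the models
and procedures it implements, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, the numerical
choices, and the known limitations.

## The calibration problem

A milk analyzer predicts fat, protein and lactose content (% w/w) from an
NIR spectrum.  Narrow-window spectra of raw milk are dominated by water
absorption and by scatter from fat globules and casein micelles, so a
successful calibration couples three decisions — how to preprocess the
spectra, how many PLSR latent variables to use, and which wavelengths to
retain — and each decision must be validated without information leaking
from validation animals into the calibration.  Milk samples from one cow
are highly correlated; all partitioning in this package (duplex split, CV
folds) therefore blocks on the cow.

## Preprocessing grid

Five ordered steps give `2 × 5 × 21 × 2 = 420` chains
(`enumerate_chains()`):

1. `Raw` or `Log`: absorbance transform `A = log10(1/T)`.
2. `No`, `Base`, `Detr`, `SNV`, `MSC`.  `Base` is offset baseline
   correction (subtract the per-spectrum minimum) — the simplest standard
   reading, deliberately distinct from detrending, which removes a
   per-spectrum least-squares quadratic in wavelength.  SNV standardizes
   each spectrum (sample SD, n−1); MSC regresses each spectrum on the mean
   calibration spectrum and inverts the affine fit.
3. `No` or a Savitzky–Golay derivative `SGxDyy`: local quadratic
   least-squares filter, derivative order x ∈ {1, 2}, window yy from
   W10 = {3, 5, …, 21}.  The ten odd windows up to 21 are a package choice:
   the abbreviation grammar (`SG2D05` … `SG2D21`) fixes odd windows and an
   upper end of 21, but no canonical list of ten exists, so the ten odd
   values up to 21 are adopted and flagged as an assumption.  Derivatives
   are per index step (classic SG coefficients), treating the grid as
   uniform within one instrument.  Edge points use the polynomial fitted on
   the truncated one-sided window; if a truncated window is too short for a
   quadratic the local order drops (derivative 0 when the requested order
   exceeds it).
4. `No` or one-component orthogonal signal correction, Wold's algorithm:
   start from the first principal-component score, alternately
   orthogonalize against the response and regress back onto the spectra
   (minimal-norm least squares via one SVD per component), convergence
   tolerance 1e-10 on the weight vector, at most 500 iterations; a final
   exact orthogonalization guarantees `|cor(t, y)| < 1e-6` for the fitted
   score.  New spectra are deflated with the stored weight and loading.
5. `MNCN`: mean centering, always, with the calibration mean.

MSC references, OSC components and centering means are *fitted state*:
estimated on calibration rows only and applied unchanged to anything else.
Processing a validation spectrum thus never depends on other validation
spectra — a property the test suite asserts directly.

## PLSR and the three parsimony selections

`fit_plsr()` is the deterministic single-response NIPALS: components
maximize covariance between spectral scores and the response; coefficients
for all sub-models 1..A come from one pass.  X and y are centered inside
the fit even though MNCN ran upstream — harmless double-centering that
makes the function safe standalone.  At full rank the A = min(n−1, p) model
equals ordinary least squares (asserted at 1e-8), and VIP scores satisfy
`mean(VIP²) = 1` by construction.

Cross-validation (`cross_validate()`) uses 10 cow-blocked folds: cows are
shuffled by seed and dealt round-robin, so 48 calibration cows give eight
folds of five and two of four.  Within every fold the *entire* chain is
refitted on the training folds.  Re-estimating preprocessing state per fold
is the statistically correct reading of train/test separation (the cheaper
alternative — preprocess once on the full calibration set — leaks the
validation fold's contribution to MSC/OSC/centering state into training).

Three selections then use the same statistic, a one-sided paired t-test
(α = 0.05) on cross-validated absolute residuals, pairing by calibration
sample, zero differences included:

* **Latent count**: smallest A whose residuals are not significantly worse
  than the RMSECV-argmin's.
* **Chain**: among 420 (or the 16-chain fast grid) candidates not
  significantly worse than the best, the fewest latent variables wins; ties
  break by lower RMSECV, then lexicographic label.  An OSC component is
  reported (`effective_latent`) but never counted in parsimony.
* **Wavelength-selection method**: among FULL/VIP/JK/RiPLS/FiPLS, the
  fewest retained wavelengths wins among statistically equivalent
  candidates; ties by fewer latent variables, then lower RMSECV.  The
  parsimony currency deliberately shifts from latent variables to retained
  wavelengths at this stage.

A zero-variance difference vector is decided by its sign (identical
residuals → not worse, p = 1; uniformly worse → p = 0), keeping the
selections total and deterministic.

## Wavelength selection

All four selectors consume per-fold chain-processed matrices computed once
on the full grid; candidate subsets index columns afterwards.  This mirrors
applying the chosen preprocessing to the spectra and then selecting
variables, keeps interval candidates contiguous in nm, and lets a
rank-deficient candidate subset degrade gracefully (sub-models beyond the
effective rank repeat the last valid one) instead of aborting a search.

* **VIP**: retain `VIP ≥ 1` — the greater-than-average-importance rule; the
  threshold is configuration (`selection_config(vip_threshold=)`).
* **Jack-knife**: Martens-style — coefficient variance estimated from the k
  leave-fold-out models around the all-data coefficient,
  `s²ⱼ = Σ(bⱼf − bⱼ)²·(g−1)/g`, two-sided t-test with g−1 df at α = 0.05.
  Under pure noise the test's measured size is close to nominal (≈ 4–5%);
  an empty retained set falls back to the top-1 wavelength with a warning
  so that downstream refits always have input.
* **RiPLS/FiPLS**: the grid is cut into `n_intervals` contiguous intervals
  (default 20, the last absorbs the remainder — documented assumption, the
  abbreviation grammar fixes none).  Backward removal / forward addition is
  greedy on cross-validated RMSECV, each candidate re-selecting its own
  latent count, accepting only strict improvements, ties to the lowest
  interval index.  RiPLS therefore never ends worse than the full model.

## Duplex splitting

Duplex runs on cow-level points: each cow is the mean of its autoscaled
sample compositions.  Calibration is seeded with the farthest pair
(Euclidean distance), validation with the farthest remaining pair, then
points are assigned in rounds of two-to-calibration, one-to-validation,
each assignment taking the point with the largest minimum distance to the
receiving set; a set stops receiving at its target size
(`n_val = floor(n/3)`, leftover to calibration), ties to the lowest cow
index.  A 71-cow herd yields 48/23.  Cow-level duplex is the cleanest
consistent combination of distance-based splitting with animal blocking;
the exact variant and tie-breaks are package decisions, stated here because
the concepts admit alternatives.

## Evaluation

`evaluate_predictions()` reports RMSEP and R²p on the validation set, the
Williams class of R², and ICAR flags (pass = RMSEP ≤ 0.25 / 0.20 / 0.10
% w/w).  The printed Williams bands leave 0.81–0.82 and 0.90–0.91 open;
each gap is closed by extending the lower band upward (approximate
quantitative = [0.66, 0.82), good = [0.82, 0.91]) — an arbitrary,
documented choice isolated in one function.

`compare_spectrometers()` analyses squared validation residuals (samples ×
instruments, complete design) with a two-way ANOVA without interaction,
sample as a fixed block.  For a balanced complete layout this F-test for
the instrument effect is numerically identical to the
randomized-complete-block / repeated-measures analysis, so no mixed-model
machinery is needed.  When the instrument effect is significant, Tukey HSD
on the instrument means (ANOVA error term) feeds a compact letter display
built by the standard insert-and-absorb algorithm, letters ordered from the
lowest mean squared residual.  A numerically zero instrument effect
(identical columns) is reported as p = 1 rather than a 0/0 F ratio.

## The synthetic generator

`synthetic_config()` defaults define the simulated herd:

| parameter | default | meaning |
|---|---|---|
| composition moments | fat 4.715/1.107 [1.71, 7.70]; protein 3.899/0.415 [2.99, 5.07]; lactose 4.620/0.154 [4.09, 5.10] | herd mean/SD/min/max, % w/w |
| `cow_effect_sd` | SD/2 per component | between-cow SD; the between/within split is an assumption (no split is observable from summary moments), overridable |
| `samples_per_cow` | 4 | ≈ the 299/71 samples-per-cow ratio of a milking-trial herd |
| `pathlength_mm` | 1.5 | transmittance cuvette thickness |
| `grid_step_nm` | 4 | ~100 points across a 400 nm module window |
| `scatter_slope_sd`, `scatter_offset_sd` | 0.05, 0.02 | per-sample multiplicative/additive distortion `A' = (1+slope)·A + offset` |
| `noise_sd` | 0.002 AU | i.i.d. detector noise |

Compositions: cow means ~ N(mean, cow_effect_sd); samples ~ N(cow mean,
√(SD² − cow_effect_sd²)) truncated to [min, max] by rejection, so the total
SD matches the target and the bounds hold exactly.  The per-cow truncation
pulls the population mean a few thousandths toward the centre of the range;
the test suite checks the sample mean against the exact expectation of this
generative law (numeric integration), not against the idealized target.

Spectra: Beer–Lambert mixing of Gaussian absorption bands.  The band
library is *fictional but plausible* (fat CH overtones near 1210/1725/2310
nm, protein and lactose combination bands at 2000–2300 nm, water OH at
1450/1940 nm); it is configuration, not a claim about any measured milk
spectrum, and easy to override.  The water term (concentration
`100 − Σ components`) gives the Log step and the scatter corrections
realistic work.  Scatter and noise streams are seeded separately from the
composition stream so the same herd can be re-rendered on any instrument
window.

What the generator does **not** emulate: Mie scattering of fat globules
(scatter is a per-sample affine distortion, which SNV/MSC can remove
exactly — real scatter is wavelength-dependent), instrument line-shape
convolution, temperature effects on the water bands, and drift between
white/dark referencing events.  Passing recovery tests therefore shows the
pipeline machinery is correct and leak-free — not that any real instrument
achieves these errors.  On defaults, SNV/MSC chains beat uncorrected chains
on median RMSECV, and the full pipeline reaches RMSEP well below each
component's SD; both are asserted, with known-truth tolerances (noise-free
recovery to 1e-6 of the range) in the noise-free configuration.

## Numerical choices and problem sizes

* SG coefficient matrices are cached per (n, window, order).
* OSC uses one SVD per component; weights via minimal-norm least squares
  with singular values below 1e-12 of the largest discarded.
* PLSR refuses A > min(n−1, p) and zero-variance responses; inside CV
  searches, rank exhaustion pads instead of erroring (`strict = FALSE`).
* Tests and the fast pipeline mode run a 16-chain grid, `max_latent` 8 and
  8 intervals on herds of 15–50 cows (30–200 samples, ~100 wavelengths) —
  sizes chosen so the whole suite exercises every stage, including two
  200-replicate Monte-Carlo checks, in well under a minute while leaving
  the full 420 × 20 × 10-fold run a single-command option
  (`grid = "full"`).
* Model JSON serialization stores flattened factor matrices at full decimal
  precision; a restored model predicts bit-identically.

## Known limitations

* No nested CV around the grid search: the reported RMSECV of the selected
  chain is optimistic, as in the standard practice this package mirrors;
  RMSEP on duplex-held-out cows is the honest figure.
* The Martens jack-knife variance is a delete-d approximation; its test
  size is near, not exactly, nominal.
* Williams band-gap closure and the duplex variant/tie-breaks are
  documented conventions, not community standards.
* The generator's affine scatter model favours SNV/MSC by construction;
  conclusions about *which* scatter correction wins do not transfer to real
  milk.
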