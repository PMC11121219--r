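---
title: "NIR chemometrics for goat-meat quality: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR chemometrics for goat-meat quality: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmeat)
```

# The problem

Meat from protected-designation-of-origin (PDO) suckling kids of the
"Serrana" and "Preta de Montesinho" goat breeds must meet certified
composition and authenticity requirements. Near-infrared (NIR) spectroscopy
offers a fast, non-destructive route to both needs: *quantification* of
quality attributes (pH, CIELab color, moisture, ash, protein, intramuscular
fat, water-holding capacity, shear force, fatty-acid composition) from the
absorbance spectrum of minced *Longissimus thoracis* muscle, and
*discrimination* between the two breeds from the same spectra.

`nirmeat` implements the full chemometric workflow: spectral pre-treatment,
variable decimation, replicate-aware Kennard–Stone partitioning, linear
support-vector calibration and classification with explicit model-selection
gates, and the closed-form meat and lipid quality indices. Because no
public spectral data accompany this kind of study, the package also ships a
synthetic data generator that emulates the study conditions (two breeds,
16 samples each, balanced sexes, three replicate spectra per sample on a
4000–10000 cm⁻¹ grid at 4 cm⁻¹), so every stage is testable offline.

# Data model

A `spectra_set` holds an `n_spectra × n_points` absorbance matrix on a
shared uniform `wavenumber_grid`, plus per-row metadata (`sample_id`,
`replicate`, `breed`, `sex`). Replicates of a sample always share identical
breed/sex labels, and all samples carry the same replicate count — both are
enforced at construction, because the partitioning logic depends on them.
The default grid is 4000→10000 cm⁻¹ at 4 cm⁻¹: 1501 points.

# Pre-treatments

Treatment chains are named by hyphen-joined codes applied left to right,
e.g. `"SNV-DV1"`. The vocabulary:

| code | operator | purpose |
|------|----------|---------|
| `SM` | Savitzky–Golay smoothing | noise reduction |
| `NORM` | unit-area normalization | removes overall intensity scale |
| `ALS` | asymmetric least squares baseline removal | drifting baselines |
| `MSC` | multiplicative scatter correction | additive + multiplicative scatter |
| `SNV` | standard normal variate | per-spectrum standardization |
| `DV1`, `DV2` | Savitzky–Golay derivatives | resolves overlapping bands, removes baseline |

Numerical choices:

* **Savitzky–Golay settings.** Window 11 points, polynomial order 2
  (configurable via `treatment_control()`). These are the de-facto standard
  in NIR work and make the operators exact on low-order polynomials, which
  gives sharp oracle tests (a quadratic has a known constant second
  derivative everywhere). Edges are handled by the filter's transient fits,
  so outputs keep full length and grid alignment across a chain.
* **Derivative scale.** Derivatives are taken with respect to the
  wavenumber axis (units absorbance·cm), so results are invariant to
  decimation-induced changes of the grid spacing.
* **`NORM` area.** The unit area is the trapezoidal integral over the
  wavenumber axis, not the plain channel sum; on a uniform grid the two
  differ only by a constant, but the integral definition survives
  decimation unchanged.
* **`ALS` settings.** `lam = 1e5`, `p = 0.01`, 10 reweighting iterations —
  canonical settings for absorbance baselines; with `p = 0.5` the smoother
  is symmetric and simply tracks a smooth input.
* **`MSC` reference.** The reference is the column mean of the rows named
  in `fit_rows`. `apply_treatment(set, spec, fit_rows = train_rows)` fits
  every data-dependent operator on the calibration rows only and then
  applies it to all rows, so prediction rows can never leak into fitted
  parameters. The tests enforce this by mutating held-out rows and
  asserting bit-identical fitted references.
* **Degenerate inputs.** Zero-variance spectra (SNV), zero-area spectra
  (NORM) and near-zero MSC slopes (|b| < 1e−12) raise errors rather than
  returning NaNs.

**Decimation.** `decimate(set, keep_every = 10)` keeps every tenth point
starting at the first: 1501 → 151 points, i.e. 10% of the variables at a
40 cm⁻¹ effective spacing. The point counts (1501 → 151) are the workflow's
stated reduction; a literal 20 cm⁻¹ selection would instead give 301
points, so the printed counts are honored and the stride is configurable.

# Kennard–Stone partitioning

`kennard_stone()` is the deterministic max–min algorithm with the Euclidean
metric: seed with the farthest pair, then repeatedly add the candidate
whose minimum distance to the selected set is largest. Ties break to the
smallest row index, making the selection fully reproducible; the test suite
checks exact equivalence with an exhaustive, independently coded max–min
search for small n, and the greedy-nesting property (the k-selection is a
prefix of the (k+1)-selection).

`split_spectra()` runs the selection at the *sample* level and lets every
replicate spectrum inherit its sample's assignment, so no sample straddles
the calibration/prediction split. Two feature spaces are supported:

* `"reference"` (default): the per-sample physicochemical table, z-scored
  before distances because the attributes live on mixed units. This follows
  the workflow's methods description; constant columns are dropped.
* `"spectra"`: replicate-averaged spectra, not standardized (single unit).

The default split is 20 calibration / remaining prediction samples. The
source study labels its 20/10 split "75%/25%" of 32 samples — arithmetic
that cannot all hold at once; the explicit counts are honored (20
calibration samples, and with the 16+16 synthetic default that leaves 12
prediction samples; with 30 samples it reproduces the 20/10, 60/30-spectra
layout).

# SVM calibration and discrimination

Both models are linear, as in the source workflow. Features are z-scored
with calibration statistics inside the fit; regression targets are
standardized too, so the SVR insensitivity tube `epsilon` (default 0.1) is
expressed in target standard deviations and means the same thing for pH as
for a fatty-acid percentage. Predictions are returned on the original
scale and are affine functions of the features. The cost grid defaults to
{1, 10, 30, 100}; `tune_C()` picks the grid member with the lowest
calibration RMSE, ties to the smallest cost. The classifier uses C = 1.

Model evaluation regresses predicted on observed values by ordinary least
squares and reports RMSE, R², slope ± SD and intercept ± SD with two-sided
t-tests. The slope test is against zero (the only null under which
"p < 0.001" footnotes are attainable); a slope-versus-one p-value is
additionally stored. The intercept is rendered `ns` when p > 0.05. The
relative standard error (RSE) is implemented as the residual standard
error of that regression divided by the observation mean — the closest
conventional reading of a "relative" error whose ideal value is zero.
Rendered tables round RMSE to 3 decimals and R² to 4, while full precision
is stored.

Model selection (`select_best_model()`) filters candidates to
R²(calibration) ≥ 0.95 and slope(calibration) ≥ 0.95, then picks the lowest
prediction RMSE among candidates with prediction R² > 0.90; ties go to the
higher prediction R², then slope. An empty filter returns `NULL` rather
than a forced winner.

# Quality indices

Closed forms, vectorized over samples:

* carcass yield = 100·CCW/LWS (%);
* chroma C\* = √(a\*² + b\*²) and hue H\* = arctan(b\*/a\*) in degrees. The
  source prints the chroma equation without the square root and the hue
  argument inverted; the standard CIELab forms are implemented — they are
  the only reading consistent with the printed magnitudes (C\* ≈ 19–23,
  H\* ≈ 35–38°);
* atherogenicity IA = (C12:0 + 4·C14:0 + C16:0)/(ΣMUFA + ΣPUFA);
* thrombogenicity IT = (C14:0 + C16:0 + C18:0)/(0.5·ΣMUFA + 0.5·Σn6 +
  3·Σn3 + Σn3/Σn6);
* h/H = (C18:1n-9 + C18:2n-6 + C20:4n-6 + C18:3n-3 + C20:5n-3 + C22:5n-3 +
  C22:6n-3)/(C14:0 + C16:0);
* family sums ΣSFA/ΣMUFA/ΣPUFA and the n-6/n-3 and PUFA/SFA ratios.

Fatty acids absent from a profile enter as zero — trace acids below the
usual 0.1% reporting threshold cannot be invented. Two aggregation orders
are supported and both are reported by `run_indices()`: the mean of
per-sample indices and the index of the mean profile. These differ for any
ratio-valued index (a Jensen gap); evaluating the indices on a published
*mean* profile therefore lands near, but not exactly on, the published
per-animal averages — about 0.7% low for IA and 0.4% low for h/H on the
Serrana means, which is the expected direction and size of the gap. IT
evaluated verbatim on the same means gives ≈1.42 against a published
1.225; no reading of the printed family sums reconciles this, so the
package implements the formula verbatim and does not force agreement. IA
and h/H are invariant to rescaling the whole profile; IT is not, because
its denominator adds a dimensionless ratio to percentage-scale terms — the
tests assert both behaviors.

# The synthetic generator

`synthetic_config()` fixes the emulated study conditions: 16 samples per
breed, 8 per sex, 3 replicate spectra per sample, the 1501-point grid.
Per-sample constituents are drawn from truncated normal distributions with
the per-breed means and SEMs of the built-in parameter tables
(SD = SEM·√16), truncated at physical bounds (percentages ≥ 0, pH in
[5, 7]); sampling uses the inverse-CDF method, so it is exact and
deterministic per seed. Chroma and hue are derived per sample from the
sampled a\*/b\*. Carcass weights are built from a sampled dressing yield so
that CCW ≤ HCW ≤ LWS always holds; the hot carcass weight, which the
emulated tables do not report, is set to CCW/0.96 (≈4% chill loss, typical
for kid carcasses).

Spectra follow a Beer–Lambert-like linear mixing model: a fixed instrument
baseline plus one Gaussian band per (constituent, region) pair, with band
centers in plausible NIR overtone/combination regions (O–H for moisture,
N–H for protein, C–H for fat and the major fatty acids) and widths of
80–200 cm⁻¹, the width class of condensed-phase NIR bands — broad enough
to survive 10× decimation and an 11-point derivative window, which
mid-IR-width bands would not. Loadings are scaled so each constituent
contributes a realistic 0.05–0.3 AU at its typical value and so that
protein, fat and moisture are identifiable from the spectra. Replicates
multiply the clean spectrum by a gain ~ N(1, 0.05), add an offset
~ N(0, 0.02 AU) and add iid noise with SD 1e−4 AU — the RMS noise class of
FT-NIR instruments. The noise matrix is drawn once per seed and scaled by
`noise_sd`, so datasets from one seed at different noise levels form a
coupled family and prediction error is monotone in the noise level by
construction.

The two breeds are separated by a fixed six-band spectral offset whose
scale, `class_separation` (default 3), puts the between-breed offset at
roughly three times the within-breed clean-spectrum variation — a clearly
NIR-discriminable regime under which the linear classifier reaches 100%
calibration accuracy.

What the generator deliberately does **not** emulate: instrument physics
(detector nonlinearity, wavelength error, stray light), non-Gaussian band
shapes, constituent covariances (attributes are drawn independently within
breed), and any nm-domain effects. Passing tests therefore demonstrate the
correctness and statistical behavior of the *workflow*, not the field
performance of NIR on real goat meat.

## A note on SNV and single constituents

SNV divides each spectrum by its own standard deviation. For the dominant
absorber — moisture, in meat — the spectrum's scale direction *is*
essentially that constituent's signature, so SNV removes a large part of
its quantitative information (the closure effect); in the degenerate case
of a spectrum that encodes exactly one constituent, SNV removes nearly all
of it. This is why the recovery tests assert R² ≥ 0.99 for the
protein/fat/fatty-acid signatures under `SNV-DV1` but only ≥ 0.95 for
moisture and pH, and why the single-constituent quantification experiment
lets the model-selection machinery choose the treatment (it settles on
smoothing-class chains) instead of forcing SNV.

# Problem sizes used by the tests

The test-suite and acceptance experiments run on the default synthetic
conditions: 32 samples × 3 replicates on the 1501-point grid, decimated to
151 variables, 20 calibration samples; oracle comparisons (exhaustive
max–min, the dual quadratic program) use n ≤ 8. A Monte-Carlo check of the
generating means uses 4000 samples per breed. These sizes were chosen so
each property is tested at the scale the workflow actually uses while the
whole suite stays fast.

# Known limitations

* The linear mixing generator cannot expose nonlinear matrix effects that
  real NIR calibrations sometimes face; treat its accuracy figures as
  upper bounds.
* IT on published mean profiles is irreconcilable with the published value
  (above); the verbatim formula is kept.
* Only two-class discrimination is implemented; multi-class breeds and
  nonlinear kernels are out of scope.
* R² is reported from the prediction-versus-observation regression; for
  simple OLS this equals the squared Pearson correlation, so the two
  common conventions coincide here by construction.
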