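---
title: "Objective DAB scoring: measurement model, phantom calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective DAB scoring: measurement model, phantom calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabquant)
```

## The measurement model

Brightfield absorption follows the Beer–Lambert law: a pixel's transmitted
intensity in channel $c$ is $I_c = I_{0,c}\,10^{-\mathrm{OD}_c}$, and the
optical density of co-localized stains is additive,
$\mathrm{OD} = \sum_s d_s \, v_s$, where $d_s$ is the (dimensionless)
density of stain $s$ and $v_s$ its unit RGB absorbance vector. `dabquant`
works in this OD space throughout:

* `rgb_to_od()` computes
  $\mathrm{OD}_c = -\log_{10}\!\big((I_c+\varepsilon)/(I_{0,c}+\varepsilon)\big)$,
  clipped below at 0. The offset $\varepsilon$ (default 1 intensity unit)
  guards the logarithm at $I = 0$; blank glass ($I = I_0$) maps to exactly
  zero OD for any $\varepsilon$.
* `stain_model()` row-normalizes the supplied stain vectors and inverts the
  stain matrix. The shipped H-DAB preset uses the canonical published
  constants — hematoxylin (0.650, 0.704, 0.286), eosin (0.072, 0.990,
  0.105), DAB (0.268, 0.570, 0.776) — stored in a versioned YAML config so
  alternatives are drop-in. Two-stain models are completed with the
  unit-norm cross-product complement (negatives zeroed, re-normalized).
* `deconvolve()` applies the inverse per pixel. Negative unmixed densities
  are clipped to zero by default because densities are physical
  concentrations; clipping can be disabled for diagnostics.

Scoring (`score_slide()`) deliberately measures on the *re-rendered* DAB
image rather than the raw density channel, mirroring the desktop-tool
protocol this package makes reproducible: the DAB channel is re-rendered
via `render_stain()` ($I_c = I_{0,c} 10^{-v_c d}$, rounded to 8 bits),
collapsed to grayscale with equal channel weights (the common default of
such tools; luminance weights 0.299/0.587/0.114 are one configuration flag
away, and the weights used are recorded in every score row), inverted
($255 - g$) so high values mean strong staining, and only then measured.
On a noiseless slide with DAB density $d$, this chain collapses to the
closed form

$$f(d) = 255\,\Big(1 - \tfrac{1}{3}\sum_c 10^{-v_c d}\Big),$$

which is strictly increasing and saturates below 255. $f$ and its inverse
(`dab_response()`, `calibrate_dab()`) are the package's analytic oracle.

Per-ROI statistics use the sample SD ($n-1$), matching the measurement
tools the protocol emulates. The tumor-to-background ratio is the ratio of
the ROI means; TBR < 1 is legal (background staining stronger than tumor)
and flagged, while a zero background mean raises an undefined-TBR error
rather than returning infinity.

### ROI handling

Annotations are GeoJSON polygons in pixel coordinates labeled `tumor` or
`background`. Rasterization uses pixel-center even-odd inclusion (a pixel
at 0-based $(x, y)$ belongs to a region iff $(x+0.5, y+0.5)$ is inside the
polygon union), which is deterministic, orientation-free and
start-index-free. Multiple polygons per label are unioned; interior rings
(holes) are rejected explicitly; tumor/background overlap is an error
reporting the overlap pixel count. Tissue-free white areas such as empty
fat vacuoles are *not* excluded from the masks — the scoring method this
package reproduces includes them in the intensity measurements, which is a
known property (and limitation) of the area-mean approach.

## Cohort statistics

Patients with several samples get the unweighted mean of per-sample tumor
and background means, and the patient TBR is recomputed from those averaged
means — not averaged over per-sample TBRs — so each patient contributes one
intensity pair. Tumor-vs-background contrast is tested with a two-sided
paired t-test; the preoperative-therapy subgroup comparison uses the
two-sided pooled-variance unpaired t-test (Welch by flag; the underlying
reference does not name a variant, so pooled is the default and the choice
is explicit configuration). Significance is called at $p \le 0.05$. No
multiple-testing correction is applied, matching the procedure being
reproduced. The "expressed" call uses an explicit threshold (tumor mean
$\ge$ 10 on the inverted 0–255 scale, configurable) because no published
criterion exists for it; it is configuration, not a hidden constant.

## What the phantom generator emulates

`forward_model()` renders H-DAB tiles from a `phantom_spec()`:

* hematoxylin counterstain everywhere at density 0.3 OD — a typical
  mid-intensity nuclear counterstain level; its exact value is immaterial
  to scoring because unmixing removes it (verified to leak $\le 2$ gray
  levels into the DAB channel);
* region-dependent DAB density: a base density plus a seeded mid-frequency
  Gaussian texture (coarse 16-px white-noise grid, bilinearly upsampled,
  standardized per region). The texture is what gives within-ROI SDs of the
  magnitude real tissue shows (~40 gray levels); white pixel noise alone
  cannot reach that at plausible noise levels;
* Gaussian pixel noise in OD space (default SD 0.03 OD per channel,
  i.e. multiplicative in intensity);
* white fat vacuoles: seeded discs of radius 3–7 px punched into the
  background until 8% of its area is tissue-free glass. Vacuole pixels
  score exactly 0 after inversion and stay inside the measured masks;
* 8-bit quantization of the rendered intensities.

The phantoms are *statistical*, not morphological: no nuclei, fascicles,
or stromal architecture, no scanner illumination gradients, no stain
vector variation between slides, no annotation error. Passing the recovery
tests therefore demonstrates that the measurement chain is unbiased and
correctly calibrated under the forward model's assumptions — it cannot
certify robustness to stain-vector mismatch or annotation variability in
real material.

### Geometry

The default layout is a central elliptical tumor (semi-axes 0.30 W ×
0.24 H), a 10-px unannotated border band standing in for the drawn tumor
border, and an elliptical annulus of adjacent healthy tissue. The annulus
is encoded as two half-annulus polygons so every ring is simple (the ROI
reader supports no holes). How far "adjacent healthy tissue" should extend
is not defined anywhere authoritative, so the margin is a parameter of the
geometry rather than a fixed truth.

### Cohort presets and calibration

Each preset (`TEM1`, `VEGFA`, `PDGFRA`) fixes 17 deterministic per-case
target pairs (tumor intensity, TBR) split 11/6 by preoperative therapy.
The lists are constructed so that:

* subgroup means equal the published subgroup summaries *exactly*
  (e.g. TEM-1: tumor intensity 85/74, TBR 3.5/2.2). The published overall
  means (81, 3.1) are the rounded versions of what those subgroup means
  imply (81.12, 3.04), so pinning the subgroups reproduces the overall
  values to well under reporting precision;
* the TBR<1 structure is reproduced (none for TEM-1; exactly three cases
  for VEGF-A and PDGFR-α, placed 2/1 across the subgroups);
* within-group spreads are wide (the assay shows large between-case
  variation) and sized so the subgroup t-tests come out non-significant,
  as published; the spread shapes are fixed zero-sum offset patterns,
  documented in `preset_targets()`, chosen once and not fitted;
* per-case within-ROI SD targets scale proportionally with the case's
  intensity, so their mean equals the published mean SD (39/45/36)
  exactly.

Calibration inverts the *actual* measurement chain, not just $f$: for each
region, `calibrate_region()` solves base density $d_0$ and texture
amplitude $a$ such that the noiseless measured distribution
$f_\text{eff}(\max(d_0 + a\,T(x), 0))$ over the region's realized texture
$T$ has the target mean and SD, where $f_\text{eff}$ includes the
$\varepsilon$ log-offset and the hematoxylin crosstalk of the real
pipeline. The solve is nested bracketed root-finding (`uniroot`): $d_0$
against the mean at fixed $a$ (the mean is strictly monotone in $d_0$),
$a$ against the SD (monotone from 0). For speed it runs on a 1024-point
quantile compression of the texture values, then polishes $d_0$ on the
full field; the background target mean is first inflated by the realized
vacuole count so that the vacuoles' zeros are part of the measured mean.
Residual recovery error is then dominated by 8-bit quantization and the
second-order bias of the OD noise through the concave response —
empirically $\lesssim 0.5$ gray levels at 512 × 512, against a ±2-gray
acceptance band.

One deliberate relaxation: with texture enabled, the per-pixel density
field is clipped at zero and the solved *base* density may in principle go
slightly negative for extreme SD targets; non-negativity is enforced on
the field, not the base. All shipped preset calibrations solve positive.

Determinism: each case derives its seed from the master seed and patient
number; texture, vacuoles and noise are drawn in a fixed order, so an
identical spec regenerates the slide bit for bit, and cohorts are
byte-identical across runs with the same seed.

## Numerical choices and degenerate inputs

* Root-finding tolerances: `calibrate_dab()` to $10^{-6}$ intensity on the
  response (spec-level guarantee; `uniroot` tol $10^{-12}$ on density);
  region calibration to $10^{-8}$ on density for means, $10^{-5}$ on the
  amplitude for SDs.
* Unattainable targets: `calibrate_dab()` errors above the saturation
  bound, stating the attainable maximum; an SD target beyond the texture's
  reach falls back to the bracket maximum (the mean is still met exactly).
* Single-pixel ROIs report SD 0 with a warning; empty masks, double
  inversion, non-normalized grayscale weights, collinear stain vectors and
  self-intersecting polygons are hard errors; each scoring stage tags its
  errors with the protocol step number.
* Gradient maps min–max scale and record the bounds; constant rasters
  render at the colormap midpoint with a degenerate-range warning.

## Problem sizes

The shipped verification runs use 512 × 512 tiles for the three 17-case
cohort recoveries (about 18 s per cohort on one CPU, ~55–60 k pixels per
ROI) and 96–256 px tiles for unit-level checks. Tile size only affects
Monte-Carlo error in the recovered means (it shrinks as pixel count
grows), not the calibration itself, which is exact per realization.

## Known limitations

* Stain vectors are always supplied or preset; there is no data-driven
  stain estimation (Macenko-style), and no whole-slide pyramid support —
  tiles only.
* The area-mean score does not correct for cell density or tissue-free
  area; vacuoles dilute the background mean by design, faithfully to the
  protocol being reproduced.
* Equivalence with any specific desktop implementation of H-DAB
  deconvolution is plausible (same published stain matrix, same step
  order) but not provable without the original slides.
* The phantoms cannot validate robustness to scanner variation,
  out-of-focus regions, or annotation error; they validate the
  measurement algebra and the statistics.
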