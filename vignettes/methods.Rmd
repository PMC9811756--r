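---
title: "Quantifying neuro- and perivascular inflammation in white matter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuro- and perivascular inflammation in white matter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliovasc)
```

## The problem

Cerebral small vessel disease is diagnosed in vivo through MRI markers —
chiefly white matter hyperintensities (WMH) on FLAIR — but the inflammatory
tissue changes underlying those markers can only be measured post mortem, on
immunostained sections. Linking the two requires (i) carrying MRI-drawn
regions of interest (WMH and normal-appearing white matter, NAWM) onto the
histology grid, (ii) turning brightfield immunostains into quantitative
per-cell and per-region measurements, and (iii) comparing groups (for
example hypertensive versus normotensive donors) while adjusting for
nuisance covariates. `gliovasc` implements that chain end to end, together
with a synthetic-cohort generator that provides exact ground truth for every
stage, so the whole pipeline can be validated quantitatively rather than by
visual inspection.

## Stain separation

Brightfield immunohistochemistry follows the Beer–Lambert law: transmitted
intensity is $I = I_0 \cdot 10^{-\mathrm{OD}}$ and optical density is linear
in chromogen concentration. A pixel's 3-vector of channel ODs is modelled as
$M c$, where the columns of $M$ are unit-norm stain OD vectors
(hematoxylin, DAB, and a residual completing the basis as the normalised
cross product) and $c$ the per-stain concentrations. `deconvolve()` inverts
this linear system per pixel; negative concentrations — noise outside the
stain simplex — are clipped at zero and the clipped mass fraction is
reported as a quality metric. The same widely used H-DAB basis serves both
DAB immunostains (IBA1 for microglia, GFAP for astroglia), which share the
brown chromogen and hematoxylin counterstain; the basis is a nine-number
config entry for labs that calibrate their own vectors.

$I_0$ defaults to the 8-bit white point (255 per channel), which matches
calibrated scanner exports and the package's own renderer.
`estimate_background_i0()` is available for slides with a tissue-free
margin; it is not the default because sections fully covered by tissue make
a margin-based estimate collapse.

The synthetic renderer (`render_slide()`) is the exact forward model of this
inversion: per-object stain amounts accumulate into concentration maps and
$RGB = I_0 \cdot 10^{-Mc}$. With `quantize_8bit = FALSE` the loop
render → deconvolve is exact to numerical precision (~1e-15 OD); with the
default 8-bit quantisation one grey level corresponds to roughly 2e-3 OD,
which is the measurement floor a real scanner imposes.

## Registration and ROI transfer

MRI-drawn ROIs reach the histology grid through a landmark transform
(`fit_landmark_transform()`): an affine least-squares fit by default, or an
exact thin-plate-spline interpolant ($U(r) = r^2 \log r$, ridge
$\lambda = 0$). Affine is the default because formalin distortion over a
2 × 2 cm block is mild; the TPS is available where visible nonlinearity
remains. The operating standard is at least 10 landmark pairs; fewer
produce a warning, not an error. `rmse_px` is the RMS over residual
components, so landmark noise of SD $\sigma$ yields
$\mathrm{rmse} \approx \sigma \sqrt{1 - 6/(2n)}$ for the 6-parameter fit.

Adjacent sections (IBA1, GFAP versus the HE reference) can be co-registered
intensity-based (`register_intensity()`): a 5-parameter affine (translation,
rotation, per-axis log-scale) maximising mutual information over a
three-level coarse-to-fine pyramid, with a translation grid search at the
coarsest level to find the basin. MI is the default because the sections are
different stains (multimodal); normalised correlation is a config switch.
Convergence is declared when the MI gain over the initial transform reaches
0.05 nats *or* the normalised MI (MI divided by the smaller marginal
entropy) reaches 0.25 — the second clause covers the legitimate case where
the initialisation is already essentially correct and no gain is possible.
Non-converged results signal the manual landmark fallback, which is recorded
with its own method tag so missing or manually registered stains stay
visible in the output.

Mask warping is inverse-mapping with nearest-neighbour interpolation, so
warped masks are strictly binary; images use bilinear interpolation.

## Glial segmentation and morphometrics

Thresholding follows a cohort-level rule: per subject, candidate positive
pixels are found by Otsu's method on the in-ROI DAB OD; the working
threshold is $\kappa$ times the cohort mean of per-subject candidate mean
ODs ($\kappa = 0.5$ by default — the candidate mean is the centre of the
positive class, and half of it approximates the positive/background
boundary). Per-subject candidate means are retained so threshold behaviour
can be audited per individual. Both the candidate definition and $\kappa$
are explicit reconstructions (config-pinned), since the underlying
protocol's exact rule is not stated anywhere we could follow.

Segmentation is 8-connected components of the thresholded map inside the
ROI, after hole-filling; components under `min_object_area_um2` (default
20 µm², below soma scale; boundary kept on ≥) are removed. Per cell we
measure:

* **area** — pixel count × pixel area;
* **perimeter** — closed-polygon length through boundary-pixel centres,
  after a 5-point circular moving average of the contour chain. The raw
  8-connected chain overestimates a disk's perimeter by ~8% (staircase
  bias); with smoothing, rasterised disks score circularity ≥ 0.95.
* **circularity** — $4\pi A / P^2$, clamped to [0, 1]; amoeboid (activated)
  microglia score near 1, ramified cells far lower, which is the
  morphological activation axis of interest;
* **skeleton length** — Zhang–Suen thinning, reduced to a minimal
  8-connected chain (removal of 8-simple non-endpoint pixels; thinning
  otherwise leaves staircase corners that inflate oblique lines by up to
  ~18%), then orthogonal steps count 1 and diagonal steps $\sqrt 2$. Drawn
  poly-lines are recovered within 10% at all orientations (worst case ~9%
  at ~40°, the inherent bias of an 8-connected chain);
* **mean OD** over the object.

Region metrics follow the outcome definitions: frequency = objects per mm²
of ROI; area % = positive pixels / ROI pixels; intensity % = mean
positive-pixel OD / `od_max` × 100 (`od_max` = 2.0 by default — an explicit
reconstruction, documented so the scale is interpretable); average length
and circularity are unweighted means over cells. For GFAP, frequency,
length and circularity are reported as `NA`: astrogliotic scarring merges
cells into contiguous sheets, so astroglia counts are not meaningful.

## Perivascular grading

Vessel lumens are detected as bright (low hematoxylin OD) connected regions
with area ≥ 80 µm² (~10 µm equivalent diameter), solidity ≥ 0.8, not
touching the image border. The perivascular zone is the set of pixels
within 15 µm Euclidean distance of the lumen (boundary value included),
excluding all lumens and clipped to the tissue mask. Grading is:

| grade | rule |
|---|---|
| 0 | no perivascular astroglia |
| 1 | mild — density < 100 / mm² |
| 2 | moderate — 100–300 / mm² (both bounds included) |
| 3 | severe — density > 300 / mm², or an astrogliotic scar |

The density denominator is the annulus area itself. This is a pinned
reconstruction — "per mm²" does not name its reference area — and it has a
structural consequence worth understanding: a 15 µm annulus around a
12–40 µm lumen is only 0.002–0.005 mm², so a single astroglia already
exceeds 300/mm² and grade 1 is essentially unreachable for small vessels
(it would require an annulus over 0.01 mm², i.e. a lumen radius above
~80 µm). Grade distributions from the generator therefore concentrate on
{0, 2, 3}. The grading *rule* is exact; the denominator choice is what a
user would revisit if their vessels are small.

Scar detection is operationalised (again a reconstruction, the original
being a visual call): GFAP-positive angular coverage ≥ 75% of 360° within
the 15 µm band *and* positive-area fraction ≥ 50%. Close-range perivascular
inflammation is flagged when any astroglia centroid lies within 5 µm of the
lumen boundary (≤ rule; the distance is config-exposed because no
operational value is stated in the original protocol). Region summaries
report the percentage of vessels at each grade (they sum to 100 with grade
0), the percentage with any inflammation, and the close-range percentage,
along with the vessel count.

## Cohort statistics

Outcomes are analysed in a long table keyed by (subject, ROI, outcome),
joined to covariates. Before each model fit, Shapiro–Wilk normality (per
group) and Levene homogeneity (mean-centred, as in mainstream statistical
packages) are checked at α = 0.05; on failure the outcome is natural-log
transformed (shifted by −min + 1e-6 first if non-positive values are
present), and the transform is recorded in the result row.

The main model is an ordinary linear model
`value ~ group + roi + age + sex + fixation_interval`, with Type-III F
tests for group and ROI. ROI is a fixed crossed factor, not a repeated
measure — this mirrors the covariate-adjusted ANOVA described for the
motivating analysis; a subject-level mixed model is a defensible
alternative but is deliberately not the default, because fidelity to the
stated method was preferred over statistical taste (the generator's noise
model is iid per subject × ROI, under which the OLS test is exactly
calibrated — verified at a 5.4% rejection rate under the null). Constant or
aliased covariates (for example sex in a single-sex cohort) are dropped with
a warning rather than failing the fit.

Bonferroni families follow the outcome blocks of the report: microglia
(5 outcomes), astroglia (2), perivascular (5);
$p_{\mathrm{bonf}} = \min(1, m\,p)$ with the family size printed in every
result row. Chi-square tests are Pearson without continuity correction.
WMH-burden stratification is Fazekas ≤ 1 (mild) versus ≥ 2
(moderate–severe), analysed with the same covariate-adjusted model with
burden replacing group. "Multivariate" group comparison of demographics is
implemented as per-variable univariate tests, which is what a per-row
p-value table implies.

## The synthetic cohort

`cohort_spec()` fixes the study conditions: 17 hypertension versus
5 control subjects by default, one 450 × 900 µm slide per stain at
1 µm/pixel, with a 350 × 350 µm NAWM block and an equal WMH block. Every
outcome follows one additive model:

$$\text{outcome} = \text{baseline} + \delta_G\,[\text{hypertension}]
 + \delta_R\,[\text{WMH}] + \text{covariate terms} + \varepsilon,$$

realised through object placement: microglial density (baseline 270 /mm²),
amoeboid fraction (0.35), IBA1 OD (0.60), branch length (12 µm), astroglial
density (700 /mm²), GFAP OD (0.55), per-vessel perivascular density
(baseline 180 /mm², chosen so that the control group is not saturated at
grade 3 given the annulus quantisation discussed above), and scar
probability. Effect directions follow the motivating pattern (hypertension
above control, WMH above NAWM for activation outcomes); magnitudes are free
simulation parameters scaled by a single `effect_scale` knob (0 gives an
exactly null cohort; ~2.5 is the "large effect" regime used in end-to-end
direction checks). Noise is iid Gaussian per subject × ROI, which makes the
statistical calibration checks exact rather than approximate.

Geometry choices that make ground truth analytic: ramified microglia are a
soma disk plus 3–6 straight arms of stated length (so circularity and
skeleton length have known behaviour); amoeboid cells are soma disks;
astroglia are 6-armed stars. Perivascular astroglia are placed so that
`round(density × annulus area)` somata sit in the 2–13 µm band of the
15 µm zone with centre spacing at least two soma radii — counts are within
one cell of target by construction, and parenchymal astroglia are kept far
enough from vessels that their arms cannot merge with perivascular cells
and corrupt the counts. The degraded "MRI" counterpart is built by pulling a
WMH-bright anatomy raster through a known affine (plus optional
low-amplitude sinusoidal warp), gamma remapping, Gaussian blur, 4×
downsampling and noise; landmark pairs are sampled exactly from the true
map, and the true transform is returned (as a dense-grid TPS when the warp
is on).

What the generator does **not** emulate — and hence what passing tests do
not establish about real slides: realistic cell morphology beyond
disks-plus-arms, stain variability across batches, tissue folds, tears and
scanner artefacts, out-of-focus blur, true 3D section geometry, and
anatomically realistic vessel shapes. Validation on this cohort
demonstrates that the measurement chain is correct, not that its defaults
are optimal for any particular staining protocol.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (x, y) with pixel centres at integers and origin
  at the top-left; all physical quantities flow through `pixel_size_um`.
* The TPS system is solved in centred, unit-RMS-scaled coordinates for
  conditioning; the dense-grid truth TPS uses a 1e-6 ridge (control points
  still reproduced to < 1e-3 px).
* Otsu's threshold uses a 256-bin histogram of the supplied values.
* Objects exactly at the minimum area are kept; a centroid exactly on the
  15 µm (or 5 µm close-range) boundary is counted; densities of exactly 100
  and 300 /mm² grade as moderate.
* Single-pixel objects have circularity 1 and skeleton length 0; constant
  outcome vectors are flagged degenerate instead of crashing the
  assumption checks; an empty annulus at vanishing zone depth is returned
  empty rather than treated as an error.
* Validation problem sizes (chosen to exercise each property at meaningful
  scale): 100 counting slides of 20–200 cells, 200 simulated vessels at
  four target densities, 500 null replicates and 150 per power point for
  the ANCOVA calibration, and one full 17-versus-5 rendered cohort for the
  end-to-end direction check.

## Known limitations

* %mild is structurally near zero for small vessels under the
  annulus-denominator reading of the grading rule (see above).
* The intensity % scale depends on the `od_max` reconstruction; compare
  within a cohort processed with one config, not across configs.
* Intensity-based registration assumes a mild affine misalignment;
  sections with strong nonlinear distortion need the landmark path.
* The OLS group test is exactly calibrated under the generator's iid noise;
  if real data show strong within-subject correlation across ROIs, the
  mixed-model alternative (config flag) is the safer choice.
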