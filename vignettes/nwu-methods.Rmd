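---
title: "Net water uptake from non-contrast CT: model, pipeline, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net water uptake from non-contrast CT: model, pipeline, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nwuct)
```

## The measurement model

Ischemic edema adds water to infarcted tissue and lowers its CT attenuation
roughly in proportion to the water fraction. Net water uptake exploits the
brain's bilateral symmetry: if a region has mean density $D_i$ (Hounsfield
units) on the stroke side and its mirror region has mean density $D_c$, then

$$\mathrm{NWU} = \left(1 - \frac{D_i}{D_c}\right) \times 100\,\%$$

estimates the fractional density deficit. Two properties follow directly
from the ratio form and drive the test design:

* **Symmetry null.** On a perfectly symmetric head, every regional NWU is
  exactly zero — not approximately. The synthetic atlas is built exactly
  mirror-symmetric so this null is testable to machine precision.
* **Calibration invariance.** A multiplicative HU calibration factor cancels
  in $D_i/D_c$, so NWU is invariant to global gain differences between
  scanners (as long as the density window moves with the calibration).

A subtlety of the one-line form of the equation: the subtraction binds
before the percentage scaling, i.e. $(1 - D_i/D_c)\times 100$. Reading the
expression literally left to right ($1 - (D_i/D_c) \times 100$) would give
values near $-8500\%$ for normal tissue, which is obviously not a
percentage water uptake; the package documents and implements the former.

Density means are taken over voxels inside the **closed window 20–50 HU**.
This single rule removes encephalomalacia and chronic infarct (≈ 0–15 HU),
calcification (≫ 50 HU), and acute hemorrhage (≈ 60–90 HU) from the
comparison without any lesion segmentation. Regions in which no voxel
survives the window on either side are *excluded* from the averages rather
than imputed as zero: a fully filtered region carries no density
information, and imputing zeros would dilute the score toward normality.

Per subject, the ten regional values are aggregated two ways: the
**conventional average** (primary; reflects both the extent and the depth of
hypoattenuation, since unaffected regions contribute zeros) and a
**volume-weighted average** with the anatomical region volume in mm³ as
weight. The anatomical volume — not the post-window valid-voxel count — is
used as the weight because "the volume of each region" is a property of the
anatomy, not of the artifact content of a particular scan; valid-count
weighting is available as an option.

## Laterality

The stroke side is one choice applied to all ten regions. Choosing
ipsilateral/contralateral per region (e.g. taking whichever side looks
denser) would make noise rectify into a positive bias. With `side = "auto"`
the package computes the candidate average NWU for each hemisphere and takes
the side with the larger value; the choice is recorded in the result. On
lesion-free noisy phantoms this estimator stays near zero because the sign
of each regional value still averages out within the chosen side.

## The preprocessing chain

The pipeline runs field-of-view selection → Gaussian smoothing → skull
stripping → affine registration → resampling onto the atlas grid.

* **Field of view**: tight bounding box (margin 2 voxels) around the
  largest connected component above an air threshold (default −500 HU); the
  affine is updated so world coordinates are unchanged.
* **Smoothing**: separable Gaussian, default σ = half the in-plane voxel
  size. This denoises mildly without moving region boundaries by more than
  a voxel; σ is configurable and σ = 0 is the identity.
* **Skull stripping**: the brain is the largest connected component of
  voxels inside a 0–100 HU window that is *interior* to the bone shell
  (unreachable from the image border without crossing ≥ 300 HU), followed
  by morphological closing and hole filling. Scalp soft tissue is excluded
  by the interiority rule, not by intensity. Thresholds are exposed in the
  configuration.
* **Registration**: 12-dof affine with rigid-first staging, maximizing
  agreement (minimizing mean squared intensity difference) over sample
  points from the fixed mask, through a 3-level pyramid of
  Gaussian-smoothed copies (σ = 4, 2, 0 mm), optimized by Nelder–Mead with
  restarts and deterministic initialization from intensity centroids and
  mask principal axes (skipped when eigenvalues nearly coincide, where the
  axes are unstable). No stochastic restarts: results are bit-reproducible.
  One deliberate detail: the metric mask is the **brain mask dilated by 3
  voxels**, so that the high-contrast bone interface is inside the metric.
  With a brain-only mask the optimizer can shrink the transform a few
  percent to pull edge samples into homogeneous parenchyma — a masked-MSE
  pathology that costs little metric but biases every scale; the dilated
  mask anchors the skull and removes it.
* **Resampling**: trilinear for intensities (out-of-field −1024 HU),
  nearest-neighbour for labels (background 0). Registration failure is
  reported via a `converged` flag, not an exception, so batch runs
  continue.

## Region sampling and partial volume

Smoothing and interpolation mix intensities across region boundaries. For a
lesion confined to one region this mixing is asymmetric — boundary voxels
of the lesioned region borrow unlesioned density — and biases regional NWU
toward zero by roughly 10–15% of the lesion magnitude at 2 mm voxels.
Because the mixing is identical in both hemispheres, discarding the
boundary layer is unbiased: `compute_nwu()` therefore erodes each region
mask by 1 voxel (box erosion) before sampling densities, with a guard that
never erodes a region to emptiness. The anatomical (uneroded) volume is
kept for weighting. With erosion in place, simulated lesions of 5–25% water
uptake are recovered within ±1.5 percentage points through the full
pipeline, including pose recovery by registration and HU noise of σ = 2.

## The synthetic atlas and phantom

No public region masks ship with the package, so it builds a **schematic
synthetic atlas**: an ellipsoidal brain (white matter 33 HU, gray matter
38 HU, ventricular CSF 8 HU) inside a 1000 HU bone shell, with the four deep
structures as medial ellipsoids and M1–M6 as cortical ribbon sectors split
by axial band and in-plane angle. The geometry is deliberately schematic:
what matters for validating the *method* is exact ground truth — exact
mirror symmetry (the grid is laid out so the mid-sagittal plane falls
between voxel columns and reflection is a pure permutation), exactly known
region masks, and exactly known lesion magnitudes. A seeded, mirrored
intensity texture (σ = 1.5 HU before smoothing) makes registration
well-conditioned while preserving exact symmetry; it can be disabled for
tests that need piecewise-constant tissue.

The **phantom** applies lesions as multiplicative density reductions over
whole regions — lesion HU = $(1-w)\times$ base HU — so the constructed
density ratio is exactly $1-w$ before noise and the downstream estimate
tests the pipeline, not the phantom. Artifacts (calcification 90 HU,
hemorrhage 70 HU, encephalomalacia 10 HU) are inserted as spheres at
intensities outside the 20–50 HU window, so correct windowing leaves the
surviving voxels' mean density *identical* — an exact invariance, testable
with `identical()`. The scanner pose is applied last by resampling; noise
(default σ = 2 HU, a plausible parenchymal noise level for smoothed
5 mm-equivalent head CT) is added after the pose, as scanner noise would
be. Lesion fractions above ≈ 0.4 push white-matter voxels below the 20 HU
window edge; the generator records a warning in the truth object when that
happens, and validation uses w ≤ 0.25.

What the phantom does **not** emulate: beam hardening, reconstruction
kernels, partial-volume anatomy at sulci, asymmetric normal anatomy, motion
or metal artifacts. Passing the recovery tests therefore demonstrates that
the algorithm chain is correct and unbiased under its stated model, not
that clinical accuracy on real scanners is ±1.5 points.

## The cohort simulator and evaluation statistics

The cohort generator draws age ~ Normal(69, 14) truncated to 18–100, NIHSS
~ round(Gamma(1.7, scale 8)) clamped to 0–42 (median ≈ 11), tPA ~
Bernoulli(0.443), EVT ~ Bernoulli(0.391) — realistic acute-stroke registry
scales — an NWU-like biomarker ~ Gamma(1.6, scale 3.5), an ASPECTS-like
score as a noisy decreasing transform of the biomarker onto 0–10, and a
binary poor-outcome indicator from a stated logistic model (default
coefficients: intercept −2.8; age 0.02; NIHSS 0.10; tPA −0.7; EVT −0.3;
biomarker 0.13 per percentage point, i.e. an odds ratio of ≈ 1.14). The
defaults produce ≈ 53% poor outcomes. All parameters live in the model
object, so parameter-recovery tests fit the generated data and compare
against the generating values.

The evaluation statistics are implemented from first principles and
cross-checked in the test suite against independent routes (`glm`,
`fisher.test`, `wilcox.test`, `pROC`, brute-force enumeration, bootstrap):

* **Logistic regression** by IRLS (≤ 100 iterations, deviance-change
  tolerance 1e−10), Wald standard errors, 95% CIs as exp(β ± 1.96 se).
  Separation is reported through the `converged` flag; no penalization by
  default. Deviance decreases monotonically across iterations by
  construction, and the tests assert it.
* **Stratified 80:20 split**: per-class test counts are
  round(class size × fraction); an exact .5 rounds up in the larger class
  and down elsewhere, keeping the total at the intended fraction.
* **AUROC** as the Mann–Whitney statistic via midranks (ties count half).
  No automatic direction flipping: an AUROC below 0.5 is reported as such.
* **DeLong test** from placement values, with the paired covariance term;
  a zero-variance difference with equal AUROCs returns z = 0, p = 1.
  Evaluation happens on the held-out test set of a single stratified split
  (the covariance term requires paired scores on the same subjects).
* **Fisher exact** (probability-ordering two-sided p; sample odds ratio
  with Haldane 0.5 correction at zero cells) and **Wilcoxon rank-sum**
  (exact by enumeration up to a combined n of 12 without ties, otherwise
  normal approximation with tie and continuity corrections).
* **Cohort description**: binary variables as n (%), continuous as median
  [IQR] with type-7 quartiles (the convention had to be fixed; type 7 is
  R's default and the most common). Percentages are rounded to one
  decimal. No multiple-testing adjustment is applied across rows; the
  p-values are raw and documented as such.

## Numerical and design choices

* Canonical orientation is RAS everywhere; all inputs are reoriented at
  load so left/right flips cannot silently corrupt the bilateral ratio.
  Voxel indexing is 0-based with the affine mapping index (0,0,0) to that
  voxel's world center.
* The HU window is closed on both ends (20 and 50 HU are kept).
* Auto side selection ties break toward "left"; a tie occurs only on
  exactly symmetric data where the choice is immaterial.
* Out-of-range or non-finite intensities at load map to a −1024 HU
  sentinel, which the air threshold and HU window then exclude.
* The DICOM reader supports classic single-frame CT series in implicit or
  explicit little-endian transfer syntax, sorts slices by projection onto
  the slice normal (never by filename), and requires rescale slope and
  intercept — refusing to guess HU calibration.
* Problem sizes: the packaged default atlas grid is 96×112×80 at 2 mm; the
  test suite uses 64×80×56 at 2.5 mm, which keeps every full-pipeline test
  comfortably fast while leaving all tolerances unchanged.

## Known limitations

Affine registration cannot correct local deformation, so regional masks on
real anatomy carry registration error beyond the phantom setting. The
synthetic atlas is schematic; clinical use requires supplying real atlas
masks in the documented directory layout. The equal-variance behaviour of
the DeLong test is verified at n = 100 per cohort; very small test sets
(tens of subjects) inherit the usual small-sample anticonservatism of
normal-approximation tests. ASPECTS in the simulator is a transform of the
same latent severity as the biomarker — adequate for structural tests of
the comparison machinery, but not a model of independent radiologist
behaviour.
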