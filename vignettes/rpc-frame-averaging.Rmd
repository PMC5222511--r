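---
title: "Methods: quantifying RPC visualization under en-face frame averaging"
author: "rpcavg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RPC visualization under en-face frame averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

The radial peripapillary capillaries (RPCs) form a quasi-two-dimensional
network of long, nearly parallel vessels with sparse anastomoses in the
retinal nerve fiber layer around the optic disc. On en-face OCTA the
network is sampled at roughly 9.6 µm per pixel (a 10×10°, 304×304 px scan),
which is coarse relative to the ~9 µm true capillary diameter: individual
capillaries are at the resolution limit, and single frames are dominated by
decorrelation noise. The package implements the measurement chain that
quantifies how much multi-frame registration and averaging improves this
picture, and at what point additional frames stop helping.

The chain is: rigid registration of a 10-frame stack to a reference frame →
per-ROI averaging of the first n frames (n = 1…10, reference first) →
upsampling ×6, contrast stretch, adaptive thresholding, skeletonization →
five metrics per (ROI, n) → one-way repeated-measures ANOVA across n with a
Greenhouse–Geisser correction and Bonferroni sequential post hoc tests →
the optimal frame count per metric and region.

## Physical scale

`scale_model()` fixes 30.4 px/degree and converts degrees to retinal microns
as 291 µm/deg scaled linearly by axial length over 24 mm (a Bennett-style
small-angle correction; the default eye gives 9.57 µm/px, 1.595 µm per
resized pixel). Axial length is an input, not something the package
estimates. All boxes and masks are derived from this scale: the 2°/60 px
ROI, the 0.1×1° (3×30 px) intercapillary-distance sampling box, and the
15 µm (9 resized px) SNR mask diameter.

## The synthetic generator: what it emulates, and what it does not

`synthetic_scene()` draws near-parallel centrelines at a mean spacing of
38 µm (healthy RPC spacing sits in the 30–40 µm range) with 8% spacing
jitter, mild sinusoidal tortuosity (3 µm amplitude, 100 px period), sparse
anastomoses, and a Gaussian cross-section whose FWHM equals the 9 µm true
diameter — sub-pixel at acquisition resolution, as in reality. Brightness
is modulated along each vessel (±20–30% on two incommensurate length
scales): OCTA decorrelation signal is not uniform along a capillary, and
without this texture the translation component parallel to a field of
uniform straight vessels would be unobservable to any registration
algorithm (an aperture problem), which no real stack exhibits.

Each frame applies, in order: the frame's rigid misalignment (uniform
within ±3 px and ±1°; frame 1 is the untransformed reference),
multiplicative speckle with factor Normal(1, 0.3) clipped at zero, additive
Normal(0, 0.05) background noise, and whole-row motion-artifact lines with
per-row probability 0.01 (rows are brightened or attenuated copies,
matching the dominant scan axis; both axes can be enabled). Noise
magnitudes were chosen once so that single frames look grainy while
10-frame averages look smooth — the acquisition device's noise statistics
are not published, so the calibration is qualitative and every parameter is
config-exposed. Per-frame noise uses a sub-RNG derived deterministically
from (scene seed, frame index), so stacks regenerate bit-for-bit.

What the generator does **not** emulate: the decorrelation statistics of
the SSADA algorithm, projection artifacts, capillary-free zones around
arteries, signal *dropout* along vessels in single frames, B-scan geometry
and the choroid. One visible consequence: on real data capillary density
*rises* with averaging (averaging reconnects vessels fragmented by signal
dropout), whereas in this generator noise only adds spurious skeleton
pixels, so synthetic density is flat-to-slightly-falling in n. Passing the
synthetic suites therefore demonstrates correctness of the operators and of
the statistics, plus the SNR/endpoint/segment-length averaging behaviour —
not a quantitative reproduction of device-specific effect sizes.

The recorded ground-truth density is the geometric path length of the
*rasterised* centreline map divided by field area, which is what an ideal
skeletonization of that map would measure (and is recomputable from the map
exactly).

## Registration

The reference frame maximises interquartile intensity range minus a
motion-artifact penalty (the fraction of rows/columns whose mean deviates
by more than 3 SD from the mean row/column level, weight λ = 1); ties break
to the lowest index. This is an automated proxy for the clinical "highest
contrast, fewest artifact lines" choice, which is not published as a
formula.

Alignment is translation + rotation only — same-device, same-session scans
do not change scale, and elastic refinement is deliberately out of scope
(the API accepts externally estimated transforms through
`transfer_transforms()`, which also covers the deep-layer fallback of
estimating on a higher-contrast slab of the same eye). The estimator:

* mild Gaussian low-pass (σ ≈ 1.5 px) — speckle is spectrally white and
  otherwise swamps the weak along-vessel texture;
* Hann-windowed cross-correlation via FFT for translation. Plain
  cross-correlation is used rather than phase correlation: spectral
  whitening weights all frequencies equally and destroys the SNR of the
  weak along-vessel components on near-periodic stripe content;
* sub-pixel refinement by evaluating the correlation on a 0.05 px grid
  around the integer peak directly from the cross-power spectrum
  (matrix-DFT local upsampling), rather than a parabola fit, which is
  biased on broad peaks;
* rotation by a coarse (0.5°) then fine (0.1°) search over the correlation
  peak score with a final parabolic refinement, followed by a second
  translation pass after warping to remove window-induced bias.

On simulated stacks at speckle SD 0.3 this recovers translation with mean
absolute residual ≈ 0.15 px and rotation ≈ 0.03° (contract: ≤ 0.5 px,
≤ 0.2°). Out-of-field pixels after resampling are marked invalid (NA)
rather than zero-filled; any ROI whose averaging window touches an invalid
pixel is excluded whole, so border fill can never bias an average.

## ROI placement

The disc margin ellipse comes from ≥ 5 clicked margin points via the
numerically conditioned direct least-squares conic fit constrained to an
ellipse. ROI centres sit at the ellipse boundary plus one degree along the
five sector directions (OD: S = 90°, ST = 45°, T = 0°, IT = −45°,
I = −90°; mirrored horizontally for OS) — the "centred ~1° from the disc
margin" reading; the 45° spacing with temporal at 0° matches the published
five-box layout but is configurable, as it is not stated numerically in
text. Boxes are 60 px (~2°) on a side; the expected capillary orientation
in each ROI is radial (the sector direction), overridable in config — the
package does not estimate orientation from image content. Manual per-label
pixel offsets emulate the clinical nudge used to avoid major vessels and
arterial capillary-free zones; off-image boxes are flagged excluded, never
clipped.

## Quantification choices

* **Binarization**: bicubic ×6 upsample (cubic-convolution kernel,
  a = −0.5), linear contrast stretch of the 1st/99th percentiles to [0,1]
  (clipped), adaptive threshold against a Gaussian-weighted local mean over
  a 50×50 px window with zero offset. The percentiles, window flavour and
  offset are not published; they are robust defaults, config-exposed, and
  the tests assert *recovery* (density, ICD, endpoint behaviour), not
  operator identity. A constant ROI binarizes to empty with a warning. At
  the default 9 µm diameter capillaries are sub-resolution, so their
  binarized width is PSF-limited (~8 resized px) rather than diameter-
  limited; width fidelity holds for resolvable vessels (≥ ~15 µm). Length
  and spacing metrics are unaffected by this widening — only centrelines
  enter them.
* **Skeletonization**: Zhang–Suen thinning to one-pixel width. Endpoints
  are skeleton pixels with ≤ 1 eight-neighbour (isolated pixels count);
  branch pixels have ≥ 3, and 8-connected branch clusters count once.
  Segments are the components left after deleting branch clusters.
* **Length**: geometric step length (1 per orthogonal step, √2 per
  diagonal; diagonals that shortcut an existing orthogonal path are not
  double-counted). Chosen over raw pixel count because density is reported
  in physical units (mm⁻¹); `length_metric = "pixels"` switches.
* **SNR**: population SDs (sample SDs differ by < 0.1% at these pixel
  counts); the mask is built once from the 10-frame average and reused for
  every n of that ROI, so SNR differences reflect intensity statistics,
  not mask changes. Endpoint/segment metrics, in contrast, re-run the
  binarize→skeletonize path per n — the per-n skeletons are the published
  behaviour being measured.
* **ICD**: the 3×30 px box is sampled at original resolution (the metric
  predates upsampling in the chain), bilinearly, averaged across the short
  dimension; the min–max-normalised profile's local maxima with prominence
  ≥ 0.1 and separation ≥ 2 px give the mean peak-to-peak distance. Fewer
  than two peaks → the value is flagged unmeasurable and excluded from
  statistics rather than silently zeroed. The box height (~2 capillary
  diameters) keeps perpendicular capillaries from contributing to the
  profile.
* **Averaging order**: acquisition order with the reference first; the
  ordering is not specified in the source description, and any fixed order
  gives exchangeable noise.

## Statistics

`rm_anova_gg()` computes the standard within-subject decomposition; the
Greenhouse–Geisser epsilon is tr(A)²/((k−1)tr(A²)) for A = CSC with S the
sample covariance of the condition columns and C the centring matrix,
clamped to [1/(k−1), 1] (exactly 1 at k = 2). F is tested on ((k−1)ε,
(n−1)(k−1)ε) df. The implementation is matrix-algebra; the test suite
checks it to 1e-8 against a loop-based sums-of-squares/eigenvalue oracle
and to 1e-10 against `car::Anova`'s repeated-measures machinery.

Post hoc tests are paired two-sided t-tests on *sequential* pairs only
(1v2 … 9v10), Bonferroni-corrected with m = 9 — the sequential reading
matches how the published comparisons are described; an all-pairs variant
(m = 45) sits behind a flag. A pair with zero within-subject variance gets
p = 1 (identical columns) or p = 0 (constant nonzero shift) and is flagged.
Under a null simulation (n = 22, k = 10) the familywise false-positive
rate stays ≤ 7%.

**Optimal frames** is operationalised as the smallest n such that every
sequential comparison from (n vs n+1) onward is non-significant at α =
0.05; no significant pair → 1, a significant last pair → 10. This rule
reproduces "no further improvement beyond averaging n frames" phrasing and
yields 1 for a metric with significant omnibus ANOVA but no significant
sequential pairs (the ICD pattern).

Percent differences are computed on across-subject means (ratio of means);
mean-of-ratios is available as a config switch since the published table
does not state which was used. Excluded ROIs propagate listwise — a
subject missing any cell of a metric×region matrix is dropped from that
ANOVA, matching whole-ROI exclusion.

The normative comparison places a patient's per-region 10-frame density at
its empirical quantile within ≥ 5 controls and flags values below the
lower box-plot whisker (Q1 − 1.5 IQR) or below the control minimum.

## Numerical and degenerate-input policy

Bicubic resampling uses the Keys a = −0.5 kernel with border replication;
the ×6 upsample is implemented as sparse band-matrix products. Constant
images: reference selection and registration refuse them (flagged
unregistrable); binarization returns empty-with-warning; SNR with zero
total variance is a degeneracy error. Ellipse fitting requires ≥ 5
non-collinear points and reports an RMS radial residual that is
monotonically nondecreasing in point noise. Ties in reference selection go
to the lowest frame index. All containers carry explicit `excluded` flags
plus reasons; nothing is silently dropped.

## Problem sizes

The bundled analyses and checks are sized for a laptop-class single core:
the test suite simulates ROI-sized (60 px) stacks for trend checks (20
seeds), full 304 px stacks for registration contracts (a handful of
stacks), 100 random images for the skeleton oracle, 50 random matrices for
the ANOVA oracle and 1000 null replicates for the type-I check; the
acceptance run uses a six-subject, ten-frame cohort. These sizes are the
package's choices for routine verification; all of them scale up by
changing one argument.

## Known limitations

* Rigid-only registration; elastic residuals of real eye motion are not
  modelled or corrected (the post-rigid hook accepts external transforms).
* The generator's noise model is qualitative (see above); effect sizes on
  synthetic cohorts are not expected to equal published in-vivo values —
  notably the sign of the density-vs-n trend.
* The statistics stage reproduces published group tables only when the
  per-subject source workbook is supplied; it is third-party data and not
  redistributed here.
* Masks use a uniform 15 µm capillary diameter; residual signal in the
  background region (and vice versa) is inherent to that simplification.
* ICD is measured in one centred sampling box per ROI, not slid across the
  region, so it samples local spacing.
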