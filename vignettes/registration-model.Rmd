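---
title: "Spherical-eye distortion correction for WF-to-UWF retinal registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical-eye distortion correction for WF-to-UWF retinal registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retialign)
```

## The problem

Two fundus imaging devices see the retina through very different optics.
An ultra-wide-field (UWF) scanning laser ophthalmoscope captures ~200°
of internal angle in a single shot; a confocal wide-field (WF) device
captures 55° fields which are steered across the retina (a 3×3 grid of
eight or nine fields spanning roughly 110-120°). Overlaying the WF
fields on the UWF image lets clinicians co-localize peripheral lesions
across modalities, but a 2D polynomial warp alone cannot do it well: in
the UWF periphery the two projections differ by a distortion that no
low-order 2D model removes. `retialign` registers each WF field to the
UWF frame with a classical feature pipeline plus an explicit 3D
spherical-eye camera model whose pose is optimized per field, then
fuses the fields into a composite.

Everything in the package is deterministic by construction (or seeded),
because the pose search compares overlap scores across hundreds of
candidate poses: any randomness upstream of the score would be
indistinguishable from signal.

## The eye model

The eyeball is a unit sphere. The UWF device is modeled as a
stereographic projector: camera at the cornea centre $(0,0,-1)$, image
plane $z = 1$. A retina point at internal polar angle $\varphi$ from
the posterior pole lands at plane radius $2\tan(\varphi/2)$; the rim of
the 200° field ($\varphi = 100°$) is mapped to the image half-width,
which fixes the pixel calibration. Stereographic projection is
conformal, which is also how the phantom knows how wide to draw a
projected vessel.

The WF camera is a pinhole inside the eye with five degrees of freedom:
position $(x, y, z)$ and optical-axis rotations
$(\theta_x, \theta_y)$, with $R = R_x(\theta_x) R_y(\theta_y)$
(right-handed, radians; the rotation order is a package convention).
The missing sixth parameter -- rotation about the optical axis -- is
deliberately left to the 2D polynomial that follows the 3D correction.
The WF image plane's centre is constrained to $z = 1$, which pins the
focal depth to $f' = (1 - z)/(\cos\theta_x \cos\theta_y)$ and keeps
exactly five free parameters.

The forward chain maps every WF pixel $(m, n)$ onto the image plane
$(m', n', f')$, along the camera ray to the *far* sphere intersection
$(m'', n'', z)$ (the retina on the far side of the eye), and through
the stereographic projector to UWF pixel coordinates $(m_p, n_p)$.
Warping the UWF image by the displacement field $(m_p, n_p) - (m, n)$
(bilinear resampling) reprojects it to the WF perspective. The chain is
closed-form in both directions; the inverse direction is what finally
places WF content in the UWF frame.

## The 2D registration pass

Both images are first reduced to vessel maps -- per-pixel vessel
probabilities in $[0,1]$ -- the common currency that bridges the
modality gap. In the original AI pipeline these come from trained
segmentation networks; here a deterministic multiscale Hessian ridge
filter stands in, and every consumer accepts externally supplied maps
so learned models can be plugged in. Keypoints are Harris corners on
the vessel map (vessel junctions and bends), described by normalized
log-polar intensity patches; matching requires bidirectional
(mutual-nearest-neighbour) consensus. Because the UWF and WF rasters
sample the retina at different densities, descriptor radii on the UWF
side are scaled by the nominal pixel-scale ratio of the two cameras.

Matched pairs are cleaned by one of two interchangeable rejectors:

* **RANSAC-SC** -- seeded hypothesize-and-verify with consensus-set
  refit/re-score rounds. Reproducible for a fixed seed, but still a
  sampling method, so the pose optimizer refuses it.
* **IRLS** -- fully deterministic robust reweighting: a
  least-median-of-squares initialization (exhaustive enumeration of
  2-point similarity hypotheses -- no sampling), a Huber warm start,
  then Tukey-biweight iterations. The scale default (1 px) is the
  expected sub-pixel corner-localization noise; 50 px mismatches get
  exactly zero weight.

The surviving weighted matches feed a weighted least-squares fit of the
2×6 second-order polynomial transform
$[u, v]^T = M_{poly}\,[m, n, m^2, n^2, mn, 1]^T$, fitted in *both*
directions (the quadratic has no closed-form inverse; resampling always
uses the output-to-input direction). Coordinates are mean/scale
normalized before the fit -- raw quadratic monomials at 512-4000 px
coordinates would condition the normal equations terribly -- and the
estimate is denormalized exactly afterwards. A guided re-matching pass
(descriptor matching under a spatial gate from the first fit) recovers
pairs that pure descriptor matching loses among repetitive vessels.

## The pose search

Per probed pose, the UWF vessel map is reprojected to the WF
perspective and registered to the WF map in 2D; the soft Dice
$\mathrm{Dice}(I_1, I_2) = 2\sum \min(I_1, I_2) / (\sum I_1 + \sum I_2)$
of the result (scored on the WF footprint) is the objective. Two design
points matter, both discovered by measuring the objective landscape on
phantoms with known poses:

* **The inner 2D model is affine during the search.** With the full
  12-DOF quadratic inner model the objective is nearly flat -- the
  polynomial absorbs almost all pose-induced distortion, and the
  maximum can sit tens of degrees from the true pose. An affine inner
  model leaves the curvature residual, which only the pose can explain,
  visible to the objective: the landscape then rises monotonically
  toward the true pose over a ±0.4 rad basin.
* **A registration-free polish finishes the search.** The bare
  reprojection Dice (no inner registration at all) is sharply peaked at
  the geometrically true pose but has a narrow basin; it is used as a
  coarse-to-fine refinement (Gaussian-blurred maps at decreasing sigma,
  default 4, 1.5, 0 WF px) after the global stages.

The search itself is a coarse grid multi-start over the two steering
rotations (default ±0.45 rad in 0.15 rad steps -- wide enough to cover
the 3×3 steering layout), Nelder-Mead over all five parameters with a
box-bound penalty, then the polish. The final report re-registers with
the full quadratic model at the best pose, and the returned pose never
scores below the initial pose (the initial on-axis pose is a fallback,
not a hope). Bounds default to $|x|,|y| \le 0.3$,
$z \in [-0.6, 0.1]$, $|\theta| \le 0.8$ rad.

Finalization pushes the matched keypoints through the chain into the
UWF frame, fits a near-identity 2D polish there, and warps the WF
image (and its mask) into the UWF frame through the closed-form
inverse chain composed with the polish.

## Compositing

Warped fields are fused as a mask-weighted average,
$\sum_i w_i I_i / \sum_i w_i$, after Gaussian feathering of the masks
(default sigma 1% of the UWF width; the devices' own montage software
makes a similar choice, and the exact value only trades seam width
against blur). Pixels with no coverage are 0; a guard at
$\sum w < 10^{-8}$ avoids division noise. A checkerboard overlay of
composite vs UWF is rendered for visual QC, the standard presentation
for judging vessel alignment across block boundaries.

## The phantom

Clinical image pairs with ground truth do not exist at desk scale, so
the package carries a phantom eye: a seeded random vessel tree grown by
great-circle random walks on the unit sphere (roots leaving a synthetic
optic disc, Gaussian heading jitter, probabilistic branching with width
decay), rendered through the *same* two camera models the registration
assumes -- which is exactly what makes it an oracle: true poses and
dense WF-to-UWF correspondences are known by construction. The
modality gap is emulated with different tone curves, blur and seeded
background texture in the two renders, so matching has to bridge
appearance. Defaults mirror the target acquisition: one 200° UWF
image, nine 55° fields steered ±0.35 rad on a 3×3 grid (a ~110-120°
mosaic), camera at $z = -0.2$.

Raster sizes default to a desk-test scale of 512 px (UWF) and 256 px
(WF) -- device-realistic 4000/768 rasters are a configuration away but
are not what the test suite runs. Two generator choices are worth
stating plainly:

* **Vessel trunk width defaults to 2.2° of arc.** At 512 px the UWF
  render resolves ~1.9 px/degree, 15 times coarser than the real
  device; a device-realistic 0.5-1° vessel would be a sub-pixel streak
  whose soft-Dice self-consistency is dominated by sampling error
  rather than geometry. Widths are set so vessels span ~4 px in the
  coarser render.
* **Stroke anti-aliasing ramps are matched to the WF/UWF
  magnification**, so the ground-truth WF map has the same boundary
  softness as a reprojected UWF map and soft Dice compares geometry,
  not point-spread functions.

With those choices, resampling the UWF ground-truth map through the
true-pose displacement field reproduces each WF ground-truth map at
Dice 0.91-0.93; that ceiling is what "perfect" looks like under
bilinear resampling at this scale.

What the phantom does *not* emulate: pathology, media opacity, vessel
pulsation or acquisition-to-acquisition deformation, eye-shape
deviation from a perfect sphere, and the real devices' optical PSFs.
Passing phantom tests therefore demonstrates the geometry, the
estimators and the pipeline plumbing -- not segmentation robustness on
diseased clinical images.

## Numerical choices and degenerate inputs

* Soft Dice with a vanishing denominator (both maps empty in the scored
  region) is defined as 0 with a warning -- no vessels, no demonstrated
  overlap.
* WLS designs are solved by QR on normalized coordinates; rank below 6
  (source points on a conic or line) is a named error, as is any match
  set smaller than 6.
* Rays to the retina always take the far sphere intersection; pixels
  whose retina point falls within $10^{-6}$ of the stereographic pole
  are marked invalid rather than projected to infinity.
* Bilinear sampling is zero-padded: anything outside the source raster
  contributes 0, so a fully out-of-frame warp yields an all-zero image
  rather than an error.
* Gaussian blurring uses direct separable convolution with mirrored
  borders (an FFT implementation would wrap content circularly, which
  corrupts mask feathering at frame edges).
* IRLS asserts its own monotonicity: the robust objective is
  non-increasing across reweighting iterations and the per-iteration
  trace is returned.

## Benchmark scales and observed behaviour

The standard benchmark registers all nine fields of the seed-1 phantom
three ways (RANSAC-SC 2D, IRLS 2D, IRLS + distortion correction) and
scores UWF-frame Dice over each warped footprint; the test suite and
`scripts/acceptance.R` recompute it from scratch (roughly five minutes
on one CPU at the 512/256 scale; pose search costs a few hundred
objective evaluations per field). On this benchmark the 2D-only
methods plateau around Dice 0.78-0.83 -- close to the measured ceiling
of *any* quadratic 2D warp under ground-truth correspondences
(~0.82) -- while distortion correction reaches ~0.95 with pose errors
of a fraction of a degree, which is the package's core claim in
miniature: the residual that blocks 2D registration is geometric, and
a 5-parameter eye model removes it.

## Known limitations

* The classical vessel filter and corner descriptor are stand-ins for
  the trained networks of the AI pipeline; on real multimodal pairs a
  learned segmenter will matter far more than it does on phantoms. The
  interfaces accept precomputed maps and keypoints for exactly that
  reason.
* The pose search is derivative-free and local beyond its grid stage;
  a field whose true steering exceeds the grid span needs a wider
  `grid_steps`.
* The eye is a perfect sphere of radius 1; axial-length variation and
  aspheric shapes are absorbed, imperfectly, by the final 2D polish.
* Soft Dice at desk-scale rasters has a resolution-bound ceiling
  (~0.93); absolute Dice values are comparable within a raster scale,
  not across scales.
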