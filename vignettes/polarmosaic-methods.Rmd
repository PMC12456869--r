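---
title: "Reconstructing and co-registering wide-field Mueller polarimetry maps: methods"
author: "polarmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and co-registering wide-field Mueller polarimetry maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wide-field imaging Mueller polarimeters built for intraoperative use see a
field of view of a few centimetres, while a formalin-fixed whole-brain
section (WBS) is several times larger (a 2.5 x 2.1 cm field covers 5.25 cm²;
a 10 x 7 cm section needs on the order of 13 fields).  The section is
therefore raster-scanned as overlapping tiles (~15% nominal overlap, with
small rigid repositioning errors between acquisitions), and the per-tile
Mueller matrices must be decomposed, aligned to a common reference
photograph, and blended into seamless whole-section parameter maps.
Histological ground truth arrives as a second, harder alignment problem:
the section is physically cut into cassette-sized pieces before staining,
so the histological label tiles are disjoint, individually deformed
(rigidly, from slide placement, plus smooth elastic distortion from tissue
processing), and separated by lost tissue at every cut line.

`polarmosaic` implements this reconstruction and validation pipeline
end-to-end, together with a synthetic phantom generator that provides exact
ground-truth deformations, so every stage is tested quantitatively without
access to any particular instrument's data.

## Polarimetric decomposition

Each pixel's 4 x 4 Mueller matrix is factored with the polar decomposition
`M = M_Delta . M_R . M_D` (depolarizer, retarder, diattenuator):

* diattenuation `D = |(m01, m02, m03)| / m00`, with
  `M_D = [[1, d'], [d, mD]]`, `mD = sqrt(1 - D^2) I + (1 - sqrt(1 - D^2)) d d'`;
* `M' = M M_D^{-1}`; the depolarizer submatrix is the signed symmetric
  square root `m_Delta = ± (m' m'^T)^{1/2}` (sign of `det m'`), giving
  depolarization `Delta = 1 - |tr m_Delta| / 3`;
* the retarder is `m_R = m_Delta^{-1} m'`; total retardance comes from
  `acos((tr m_R - 1) / 2)`, linear retardance from
  `acos(sqrt((m_R[1,1] + m_R[2,2])^2 + (m_R[2,1] - m_R[1,2])^2) - 1)`, and
  the fast-axis azimuth from
  `theta = 0.5 atan2(m_R[3,1] - m_R[1,3], m_R[2,3] - m_R[3,2])`,
  reported in `[0, 180)` (orientation, not direction).

Numerical choices: matrices are normalized by `m00` first, so all outputs
except intensity are invariant under exposure scaling; `acos` arguments are
clipped with a `1e-9` tolerance rather than erroring, so single marginal
pixels do not abort a whole-image decomposition; genuinely degenerate
pixels (non-positive `m00`, `D >= 1`, singular depolarizer) are flagged,
excluded from the validity mask, and set to `NA`.  Parameter recovery on
`depolarizer(a) %*% retarder(theta, delta)` constructions is exact to
better than `1e-12` over the full `(theta, delta, a)` grid — the forward
constructors are the test oracle.

Two visualization products follow the standard display conventions for
fiber orientation: a quiver grid that averages azimuth in 25 x 25-pixel
blocks using doubled-angle vector summation, masking blocks whose mean
depolarization falls below 0.88 (which suppresses gray matter), and an
azimuth local-variability map.  No standard formula exists for the latter,
so the package defines it as the circular variance of doubled angles in a
square window, `1 - |mean(cos 2 theta, sin 2 theta)|`: 0 when the window's
orientations agree, 1 on complete cancellation.  This is the natural
dispersion statistic for a 180-degree-periodic quantity; the window
defaults to 25 px to mirror the quiver block, and the variability map is
not depolarization-masked by default (the mask is a display choice, exposed
as a flag).

## Tile blending

Aligned tiles are blended with a sigmoid distance weight.  For a pixel at
border distance `d_border` inside a tile (Euclidean distance transform of
the tile's validity footprint — "no signal" means outside the warped
footprint, never a dark tissue pixel),

```
w   = 1 - (d_max - d_border) / d_max      (clamped to [0, 1])
sig(x) = 1 / (1 + exp(-(2 x - 1) / 0.2))
f   = (sig(w) - sig(0)) / (sig(1) - sig(0))
```

so `f(0) = 0`, `f(d_max) = 1`, and `f(d_max / 2) = 0.5` by symmetry.
`d_max` sets the seam gradient length and defaults to 15% of the tile's
shorter side, matching the nominal overlap scale.  The default mosaic is
the *normalized* weighted mean `sum(f_t p_t) / sum(f_t)`, which preserves
constant fields in overlaps; the literal unnormalized sum is retained as
`mode = "as_printed"` for fidelity experiments (it inflates values wherever
tiles overlap).  Pixels covered only by zero-weight border pixels would be
0/0 under either formula; they fall back to the unweighted mean so coverage
has no pinholes.  Azimuth channels are blended on doubled-angle unit
vectors and re-extracted with `0.5 atan2`; a pixel whose contributions
cancel has no defined orientation and is masked rather than invented.

## Keypoint matching and its evaluation

The shipped matcher is the classic pipeline: difference-of-Gaussians
scale-space extrema (3 scales per octave, up to 4 octaves), quadratic
subpixel/subscale refinement, contrast and edge-curvature rejection,
dominant gradient orientation, and a 4 x 4 x 8 orientation-normalized
gradient-histogram descriptor (unit norm, 0.2 clipping).  Matching is
mutual nearest neighbour in descriptor space with Lowe's ratio test
(default 0.75) on the fixed-to-moving side; the result is one-to-one.  The
detector's default contrast threshold is 0.01 of the normalized intensity
range, chosen for adequate keypoint density on band-limited textures.
Learned matchers are deliberately out of scope; any external matcher that
returns the same match-table shape can be scored by the same evaluation
harness.

Evaluation maps each fixed keypoint through a ground-truth deformation and
measures the Euclidean distance to the predicted moving point:
`RMSE = sqrt(mean(d_i^2))`, and precision is the percentage of matches with
distance *strictly* below a threshold — 15 px for reference-photograph-scale
alignments, 5 px for histology-pair-scale, with good/moderate/outlier bands
at (15, 50) and (5, 10) respectively.  Fixed points outside the
ground-truth domain cannot be scored; they are excluded from the statistics
and reported separately (`dropped`), so the denominator choice is explicit
in every report.

## Landmark-constrained elastic warping

Matched keypoints (or manual landmarks) drive a thin-plate spline from
reference coordinates to tile coordinates, minimizing landmark error plus
`lambda` times the bending energy.  `lambda = 0` interpolates landmarks
exactly and reproduces any affine relationship to machine precision;
`lambda > 0` approximates, and the landmark residual is non-decreasing in
`lambda`.  This is a deliberate simplification of full bidirectional
consistency-energy registration: landmark constraints are the only input
the pipeline's matchers produce, so the image-similarity term of such tools
is out of scope, and the gap is stated rather than imitated.  A cubic
B-spline grid would serve equally here; the package ships the single TPS
backend and uses `grid_spacing` to control rasterization of the fitted
spline (exact at grid nodes, bilinear between — affine parts remain exact
at any spacing).  Fitted fields carry their spline model, so point mapping
through a fitted field is analytic, independent of the rasterization.

The canonical representation is the *backward* field (reference pixel to
moving-frame coordinates; 0-based, x = column, pixel centers at integers,
fixed project-wide).  Forward ground-truth constructions are inverted by
fixed-point iteration (tolerance 0.01 px, cap 50 iterations); diverged
border pixels are masked and their values removed so they cannot leak into
later bilinear lookups.  Field composition — evaluate the second field at
the first field's output — implements stain-to-stain transfer: once one
staining is aligned to the reference, a second staining aligned to the
first is carried into the reference frame by composition, and associativity
holds to interpolation tolerance.

Two robustness measures guard the automatic path from matches to warps:

* candidate reference keypoints are restricted to the tile's *nominal*
  placement (raster grid position, or cassette cell for fragments) plus a
  margin.  This is acquisition metadata, not ground truth: a keypoint far
  from where the protocol put the tile cannot correspond to it, and on
  self-similar texture such impossible matches otherwise pass the ratio and
  mutual checks;
* leave-one-out spline consistency trimming: each landmark is predicted by
  the TPS fitted to all the others; landmarks whose prediction error
  exceeds `max(1.5 px, 4 x median)` are inconsistent with *any* smooth
  deformation and are removed (at most two rounds).  No global rigid or
  affine consensus model is ever estimated.

## Label reconstruction and validation

Label tiles are categorical, so they are warped by nearest-neighbour
resampling only.  Gaps left by tissue lost at cut lines are filled by
nearest-labeled-pixel assignment (Euclidean, per-class distance
transforms), restricted to gaps no deeper than `max_gap` (default twice the
cut width); ties go to white matter, and a morphological closing on the WM
class — applied only to filled pixels — reconnects WM bands severed by
cuts.  Originally labeled pixels are never altered; unfillable gaps are
reported, not silently painted.

The GM/WM border is extracted single-sidedly — WM pixels 4-adjacent to a GM
pixel — so a straight border is exactly 1 px wide before dilation
(8-connectivity would thicken diagonals; the WM side is an arbitrary but
fixed convention).  The validation protocol dilates the border with an
11 x 11 full-square kernel five times, then 5 x 5 once: each pass with an
odd `k x k` square adds `(k - 1)/2` px per side, so the band is exactly
`1 + 2*(5*5) + 2*2 = 55` px wide, i.e. 1.595 mm at the 0.029 mm/px
reference pitch — the width of the uncertainty region the protocol is
designed to represent.  Agreement between two border bands is the dice
score `2|X n Y| / (|X| + |Y|)`; two empty masks are a 0/0 case and return
`NaN` with a warning rather than a reassuring number.  The pixel pitch is
always an explicit input (reported pitches for such setups vary between
~27 and 29 µm/px depending on how they are derived, so nothing is
inferred).  Landmark validation is the same RMSE harness applied to
corresponding point sets, with mm conversion.

In the end-to-end pipeline, border dice is computed on labels clipped to
the tissue interior (a 7 x 7 erosion of the silhouette, applied to truth
and reconstruction alike): within a ~2-px rim of the tissue/background
edge, blended parameter values are resampling mixtures with background
signal and carry no information about the GM/WM border, while any spurious
rim classification would contribute a whole 55-px dilated band.  This
mirrors validating against borders drawn inside the tissue.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a brain-section-like scene: a perturbed-ellipse
tissue silhouette on a dark background (the no-signal region the blending
weights need), split into connected gray- and white-matter regions by a
thresholded smooth random field, with a reference image of class-dependent
brightness plus band-limited texture (Gaussian-smoothed noise at
`texture_scale`, default 16 px, which gives blob detectors something to
find).  Ground-truth parameter fields are smooth within class:
depolarization in [0.92, 0.98] for WM and [0.80, 0.87] for GM — so the 0.88
masking rule separates the classes by construction, as it does in tissue,
where strongly scattering GM depolarizes more — retardance elevated in WM
(25–60 degrees vs 2–12), azimuth a smooth orientation field.  The Mueller
field is the exact forward model
`intensity * depolarizer(1 - Delta) * retarder(theta, delta)`, so
decomposition must recover the parameter maps; the forward constructors and
the decomposition are implemented and tested as independent routes.

Polarimetric tiles resample the scene under small random rigid
perturbations on a raster grid with 15% default overlap, plus per-tile
photometric gain/offset jitter (±10% gain) so that matching across tiles is
not trivially photometric.  Histology fragments are disjoint by
construction (each fragment's reference-frame footprint is its cassette
cell minus half the cut gap on internal edges) and deformed by rigid +
smooth elastic displacement; elastic fields are per-axis Gaussian-smoothed
noise, max-normalized to the requested amplitude, with amplitude required
to stay below half the correlation length so the map cannot fold (the
Jacobian stays positive, and tests check it).  Every tile and fragment
carries its exact backward ground-truth field.  The magnitudes of the
rigid/elastic fragment deformations are not prescribed by any protocol;
the defaults (4 px, 2 degrees rigid; 2 px elastic at 64 px correlation)
are plausible stand-ins and are exposed in the configuration.

What the phantom does *not* emulate: cellular-resolution histology texture
or staining appearance, cross-modal contrast inversions between staining
and photography, specular artifacts, or out-of-plane tissue loss between
sectioning planes.  Passing the phantom pipeline therefore demonstrates
that the geometry of the method — detection, matching, trimming, spline
fitting, blending, gap filling, border scoring — is correct and accurate
under known deformations; it does not certify matcher performance on real
cross-modal image pairs, which is known to be far harder and is the reason
the matcher interface is pluggable.

## Problem sizes and reproducibility

The default end-to-end configuration is a 512 x 512 scene, a 3 x 3 tile
raster at 15% overlap with 3-px translation and 1-degree rotation jitter,
and a 2 x 2 cassette grid with 6-px cut gaps — sizes chosen so the full
pipeline (two keypoint detections per tile, TPS fits, blending, label
reconstruction, dice) runs in well under a minute on one CPU while still
exercising every seam and gap code path.  All randomness flows from the
single configuration seed; two runs with the same configuration are
bit-identical.  `scripts/acceptance.R` re-runs the whole computation from
scratch and writes the headline numbers (border-band width in px and mm,
field-of-view coverage, decomposition recovery error, blend-weight anchors,
match precision/RMSE, mosaic landmark RMSE, and both border dice scores) as
JSON; the README shows a worked example with the numbers it printed.

## Known limitations

* The elastic model is landmark-only TPS; image-intensity registration
  energies are out of scope, so alignment quality is bounded by match
  density and distribution.
* Lu-Chipman factor ordering is fixed to depolarizer–retarder–diattenuator;
  other orderings (and hence other depolarization conventions) are not
  provided.
* Blending assumes photometrically consistent tiles up to the gain jitter
  the phantom models; there is no vignetting or exposure correction and no
  multi-band blending.
* Mosaics are computed in full frames at these problem sizes; arbitrarily
  large sections would need the subregion-tiling path of the CLI config
  rather than more memory.
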