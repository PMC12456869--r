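# polarmosaic

Whole-section reconstruction and histology co-registration for wide-field
imaging Mueller polarimetry.

Intraoperative Mueller polarimeters image a field of a few centimetres
(2.5 × 2.1 cm ≈ 5.25 cm²), while a formalin-fixed whole-brain section is
several times larger (10 × 7 cm needs ~13 fields).  The section is
raster-scanned as overlapping Mueller-matrix tiles that must be decomposed
into tissue parameter maps, aligned to a reference photograph, and blended
seamlessly; histological ground truth arrives as physically disjoint,
individually deformed label fragments that must be aligned to the same
reference and validated.  `polarmosaic` is the full pipeline for people
building such datasets — polarimetry groups assembling co-registered
polarimetric/histological sections for segmentation-model training and
validation — plus a synthetic phantom with exact ground-truth deformations
so every stage is testable without instrument data.

The core pieces, in the field's standard notation:

* **Lu-Chipman polar decomposition** `M = M_Δ·M_R·M_D` per pixel:
  depolarization `Δ = 1 − |tr m_Δ|/3`, linear retardance
  `δ = cos⁻¹(√((m_R22+m_R33)² + (m_R32−m_R23)²) − 1)`, fast-axis azimuth
  `θ = ½ atan2(...) ∈ [0°, 180°)`, diattenuation `D = |(m01,m02,m03)|/m00`;
  plus the masked 25-px quiver display (blocks with mean `Δ < 0.88`
  suppressed) and a doubled-angle circular-variance azimuth variability map.
* **Sigmoid distance-weighted blending**: tile weight
  `f = (sig(w) − sig(0))/(sig(1) − sig(0))` with
  `w = 1 − (d_max − d_border)/d_max`, `sig(x) = 1/(1+e^{−(2x−1)/0.2})`;
  normalized weighted mean by default, orientation channels blended on
  doubled-angle vectors.
* **Classic keypoint matching + evaluation**: difference-of-Gaussians
  detector, 4×4×8 gradient descriptors, mutual-nearest-neighbour matching
  with Lowe's ratio test, and an evaluation harness computing
  `RMSE = √(mean dᵢ²)` and precision (% of matches with `d` strictly below
  15 px at photograph scale, 5 px at histology scale) against a
  ground-truth deformation.
* **Landmark thin-plate-spline warping** (exact at `λ = 0`, bending-energy
  regularized otherwise), dense backward deformation fields, numerical
  inversion, and field composition for stain-to-stain transfer.
* **Label reconstruction**: nearest-neighbour label warping, nearest-label
  gap filling with WM reconnection, single-sided GM/WM border extraction,
  the 11×11×5 + 5×5×1 dilation protocol (1-px line → exactly 55 px ≈
  1.595 mm at 0.029 mm/px), and dice validation `2|X∩Y|/(|X|+|Y|)`.

## Worked example

```r
library(polarmosaic)

# a brain-section-like phantom with known polarimetric ground truth
scene <- generate_phantom(256, 256, seed = 1)

# per-pixel polar decomposition of its Mueller field
maps <- decompose_image(scene$mueller)
q <- quiver_downsample(maps$azimuth, maps$depolarization,
                       block = 25, threshold = 0.88)
sum(!q$masked)           # 25 of 121 blocks kept: only white matter passes
                         # the 0.88 depolarization mask
autoplot(q)              # masked fiber-orientation quiver

# a deformed copy with exact ground truth, matched and scored
pair <- make_pair(scene$reference_image, rigid = c(5, -3, 2), seed = 2)
m  <- match_mnn(detect_keypoints(scene$reference_image),
                detect_keypoints(pair$moving))
evaluate_matches(m, pair$gt, threshold = 15, pixel_pitch = 0.029)
#> <match_evaluation> n = 113 (dropped 0)
#>   RMSE 0.438 px (0.013 mm) | precision 100.00% at < 15 px
#>   bands: good 113, moderate 0, outlier 0
```

113 keypoint matches survive the ratio and mutual checks; every one lands
within 15 px of where the known deformation says it should (100%
precision), with sub-pixel aggregate error (0.44 px RMSE, 13 µm at the
reference pitch).  `tidy()`/`glance()` return the same results as tibbles,
and `autoplot()` draws the banded distance histogram.

The full pipeline — tiles, matching, TPS warps, blending, label
reconstruction, border dice — is one call:

```r
res <- run_phantom_pipeline(default_config(seed = 1))
res
#> <phantom_pipeline_result>
#>   tiles aligned: 9, warp RMSE 0.26 px (max 0.47)
#>   border dice: polarimetric 0.997, histology 0.995
```

A command-line wrapper with `simulate`, `decompose`, `mosaic`, `match`,
`eval-match`, `warp`, `labels`, `validate` and `pipeline` subcommands is
installed at `inst/cli/polarmosaic`.

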