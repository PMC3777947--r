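---
title: "Methods: kite photogrammetry and multispectral mapping of intertidal shores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kite photogrammetry and multispectral mapping of intertidal shores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Intertidal rocky shores vary ecologically at scales from centimetres to
hundreds of metres, far below the resolution of satellite or manned-aircraft
remote sensing.  A low-cost alternative is to fly two consumer cameras — one
standard colour body and one converted to near-infrared (NIR, > 720 nm) — from
a kite at 10–20 m altitude, collect hundreds of overlapping near-nadir
photographs, and reconstruct the shore photogrammetrically.  `shoremapper`
implements the post-acquisition half of that workflow: from overlapping
colour and NIR images plus a handful of ground control points it produces a
geo-referenced 3D terrain model, colour/NIR orthomosaics, elevation, slope
and aspect rasters, and a white-balanced NDVI map, together with a synthetic
survey generator that makes the whole chain testable at desk scale without
field data.

# Pipeline overview

1. **Feature extraction and matching** (`extract_features`, `match_pair`,
   `filter_epipolar`, `build_tracks`).  Local invariant features are detected
   in every image and matched across *all* image pairs, including colour↔NIR;
   epipolar geometry rejects false matches; surviving matches are chained
   into multi-image tracks.
2. **Incremental structure-from-motion** (`run_incremental_sfm`).  A seed
   pair with good parallax initialises the reconstruction; remaining views
   are added by robust perspective-n-point; bundle adjustment refines all
   poses, 3D points and the shared intrinsics of each camera body
   (self-calibration).  The result is metrically self-consistent but has
   arbitrary scale, orientation and position.
3. **Densification** (`densify`).  Epipolar ZNCC search on a 5-pixel grid
   produces a dense cloud at roughly one point per 5×5-pixel patch.
4. **Geo-registration** (`estimate_scale`, `horn_align`, `georegister`,
   `adjust_vertical_datum`).  Tape-measured 2 m GCP triangle edges fix the
   absolute scale; Horn's closed-form absolute orientation places the scaled
   model at the GPS coordinates; a waterline contour pins the vertical datum.
5. **Terrain and products** (`triangulate_surface`, `rasterize_terrain`,
   `select_views`, `render_orthomosaic`, `compute_ndvi`,
   `patch_statistics`).  A 2.5D Delaunay surface carries elevation, slope and
   aspect; each face is textured from its four nearest views per band;
   orthographic re-rendering yields the mosaics and the NDVI layer.

# Models and conventions

**Camera model.**  Pinhole with focal length and principal point in pixels
and a two-parameter even radial distortion acting on normalised coordinates,
`x_d = x (1 + k1 r² + k2 r⁴)`.  Pixel origin is the centre of the top-left
pixel, x rightward, y downward, 0-based.  One intrinsics block is shared per
camera body (colour, NIR): exposures and lenses were fixed per camera during
a survey, and per-image intrinsics would be badly under-constrained.  The
principal point is held at the image centre during bundle adjustment; focal
length and both distortion terms are refined.

**Poses.**  World-to-camera: `X_c = R (X − C)` with `R` proper orthonormal
and `C` the camera centre.  The world frame is a local east-north-up (ENU)
tangent plane anchored at a configurable geodetic origin; conversion uses
the WGS84 meridian and prime-vertical radii at the origin latitude.
Handheld-GPS-grade inputs make the ellipsoid/geoid distinction immaterial,
so altitudes are treated as relative heights.

**Terrain.**  The surface is a plan-view (2.5D) Delaunay triangulation with
vertex elevations lifted — appropriate for a shore platform imaged from
above; overhangs are out of scope.  Per-face slope is `arccos(−n_D)` and
aspect `atan2(n_E, n_N)` mapped to [0°, 360°), clockwise from north, from
the upward unit normal written in north-east-down components; horizontal
faces have undefined aspect and are flagged.

**NDVI.**  `NDVI = (g_nir·NIR − g_red·R)/(g_nir·NIR + g_red·R)` per mosaic
cell.  The white-balance gains `g_c = (t_white_c / t_survey_c) / W_c` come
from photographs of a Spectralon diffuse white standard (channel mean `W_c`)
and the exposure-time ratio between the cameras.  The defining property —
and the unit test — is that a spectrally flat surface maps to NDVI 0.  NDVI
is computed on the orthomosaic grid (not per-face texels) so both bands
share one geometry, and is invariant to any common positive rescaling of
the gains.

# Key algorithmic choices

**Features.**  Harris corners on a σ = 1.2 smoothed image with non-max
suppression (radius 3), subpixel quadratic refinement, and upright
SIFT-style descriptors (4×4 spatial cells × 8 orientation bins,
Gaussian-weighted, L2-normalised, clipped at 0.2, renormalised).  A
fixed-altitude near-nadir survey needs translation repeatability and
contrast invariance, not full scale/rotation invariance; descriptor
normalisation is also what makes colour↔NIR matching work, since within a
coverage class the two bands differ mainly by a multiplicative factor.
Matching uses mutual nearest neighbours with Lowe's ratio test (default
0.8) applied from both sides, making the operation symmetric.

**Epipolar filtering.**  RANSAC (confidence 0.999, adaptive iteration
count, fixed seed) over the Hartley-normalised eight-point estimate;
inliers by Sampson distance (default 2 px); final F re-estimated on all
inliers.  None of these constants is dictated by the physics of the
problem; the defaults are this package's stated choices and are echoed
into every run manifest.

**Perspective-n-point.**  The classic minimal DLT solver is degenerate on
near-planar scenes, and a shore platform seen from 15 m is very nearly
planar.  Registration therefore runs RANSAC whose hypothesis step is a
Gauss-Newton pose fit to a small random sample, seeded from the
already-registered camera sharing the most tracks — on an incremental
survey that camera is always a close spatial neighbour, so the seed is in
the convergence basin.  Inliers are counted by reprojection error and the
pose is re-fit on all inliers under a Huber loss.

**Bundle adjustment.**  Levenberg-Marquardt with analytic Jacobians, Huber
loss at 2 px, and a Schur complement on the point blocks; the gauge is
fixed by holding the first registered camera constant (the remaining scale
gauge is handled by LM damping).  Accepted steps never increase the
objective; pruning removes points with mean reprojection error above 4 px,
triangulation angle below 2°, or non-positive depth.

**Densification.**  Deliberately a simplified two-view scheme rather than
full patch-expansion multi-view stereo: for each reference view on a
5-pixel grid, the epipolar segment spanning the sparse-depth range in a
same-band partner view (baseline/depth between 0.04 and 0.6, most shared
tracks) is scanned at 0.75 px steps with 7×7 zero-mean normalised
cross-correlation; the peak is refined parabolic-subpixel and must exceed
0.85 and be unique (no separated secondary peak within 0.03).  This reaches
the intended density regime of about one 3D point per 5×5-pixel patch on
textured scenes and keeps the desk-scale runtime in minutes.

**Geo-registration.**  Two deliberately separate stages, not a joint
7-parameter fit: scale comes only from the tape-measured triad edges (mean
of measured/reconstructed edge ratios), then Horn's quaternion solution
estimates rotation and translation with the scale frozen.  GPS error
therefore perturbs where the map sits (global accuracy) but never how large
it is (local accuracy) — the central accuracy argument of the kite
workflow, and a property the tests assert by Monte-Carlo.  The waterline
datum shift is applied after Horn alignment as a final rigid vertical
correction.

**Texturing.**  Per face and band, candidate views must project the face
centre inside the image, be on the upper side of the face, and pass a
z-buffer occlusion test; the four nearest cameras win (ties broken by image
id), with blend weights 4:3:2:1 normalised over however many views were
assigned.  The cited band-limited multi-band blending of the original
pipeline is simplified to this single-band weighted average; a fidelity
reduction documented here, acceptable because the defining convexity and
"blending creates no structure" properties are tested.

# The synthetic survey generator

`generate_scene` builds a heightfield from octaves of band-limited value
noise on a cross-shore ramp (seaward edge below the tidal datum), with
carved rock-pool depressions; coverage classes (dry/wet rock, sand, green/
brown/red macroalgae, cunjevoi) form contiguous patches driven by smooth
random fields with elevation preferences, and every cell below the water
datum is water by construction.  Class reflectance spectra are smooth
analytic curves with the chlorophyll red edge for the algae and sub-percent
NIR reflectance for water.  `plan_flight` walks a serpentine track at 15 m
with pose jitter bounded at 5° — both a realistic kite-motion model and the
perspective diversity self-calibration needs.  `render_views` integrates
class reflectance against the four channel response curves (Gaussians
peaking at 606/530/470 nm and 740 nm for the converted body), multiplies by
a procedural speckle field shared across bands, and adds optional Gaussian
noise.  The speckle octaves are 0.12–0.6 m: texture must be band-limited
relative to the ~3 cm ground sampling distance of the synthetic survey or
it would alias between views and break matching (real rock texture at 5 mm
pixels plays the same role in the field).

What the generator does *not* emulate: shadows and sun glint, moving water,
blur from wind gusts, vignetting, BRDF effects, and real macroalgal
spectral variability.  Passing tests therefore demonstrate the correctness
of the geometry and radiometry chain, not robustness to every field
nuisance; the manual image-culling step of a real survey is replaced by an
exclusion list.

Default survey conditions (the study conditions of the test suite): a
60 × 25 m shore, 24 colour + 20 NIR views at 640 × 480 with ~0.85
along-track overlap in two rows, focal 436 px (≈22 × 16.5 m footprint at
15 m), distortion k1 = −0.08, k2 = 0.01, exposure ratio NIR/colour 2.2,
three GCP triads of 2 m tape-measured edge, handheld-GPS noise σ = 1.2 m
per horizontal axis (1.5× vertically), tidal datum 0.16 m, noise-free
rendering.  `scale` shrinks the survey extent and view count — not the
image geometry — so reduced-scale runs exercise the same imaging regime.

# Numerical choices and degenerate inputs

* Distortion inversion by fixed point (6–8 iterations); ray/heightfield
  intersection by fixed-point depth iteration (14 iterations), valid for
  descending rays over bounded-slope terrain.
* Triangulation is the midpoint (ray least-squares) method; points behind
  any camera, below 2° triangulation angle, or above the reprojection gate
  are rejected.
* The GCP tape fixes the *3D* panel separation, so synthetic triads are
  equilateral in the local terrain tangent plane (exact 3D edge length);
  draping error appears only as panel-to-ground offset on curved terrain.
* Terrain outlier filter: points deviating more than 0.2 m from their
  0.25 m-cell median elevation, or in cells with fewer than 3 points, are
  dropped before triangulation; faces with plan edges above 10× the median
  edge length (bridges across data gaps) are removed afterwards.
* Rasters use nodata −9999; NDVI guards its denominator at 1e-12.
* Every random element (RANSAC draws, scene noise, jitter) is governed by
  a single user seed; two runs with one seed are byte-identical.

# Validation frames

The demo survey reports GCP residuals with the simulated handheld GPS —
global error on the metre scale, edge-length error on the centimetre scale,
mirroring the field workflow's accuracy table.  Reconstruction-fidelity
metrics (median dense-point error, elevation-raster RMSE against the true
heightfield) are evaluated after geo-registering against the *true* GCP
coordinates, i.e. as if surveyed with an error-free instrument: GPS noise
by design moves the whole map rigidly, and leaving it in those metrics
would measure the noise, not the reconstruction.

# Problem sizes

The full demonstration survey (24 + 20 views at 640 × 480) reconstructs
roughly 15–20k sparse tracks and 400k+ dense points and completes in
about ten minutes on one core; the reduced `scale = 0.35` survey used for
the determinism checks runs in about a minute.  These sizes are the
package's chosen desk-scale study conditions.

# Known limitations

* Two-view ZNCC densification under-performs true multi-view stereo in
  repetitive or low-texture areas (standing water at full sun would be
  worse in the field).
* Self-calibration of focal length on near-planar terrain leans on the
  jitter-induced perspective diversity; a survey flown perfectly nadir over
  perfectly flat ground would leave focal and flying height entangled.
* The NIR camera contributes only its red Bayer channel, as in the
  converted-camera design the package models.
* Orthomosaic sampling is nearest-face; no seam-line optimisation or
  radiometric feathering beyond the ranked-weight blend.
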