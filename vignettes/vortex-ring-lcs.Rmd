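---
title: "Quantifying diastolic vortex rings with Lagrangian coherent structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diastolic vortex rings with Lagrangian coherent structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexlcs)
```

## The measurement problem

During early diastole, blood entering the left ventricle (LV) through the
mitral valve rolls up into a ring vortex. The ring's outer boundary is a
*material* surface: blood that arrived with the inflow stays on one side,
blood that resided in the chamber after the previous ejection stays on the
other, and no trajectory crosses it. Delineating that boundary over the
filling phase, and relating its volume and position to the moving
endocardium, yields measures of vortex–wall interaction: the vortex volume
fraction VV% (vortex volume over LV volume at the same timeframe), the
sphere-equivalent wall distance, the ratio of the largest vortex
cross-sectional diameter to the effective mitral diameter, and the vortex
formation ratio (VFR = L/D).

The boundary is found with backward-time finite-time Lyapunov exponent
(FTLE) fields. Particles seeded on an imaging plane at a timeframe `t` are
advected backwards through the time-resolved velocity field to the onset of
vortex formation, giving the flow map `Φ`. Its in-plane gradient `G`
(central differences over neighboring seeds, one-sided at plane edges)
forms the Cauchy–Green tensor `C = GᵀG`, and

    FTLE = ln( sqrt( λ_max(C) ) ) / |T|,   units 1/s,

with `|T|` the integration span. Attracting material surfaces — the vortex
boundary among them — appear as ridges of the backward FTLE field.

## Pipeline and parameters

The stages mirror a 4D phase-contrast MRI post-processing chain:

1. **I/O and validation** (`read_velocity_field`, `read_contours`).
   Velocities are converted to cm/s at the boundary; internally positions
   are mm and times ms throughout (1 cm/s = 0.01 mm/ms), so the integrator
   never rescales.
2. **Phase background correction** (`correct_background_phase`). A
   first-order polynomial in world coordinates is fit per timeframe and
   component to stationary-tissue voxels by least squares and subtracted
   everywhere. The design matrix is centered on the volume centroid purely
   for conditioning; the subtracted plane is identical either way. The fit
   needs at least 10 non-collinear mask voxels.
3. **Velocity unwrapping** (`unwrap_velocity`). Values differing from a
   local reference by more than VENC are shifted by ±2·VENC. The reference
   is first temporal (each frame against the already-corrected previous
   frame — aliased jets build up from rest over the cycle, so the first
   frame anchors the recursion) and then spatial (median of the 6 face
   neighbors). A shift is only applied against the stored sign, because a
   single-wrapped value always has the opposite sign of its true value;
   this keeps genuine fast transients untouched. Residual ambiguity is the
   user's call via the declarative `manual_overrides` table, which stands
   in for the interactive step of semiautomatic unwrapping and is frozen
   against the automatic passes.
4. **Advection and FTLE** (`seed_grid`, `advect_backward`, `compute_ftle`).
   Classic RK4, integrated backwards with a 5 ms step (the final partial
   step lands exactly on the origin time); space–time sampling is trilinear
   in space and linear in time, which realizes "linear upsampling" exactly
   without materializing upsampled volumes. Seeds default to 0.8 mm
   spacing. Particles that leave the voxel-center hull freeze (velocity
   zero) and are flagged; flagged seeds and their stencil neighbors are
   excluded from everything downstream.
5. **LCS extraction** (`extract_lcs`). The FTLE field of each time phase is
   normalized to its 95th percentile (linear-interpolation percentile) and
   seeds above 50% of that value form the ridge mask. When one phase is
   seeded on a stack of short-axis planes, the percentile is pooled over
   the whole stack (`norm_value`), and `analyze_vortex_ring` restricts the
   normalization to seeds inside the endocardial contour: the percentile
   is then anchored to ventricular flow rather than to the static
   surroundings, which matters early in diastole when the young ring
   occupies a small fraction of the chamber.
6. **Delineation** (`delineate_vortex`). Ridge-mask components smaller than
   `min_component` seeds are discarded; the remaining points are binned by
   angle about their centroid (72 bins of 5°); per bin the outermost
   contiguous radial band collapses to its FTLE maximizer, refined to
   sub-grid precision by a parabolic fit through the maximizer's radial
   neighbors; empty bins are closed with straight segments — the
   straight-line closure of blind-ended ridges — and the bridge count is
   reported. A contour must cover at least a quarter of the angular bins
   (`min_coverage`): scattered specks spanning a few degrees of arc cannot
   define a ring. Polygons under `area_floor` (50 mm², about an 8 mm circle)
   are dropped.
7. **Cropping and volumetrics** (`crop_to_endocardium`,
   `slice_summation_volume`). LCS polygons are clipped to the endocardial
   polygon (Sutherland–Hodgman; endocardial cross-sections are convex);
   volumes are per-slice enclosed area times slice thickness, summed over
   the stack, with overlapping polygons in one slice unioned rather than
   double-counted.
8. **Metrics and statistics** (`vortex_wall_distance`,
   `mitral_effective_diameter`, `vortex_formation_ratio`,
   `rank_sum_test`, `linear_correlation`, `correlation_battery`,
   `bonferroni_threshold`).

Key defaults, all overridable in the pipeline config: seed spacing 0.8 mm;
RK4 step 5 ms; normalization percentile 0.95 with threshold fraction 0.5;
flow-profile speed threshold 10 cm/s (separates the transmitral jet from
background at typical 4D-flow noise levels); alpha 0.05 over a 32-analysis
battery. The integration origin ("beginning of vortex ring formation") is
the first timeframe at which the transmitral flow-rate magnitude exceeds 5%
of its diastolic peak (`detect_e_wave_onset`), overridable.

## The synthetic chamber and what it does (not) emulate

No imaging data ship with the package; `synthetic_ventricle()` generates
the test substrate with exact ground truth:

* a deforming ellipsoidal cavity (transverse-to-long axis ratio 0.65) whose
  volume integrates a biphasic raised-cosine E/A inflow curve — defaults:
  end-diastolic volume 195 ml, end-systolic 72 ml, cycle 1000 ms, 40
  reconstructed timephases, 3 mm isotropic voxels, 8 mm slices, E-wave
  carrying 70% of the inflow;
* a pinned Hill-type recirculation cell whose spherical boundary grows with
  the cumulative inflow until it encloses a prescribed fraction of the
  chamber at end-diastole (53% by default). The interior is the classic
  spherical-vortex solution; a radial dilation matching the boundary growth
  rate (continued outside the sphere as a short-range `(a/r)^4` field
  tapered to zero at the wall) makes the sphere a material surface at every
  instant — exactly the object a backward-FTLE ridge marks;
* a plug jet through a disc orifice (27 mm effective diameter) in a slab
  above the base carrying the same flow curve, for the flow-profile,
  annulus-diameter and E-wave-onset measurements;
* optional Gaussian velocity noise and single VENC wraps
  (`inject_noise`, `inject_wraps`), both seeded and recorded.

The generator is kinematic, not a Navier–Stokes solution: ground truth must
be exact, and the pipeline under test is itself purely kinematic (it
advects whatever field it is given). Consequently the synthetic data do
not reproduce papillary-muscle deformation of the ring, trailing jets at
formation ratios beyond ~4, intravoxel dephasing, or the asymmetric,
wall-hugging rings of real ventricles. Passing the end-to-end recovery
test therefore demonstrates that the measurement chain is unbiased at
acquisition-like resolution on a flow whose boundary is known exactly — not
that segmentation-free delineation is reliable on clinical images, where
the original workflow kept a manual delineation step (which this package
supports by editing the intermediate contour CSVs between stages).

Analytic benchmark models ship alongside the chamber: `uniform`,
`solid_rotation` and `planar_strain` (closed-form flow maps and FTLE),
`double_gyre` (the standard unsteady LCS benchmark), and a translating
`hill_vortex` whose material sphere tests boundary recovery end to end.

## Numerical choices and degenerate inputs

* **Out-of-domain particles** freeze at zero velocity and are flagged;
  freezing avoids extrapolation artifacts and the flags propagate through
  the FTLE stencil, the normalization and the mask.
* **Percentile method**: linear-interpolation (type-7) percentile over the
  unflagged seeds of the time phase.
* **Ridge position**: the FTLE maximizer of the outermost band rather than
  the band centerline — threshold bands are asymmetric around a ridge
  whenever the outer flank decays at a different rate than the inner one,
  and the maximizer is the ridge definition used throughout the LCS
  literature. Sub-grid refinement uses the parabola through the maximizer
  and its radial neighbors, clamped to the neighbor interval.
* **Tie-breaks**: angular ordering proceeds counterclockwise from the
  negative x-axis; within a bin the outermost band wins; bridging connects
  angular neighbors, which realizes nearest-available-ridge closure
  deterministically.
* **Degenerate grids**: zero-extent planes seed a single particle; spacing
  larger than an extent degenerates to a single row with a warning; FTLE
  requires at least 3×3 seeds.
* **Empty results**: a non-positive normalization value yields an empty
  mask with a warning; un-closable ridges (below the angular coverage
  floor) yield an empty contour set with a warning; missing endocardial
  contours skip that slice/timeframe with a message.
* **Units**: the archive dialect stores cm/s; the NIfTI sidecar may declare
  `m/s` or `mm/s` and conversion happens only on read.

## Design decisions on genuinely open points

* The two on-disk dialects are NIfTI-per-component with a JSON sidecar, and
  a single-file RDS archive holding the 5-D array with its metadata; the
  archive round-trips bit-exactly and is the native interchange format
  between pipeline stages.
* Inputs are assumed spatially co-registered; a rigid offset can be applied
  by shifting `grid_origin`.
* FTLE gradients use the 2-D in-plane stencil on the seeding plane (the
  delineations live on long- and short-axis planes); volumetric 3-D ridge
  surfaces are out of scope.
* "Largest LCS diameter" uses per-slice equal-area-circle diameters, the
  same reduction as the mitral annulus measurement, and the diameter ratio
  is reported as the primary quantity (the area ratio is its square).
* Peak filling rate is the maximum central-difference derivative of the LV
  volume curve.
* The stationary-tissue mask is an input; `stationary_mask_from_sd` is a
  convenience thresholding helper, not part of the measurement definition.
* The rank-sum test switches from the exact distribution to the
  tie-corrected normal approximation above a combined n of 20 (typical
  group sizes sit in the approximation regime); the continuity correction
  is on by default and exposed.

## Problem sizes used in the shipped validation

The test-suite and `scripts/acceptance.R` run, among others: the double
gyre at `A = 0.1, ε = 0.25, ω = π/5` on a 100×50 seed grid over `|T| = 15`
against a brute-force re-advection oracle; a translating Hill vortex
(a = 25 mm, U = 30 cm/s) sampled at 3 mm and delineated from 0.8 mm seeds;
and the full synthetic ventricle at its acquisition-scale defaults (3 mm
voxels, 40 phases, 0.8 mm seeds, every diastolic frame), which completes in
a few minutes on one core. Unit tests use a compact chamber (120/50 ml,
20 phases) where acquisition scale is not the point.

## Known limitations

* Slice-wise delineation is least reliable where the boundary runs nearly
  parallel to the slice (the ring's caps): partial-volume blur there
  projects to several millimetres in-plane. The same caveat applies to any
  2-D cut of an irregular ring.
* The unwrapping recursion assumes the first frame is wrap-free and the
  aliased region builds up smoothly in time; fields aliased identically in
  every frame need manual overrides.
* Convex clipping is exact only for convex endocardial cross-sections;
  strongly concave chambers would need a general polygon clipper.
* The percentile normalization presumes the imaged phase contains a
  coherent structure; on structure-free data the optional `min_separation`
  coherence floor in `extract_lcs` suppresses noise ridges.
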