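# vortexlcs

Quantifies the diastolic vortex ring of the left ventricle from
time-resolved, three-component (4D flow) velocity fields, using Lagrangian
coherent structures (LCS). During early filling, transmitral inflow rolls
up into a ring vortex whose outer boundary is a material surface separating
inflow-origin blood from the residual blood of the previous beat. The
package finds that boundary as ridges of the backward-time finite-time
Lyapunov exponent field,

    FTLE = ln( sqrt( λ_max(GᵀG) ) ) / |T|,

where `G` is the in-plane gradient of the flow map obtained by seeding
particle grids (0.8 mm spacing) on the imaging planes and integrating them
backwards through the velocity field with fourth-order Runge–Kutta (5 ms
step) to the onset of vortex formation. Per time phase the FTLE field is
normalized to its 95th percentile and values above 50% of that are
extracted as LCS, closed with straight segments where ridges end blindly,
cropped to the endocardium, and converted to volumes by slice summation
(area × slice thickness). From these it derives the clinical vortex–wall
interaction metrics: the vortex volume fraction VV%, the sphere-equivalent
vortex-to-wall distance, effective mitral and vortex diameters and their
ratio, the vortex formation ratio (VFR = 4V/πD³), and transmitral flow
profiles — plus group statistics (Mann–Whitney–Wilcoxon, linear
correlation, Bonferroni-corrected batteries).

The intended audience is researchers post-processing cardiac 4D flow MRI
(or any gridded, time-resolved velocity data) who want a reproducible,
scriptable version of this analysis. Because acquisitions of this kind are
rarely shareable, the package also ships a first-class synthetic-flow
module — analytic benchmark flows (double gyre, Hill's spherical vortex,
solid rotation, planar strain) and a kinematic beating ventricle with an
embedded vortex whose boundary, volumes and flow curves are known exactly —
so the whole chain is testable without any download.

## Worked example

```r
library(vortexlcs)

# a compact synthetic chamber: 120 ml end-diastolic, 50 ml end-systolic,
# 20 timephases, vortex prescribed to fill 53% of the chamber at end-diastole
sv <- synthetic_ventricle(edv_ml = 120, esv_ml = 50, n_phases = 20L,
                          slice_thickness_mm = 10)

# transmitral flow profile and E-wave onset measured from the field itself
profile <- through_plane_flow_profile(sv$field, sv$truth$orifice$slice_z,
                                      sv$truth$orifice$roi)
t0 <- detect_e_wave_onset(profile)
t0
#> [1] 400

# backward FTLE -> LCS delineation -> cropping -> slice-summation volumes
res <- analyze_vortex_ring(sv$field, sv$truth$endo_contours,
                           t_origin = t0, slice_z = sv$truth$slice_z,
                           seed_spacing = 2)
tail(data.frame(time_ms = res$time_ms,
                vv_percent = round(res$vv_percent, 1),
                truth = round(sv$truth$vv_percent[res$frames], 1),
                wall_distance_mm = round(res$wall_distance_mm, 1)), 4)
#>    time_ms vv_percent truth wall_distance_mm
#> 8      800       43.8  45.0              6.9
#> 9      850       46.8  47.0              6.5
#> 10     900       50.4  50.9              6.2
#> 11     950       52.8  52.9              5.9

ann <- mitral_effective_diameter(sv$field, sv$truth$orifice$slice_z,
                                 sv$truth$orifice$roi)
round(ann$diameter_mm, 1)
#> [1] 27.3

vortex_formation_ratio(120 - 50, ann$diameter_mm)
#> [1] 4.38
```

The E-wave onset is detected at 400 ms; the recovered vortex fraction
climbs toward the prescribed 53% by end-diastole (52.8% measured vs 52.9%
ground truth at the last frame) while the sphere-equivalent wall distance
shrinks as the ring approaches the wall; the measured effective mitral
diameter (27.3 mm) matches the generator's 27 mm orifice to one voxel; and
a 70 ml diastolic inflow through that orifice corresponds to a vortex
formation ratio of 4.4 — just past the ~4 limit beyond which rings shed
trailing jets.

A YAML-driven end-to-end pipeline (synthesis → preprocessing → FTLE →
delineation → metrics, with a manifest and plain-file stage outputs that
can be hand-edited between stages) is available as `run_pipeline()` and as
a shell script in `inst/scripts/vortexlcs.R`.

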