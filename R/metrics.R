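# Vortex and chamber volumetrics, vortex-wall distance, valve and vortex
# diameters, transmitral flow profiles, and the vortex formation ratio.

#' Slice-summation volume of a contour set
#'
#' For each timeframe, sums over slices the enclosed polygon area multiplied
#' by the slice thickness. Overlapping polygons within one slice are unioned
#' (rasterization), not double-counted.
#'
#' @param contours a `contour_set`.
#' @param label which contours to measure (default all present).
#' @return named numeric vector, ml per timeframe (empty set: ml = 0 for no
#'   frames).
#' @export
slice_summation_volume <- function(contours, label = NULL) {
  stopifnot(inherits(contours, "contour_set"))
  thick <- attr(contours, "slice_thickness")
  polys <- contour_polygons(contours, label = label)
  if (length(polys) == 0) return(setNames(numeric(0), character(0)))
  tf <- vapply(polys, function(p) p$timeframe, numeric(1))
  out <- vapply(sort(unique(tf)), function(t) {
    pt <- polys[tf == t]
    sl <- vapply(pt, function(p) p$slice_index, numeric(1))
    vol <- 0
    for (s in unique(sl)) {
      ps <- pt[sl == s]
      if (length(ps) == 1) {
        a <- polygon_area(ps[[1]]$xy)
      } else {
        bb <- lapply(ps, function(p) apply(p$xy, 2, range))
        overlap <- FALSE
        for (i in seq_along(ps)) for (j in seq_along(ps)) {
          if (i < j &&
              bb[[i]][1, 1] <= bb[[j]][2, 1] && bb[[j]][1, 1] <= bb[[i]][2, 1] &&
              bb[[i]][1, 2] <= bb[[j]][2, 2] && bb[[j]][1, 2] <= bb[[i]][2, 2])
            overlap <- TRUE
        }
        if (overlap) {
          message("overlapping polygons in slice ", s, ", timeframe ", t,
                  ": areas unioned")
          a <- polygon_union_area(lapply(ps, function(p) p$xy))
        } else {
          a <- sum(vapply(ps, function(p) polygon_area(p$xy), numeric(1)))
        }
      }
      vol <- vol + a * thick
    }
    vol / 1000 # mm^3 -> ml
  }, numeric(1))
  setNames(out, sort(unique(tf)))
}

#' Sphere-equivalent vortex-wall distance
#'
#' Radius of the sphere with the LV's volume minus the radius of the sphere
#' with the vortex's volume: an orientation-free average distance between the
#' vortex boundary and the endocardium.
#'
#' @param lv_volume LV volume, ml (>= vortex volume).
#' @param vortex_volume vortex (LCS-enclosed) volume, ml (>= 0).
#' @return distance in mm.
#' @export
vortex_wall_distance <- function(lv_volume, vortex_volume) {
  if (any(vortex_volume < 0) || any(lv_volume < vortex_volume))
    stop("require lv_volume >= vortex_volume >= 0")
  r <- function(v_ml) (3 * v_ml * 1000 / (4 * pi))^(1 / 3) # ml -> mm^3 -> mm
  r(lv_volume) - r(vortex_volume)
}

#' Vortex volume as a percentage of LV volume
#'
#' @param vortex_volume vortex volume, ml.
#' @param lv_volume LV volume, ml (> 0).
#' @return VV% in percent.
#' @export
vortex_volume_fraction <- function(vortex_volume, lv_volume) {
  if (any(lv_volume <= 0)) stop("lv_volume must be positive")
  100 * vortex_volume / lv_volume
}

#' Through-plane flow profile over a region of interest
#'
#' Reconstructs the through-plane (z-component) velocity map of one
#' short-axis slice and integrates it over the ROI polygon: the signed flow
#' rate is the sum over ROI voxels of velocity times in-plane voxel area
#' (1 cm/s over 1 mm^2 = 0.01 ml/s). Also reports the peak through-plane
#' velocity within the ROI per timeframe.
#'
#' @param field a `velocity_field`.
#' @param slice_z slice position, mm (nearest voxel plane is used).
#' @param roi ROI polygon: a `contour_set` with label `"roi"` (first polygon
#'   used) or a two-column vertex matrix in mm.
#' @return data frame with `time_ms`, `flow_ml_s`, `peak_velocity_cm_s`.
#' @export
through_plane_flow_profile <- function(field, slice_z, roi) {
  validate_velocity_field(field)
  if (inherits(roi, "contour_set")) {
    rp <- contour_polygons(roi, label = "roi")
    if (length(rp) == 0) rp <- contour_polygons(roi)
    if (length(rp) == 0) stop("empty ROI")
    roi <- rp[[1]]$xy
  }
  zs <- axis_coords(field, 3)
  k <- which.min(abs(zs - slice_z))
  xs <- axis_coords(field, 1); ys <- axis_coords(field, 2)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- point_in_polygon(pts, roi)
  if (!any(inside)) stop("empty ROI: no voxel centers inside the polygon")
  pix <- field$spacing[1] * field$spacing[2]
  nt <- dim(field$v)[4]
  flow <- peak <- numeric(nt)
  for (t in seq_len(nt)) {
    vz <- field$v[, , k, t, 3]
    vin <- vz[inside]
    flow[t] <- sum(vin) * pix * 0.01
    peak[t] <- vin[which.max(abs(vin))]
  }
  data.frame(time_ms = field$time_points, flow_ml_s = flow,
             peak_velocity_cm_s = peak)
}

#' Detect the onset of early (E-wave) inflow
#'
#' First timeframe at which the magnitude of the transmitral flow rate
#' exceeds `fraction` (default 5%) of its diastolic peak; used as the
#' backward-integration origin ("beginning of vortex ring formation").
#'
#' @param profile data frame from [through_plane_flow_profile()].
#' @param fraction onset threshold as a fraction of the peak (default 0.05).
#' @return onset time, ms.
#' @export
detect_e_wave_onset <- function(profile, fraction = 0.05) {
  q <- abs(profile$flow_ml_s)
  if (max(q) <= 0) stop("flow profile is identically zero")
  i <- which(q > fraction * max(q))[1]
  profile$time_ms[i]
}

#' Mitral annular effective area and diameter
#'
#' At the timeframe of peak transmitral flow, measures per candidate slice
#' the flow-profile area (area of ROI voxels with through-plane speed above
#' `flow_threshold`), selects the smallest across slices, and converts it to
#' the diameter of the equal-area circle.
#'
#' @param field a `velocity_field`.
#' @param slice_z numeric vector of candidate slice positions, mm.
#' @param roi ROI polygon (shared across slices) as in
#'   [through_plane_flow_profile()].
#' @param flow_threshold speed threshold separating jet from background,
#'   cm/s (default 10).
#' @return list with `area_mm2`, `diameter_mm`, `timeframe`, `slice_z`.
#' @export
mitral_effective_diameter <- function(field, slice_z, roi, flow_threshold = 10) {
  validate_velocity_field(field)
  if (inherits(roi, "contour_set")) {
    rp <- contour_polygons(roi, label = "roi")
    if (length(rp) == 0) rp <- contour_polygons(roi)
    if (length(rp) == 0) stop("empty ROI")
    roi <- rp[[1]]$xy
  }
  profiles <- lapply(slice_z, function(z) through_plane_flow_profile(field, z, roi))
  total <- do.call(pmax, lapply(profiles, function(p) abs(p$flow_ml_s)))
  tpk <- which.max(total)
  xs <- axis_coords(field, 1); ys <- axis_coords(field, 2)
  zs <- axis_coords(field, 3)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- point_in_polygon(pts, roi)
  pix <- field$spacing[1] * field$spacing[2]
  areas <- vapply(slice_z, function(z) {
    k <- which.min(abs(zs - z))
    vz <- field$v[, , k, tpk, 3]
    sum(abs(vz[inside]) > flow_threshold) * pix
  }, numeric(1))
  pos <- which(areas > 0)
  if (length(pos) == 0)
    stop("no voxel above the flow threshold: cannot measure the annulus")
  best <- pos[which.min(areas[pos])]
  list(area_mm2 = areas[best], diameter_mm = effective_diameter(areas[best]),
       timeframe = tpk, slice_z = slice_z[best])
}

#' Largest LCS effective diameter and its ratio to the mitral diameter
#'
#' Per slice and timeframe the LCS cross-section is reduced to its equal-area
#' circle diameter (the same approach as the mitral measurement); the maximum
#' over all slices and timeframes is the largest LCS diameter.
#'
#' @param lcs a non-empty `contour_set` of LCS delineations.
#' @return `max_lcs_diameter`: diameter in mm.
#' @export
max_lcs_diameter <- function(lcs) {
  stopifnot(inherits(lcs, "contour_set"))
  polys <- contour_polygons(lcs, label = "lcs")
  if (length(polys) == 0) polys <- contour_polygons(lcs)
  if (length(polys) == 0) stop("empty contour set")
  max(vapply(polys, function(p) effective_diameter(polygon_area(p$xy)), numeric(1)))
}

#' @rdname max_lcs_diameter
#' @param lcs_diameter,mitral_diameter diameters in mm.
#' @return `diameter_ratio`: dimensionless ratio.
#' @export
diameter_ratio <- function(lcs_diameter, mitral_diameter) {
  if (mitral_diameter <= 0) stop("mitral diameter must be positive")
  lcs_diameter / mitral_diameter
}

#' Vortex formation ratio (L/D)
#'
#' Ratio of the ejected fluid column length `L = V / (pi D^2 / 4)` to the
#' inlet diameter `D`, i.e. `VFR = 4 V / (pi D^3)`. Vortex rings stop growing
#' and shed trailing jets at VFR around 4.
#'
#' @param inflow_volume pulsatile inflow volume, ml.
#' @param inlet_diameter inlet (mitral) effective diameter, mm.
#' @return dimensionless VFR.
#' @export
vortex_formation_ratio <- function(inflow_volume, inlet_diameter) {
  if (any(inlet_diameter <= 0)) stop("inlet diameter must be positive")
  4 * (inflow_volume * 1000) / (pi * inlet_diameter^3)
}

#' Peak filling rate from an LV volume curve
#'
#' Maximum temporal derivative of the volume curve by central differences
#' (one-sided at the ends).
#'
#' @param volume_ml LV volume per timeframe, ml.
#' @param time_ms timeframe times, ms.
#' @return peak filling rate, ml/s.
#' @export
peak_filling_rate <- function(volume_ml, time_ms) {
  stopifnot(length(volume_ml) == length(time_ms), length(volume_ml) >= 2)
  n <- length(volume_ml)
  up <- c(2:n, n); dn <- c(1, 1:(n - 1))
  dv <- (volume_ml[up] - volume_ml[dn]) / (time_ms[up] - time_ms[dn])
  max(dv) * 1000 # ml/ms -> ml/s
}

#' Assemble a per-subject metrics table
#'
#' One row per timeframe with LV volume, vortex volume, VV% and the
#' sphere-equivalent wall distance, plus per-subject scalars repeated on
#' every row (mitral area/diameter, largest LCS diameter, diameter ratio,
#' VFR, E-peak velocity, peak filling rate).
#'
#' @param subject_id subject identifier.
#' @param lv_volume_ml,vortex_volume_ml volumes per timeframe (ml); frames
#'   missing from the vortex curve count as 0 ml.
#' @param time_ms timeframe times, ms.
#' @param scalars optional named list of per-subject scalars.
#' @return data frame of class `metrics_table`.
#' @export
metrics_table <- function(subject_id, lv_volume_ml, vortex_volume_ml, time_ms,
                          scalars = list()) {
  stopifnot(length(lv_volume_ml) == length(time_ms))
  vv <- vortex_volume_ml
  if (is.null(names(vv)) && length(vv) != length(time_ms))
    stop("vortex volumes must be named by timeframe or match time_ms")
  if (!is.null(names(vv))) {
    full <- numeric(length(time_ms))
    tf <- as.integer(names(vv))
    full[tf] <- vv
    vv <- full
  }
  vv <- pmin(vv, lv_volume_ml) # cropped vortex cannot exceed the chamber
  df <- data.frame(subject_id = subject_id, timeframe = seq_along(time_ms),
                   time_ms = time_ms, lv_volume_ml = lv_volume_ml,
                   vortex_volume_ml = vv,
                   vv_percent = vortex_volume_fraction(vv, lv_volume_ml),
                   wall_distance_mm = vortex_wall_distance(lv_volume_ml, vv))
  for (nm in names(scalars)) df[[nm]] <- scalars[[nm]]
  class(df) <- c("metrics_table", "data.frame")
  df
}
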