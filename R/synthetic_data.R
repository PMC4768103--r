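# Analytic and kinematic synthetic flow fields with known vortex ground
# truth: every pipeline stage is testable without any acquisition.

# analytic velocity function factories: f(pts n x 3 mm, t ms) -> n x 3 cm/s
velocity_fun <- function(model, params) {
  switch(model,
    uniform = {
      cc <- params$c
      function(pts, t) matrix(cc, nrow(pts), 3, byrow = TRUE)
    },
    solid_rotation = {
      om <- params$omega # rad/s, vector
      ctr <- if (is.null(params$center)) c(0, 0, 0) else params$center
      function(pts, t) {
        r <- sweep(pts, 2, ctr)
        # omega (1/s) x r (mm) = mm/s -> cm/s
        0.1 * cbind(om[2] * r[, 3] - om[3] * r[, 2],
                    om[3] * r[, 1] - om[1] * r[, 3],
                    om[1] * r[, 2] - om[2] * r[, 1])
      }
    },
    planar_strain = {
      k <- params$k # 1/s
      ctr <- if (is.null(params$center)) c(0, 0, 0) else params$center
      function(pts, t)
        cbind(k * (pts[, 1] - ctr[1]) / 10, -k * (pts[, 2] - ctr[2]) / 10, 0)
    },
    double_gyre = {
      # standard unsteady double gyre on [0,2] x [0,1] (mm, ms units);
      # stream function A sin(pi f(x,t)) sin(pi y)
      A <- params$A; eps <- params$eps; om <- params$omega
      function(pts, t) {
        x <- pts[, 1]; y <- pts[, 2]
        st <- eps * sin(om * t)
        f <- st * x^2 + (1 - 2 * st) * x
        dfdx <- 2 * st * x + (1 - 2 * st)
        u <- -pi * A * sin(pi * f) * cos(pi * y)
        v <- pi * A * cos(pi * f) * sin(pi * y) * dfdx
        100 * cbind(u, v, 0) # mm/ms -> cm/s
      }
    },
    hill_vortex = {
      a <- params$a; U <- params$U
      ctr <- if (is.null(params$center)) c(0, 0, 0) else params$center
      function(pts, t) {
        cz <- ctr[3] + 0.01 * U * t # translation, mm
        hill_lab_velocity(pts, c(ctr[1], ctr[2], cz), a, U)
      }
    },
    stop("unknown synthetic flow model: ", model)
  )
}

# Hill's spherical vortex, lab frame (fluid at rest at infinity), translating
# along +z at speed U; sphere of radius a about `center` is material.
hill_lab_velocity <- function(pts, center, a, U) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]; dz <- pts[, 3] - center[3]
  s2 <- dx^2 + dy^2
  r2 <- s2 + dz^2
  r <- sqrt(r2)
  inside <- r < a
  uz <- us_over_s <- numeric(length(r))
  # interior: co-moving recirculation + translation U
  uz[inside] <- 1.5 * U * (1 - (2 * s2[inside] + dz[inside]^2) / a^2) + U
  us_over_s[inside] <- 1.5 * U * dz[inside] / a^2
  # exterior: dipole
  out <- !inside
  r5 <- r2[out]^2 * pmax(r[out], 1e-12)
  uz[out] <- U * a^3 * (2 * dz[out]^2 - s2[out]) / (2 * r5)
  us_over_s[out] <- 1.5 * U * a^3 * dz[out] / r5
  cbind(us_over_s * dx, us_over_s * dy, uz)
}

#' Specify a synthetic flow dataset
#'
#' @param model one of `uniform`, `solid_rotation`, `planar_strain`,
#'   `double_gyre`, `hill_vortex` (see [synthetic_ventricle()] for the
#'   chamber model).
#' @param params named list of model parameters (e.g. `c` for uniform;
#'   `omega`, `center` for solid rotation; `k` for planar strain; `A`, `eps`,
#'   `omega` for the double gyre; `a` mm, `U` cm/s, `center` for the Hill
#'   vortex).
#' @param origin,spacing,dims grid geometry (mm; `dims` = voxels per axis).
#' @param time_points frame times, ms.
#' @param noise_sigma additive Gaussian velocity noise SD, cm/s.
#' @param venc optional VENC recorded on the output field, cm/s.
#' @param seed RNG seed for the noise stream.
#' @return list of class `synthetic_flow_spec`.
#' @export
synthetic_flow_spec <- function(model, params = list(), origin = c(0, 0, 0),
                                spacing = c(3, 3, 3), dims, time_points,
                                noise_sigma = 0, venc = NULL, seed = 1L) {
  stopifnot(all(is.finite(unlist(params))), noise_sigma >= 0)
  structure(list(model = model, params = params, origin = as.numeric(origin),
                 spacing = rep(as.numeric(spacing), length.out = 3),
                 dims = as.integer(dims), time_points = as.numeric(time_points),
                 noise_sigma = noise_sigma, venc = venc, seed = as.integer(seed)),
            class = "synthetic_flow_spec")
}

#' Generate a synthetic velocity field with ground truth
#'
#' Samples the requested analytic model onto the voxel grid for every frame.
#' The returned truth carries the analytic velocity function and, where
#' defined, material-boundary geometry (the Hill sphere) for downstream
#' checks.
#'
#' @param spec a `synthetic_flow_spec`.
#' @return list with `field` (a validated `velocity_field`) and `truth`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_flow_spec"))
  vfun <- velocity_fun(spec$model, spec$params)
  d <- spec$dims
  xs <- spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  pts <- cbind(rep(xs, times = d[2] * d[3]),
               rep(rep(ys, each = d[1]), times = d[3]),
               rep(zs, each = d[1] * d[2]))
  nt <- length(spec$time_points)
  v <- array(0, dim = c(d, nt, 3))
  for (t in seq_len(nt)) {
    vt <- vfun(pts, spec$time_points[t])
    for (c in 1:3) v[, , , t, c] <- vt[, c]
  }
  field <- velocity_field(v, spec$spacing, spec$origin, spec$time_points,
                          venc = spec$venc)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    field <- inject_noise(field, spec$noise_sigma)
  }
  truth <- list(velocity_fun = vfun, model = spec$model, params = spec$params,
                seed = spec$seed)
  if (spec$model == "hill_vortex") {
    ctr <- if (is.null(spec$params$center)) c(0, 0, 0) else spec$params$center
    truth$boundary_radius <- spec$params$a
    truth$boundary_center <- function(t)
      c(ctr[1], ctr[2], ctr[3] + 0.01 * spec$params$U * t)
  }
  list(field = field, truth = truth)
}

#' Add Gaussian velocity noise
#'
#' Additive iid Gaussian noise per component from the current RNG stream
#' (seed under the caller's control); `sigma = 0` is the identity.
#'
#' @param field a `velocity_field`.
#' @param sigma noise SD, cm/s (>= 0).
#' @return the noisy `velocity_field`.
#' @export
inject_noise <- function(field, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(field)
  field$v <- field$v + array(rnorm(length(field$v), 0, sigma), dim = dim(field$v))
  field
}

#' Inject single VENC phase wraps
#'
#' Maps every velocity with `|v| > venc` to `v - 2 * venc * sign(v)` (one
#' wrap), emulating phase-contrast aliasing; the affected voxel count and
#' indices are recorded as attributes.
#'
#' @param field a `velocity_field`.
#' @param venc velocity-encoding limit, cm/s (> 0); also recorded on the
#'   output field.
#' @return the wrapped `velocity_field` with attributes `n_wrapped` and
#'   `wrapped_index`.
#' @export
inject_wraps <- function(field, venc) {
  stopifnot(venc > 0)
  w <- abs(field$v) > venc
  field$v[w] <- field$v[w] - 2 * venc * sign(field$v[w])
  field$venc <- venc
  attr(field, "n_wrapped") <- sum(w)
  attr(field, "wrapped_index") <- which(w, arr.ind = TRUE)
  field
}

# raised-cosine bump: peak `q` over [t0, t0 + w]; integral q*w/2
rc_bump <- function(t, t0, w, q) {
  ifelse(t >= t0 & t <= t0 + w, q * 0.5 * (1 - cos(2 * pi * (t - t0) / w)), 0)
}
rc_bump_integral <- function(t, t0, w, q) { # time-integral in [t0, t], per-ms units
  x <- pmin(pmax(t - t0, 0), w)
  q * 0.5 * (x - w * sin(2 * pi * x / w) / (2 * pi))
}

#' Kinematic synthetic left ventricle with embedded vortex ring
#'
#' A deforming ellipsoidal cavity whose volume follows a prescribed biphasic
#' (E/A) diastolic filling curve, containing a Hill-type recirculation cell
#' whose spherical material boundary grows with the cumulative inflow until
#' it encloses a prescribed fraction of the cavity at end-diastole. An
#' orifice slab above the base carries a plug jet with the transmitral flow
#' profile for flow-profile metrics. The construction is kinematic, not a
#' flow simulation: the recirculation cell has zero normal velocity relative
#' to its spherical boundary, and a radial dilation field carries the
#' boundary growth, so the sphere is a material surface separating
#' inflow-origin from residual blood at every instant — the exact analogue
#' of the boundary that backward-time FTLE ridges mark.
#'
#' @param edv_ml,esv_ml end-diastolic and end-systolic LV volumes, ml.
#' @param vv_percent_ed prescribed end-diastolic vortex volume fraction, %.
#' @param cycle_ms cardiac cycle length, ms.
#' @param n_phases reconstructed timeframes per cycle.
#' @param spacing_mm isotropic voxel size, mm.
#' @param slice_thickness_mm short-axis slice thickness, mm.
#' @param systole_ms end of systolic ejection, ms.
#' @param e_onset_ms,e_width_ms E-wave bump start and width, ms.
#' @param a_onset_ms,a_width_ms A-wave bump start and width, ms.
#' @param e_fraction fraction of the diastolic inflow carried by the E-wave.
#' @param orifice_diameter_mm inlet (mitral) effective diameter, mm.
#' @param vortex_strength_cm_s peak recirculation speed scale of the ring,
#'   cm/s.
#' @param aspect transverse-to-long semi-axis ratio of the cavity.
#' @param venc VENC recorded on the field, cm/s.
#' @param noise_sigma additive velocity noise SD, cm/s.
#' @param seed RNG seed for the noise stream.
#' @return list with `field` and `truth`; `truth` carries the endocardial and
#'   vortex-boundary contour sets, the analytic volume curves, `vv_percent`
#'   and `wall_distance` per frame, the flow profile, the E-wave onset, and
#'   the orifice geometry.
#' @export
synthetic_ventricle <- function(edv_ml = 195, esv_ml = 72, vv_percent_ed = 53,
                                cycle_ms = 1000, n_phases = 40L,
                                spacing_mm = 3, slice_thickness_mm = 8,
                                systole_ms = 350, e_onset_ms = 360,
                                e_width_ms = 250, a_onset_ms = 780,
                                a_width_ms = 200, e_fraction = 0.7,
                                orifice_diameter_mm = 27,
                                vortex_strength_cm_s = 40, aspect = 0.65,
                                venc = 150, noise_sigma = 0, seed = 1L) {
  stopifnot(edv_ml > esv_ml, esv_ml > 0, vv_percent_ed > 0, vv_percent_ed < 100,
            e_fraction > 0, e_fraction <= 1, aspect > 0, aspect < 1)
  dv <- edv_ml - esv_ml
  qE <- 2 * e_fraction * dv * 1000 / e_width_ms        # peak inflow, ml/s
  qA <- 2 * (1 - e_fraction) * dv * 1000 / a_width_ms
  if (a_onset_ms + a_width_ms > cycle_ms)
    stop("A-wave extends past the cycle end")

  Q_fun <- function(t) rc_bump(t, e_onset_ms, e_width_ms, qE) +
    rc_bump(t, a_onset_ms, a_width_ms, qA) # ml/s
  cum_in <- function(t) (rc_bump_integral(t, e_onset_ms, e_width_ms, qE) +
    rc_bump_integral(t, a_onset_ms, a_width_ms, qA)) / 1000 # ml

  V_fun <- function(t) { # LV volume, ml
    ifelse(t <= systole_ms,
           esv_ml + (edv_ml - esv_ml) * (1 + cos(pi * pmin(t, systole_ms) / systole_ms)) / 2,
           esv_ml + cum_in(t))
  }
  c_fun <- function(t) ifelse(t <= systole_ms, 0, cum_in(t) / dv)
  f_ed <- vv_percent_ed / 100
  a_fun <- function(t) (3 * f_ed * edv_ml * 1000 * pmax(c_fun(t), 0) / (4 * pi))^(1 / 3)
  adot_over_a <- function(t) { # boundary growth rate, 1/ms
    cc <- c_fun(t)
    ifelse(cc > 1e-9, (Q_fun(t) / 1000 / dv) / (3 * cc), 0)
  }
  U_fun <- function(t) vortex_strength_cm_s * Q_fun(t) / qE

  # cavity semi-axes: ax = ay = aspect * az
  semi_axes <- function(t) {
    az <- (3 * V_fun(t) * 1000 / (4 * pi * aspect^2))^(1 / 3)
    c(aspect * az, aspect * az, az)
  }
  ax_ed <- semi_axes(cycle_ms)[1]; az_ed <- semi_axes(cycle_ms)[3]

  # orifice slab above the cavity base
  z0_slab <- az_ed + 3
  z1_slab <- z0_slab + 10
  orifice_area <- pi * (orifice_diameter_mm / 2)^2

  vfun <- function(pts, t) {
    ax <- semi_axes(t)
    a <- a_fun(t); U <- U_fun(t); aoa <- adot_over_a(t)
    dx <- pts[, 1]; dy <- pts[, 2]; dz <- pts[, 3]
    v <- matrix(0, nrow(pts), 3)
    rho <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2 + (dz / ax[3])^2)
    in_cav <- rho <= 1
    if (a > 1e-6 && any(in_cav)) {
      s2 <- dx^2 + dy^2
      r2 <- s2 + dz^2
      r <- sqrt(r2)
      # Hill recirculation cell (co-moving pattern: the ring is pinned),
      # plus the radial dilation that carries the boundary growth: fluid at
      # the sphere moves with the sphere, so r = a(t) is a material surface
      # separating inflow-origin from residual blood — the ground truth the
      # backward-FTLE ridge must recover
      inside <- in_cav & r < a
      outside <- in_cav & r >= a
      gr <- 100 * aoa # dilation scale, cm/s per mm
      if (any(inside)) {
        uz <- 1.5 * U * (1 - (2 * s2[inside] + dz[inside]^2) / a^2)
        us <- 1.5 * U * dz[inside] / a^2 # per unit s
        v[inside, 1] <- us * dx[inside] + gr * dx[inside]
        v[inside, 2] <- us * dy[inside] + gr * dy[inside]
        v[inside, 3] <- uz + gr * dz[inside]
      }
      if (any(outside)) {
        # short-range continuation of the dilation outside the boundary
        # (radial velocity a-continuous at r = a, decaying as (a/r)^4), and
        # additionally tapered to zero at the endocardium: the accommodation
        # shear stays concentrated at the material interface instead of
        # painting a second, displaced shear structure into the cavity
        rho_s <- a * rho[outside] / pmax(r[outside], 1e-9) # rho of the sphere along the ray
        frac <- (rho[outside] - rho_s) / pmax(1 - rho_s, 1e-6)
        ww <- 0.5 * (1 + cos(pi * pmin(pmax(frac, 0), 1)))
        dil <- ww * gr * a^5 / (r2[outside]^2 * r[outside])
        v[outside, 1] <- dil * dx[outside]
        v[outside, 2] <- dil * dy[outside]
        v[outside, 3] <- dil * dz[outside]
      }
    }
    # orifice jet slab (plug profile carrying Q(t) into the cavity, -z)
    Q <- Q_fun(t)
    if (Q > 0) {
      in_jet <- dz >= z0_slab & dz <= z1_slab &
        (dx^2 + dy^2) <= (orifice_diameter_mm / 2)^2
      v[in_jet, 3] <- v[in_jet, 3] - 100 * Q / orifice_area # cm/s
    }
    v
  }

  times <- seq(0, cycle_ms - cycle_ms / n_phases, by = cycle_ms / n_phases)
  half_xy <- ax_ed + 2 * spacing_mm
  nx <- ceiling(2 * half_xy / spacing_mm) + 1L
  z_lo <- -(az_ed + 2 * spacing_mm)
  z_hi <- z1_slab + spacing_mm
  nz <- ceiling((z_hi - z_lo) / spacing_mm) + 1L
  spec <- synthetic_flow_spec("uniform", list(c = c(0, 0, 0)),
                              origin = c(-half_xy, -half_xy, z_lo),
                              spacing = rep(spacing_mm, 3),
                              dims = c(nx, nx, nz), time_points = times,
                              noise_sigma = 0, venc = venc, seed = seed)
  # sample the ventricle field directly (generate_field handles the plumbing
  # for the closed-form models; the chamber field is sampled here)
  d <- spec$dims
  xs <- spec$origin[1] + (seq_len(d[1]) - 1) * spacing_mm
  ys <- spec$origin[2] + (seq_len(d[2]) - 1) * spacing_mm
  zs <- spec$origin[3] + (seq_len(d[3]) - 1) * spacing_mm
  pts <- cbind(rep(xs, times = d[2] * d[3]),
               rep(rep(ys, each = d[1]), times = d[3]),
               rep(zs, each = d[1] * d[2]))
  v <- array(0, dim = c(d, length(times), 3))
  for (t in seq_along(times)) {
    vt <- vfun(pts, times[t])
    for (c in 1:3) v[, , , t, c] <- vt[, c]
  }
  field <- velocity_field(v, spec$spacing, spec$origin, times, venc = venc,
                          cycle_length = cycle_ms)
  if (noise_sigma > 0) {
    set.seed(seed)
    field <- inject_noise(field, noise_sigma)
  }

  # volume bookkeeping: cavity volume increase must equal integrated inflow
  # (checked on a dense time grid, independent of the frame sampling)
  dia <- seq(systole_ms, cycle_ms, by = 1)
  dV <- V_fun(max(dia)) - V_fun(min(dia))
  qint <- sum((Q_fun(head(dia, -1)) + Q_fun(tail(dia, -1))) / 2 * diff(dia)) / 1000
  if (dV > 1 && abs(qint - dV) / dV > 0.02)
    stop("generation error: integrated inflow deviates from the cavity ",
         "volume change by more than 2%")

  # ground-truth contours on the fixed short-axis slice stack
  z_slices <- seq(-az_ed + slice_thickness_mm / 2, az_ed - slice_thickness_mm / 2,
                  by = slice_thickness_mm)
  endo <- list(); vort <- list()
  for (ti in seq_along(times)) {
    t <- times[ti]
    ax <- semi_axes(t); a <- a_fun(t)
    for (si in seq_along(z_slices)) {
      z <- z_slices[si]
      if (abs(z) < ax[3]) {
        rf <- sqrt(1 - (z / ax[3])^2)
        endo[[length(endo) + 1]] <- list(
          label = "endocardium", timeframe = ti, slice_index = si,
          polygon_id = 1L, xy = ellipse_polygon(0, 0, ax[1] * rf, ax[2] * rf), z = z)
      }
      if (a > 0 && abs(z) < a) {
        rs <- sqrt(a^2 - z^2)
        if (rs > 0.5)
          vort[[length(vort) + 1]] <- list(
            label = "lcs", timeframe = ti, slice_index = si,
            polygon_id = 1L, xy = ellipse_polygon(0, 0, rs, rs), z = z)
      }
    }
  }
  endo_cs <- contours_from_polygons(endo, slice_thickness = slice_thickness_mm)
  vort_cs <- contours_from_polygons(vort, slice_thickness = slice_thickness_mm)

  V_t <- V_fun(times)
  Vs_t <- f_ed * edv_ml * pmax(c_fun(times), 0)
  flow <- data.frame(time_ms = times, flow_ml_s = Q_fun(times))
  e_onset <- times[which(Q_fun(times) > 0.05 * qE)[1]]

  truth <- list(
    endo_contours = endo_cs, vortex_contours = vort_cs,
    lv_volume_ml = V_t, vortex_volume_ml = Vs_t,
    vv_percent = 100 * Vs_t / V_t,
    wall_distance_mm = vortex_wall_distance(V_t, pmin(Vs_t, V_t)),
    flow = flow, e_onset_ms = e_onset,
    e_peak = list(time_ms = e_onset_ms + e_width_ms / 2, flow_ml_s = qE,
                  velocity_cm_s = 100 * qE / orifice_area),
    orifice = list(diameter_mm = orifice_diameter_mm,
                   slice_z = (z0_slab + z1_slab) / 2,
                   roi = ellipse_polygon(0, 0, orifice_diameter_mm / 2 + 6,
                                         orifice_diameter_mm / 2 + 6)),
    slice_z = z_slices, slice_thickness_mm = slice_thickness_mm,
    a_fun = a_fun, V_fun = V_fun, c_fun = c_fun, semi_axes = semi_axes,
    velocity_fun = vfun, times = times, systole_ms = systole_ms,
    vv_percent_ed = vv_percent_ed, seed = seed)
  list(field = field, truth = truth)
}
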