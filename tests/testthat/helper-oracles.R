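# Independent pure-R oracles used across the suite: a trilinear/time-linear
# field sampler and RK4 integrator written without reference to the package
# internals, plus analytic velocity models for closed-form checks.

# pure-R space-time sampler over a velocity_field (oracle for the C++ path)
oracle_sample <- function(field, P, t) {
  tp <- field$time_points
  nt <- length(tp)
  if (t <= tp[1]) { ti <- 1L; w <- 0 }
  else if (t >= tp[nt]) { ti <- nt - 1L; w <- 1 }
  else { ti <- findInterval(t, tp); w <- (t - tp[ti]) / (tp[ti + 1] - tp[ti]) }
  d <- dim(field$v)
  fx <- (P[, 1] - field$origin[1]) / field$spacing[1]
  fy <- (P[, 2] - field$origin[2]) / field$spacing[2]
  fz <- (P[, 3] - field$origin[3]) / field$spacing[3]
  oob <- fx < -1e-9 | fy < -1e-9 | fz < -1e-9 |
    fx > d[1] - 1 + 1e-9 | fy > d[2] - 1 + 1e-9 | fz > d[3] - 1 + 1e-9
  fx <- pmin(pmax(fx, 0), d[1] - 1); fy <- pmin(pmax(fy, 0), d[2] - 1)
  fz <- pmin(pmax(fz, 0), d[3] - 1)
  i0 <- pmin(pmax(floor(fx), 0), max(d[1] - 2, 0))
  j0 <- pmin(pmax(floor(fy), 0), max(d[2] - 2, 0))
  k0 <- pmin(pmax(floor(fz), 0), max(d[3] - 2, 0))
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- matrix(0, nrow(P), 3)
  for (tt in 0:1) {
    tw <- if (tt == 0) 1 - w else w
    if (tw == 0) next
    for (c in 1:3) {
      vc <- field$v[, , , ti + tt, c]
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wgt <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
          (if (dz) wz else 1 - wz)
        acc <- acc + wgt * vc[cbind(pmin(i0 + dx, d[1] - 1) + 1,
                                    pmin(j0 + dy, d[2] - 1) + 1,
                                    pmin(k0 + dz, d[3] - 1) + 1)]
      }
      out[, c] <- out[, c] + tw * acc
    }
  }
  out[oob, ] <- 0
  list(v = out, out_of_domain = oob)
}

# pure-R backward RK4 over a velocity_field (oracle for advect_backward)
oracle_advect <- function(field, P, t_seed, t_origin, step) {
  t <- t_seed
  while (t > t_origin + 1e-9) {
    h <- -min(step, t - t_origin)
    k1 <- oracle_sample(field, P, t)$v * 0.01
    k2 <- oracle_sample(field, P + h / 2 * k1, t + h / 2)$v * 0.01
    k3 <- oracle_sample(field, P + h / 2 * k2, t + h / 2)$v * 0.01
    k4 <- oracle_sample(field, P + h * k3, t + h)$v * 0.01
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  P
}

# 2x2 symmetric largest eigenvalue -> FTLE, for oracle gradients
oracle_ftle_from_grad <- function(gxx, gyx, gxy, gyy, T_s) {
  c11 <- gxx^2 + gyx^2; c22 <- gxy^2 + gyy^2; c12 <- gxx * gxy + gyx * gyy
  lam <- ((c11 + c22) + sqrt((c11 - c22)^2 + 4 * c12^2)) / 2
  log(pmax(sqrt(lam), 1e-300)) / T_s
}

# small gridded fields for the analytic models
make_model_field <- function(model, params, half = 60, spacing = 3,
                             times = seq(0, 300, 25)) {
  n <- floor(2 * half / spacing) + 1
  generate_field(synthetic_flow_spec(
    model, params, origin = c(-half, -half, -half),
    spacing = rep(spacing, 3), dims = rep(n, 3), time_points = times))
}

# convenience: effective radius of the first polygon of a contour set
contour_eff_radius <- function(cs) {
  p <- vortexlcs:::contour_polygons(cs)[[1]]
  sqrt(polygon_area(p$xy) / pi)
}

# a compact synthetic ventricle used where full acquisition scale is not the
# point (coarser seeds keep unit tests fast)
small_ventricle <- function(...) {
  synthetic_ventricle(edv_ml = 120, esv_ml = 50, n_phases = 20L,
                      slice_thickness_mm = 10, ...)
}
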