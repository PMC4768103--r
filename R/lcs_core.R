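# Backward flow maps, finite-time Lyapunov exponents, and LCS vortex
# boundary delineation.

#' Define a planar seeding region
#'
#' @param origin plane corner, mm.
#' @param u,v in-plane direction vectors (normalized internally; must not be
#'   parallel).
#' @param extent in-plane extents along `u` and `v`, mm (length 2, >= 0).
#' @return list of class `seed_plane`.
#' @export
seed_plane <- function(origin, u, v, extent) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("plane axes must be non-zero")
  u <- u / nu; v <- v / nv
  if (abs(sum(u * v)) > 1 - 1e-9) stop("plane axes must not be parallel")
  structure(list(origin = as.numeric(origin), u = u, v = v,
                 extent = as.numeric(extent)), class = "seed_plane")
}

#' Seed a rectangular particle grid on a plane
#'
#' Rectangular lattice covering the plane extents, inclusive of both edges
#' where the spacing divides the extent; a zero extent yields a single
#' row/seed.
#'
#' @param plane a `seed_plane`.
#' @param spacing seed spacing, mm (default 0.8).
#' @param t_seed seeding time, ms.
#' @return object of class `particle_grid` with `positions` (n x 3, mm, in
#'   row-major plane order), lattice size `n1 x n2`, and the seeding time.
#' @export
seed_grid <- function(plane, spacing = 0.8, t_seed = 0) {
  stopifnot(inherits(plane, "seed_plane"))
  if (spacing <= 0) stop("seed spacing must be positive")
  if (any(plane$extent < 0)) stop("plane extents must be >= 0")
  n1 <- floor(plane$extent[1] / spacing + 1e-9) + 1L
  n2 <- floor(plane$extent[2] / spacing + 1e-9) + 1L
  if (all(plane$extent > 0) && (n1 == 1L || n2 == 1L))
    warning("seed spacing exceeds a plane extent: degenerate single-row grid")
  s1 <- (seq_len(n1) - 1) * spacing
  s2 <- (seq_len(n2) - 1) * spacing
  a <- rep(s1, times = n2)
  b <- rep(s2, each = n1)
  pos <- cbind(plane$origin[1] + a * plane$u[1] + b * plane$v[1],
               plane$origin[2] + a * plane$u[2] + b * plane$v[2],
               plane$origin[3] + a * plane$u[3] + b * plane$v[3])
  structure(list(plane = plane, spacing = spacing, n1 = n1, n2 = n2,
                 positions = pos, t_seed = t_seed), class = "particle_grid")
}

#' Backward particle advection (flow map)
#'
#' Integrates every seed of the grid backwards in time from the seeding time
#' to `t_origin` with a classic fourth-order Runge-Kutta scheme; the final
#' partial step is shortened to land exactly on `t_origin`. Particles whose
#' stage samples leave the spatial grid are flagged (velocity outside the
#' grid is zero, so such particles freeze).
#'
#' @param grid a `particle_grid`.
#' @param field a `velocity_field` whose time span covers
#'   `[t_origin, t_seed]`.
#' @param t_origin integration end time, ms (earlier than the seeding time).
#' @param step RK4 time step, ms (default 5, > 0).
#' @return object of class `flow_map` with end positions, out-of-domain
#'   flags, and the integration span.
#' @export
advect_backward <- function(grid, field, t_origin, step = 5) {
  stopifnot(inherits(grid, "particle_grid"))
  validate_velocity_field(field)
  if (step <= 0) stop("integration step must be positive")
  t_seed <- grid$t_seed
  if (t_origin >= t_seed) stop("t_origin must be earlier than the seeding time")
  tp <- field$time_points
  if (t_origin < tp[1] - 1e-9 || t_seed > tp[length(tp)] + 1e-9)
    stop("integration span outside the field's acquired time span")
  res <- advect_rk4_cpp(as.numeric(field$v), as.integer(dim(field$v)),
                        field$spacing, field$origin, tp, grid$positions,
                        t_seed, t_origin, step)
  structure(list(end = res$end, out_of_domain = as.logical(res$out_of_domain),
                 t_seed = t_seed, t_origin = t_origin, step = step),
            class = "flow_map")
}

#' Finite-time Lyapunov exponent field
#'
#' In-plane gradient of the flow map by central differences over neighboring
#' seeds (one-sided at grid edges), Cauchy-Green tensor `C = G'G`, and
#' `FTLE = ln(sqrt(lambda_max(C))) / |T|` with `|T|` in seconds (units 1/s).
#' Seeds whose finite-difference stencil touches an out-of-domain particle
#' are flagged and excluded downstream.
#'
#' @param flowmap a `flow_map` from [advect_backward()].
#' @param grid the `particle_grid` that seeded it (at least 3 x 3).
#' @return object of class `ftle_field`: `values` (`n1 x n2` matrix, 1/s),
#'   `flagged` (logical matrix), the grid and the integration span.
#' @export
compute_ftle <- function(flowmap, grid) {
  stopifnot(inherits(flowmap, "flow_map"), inherits(grid, "particle_grid"))
  n1 <- grid$n1; n2 <- grid$n2
  if (n1 < 3 || n2 < 3) stop("FTLE needs a grid of at least 3 x 3 seeds")
  h <- grid$spacing
  Tms <- flowmap$t_seed - flowmap$t_origin
  Ts <- Tms / 1000

  ex <- matrix(flowmap$end[, 1], n1, n2)
  ey <- matrix(flowmap$end[, 2], n1, n2)
  ez <- matrix(flowmap$end[, 3], n1, n2)
  oob <- matrix(flowmap$out_of_domain, n1, n2)

  d_axis <- function(m, axis) {
    # central differences along rows (axis 1) or columns (axis 2),
    # one-sided at the edges
    if (axis == 1) {
      up <- rbind(m[2:n1, ], m[n1, ]); dn <- rbind(m[1, ], m[1:(n1 - 1), ])
      den <- matrix(2 * h, n1, n2); den[1, ] <- h; den[n1, ] <- h
    } else {
      up <- cbind(m[, 2:n2], m[, n2]); dn <- cbind(m[, 1], m[, 1:(n2 - 1)])
      den <- matrix(2 * h, n1, n2); den[, 1] <- h; den[, n2] <- h
    }
    (up - dn) / den
  }
  g11 <- d_axis(ex, 1); g12 <- d_axis(ex, 2)
  g21 <- d_axis(ey, 1); g22 <- d_axis(ey, 2)
  g31 <- d_axis(ez, 1); g32 <- d_axis(ez, 2)

  # C = G'G, 2x2 symmetric; largest eigenvalue in closed form
  c11 <- g11^2 + g21^2 + g31^2
  c22 <- g12^2 + g22^2 + g32^2
  c12 <- g11 * g12 + g21 * g22 + g31 * g32
  lam <- ((c11 + c22) + sqrt((c11 - c22)^2 + 4 * c12^2)) / 2
  ftle <- log(pmax(sqrt(lam), .Machine$double.eps)) / Ts

  # flag seeds whose stencil touched a flagged particle
  spread <- function(m, axis) {
    if (axis == 1) rbind(m[1, ], m[1:(n1 - 1), ]) | m | rbind(m[2:n1, ], m[n1, ])
    else cbind(m[, 1], m[, 1:(n2 - 1)]) | m | cbind(m[, 2:n2], m[, n2])
  }
  flagged <- spread(spread(oob, 1), 2)
  if (all(flagged)) stop("all seeds flagged out-of-domain: empty FTLE field")

  structure(list(values = ftle, flagged = flagged, grid = grid,
                 t_seed = flowmap$t_seed, t_origin = flowmap$t_origin),
            class = "ftle_field")
}

#' Extract the LCS ridge mask from an FTLE field
#'
#' The field is normalized to the 95th percentile (linear-interpolation
#' percentile over the unflagged seeds of the time phase) and seeds above
#' `threshold_fraction` of that value form the ridge mask. Flagged seeds are
#' excluded from both the normalization and the mask.
#'
#' @param ftle an `ftle_field`.
#' @param threshold_fraction fraction of the normalization value (default
#'   0.5, in (0,1)).
#' @param percentile normalization percentile (default 0.95).
#' @param norm_value optional externally supplied normalization value (1/s),
#'   e.g. the pooled percentile over all slices of the time phase when one
#'   time phase is seeded on several planes; default: computed from this
#'   field alone.
#' @param min_separation optional coherence floor: a seed only enters the
#'   mask if its trajectories separated by at least this factor over the
#'   integration window (i.e. `ftle > log(min_separation) / |T|`), guarding
#'   against the relative percentile threshold promoting numerical noise on
#'   data with no coherent structure. Default 1 (disabled): normalizing over
#'   the ventricular region already keeps the percentile anchored to real
#'   structure.
#' @return object of class `lcs_mask`: logical `mask` matrix, the
#'   normalization value `p95`, and the parameters used.
#' @export
extract_lcs <- function(ftle, threshold_fraction = 0.5, percentile = 0.95,
                        norm_value = NULL, min_separation = 1) {
  stopifnot(inherits(ftle, "ftle_field"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  vals <- ftle$values[!ftle$flagged]
  p95 <- if (is.null(norm_value))
    as.numeric(quantile(vals, percentile, type = 7, names = FALSE))
  else as.numeric(norm_value)
  if (!is.finite(p95) || p95 <= 0) {
    warning("non-positive FTLE normalization value: empty LCS mask")
    mask <- matrix(FALSE, nrow(ftle$values), ncol(ftle$values))
  } else {
    Ts <- (ftle$t_seed - ftle$t_origin) / 1000
    floor_abs <- if (min_separation > 1) log(min_separation) / Ts else -Inf
    mask <- ftle$values > pmax(threshold_fraction * p95, floor_abs) &
      !ftle$flagged
  }
  structure(list(mask = mask, p95 = p95, threshold_fraction = threshold_fraction,
                 percentile = percentile, ftle = ftle), class = "lcs_mask")
}

# 8-connected component labelling of a logical matrix (BFS)
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((p - 1L) %% n1) + 1L
      j <- ((p - 1L) %/% n1) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= n1 && jj >= 1L && jj <= n2) {
          q <- ii + (jj - 1L) * n1
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Delineate the vortex boundary from an LCS ridge mask
#'
#' Reduces the ridge band to a closed boundary polygon: connected components
#' below `min_component` seeds are discarded as specks; the remaining ridge
#' points are ordered by angle around their centroid; within each angular bin
#' the outermost contiguous radial run of ridge points is collapsed to the
#' radius of its FTLE maximizer (the ridge line proper; the run's mean radius
#' when only a bare mask is supplied); bins without ridge points are bridged
#' by the straight segment between their angular neighbors, closing blind-
#' ended arcs. Polygons below `area_floor` are discarded.
#'
#' @param lcs an `lcs_mask` from [extract_lcs()] (or a logical matrix).
#' @param grid the seeding `particle_grid`.
#' @param timeframe,slice_index indices recorded in the output contours.
#' @param n_bins angular bins (default 72, i.e. 5 degrees).
#' @param min_component minimum seeds per ridge component (default 5).
#' @param min_coverage minimum fraction of angular bins holding ridge points
#'   for the contour to count as closable (default 0.25): scattered specks
#'   spanning a few degrees of arc cannot define a ring boundary.
#' @param area_floor minimum polygon area retained, mm^2 (default 50).
#' @param label contour label for the output (default `"lcs"`).
#' @return a `contour_set` (possibly empty) with an `n_bridges` attribute
#'   counting the straight-line closures that were added.
#' @export
delineate_vortex <- function(lcs, grid, timeframe = 1L, slice_index = 1L,
                             n_bins = 72L, min_component = 5L,
                             min_coverage = 0.25, area_floor = 50,
                             label = "lcs") {
  mask <- if (inherits(lcs, "lcs_mask")) lcs$mask else lcs
  ftle_vals <- if (inherits(lcs, "lcs_mask")) lcs$ftle$values else NULL
  stopifnot(inherits(grid, "particle_grid"))
  if (!any(mask)) {
    warning("empty ridge mask: no contour")
    return(contour_set())
  }
  lab <- label_components(mask)
  keep <- which(tabulate(lab[lab > 0]) >= min_component)
  sel <- lab %in% keep & mask
  if (!any(sel)) {
    warning("no ridge component above the size floor: no contour")
    return(contour_set())
  }
  n1 <- grid$n1
  idx <- which(sel)
  i <- ((idx - 1L) %% n1) + 1L
  j <- ((idx - 1L) %/% n1) + 1L
  # in-plane coordinates (mm)
  a <- (i - 1) * grid$spacing
  b <- (j - 1) * grid$spacing
  ca <- mean(a); cb <- mean(b)
  th <- atan2(b - cb, a - ca)
  r <- sqrt((a - ca)^2 + (b - cb)^2)
  fv <- if (is.null(ftle_vals)) NULL else ftle_vals[idx]
  bin <- pmin(floor((th + pi) / (2 * pi) * n_bins) + 1L, n_bins)

  gap <- 3 * grid$spacing
  ring <- rep(NA_real_, n_bins)
  for (k in unique(bin)) {
    sel <- bin == k
    ord <- order(r[sel], decreasing = TRUE)
    rs <- r[sel][ord]
    # outermost contiguous radial run of the band
    run_end <- which(diff(rs) < -gap)[1]
    if (is.na(run_end)) run_end <- length(rs)
    run <- seq_len(run_end)
    # ridge line = FTLE maximizer within the outermost band (the band's
    # mean radius when only a bare mask is supplied), refined to sub-grid
    # precision by the vertex of the parabola through the maximizer and its
    # radial neighbors
    if (is.null(fv)) {
      ring[k] <- mean(rs[run])
    } else {
      vr <- fv[sel][ord][run]
      i0 <- which.max(vr)
      ring[k] <- rs[run][i0]
      if (i0 > 1 && i0 < length(run)) {
        r3 <- rs[run][(i0 - 1):(i0 + 1)]
        v3 <- vr[(i0 - 1):(i0 + 1)]
        den <- (r3[1] - r3[2]) * (r3[1] - r3[3]) * (r3[2] - r3[3])
        if (abs(den) > 1e-12) {
          A <- (r3[3] * (v3[2] - v3[1]) + r3[2] * (v3[1] - v3[3]) +
                r3[1] * (v3[3] - v3[2])) / den
          B <- (r3[3]^2 * (v3[1] - v3[2]) + r3[2]^2 * (v3[3] - v3[1]) +
                r3[1]^2 * (v3[2] - v3[3])) / den
          if (A < 0) {
            rv <- -B / (2 * A)
            if (rv > min(r3) && rv < max(r3)) ring[k] <- rv
          }
        }
      }
    }
  }
  filled <- which(!is.na(ring))
  n_bridges <- 0L
  if (length(filled) < n_bins) {
    # count maximal runs of empty bins (cyclic): each is one straight bridge
    empty <- is.na(ring)
    runs <- rle(empty[c(which(!empty)[1]:n_bins, seq_len(which(!empty)[1] - 1))])
    n_bridges <- sum(runs$values)
  }
  if (length(filled) < max(3L, ceiling(min_coverage * n_bins))) {
    warning("ridge covers too little arc: no closable contour")
    return(contour_set())
  }
  th_mid <- -pi + (filled - 0.5) * (2 * pi / n_bins)
  pa <- ca + ring[filled] * cos(th_mid)
  pb <- cb + ring[filled] * sin(th_mid)
  if (polygon_area(cbind(pa, pb)) < area_floor) {
    return(contour_set())
  }
  pl <- grid$plane
  xyz <- cbind(pl$origin[1] + pa * pl$u[1] + pb * pl$v[1],
               pl$origin[2] + pa * pl$u[2] + pb * pl$v[2],
               pl$origin[3] + pa * pl$u[3] + pb * pl$v[3])
  out <- contours_from_polygons(list(list(
    label = label, timeframe = timeframe, slice_index = slice_index,
    polygon_id = 1L, xy = xyz[, 1:2], z = xyz[, 3])))
  # keep full 3-D vertices for oblique planes
  out$x_mm <- xyz[, 1]; out$y_mm <- xyz[, 2]; out$z_mm <- xyz[, 3]
  attr(out, "n_bridges") <- n_bridges
  out
}

#' Crop LCS delineations to the endocardium
#'
#' Per matching (slice, timeframe), intersects each LCS polygon with the
#' endocardial polygon (convex clipping), so LCS that grew across the
#' endocardial border are cut back to it. Timeframes or slices without an
#' endocardial contour are skipped with a message.
#'
#' @param lcs a `contour_set` with label `"lcs"`.
#' @param endo a `contour_set` with label `"endocardium"`.
#' @return the cropped `contour_set`.
#' @export
crop_to_endocardium <- function(lcs, endo) {
  stopifnot(inherits(lcs, "contour_set"), inherits(endo, "contour_set"))
  lp <- contour_polygons(lcs, label = "lcs")
  out <- list()
  for (p in lp) {
    ep <- contour_polygons(endo, label = "endocardium",
                           timeframe = p$timeframe, slice_index = p$slice_index)
    if (length(ep) == 0) {
      message("no endocardial contour for timeframe ", p$timeframe,
              ", slice ", p$slice_index, ": skipped")
      next
    }
    if (length(ep) > 1) {
      areas <- vapply(ep, function(e) polygon_area(e$xy), numeric(1))
      ep <- ep[which.max(areas)]
    }
    cl <- clip_polygon_convex(p$xy, ep[[1]]$xy)
    if (nrow(cl) >= 3) {
      p$xy <- cl
      p$z <- rep(p$z[1], nrow(cl))
      out[[length(out) + 1]] <- p
    }
  }
  contours_from_polygons(out, slice_thickness = attr(lcs, "slice_thickness"))
}
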