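test_that("seed grids cover the plane at the requested spacing", {
  g <- seed_grid(seed_plane(c(-20, -20, 0), c(1, 0, 0), c(0, 1, 0), c(40, 40)),
                 spacing = 0.8, t_seed = 0)
  expect_equal(c(g$n1, g$n2), c(51L, 51L)) # 40 mm at 0.8 mm: 51 per edge
  expect_equal(nrow(g$positions), 2601L)
  expect_equal(g$positions[1, ], c(-20, -20, 0))
  expect_equal(g$positions[2601, ], c(20, 20, 0))

  g0 <- seed_grid(seed_plane(c(1, 2, 3), c(1, 0, 0), c(0, 1, 0), c(0, 0)), 0.8)
  expect_equal(nrow(g0$positions), 1L)
  expect_equal(g0$positions[1, ], c(1, 2, 3))

  expect_warning(
    seed_grid(seed_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1)), 5),
    "degenerate")
})

test_that("oblique seed planes hold their seeds to the plane and spacing", {
  th <- 30 * pi / 180
  u <- c(cos(th), 0, sin(th))
  v <- c(0, 1, 0)
  g <- seed_grid(seed_plane(c(5, -3, 2), u, v, c(16, 8)), spacing = 0.8)
  nrm <- c(-sin(th), 0, cos(th))
  off <- (g$positions - matrix(c(5, -3, 2), nrow(g$positions), 3,
                               byrow = TRUE)) %*% nrm
  expect_lt(max(abs(off)), 1e-9)
  # in-row nearest neighbor spacing
  d1 <- sqrt(sum((g$positions[2, ] - g$positions[1, ])^2))
  d2 <- sqrt(sum((g$positions[g$n1 + 1, ] - g$positions[1, ])^2))
  expect_equal(c(d1, d2), c(0.8, 0.8), tolerance = 1e-12)
})

test_that("flow maps of simple fields match their closed forms", {
  # zero field: identity
  fz <- make_model_field("uniform", list(c = c(0, 0, 0)), times = c(0, 300))
  g <- seed_grid(seed_plane(c(-20, -20, 0), c(1, 0, 0), c(0, 1, 0), c(40, 40)),
                 2, t_seed = 250)
  fm <- advect_backward(g, fz$field, t_origin = 50)
  expect_equal(fm$end, g$positions, tolerance = 1e-14)

  # uniform field: x - c |T|
  fu <- make_model_field("uniform", list(c = c(10, 0, 0)), times = c(0, 300))
  fm2 <- advect_backward(g, fu$field, t_origin = 50, step = 5)
  expect_equal(fm2$end[, 1], g$positions[, 1] - 10 * 0.01 * 200,
               tolerance = 1e-10)
  expect_equal(fm2$end[, 2:3], g$positions[, 2:3], tolerance = 1e-12)
  expect_error(advect_backward(g, fu$field, t_origin = 50, step = -1),
               "positive")
  expect_error(advect_backward(g, fu$field, t_origin = 300), "earlier")
})

test_that("backward advection matches the independent R integrator", {
  sv <- small_ventricle()
  g <- seed_grid(seed_plane(c(-20, -20, -5), c(1, 0, 0), c(0, 1, 0), c(40, 40)),
                 4, t_seed = 900)
  fm <- advect_backward(g, sv$field, t_origin = 400, step = 5)
  ref <- oracle_advect(sv$field, g$positions, 900, 400, 5)
  expect_lt(max(abs(fm$end - ref)), 1e-8)
})

test_that("solid-body rotation shows fourth-order RK4 convergence", {
  om <- 2 * pi # rad/s
  fld <- make_model_field("solid_rotation", list(omega = c(0, 0, om)),
                          times = c(0, 400))$field
  th0 <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- cbind(30 * cos(th0), 30 * sin(th0), 0)
  pl <- seed_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0))
  errs <- vapply(c(20, 10, 5, 2.5), function(h) {
    grid <- structure(list(plane = pl, spacing = 1, n1 = nrow(pts), n2 = 1L,
                           positions = pts, t_seed = 300),
                      class = "particle_grid")
    fm <- advect_backward(grid, fld, t_origin = 100, step = h)
    ang <- -om * 0.2
    exact <- cbind(30 * cos(th0 + ang), 30 * sin(th0 + ang), 0)
    max(sqrt(rowSums((fm$end - exact)^2)))
  }, numeric(1))
  orders <- log2(errs[-4] / errs[-1])
  expect_true(all(orders >= 3.5))
})

test_that("FTLE vanishes for uniform translation and equals |k| under planar strain", {
  fu <- make_model_field("uniform", list(c = c(25, -10, 5)), times = c(0, 300))
  g <- seed_grid(seed_plane(c(-16, -16, 0), c(1, 0, 0), c(0, 1, 0), c(32, 32)),
                 0.8, t_seed = 250)
  f <- compute_ftle(advect_backward(g, fu$field, 50), g)
  expect_lt(max(abs(f$values[!f$flagged])), 1e-10)

  k <- 1.5
  fs <- make_model_field("planar_strain", list(k = k), times = c(0, 300))
  for (Tms in c(100, 200)) {
    g2 <- seed_grid(seed_plane(c(-16, -16, 0), c(1, 0, 0), c(0, 1, 0),
                               c(32, 32)), 0.8, t_seed = Tms + 50)
    f2 <- compute_ftle(advect_backward(g2, fs$field, 50), g2)
    interior <- f2$values[5:(g2$n1 - 4), 5:(g2$n2 - 4)]
    expect_lt(max(abs(interior - k)) / k, 0.01) # independent of |T|
  }
  expect_error(compute_ftle(advect_backward(g, fu$field, 50),
                            seed_grid(seed_plane(c(0, 0, 0), c(1, 0, 0),
                                                 c(0, 1, 0), c(1, 1)), 0.8)),
               "3 x 3")
})

test_that("flow maps compose across an intermediate time", {
  fld <- make_model_field("solid_rotation", list(omega = c(0, 0, pi)),
                          times = seq(0, 400, 50))$field
  g <- seed_grid(seed_plane(c(-15, -15, 0), c(1, 0, 0), c(0, 1, 0), c(30, 30)),
                 3, t_seed = 350)
  direct <- advect_backward(g, fld, t_origin = 50, step = 5)
  half <- advect_backward(g, fld, t_origin = 200, step = 5)
  g2 <- g
  g2$positions <- half$end
  g2$t_seed <- 200
  two_step <- advect_backward(g2, fld, t_origin = 50, step = 5)
  expect_lt(max(sqrt(rowSums((direct$end - two_step$end)^2))), 0.1)
})

test_that("backward FTLE of incompressible planar flow is non-negative", {
  # double gyre lives on [0,2]x[0,1]: build its own grid
  sp <- synthetic_flow_spec("double_gyre", list(A = 0.1, eps = 0.25,
                                                omega = pi / 5),
                            origin = c(0, 0, -0.02),
                            spacing = c(0.02, 0.02, 0.02),
                            dims = c(101, 51, 3), time_points = seq(0, 10, 0.5))
  fld <- generate_field(sp)$field
  g <- seed_grid(seed_plane(c(0.1, 0.1, 0), c(1, 0, 0), c(0, 1, 0),
                            c(1.8, 0.8)), 0.05, t_seed = 10)
  f <- compute_ftle(advect_backward(g, fld, t_origin = 0, step = 0.2), g)
  vals <- f$values[2:(g$n1 - 1), 2:(g$n2 - 1)]
  expect_gt(min(vals), -1e-6 / 0.01) # lambda_max(C) >= 1 up to numerics
})

test_that("LCS extraction normalizes to the percentile and thresholds at half", {
  g <- seed_grid(seed_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(9, 10)), 1)
  vals <- matrix(seq(0, 100, length.out = 110), g$n1, g$n2) # uniform 0..100
  f <- structure(list(values = vals, flagged = matrix(FALSE, g$n1, g$n2),
                      grid = g, t_seed = 1000, t_origin = 0),
                 class = "ftle_field")
  l <- extract_lcs(f)
  expect_equal(l$p95, unname(quantile(vals, 0.95)), tolerance = 1e-12)
  expect_equal(l$p95, 95, tolerance = 0.1)
  expect_equal(l$mask, vals > 0.5 * l$p95)

  # constant positive field: c > 0.5 c everywhere
  f2 <- f
  f2$values[] <- 3
  expect_true(all(extract_lcs(f2)$mask))

  # non-positive normalization: empty mask with a warning
  f3 <- f
  f3$values[] <- 0
  expect_warning(l3 <- extract_lcs(f3), "empty")
  expect_false(any(l3$mask))
  # flagged seeds are excluded from normalization and mask
  f4 <- f
  f4$flagged[vals > 50] <- TRUE
  l4 <- extract_lcs(f4)
  expect_false(any(l4$mask & f4$flagged))
  expect_lt(l4$p95, 50)
})

annulus_mask <- function(g, r0, r1, ctr = NULL, gaps = NULL) {
  if (is.null(ctr)) ctr <- c(mean(range(g$positions[, 1])),
                             mean(range(g$positions[, 2])))
  x <- matrix(g$positions[, 1], g$n1, g$n2) - ctr[1]
  y <- matrix(g$positions[, 2], g$n1, g$n2) - ctr[2]
  r <- sqrt(x^2 + y^2)
  m <- r >= r0 & r <= r1
  if (!is.null(gaps)) {
    th <- atan2(y, x)
    for (gp in gaps) m[th > gp[1] & th < gp[2]] <- FALSE
  }
  m
}

test_that("closed ridge masks delineate without bridges; gapped ones bridge", {
  g <- seed_grid(seed_plane(c(-30, -30, 4), c(1, 0, 0), c(0, 1, 0), c(60, 60)),
                 0.8, t_seed = 100)
  full <- delineate_vortex(annulus_mask(g, 18, 22), g)
  expect_equal(attr(full, "n_bridges"), 0L)
  expect_equal(length(vortexlcs:::contour_polygons(full)), 1L)
  expect_equal(unique(full$z_mm), 4)
  a_full <- polygon_area(cbind(full$x_mm, full$y_mm))

  # three ~3-seed gaps: bridged straight, area within 2% of the gap-free one
  w <- 2.5 * 0.8 / 20 # angular width of a ~3-seed gap at r = 20
  gaps <- list(c(0, w), c(2, 2 + w), c(4, 4 + w))
  gapped <- delineate_vortex(annulus_mask(g, 18, 22, gaps = gaps), g)
  expect_gte(attr(gapped, "n_bridges"), 1L)
  a_gap <- polygon_area(cbind(gapped$x_mm, gapped$y_mm))
  expect_lt(abs(a_gap - a_full) / a_full, 0.02)
})

test_that("sub-floor specks yield an empty contour set", {
  g <- seed_grid(seed_plane(c(-30, -30, 0), c(1, 0, 0), c(0, 1, 0), c(60, 60)),
                 0.8, t_seed = 100)
  m <- matrix(FALSE, g$n1, g$n2)
  m[10:12, 10:12] <- TRUE
  m[60:62, 60:62] <- TRUE
  expect_warning(out <- delineate_vortex(m, g, area_floor = 50), "arc")
  expect_equal(nrow(out), 0L)
  expect_warning(delineate_vortex(matrix(FALSE, g$n1, g$n2), g), "empty")
})

test_that("delineation recovers a translating Hill vortex boundary within 5%", {
  a <- 25; U <- 30
  sp <- synthetic_flow_spec("hill_vortex", list(a = a, U = U,
                                                center = c(0, 0, -50)),
                            origin = c(-40.5, -40.5, -78),
                            spacing = c(3, 3, 3), dims = c(28, 28, 57),
                            time_points = seq(0, 350, 25))
  fld <- generate_field(sp)$field
  ctr_z <- -50 + 0.01 * U * 350
  pl <- seed_plane(c(-30, 0, ctr_z - 30), c(1, 0, 0), c(0, 0, 1), c(60, 60))
  g <- seed_grid(pl, 0.8, t_seed = 350)
  f <- compute_ftle(advect_backward(g, fld, t_origin = 25, step = 5), g)
  cs <- delineate_vortex(extract_lcs(f), g)
  r_eff <- sqrt(polygon_area(cbind(cs$x_mm, cs$z_mm)) / pi)
  expect_lt(abs(r_eff - a) / a, 0.05)
})

test_that("cropping to the endocardium clips and never grows regions", {
  mk <- function(label, xy, tf = 1L, si = 1L) {
    data.frame(label = label, timeframe = tf, slice_index = si,
               polygon_id = 1L, vertex_index = seq_len(nrow(xy)) - 1L,
               x_mm = xy[, 1], y_mm = xy[, 2], z_mm = 0)
  }
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  # LCS fully inside: unchanged area
  lcs <- contour_set(mk("lcs", sq(2, 2, 6)))
  endo <- contour_set(mk("endocardium", sq(0, 0, 20)))
  out <- crop_to_endocardium(lcs, endo)
  expect_equal(polygon_area(cbind(out$x_mm, out$y_mm)), 36)

  # half-overlapping 20 mm squares: area 200
  lcs2 <- contour_set(mk("lcs", sq(-10, 0, 20)))
  endo2 <- contour_set(mk("endocardium", sq(0, 0, 20)))
  out2 <- crop_to_endocardium(lcs2, endo2)
  expect_equal(polygon_area(cbind(out2$x_mm, out2$y_mm)), 200)

  # missing endocardium for the timeframe: skipped with a message
  lcs3 <- contour_set(mk("lcs", sq(0, 0, 5), tf = 9L))
  expect_message(out3 <- crop_to_endocardium(lcs3, endo2), "skipped")
  expect_equal(nrow(out3), 0L)
})

test_that("convex clipping agrees with a rasterization oracle on random pairs", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  rand_convex <- function(n = 8, scale = 30) {
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(1, 0.4, 1) * scale
    cbind(r * cos(th) + runif(1, -8, 8), r * sin(th) + runif(1, -8, 8))
  }
  for (i in 1:100) {
    A <- rand_convex(); B <- rand_convex()
    got <- clip_polygon_convex(A, B)
    a_got <- if (nrow(got) >= 3) polygon_area(got) else 0
    # oracle: midpoint rasterization with an independent point-in-polygon
    n <- 250
    xr <- range(c(A[, 1], B[, 1])); yr <- range(c(A[, 2], B[, 2]))
    gx <- seq(xr[1], xr[2], length.out = n)
    gy <- seq(yr[1], yr[2], length.out = n)
    pts <- cbind(rep(gx, n), rep(gy, each = n))
    ina <- mgcv::in.out(rbind(A, A[1, ]), pts)
    inb <- mgcv::in.out(rbind(B, B[1, ]), pts)
    cell <- diff(xr) / (n - 1) * diff(yr) / (n - 1)
    a_ref <- sum(ina & inb) * cell
    tol <- max(0.01 * max(a_ref, a_got), 4 * sqrt(max(a_ref, 1)) *
                 sqrt(cell)) # perimeter-dominated raster error floor
    expect_lt(abs(a_got - a_ref), max(tol, 1.5))
  }
})
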