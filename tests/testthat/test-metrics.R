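square_contours <- function(n_slices = 10, side = 10, thick = 8, tf = 1L) {
  rows <- lapply(seq_len(n_slices), function(s) {
    data.frame(label = "endocardium", timeframe = tf, slice_index = s,
               polygon_id = 1L, vertex_index = 0:3,
               x_mm = c(0, side, side, 0), y_mm = c(0, 0, side, side),
               z_mm = (s - 1) * thick)
  })
  contour_set(do.call(rbind, rows), slice_thickness = thick)
}

test_that("slice-summation volume sums area times thickness", {
  cs <- square_contours() # 10 slices x 100 mm^2 x 8 mm
  expect_equal(unname(slice_summation_volume(cs)), 8.0)
  expect_length(slice_summation_volume(contour_set()), 0L)
})

test_that("a digitized sphere's slice volume is within 3% of 4/3 pi r^3", {
  r <- 30; thick <- 8
  z <- seq(-r + thick / 2, r - thick / 2, by = thick)
  rows <- lapply(seq_along(z), function(s) {
    rs <- sqrt(r^2 - z[s]^2)
    xy <- ellipse_poly <- cbind(rs * cos(seq(0, 2 * pi, length.out = 181)[-181]),
                                rs * sin(seq(0, 2 * pi, length.out = 181)[-181]))
    data.frame(label = "lcs", timeframe = 1L, slice_index = s, polygon_id = 1L,
               vertex_index = seq_len(nrow(xy)) - 1L,
               x_mm = xy[, 1], y_mm = xy[, 2], z_mm = z[s])
  })
  cs <- contour_set(do.call(rbind, rows), slice_thickness = thick)
  vol <- unname(slice_summation_volume(cs))
  expect_lt(abs(vol - 4 / 3 * pi * r^3 / 1000) / (4 / 3 * pi * r^3 / 1000), 0.03)
})

test_that("overlapping polygons in one slice are unioned, not double-counted", {
  sq <- function(x0, s, id) data.frame(
    label = "lcs", timeframe = 1L, slice_index = 1L, polygon_id = id,
    vertex_index = 0:3, x_mm = c(x0, x0 + s, x0 + s, x0),
    y_mm = c(0, 0, s, s), z_mm = 0)
  cs <- contour_set(rbind(sq(0, 20, 1L), sq(10, 20, 2L)), slice_thickness = 10)
  expect_message(v <- slice_summation_volume(cs), "unioned")
  expect_equal(unname(v), 600 * 10 / 1000, tolerance = 0.01) # 30x20 union
})

test_that("sphere-equivalent wall distance follows the closed form", {
  expect_equal(vortex_wall_distance(100, 100), 0)
  expect_equal(vortex_wall_distance(150, 0), (3 * 150e3 / (4 * pi))^(1 / 3))
  d <- vortex_wall_distance(195, 100)
  d_oracle <- (3 * 195e3 / (4 * pi))^(1 / 3) - (3 * 100e3 / (4 * pi))^(1 / 3)
  expect_equal(d, d_oracle, tolerance = 1e-12)
  expect_equal(d, 7.18, tolerance = 0.01)
  expect_error(vortex_wall_distance(100, 150), "lv_volume")
  # monotone decreasing in vortex volume at fixed LV volume
  vv <- seq(0, 150, 10)
  expect_true(all(diff(vortex_wall_distance(rep(150, 16), vv)) < 0))
})

test_that("vortex volume fraction is a plain percentage with guarded input", {
  expect_equal(vortex_volume_fraction(100, 200), 50)
  expect_equal(vortex_volume_fraction(0, 200), 0)
  expect_error(vortex_volume_fraction(10, 0), "positive")
})

test_that("through-plane flow rate integrates velocity over the ROI", {
  # uniform 50 cm/s through a 20x20 mm ROI: 50 * 400 * 0.01 = 200 ml/s
  v <- array(0, dim = c(41, 41, 5, 3, 3))
  v[, , 3, , 3] <- 50
  fld <- velocity_field(v, c(1, 1, 1), origin = c(-20, -20, -2),
                        time_points = c(0, 50, 100))
  roi <- cbind(c(-9.5, 10.5, 10.5, -9.5), c(-9.5, -9.5, 10.5, 10.5))
  pr <- through_plane_flow_profile(fld, 0, roi)
  expect_equal(pr$flow_ml_s, rep(200, 3))
  expect_equal(pr$peak_velocity_cm_s, rep(50, 3))

  v0 <- fld; v0$v[] <- 0
  expect_equal(through_plane_flow_profile(v0, 0, roi)$flow_ml_s, rep(0, 3))
  expect_error(through_plane_flow_profile(fld, 0, cbind(c(100, 101, 100.5),
                                                        c(0, 0, 1))), "ROI")
})

test_that("the synthetic E-wave peak is recovered within one frame and 2%", {
  sv <- synthetic_ventricle()
  tr <- sv$truth
  pr <- through_plane_flow_profile(sv$field, tr$orifice$slice_z,
                                   tr$orifice$roi)
  ipk <- which.max(abs(pr$flow_ml_s))
  expect_lte(abs(pr$time_ms[ipk] - tr$e_peak$time_ms),
             diff(pr$time_ms[1:2])) # within one timeframe
  vpk <- max(abs(pr$peak_velocity_cm_s))
  expect_lt(abs(vpk - tr$e_peak$velocity_cm_s) / tr$e_peak$velocity_cm_s, 0.02)
  expect_equal(detect_e_wave_onset(pr), tr$e_onset_ms)
})

test_that("mitral effective diameter comes from the smallest flow area", {
  # circular plug jet of radius 12.5 mm at 1 mm pixels: diameter ~ 25 mm
  v <- array(0, dim = c(61, 61, 5, 3, 3))
  xs <- seq(-30, 30, 1)
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  jet <- ifelse(rr <= 12.5, 60, 0)
  v[, , 2, 2, 3] <- jet # widest at one slice
  v[, , 3, 2, 3] <- ifelse(rr <= 14, 60, 0)
  fld <- velocity_field(v, c(1, 1, 4), origin = c(-30, -30, -4),
                        time_points = c(0, 50, 100))
  roi <- cbind(c(-20, 20, 20, -20), c(-20, -20, 20, 20))
  got <- mitral_effective_diameter(fld, slice_z = c(0, 4), roi)
  expect_equal(got$slice_z, 0) # the smaller of the two flow areas
  expect_equal(got$diameter_mm, 25, tolerance = 0.02)
  expect_equal(got$timeframe, 2L)

  # elliptic profile, semi-axes 10 x 15 mm: 2 sqrt(A/pi) = 24.49 mm
  v2 <- array(0, dim = c(61, 61, 3, 3, 3))
  ell <- outer(xs^2 / 100, xs^2 / 225, "+") <= 1
  v2[, , 2, 2, 3] <- ifelse(ell, 60, 0)
  fld2 <- velocity_field(v2, c(1, 1, 4), origin = c(-30, -30, -4),
                         time_points = c(0, 50, 100))
  got2 <- mitral_effective_diameter(fld2, 0, roi)
  expect_equal(got2$diameter_mm, 2 * sqrt(pi * 10 * 15 / pi), tolerance = 0.02)

  expect_error(mitral_effective_diameter(fld, 0, roi, flow_threshold = 500),
               "threshold")
})

test_that("LCS diameters and their ratio are effective-circle based", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  r <- sqrt(707 / pi) # area 707 mm^2 -> diameter 30 mm
  df <- data.frame(label = "lcs", timeframe = 1L, slice_index = 1L,
                   polygon_id = 1L, vertex_index = seq_along(th) - 1L,
                   x_mm = r * cos(th), y_mm = r * sin(th), z_mm = 0)
  cs <- contour_set(df)
  expect_equal(max_lcs_diameter(cs), 30, tolerance = 0.01)
  expect_equal(diameter_ratio(30, 25), 1.2)
  expect_error(diameter_ratio(30, 0), "positive")
  expect_error(max_lcs_diameter(contour_set()), "empty")

  # invariance to vertex ordering and in-plane rotation
  rot <- 0.7
  df2 <- df
  df2$x_mm <- r * cos(th + rot); df2$y_mm <- r * sin(th + rot)
  df2 <- df2[rev(seq_len(nrow(df2))), ]
  df2$vertex_index <- seq_along(th) - 1L
  expect_equal(max_lcs_diameter(contour_set(df2)), max_lcs_diameter(cs),
               tolerance = 1e-10)
})

test_that("vortex formation ratio is 4V / (pi D^3)", {
  expect_equal(vortex_formation_ratio(21.991, 20), 3.5, tolerance = 1e-3)
  expect_equal(vortex_formation_ratio(0, 20), 0)
  expect_equal(vortex_formation_ratio(2 * 21.991, 20),
               2 * vortex_formation_ratio(21.991, 20))
  expect_error(vortex_formation_ratio(10, 0), "positive")
})

test_that("peak filling rate is the maximal central-difference volume slope", {
  t <- seq(0, 900, 100)
  vol <- 100 + 50 * sin(t / 900 * pi)
  pfr <- peak_filling_rate(vol, t)
  # analytic maximum slope of the volume curve: 50 pi / 0.9 ml/s
  expect_equal(pfr, 50 * pi / 0.9, tolerance = 0.05)
  expect_equal(peak_filling_rate(c(0, 10), c(0, 100)), 100)
})

test_that("metrics tables enforce the cropped-volume and percentage bounds", {
  mt <- metrics_table("s1", lv_volume_ml = c(100, 120, 140),
                      vortex_volume_ml = c(20, 150, 70),
                      time_ms = c(0, 100, 200),
                      scalars = list(vfr = 3.1))
  expect_true(all(mt$vv_percent >= 0 & mt$vv_percent <= 100))
  expect_true(all(mt$vortex_volume_ml <= mt$lv_volume_ml))
  expect_equal(mt$vfr, rep(3.1, 3))
})
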