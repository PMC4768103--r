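# Field builders shared by the preprocessing and acceptance suites.

make_shelled_hill <- function() {
  # Hill vortex zeroed outside r = 20 mm so that a border shell is truly
  # static flow, with a known first-order plane injected on component 1
  fld <- make_model_field("hill_vortex", list(a = 15, U = 30),
                          half = 45, times = c(0, 50, 100))$field
  d <- dim(fld$v)
  xs <- seq(-45, 45, 3)
  gx <- rep(xs, times = 31 * 31)
  gy <- rep(rep(xs, each = 31), times = 31)
  gz <- rep(xs, each = 31 * 31)
  rr <- array(sqrt(gx^2 + gy^2 + gz^2), d[1:3])
  plane <- array(1 + 0.05 * gx - 0.02 * gy, d[1:3])
  truth <- fld
  for (t in 1:3) for (c in 1:3) {
    vol <- fld$v[, , , t, c]
    vol[rr > 20] <- 0
    truth$v[, , , t, c] <- vol
    fld$v[, , , t, c] <- vol + if (c == 1) plane else 0
  }
  shell <- rr > 36
  list(field = fld, truth = truth, shell = shell,
       plane_coef = c(0.05, -0.02, 0), gx = gx, gy = gy, gz = gz)
}

smooth_jet_field <- function(peak_frac, venc = 100) {
  # spatially smooth jet, temporally ramped from rest (as an E-wave builds)
  spec <- synthetic_flow_spec("uniform", list(c = c(0, 0, 0)),
                              origin = c(-30, -30, -30), spacing = c(3, 3, 3),
                              dims = c(21, 21, 21),
                              time_points = seq(0, 150, 50))
  fld <- generate_field(spec)$field
  g <- expand.grid(x = seq(-30, 30, 3), y = seq(-30, 30, 3),
                   z = seq(-30, 30, 3))
  jet <- peak_frac * venc *
    exp(-(g$x^2 + g$y^2) / (2 * 10^2)) * exp(-g$z^2 / (2 * 15^2))
  ramp <- c(0.3, 0.6, 1.0, 0.8)
  for (t in 1:4) fld$v[, , , t, 3] <- array(ramp[t] * jet, c(21, 21, 21))
  fld$venc <- venc
  fld
}

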