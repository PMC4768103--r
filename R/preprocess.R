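# Phase background correction, velocity-aliasing unwrapping, and space-time
# sampling of the velocity field.

#' Correct background phase offsets
#'
#' Fits, per timeframe and velocity component, a first-order polynomial
#' `c0 + cx*x + cy*y + cz*z` (world mm, centered on the volume centroid for
#' conditioning) to the velocities of stationary-tissue voxels by least
#' squares, and subtracts the fitted plane from the whole volume. After
#' correction the masked-voxel mean is ~0 for every frame and component.
#'
#' @param field a `velocity_field`.
#' @param mask a `stationary_mask` on the same grid (>= 10 voxels, not
#'   collinear).
#' @return list with `field` (corrected `velocity_field`) and `model` (class
#'   `background_model`: coefficient array `nt x 3 x 4` in cm/s and cm/s/mm
#'   about the recorded centroid, plus per-fit residual RMS).
#' @export
correct_background_phase <- function(field, mask) {
  validate_velocity_field(field)
  if (!inherits(mask, "stationary_mask")) mask <- stationary_mask(mask, field)
  d <- dim(field$v)
  if (!all(dim(mask)[1:3] == d[1:3]))
    stop("mask dimensions do not match the velocity grid")

  xs <- axis_coords(field, 1); ys <- axis_coords(field, 2); zs <- axis_coords(field, 3)
  centroid <- c(mean(range(xs)), mean(range(ys)), mean(range(zs)))
  idx <- which(mask)
  ai <- arrayInd(idx, d[1:3])
  X <- cbind(1, xs[ai[, 1]] - centroid[1], ys[ai[, 2]] - centroid[2],
             zs[ai[, 3]] - centroid[3])
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("degenerate stationary mask geometry: background fit is rank-deficient")

  # full-volume design evaluated once
  gx <- rep(xs, times = d[2] * d[3]) - centroid[1]
  gy <- rep(rep(ys, each = d[1]), times = d[3]) - centroid[2]
  gz <- rep(zs, each = d[1] * d[2]) - centroid[3]

  nt <- d[4]
  coef <- array(NA_real_, dim = c(nt, 3, 4),
                dimnames = list(NULL, c("vx", "vy", "vz"), c("c0", "cx", "cy", "cz")))
  rms <- matrix(NA_real_, nt, 3)
  out <- field
  for (t in seq_len(nt)) {
    for (c in 1:3) {
      vol <- field$v[, , , t, c]
      b <- qr.coef(qrX, vol[idx])
      fit_mask <- X %*% b
      coef[t, c, ] <- b
      rms[t, c] <- sqrt(mean((vol[idx] - fit_mask)^2))
      plane <- b[1] + b[2] * gx + b[3] * gy + b[4] * gz
      out$v[, , , t, c] <- vol - array(plane, dim = d[1:3])
    }
  }
  model <- structure(list(coefficients = coef, residual_rms = rms,
                          centroid = centroid), class = "background_model")
  list(field = out, model = model)
}

# vectorized median of the 6 face-neighbor volumes (edge-replicated),
# via a sorting network of pmin/pmax exchanges
shift_vol <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  idx[[axis]] <- i
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

neighbor_median6 <- function(vol) {
  cols <- list(shift_vol(vol, 1, -1L), shift_vol(vol, 1, 1L),
               shift_vol(vol, 2, -1L), shift_vol(vol, 2, 1L),
               shift_vol(vol, 3, -1L), shift_vol(vol, 3, 1L))
  # bubble sorting network over the 6 slots
  for (pass in 1:5) {
    for (i in 1:(6 - pass)) {
      lo <- pmin(cols[[i]], cols[[i + 1]])
      hi <- pmax(cols[[i]], cols[[i + 1]])
      cols[[i]] <- lo; cols[[i + 1]] <- hi
    }
  }
  (cols[[3]] + cols[[4]]) / 2
}

#' Unwrap velocity aliasing
#'
#' Voxels whose value differs from a local reference by more than VENC are
#' shifted by `+/- 2 * venc` toward the reference. Two references are used
#' in turn within each sweep: first a sequential temporal reference (each
#' frame against the already-corrected previous frame — aliased jets build
#' up from below VENC over the cycle, so the first frame anchors the
#' recursion), then the spatial median of the 6 face neighbors, which
#' resolves spatially isolated wraps. Sweeps iterate to a fixed point, up to
#' `max_iters`.
#'
#' A declarative override list stands in for the interactive part of
#' semiautomatic unwrapping: each row forces a voxel/timeframe/component by a
#' given number of wraps before the automatic passes run.
#'
#' @param field a `velocity_field` with `venc` set.
#' @param max_iters sweep cap (default 10).
#' @param manual_overrides optional data frame with columns `i, j, k, t,
#'   component, n_wraps` (1-based voxel indices; `n_wraps` signed).
#' @return the unwrapped `velocity_field`, with attributes `n_changed`
#'   (voxels changed per sweep) and `converged`.
#' @export
unwrap_velocity <- function(field, max_iters = 10L, manual_overrides = NULL) {
  validate_velocity_field(field)
  if (is.null(field$venc))
    stop("unwrap_velocity requires venc to be set on the field")
  venc <- field$venc
  d <- dim(field$v)
  v <- field$v

  # manual overrides are declarative truth: apply them first and freeze the
  # voxels against the automatic passes
  frozen <- array(FALSE, dim = d)
  if (!is.null(manual_overrides) && nrow(manual_overrides) > 0) {
    mo <- manual_overrides
    for (r in seq_len(nrow(mo))) {
      v[mo$i[r], mo$j[r], mo$k[r], mo$t[r], mo$component[r]] <-
        v[mo$i[r], mo$j[r], mo$k[r], mo$t[r], mo$component[r]] +
        2 * venc * mo$n_wraps[r]
      frozen[mo$i[r], mo$j[r], mo$k[r], mo$t[r], mo$component[r]] <- TRUE
    }
  }

  n_changed <- integer(0)
  converged <- FALSE
  for (iter in seq_len(max_iters)) {
    changed <- 0L
    # temporal pass: each frame against the corrected previous frame
    if (d[4] >= 2) {
      for (c in 1:3) {
        for (t in 2:d[4]) {
          vol <- v[, , , t, c]
          dlt <- vol - v[, , , t - 1L, c]
          # single-wrap consistency: a wrapped value has the opposite sign
          # of its true value, so only shift against the stored sign
          wrap <- ((dlt > venc & vol > 0) | (dlt < -venc & vol < 0)) &
            !frozen[, , , t, c]
          if (any(wrap)) {
            vol[wrap] <- vol[wrap] - 2 * venc * sign(dlt[wrap])
            v[, , , t, c] <- vol
            changed <- changed + sum(wrap)
          }
        }
      }
    }
    # spatial pass: median of the 6 face neighbors
    for (t in seq_len(d[4])) {
      for (c in 1:3) {
        vol <- v[, , , t, c]
        ref <- neighbor_median6(vol)
        dlt <- vol - ref
        wrap <- ((dlt > venc & vol > 0) | (dlt < -venc & vol < 0)) &
          !frozen[, , , t, c]
        if (any(wrap)) {
          vol[wrap] <- vol[wrap] - 2 * venc * sign(dlt[wrap])
          v[, , , t, c] <- vol
          changed <- changed + sum(wrap)
        }
      }
    }
    n_changed <- c(n_changed, changed)
    if (changed == 0L) { converged <- TRUE; break }
  }
  if (!converged && sum(tail(n_changed, 1)) > 0)
    warning("unwrap_velocity did not reach a fixed point within ",
            max_iters, " sweeps; result is partial")
  out <- field
  out$v <- v
  attr(out, "n_changed") <- n_changed
  attr(out, "converged") <- converged
  out
}

#' Sample the velocity field at arbitrary positions and time
#'
#' Trilinear interpolation in space and linear interpolation in time,
#' realizing on-demand linear space-time upsampling of the acquired field.
#' Positions outside the voxel-center hull return the zero vector and are
#' flagged out-of-domain; times must lie within the acquired span.
#'
#' @param field a `velocity_field`.
#' @param positions n x 3 matrix of world positions, mm.
#' @param time query time, ms (scalar, within the acquired span).
#' @return list with `v` (n x 3 velocities, cm/s) and `out_of_domain`
#'   (logical n).
#' @export
sample_velocity <- function(field, positions, time) {
  validate_velocity_field(field)
  positions <- matrix(as.numeric(positions), ncol = 3)
  tp <- field$time_points
  if (time < tp[1] - 1e-9 || time > tp[length(tp)] + 1e-9)
    stop("query time ", time, " ms outside the acquired span [",
         tp[1], ", ", tp[length(tp)], "] ms")
  res <- sample_velocity_cpp(as.numeric(field$v), as.integer(dim(field$v)),
                             field$spacing, field$origin, tp, positions, time)
  res
}

#' Derive a stationary-tissue mask from temporal variation
#'
#' Convenience helper (not part of the measurement method): marks voxels
#' whose velocity magnitude stays below `threshold` across all timeframes as
#' stationary.
#'
#' @param field a `velocity_field`.
#' @param threshold speed ceiling, cm/s (default 2).
#' @return a `stationary_mask`.
#' @export
stationary_mask_from_sd <- function(field, threshold = 2) {
  validate_velocity_field(field)
  speed <- sqrt(field$v[, , , , 1]^2 + field$v[, , , , 2]^2 + field$v[, , , , 3]^2)
  m <- apply(speed, 1:3, max) < threshold
  stationary_mask(m, field)
}
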