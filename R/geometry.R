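#' Signed and absolute polygon area (shoelace formula)
#'
#' Vertices are implicitly closed: the last vertex connects back to the first.
#' The signed area is positive for counter-clockwise orientation.
#'
#' @param xy numeric matrix with two columns (x, y), mm.
#' @param signed return the signed area instead of its absolute value.
#' @return area in mm^2.
#' @export
polygon_area <- function(xy, signed = FALSE) {
  xy <- drop_closing_vertex(as.matrix(xy))
  if (nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- sum(x * y2 - x2 * y) / 2
  if (signed) a else abs(a)
}

# remove an explicit repeated closing vertex, if present
drop_closing_vertex <- function(xy) {
  n <- nrow(xy)
  if (n >= 2 && all(abs(xy[1, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  xy
}

#' Polygon centroid (area-weighted)
#' @param xy two-column vertex matrix, implicitly closed.
#' @return length-2 centroid; falls back to the vertex mean for degenerate
#'   (zero-area) polygons.
#' @export
polygon_centroid <- function(xy) {
  xy <- drop_closing_vertex(as.matrix(xy))
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Test points for inclusion in a polygon
#'
#' Crossing-number (even-odd) rule; points exactly on an edge are treated as
#' inside up to floating-point tolerance.
#'
#' @param pts n x 2 matrix of query points.
#' @param poly polygon vertex matrix, implicitly closed.
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- drop_closing_vertex(as.matrix(poly))
  nv <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- poly[c(2:nv, 1), 1]; qy <- poly[c(2:nv, 1), 2]
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  for (e in seq_len(nv)) {
    crosses <- ((py[e] > y) != (qy[e] > y))
    if (any(crosses)) {
      xin <- px[e] + (y[crosses] - py[e]) * (qx[e] - px[e]) / (qy[e] - py[e])
      flip <- x[crosses] < xin
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# orientation helpers -------------------------------------------------------

ensure_ccw <- function(xy) {
  xy <- drop_closing_vertex(as.matrix(xy))
  if (polygon_area(xy, signed = TRUE) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy
}

#' Clip a polygon to a convex region (Sutherland-Hodgman)
#'
#' Clips `subject` against the convex polygon `clip`. The subject polygon may
#' be arbitrary; the clip polygon must be convex (endocardial cross-sections
#' in this package are). Returns a vertex matrix, possibly with zero rows when
#' the polygons do not overlap.
#'
#' @param subject vertex matrix (implicitly closed), mm.
#' @param clip convex vertex matrix (implicitly closed), mm.
#' @return clipped vertex matrix (implicitly closed, no repeated last vertex).
#' @export
clip_polygon_convex <- function(subject, clip) {
  out <- ensure_ccw(subject)
  clip <- ensure_ccw(clip)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # cross((b-a),(p-a)) >= 0 means p lies inside this (ccw) clip edge
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    keep <- side >= -1e-12
    newv <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      p <- out[i, ]; q <- out[j, ]
      pin <- keep[i]; qin <- keep[j]
      if (pin) newv <- rbind(newv, p)
      if (pin != qin) {
        # intersection of segment pq with clip edge line
        d1 <- side[i]; d2 <- side[j]
        t <- d1 / (d1 - d2)
        newv <- rbind(newv, p + t * (q - p))
      }
    }
    out <- newv
  }
  if (nrow(out) > 0) rownames(out) <- NULL
  out
}

#' Effective (equal-area circle) diameter of a polygon
#' @param area_mm2 enclosed area, mm^2.
#' @return diameter in mm of the circle with the same area.
#' @export
effective_diameter <- function(area_mm2) {
  stopifnot(all(area_mm2 >= 0))
  2 * sqrt(area_mm2 / pi)
}

# regular n-gon approximation of an ellipse, used by the synthetic generator
ellipse_polygon <- function(cx, cy, rx, ry, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# union area of possibly-overlapping polygons in one plane, by midpoint
# rasterization over the joint bounding box (resolution `n` per axis)
polygon_union_area <- function(polys, n = 256L) {
  if (length(polys) == 0) return(0)
  if (length(polys) == 1) return(polygon_area(polys[[1]]))
  bb <- do.call(rbind, lapply(polys, function(p) {
    p <- as.matrix(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }))
  x0 <- min(bb[, 1]); x1 <- max(bb[, 2]); y0 <- min(bb[, 3]); y1 <- max(bb[, 4])
  dx <- (x1 - x0) / n; dy <- (y1 - y0) / n
  if (dx <= 0 || dy <= 0) return(0)
  gx <- x0 + (seq_len(n) - 0.5) * dx
  gy <- y0 + (seq_len(n) - 0.5) * dy
  pts <- cbind(rep(gx, times = n), rep(gy, each = n))
  inside <- rep(FALSE, nrow(pts))
  for (p in polys) inside <- inside | point_in_polygon(pts, p)
  sum(inside) * dx * dy
}
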