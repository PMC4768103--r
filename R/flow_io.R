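#' @useDynLib vortexlcs, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile median rnorm lm pt var wilcox.test sd setNames coef
#' @importFrom utils read.csv write.csv head tail modifyList packageVersion
NULL

# Unit conventions, fixed package-wide: positions mm, time ms, velocity cm/s.
# Conversion happens at the I/O boundary only (see read_velocity_field()).

#' Construct a time-resolved 3-component velocity field
#'
#' The core data container of the package: a 5-D array of velocities on a
#' regular grid, one volume per timeframe and velocity component, together
#' with the physical metadata needed for particle advection.
#'
#' @param v numeric array with dim `(nx, ny, nz, nt, 3)`, cm/s.
#' @param spacing per-axis voxel spacing, mm (length 3, all > 0).
#' @param origin world coordinate of voxel `(0,0,0)`'s center, mm.
#' @param time_points timeframe times from the R-wave, ms; strictly
#'   increasing, at least 2 frames.
#' @param venc optional velocity-encoding limit, cm/s.
#' @param cycle_length optional cardiac cycle length, ms.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(v, spacing, origin = c(0, 0, 0), time_points,
                           venc = NULL, cycle_length = NULL) {
  x <- structure(list(v = v, spacing = as.numeric(spacing),
                      origin = as.numeric(origin),
                      time_points = as.numeric(time_points),
                      venc = if (is.null(venc)) NULL else as.numeric(venc),
                      cycle_length = if (is.null(cycle_length)) NULL else as.numeric(cycle_length)),
                 class = "velocity_field")
  validate_velocity_field(x)
  x
}

#' Validate a velocity field
#'
#' Checks the grid regularity and metadata invariants: positive uniform
#' spacing, strictly increasing time points (>= 2 frames), finite velocities,
#' and the sanity bound `|v| <= 10 * venc` when a VENC is declared.
#'
#' @param x a `velocity_field`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_velocity_field <- function(x) {
  stopifnot(inherits(x, "velocity_field"))
  d <- dim(x$v)
  if (length(d) != 5L || d[5] != 3L)
    stop("velocity array must have dim (nx, ny, nz, nt, 3)")
  if (length(x$spacing) != 3L || any(!is.finite(x$spacing)) || any(x$spacing <= 0))
    stop("grid spacing must be three positive finite values (mm)")
  if (length(x$origin) != 3L || any(!is.finite(x$origin)))
    stop("grid origin must be three finite values (mm)")
  nt <- d[4]
  if (length(x$time_points) != nt)
    stop("length(time_points) must equal the number of timeframes")
  if (nt < 2L) stop("at least 2 timeframes are required")
  if (any(diff(x$time_points) <= 0))
    stop("time_points must be strictly increasing")
  if (anyNA(x$v) || any(!is.finite(range(x$v))))
    stop("all velocity values must be finite")
  if (!is.null(x$venc)) {
    if (x$venc <= 0) stop("venc must be positive (cm/s)")
    if (max(abs(range(x$v))) > 10 * x$venc)
      stop("velocity magnitudes exceed 10 * venc; corrupt data or wrong units")
  }
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d timeframes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm; t = %.1f..%.1f ms%s\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              x$time_points[1], x$time_points[length(x$time_points)],
              if (is.null(x$venc)) "" else sprintf("; venc %.0f cm/s", x$venc)))
  invisible(x)
}

# world coordinates of voxel centers along one axis (1-based array index)
axis_coords <- function(field, axis) {
  n <- dim(field$v)[axis]
  field$origin[axis] + (seq_len(n) - 1) * field$spacing[axis]
}

#' Construct a stationary-tissue mask
#'
#' Boolean mask on the same voxel grid as a velocity field, marking voxels of
#' static tissue used to fit the phase background model. At least 10 voxels
#' must be marked so the 4-coefficient fit is overdetermined.
#'
#' @param mask logical array with dim `(nx, ny, nz)`.
#' @param field optional `velocity_field` to check grid congruence against.
#' @return object of class `stationary_mask`.
#' @export
stationary_mask <- function(mask, field = NULL) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D logical array")
  if (sum(mask) < 10L) stop("stationary mask must contain at least 10 voxels")
  if (!is.null(field) && !all(dim(mask) == dim(field$v)[1:3]))
    stop("mask dimensions do not match the velocity grid")
  structure(mask, class = c("stationary_mask", class(mask)))
}

#' Subject acquisition metadata
#'
#' Carries the per-subject covariates (group, heart rate, slice thickness)
#' used by the statistics module.
#'
#' @param subject_id character scalar.
#' @param group `"control"` or `"patient"`.
#' @param heart_rate_bpm heart rate, beats/min, > 0.
#' @param slice_thickness_mm short-axis slice thickness, mm.
#' @return a list of class `acquisition_meta`.
#' @export
acquisition_meta <- function(subject_id, group = c("control", "patient"),
                             heart_rate_bpm, slice_thickness_mm = 8) {
  group <- match.arg(group)
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop("heart rate must be positive")
  structure(list(subject_id = as.character(subject_id), group = group,
                 heart_rate_bpm = heart_rate_bpm,
                 slice_thickness_mm = slice_thickness_mm),
            class = "acquisition_meta")
}

# ---------------------------------------------------------------------------
# contour sets

#' Construct a contour set
#'
#' Closed planar polygons per (slice, timeframe), used for LCS delineations,
#' endocardial borders and flow-profile ROIs. Polygons are implicitly closed
#' (the last vertex connects back to the first) and stored in world mm.
#'
#' @param df data frame with columns `label`, `timeframe`, `slice_index`,
#'   `polygon_id`, `vertex_index`, `x_mm`, `y_mm`, `z_mm`.
#' @param slice_thickness slice thickness, mm.
#' @param normal slice normal (default short-axis, z).
#' @return object of class `contour_set` (a data frame with attributes).
#' @export
contour_set <- function(df = empty_contour_df(), slice_thickness = 8,
                        normal = c(0, 0, 1)) {
  need <- c("label", "timeframe", "slice_index", "polygon_id", "vertex_index",
            "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("contour data frame must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$label <- as.character(df$label)
  x <- structure(df, slice_thickness = as.numeric(slice_thickness),
                 normal = as.numeric(normal),
                 class = c("contour_set", "data.frame"))
  validate_contour_set(x)
  x
}

empty_contour_df <- function() {
  data.frame(label = character(), timeframe = integer(), slice_index = integer(),
              polygon_id = integer(), vertex_index = integer(),
              x_mm = numeric(), y_mm = numeric(), z_mm = numeric())
}

#' Validate a contour set
#'
#' Each polygon must have at least 3 distinct vertices; the labels must come
#' from the closed set `lcs`, `endocardium`, `roi`; slice thickness positive.
#'
#' @param x a `contour_set`.
#' @return `x`, invisibly.
#' @export
validate_contour_set <- function(x) {
  stopifnot(inherits(x, "contour_set"))
  if (attr(x, "slice_thickness") <= 0) stop("slice_thickness must be > 0")
  if (nrow(x) > 0) {
    if (!all(x$label %in% c("lcs", "endocardium", "roi")))
      stop("contour labels must be one of: lcs, endocardium, roi")
    key <- interaction(x$label, x$timeframe, x$slice_index, x$polygon_id, drop = TRUE)
    for (k in levels(key)) {
      vv <- x[key == k, c("x_mm", "y_mm")]
      if (nrow(unique(vv)) < 3L)
        stop("polygon ", k, " has fewer than 3 distinct vertices")
    }
  }
  invisible(x)
}

# iterate polygons of a contour set; returns list of entries with metadata
contour_polygons <- function(cs, label = NULL, timeframe = NULL, slice_index = NULL) {
  df <- cs
  if (!is.null(label)) df <- df[df$label %in% label, , drop = FALSE]
  if (!is.null(timeframe)) df <- df[df$timeframe %in% timeframe, , drop = FALSE]
  if (!is.null(slice_index)) df <- df[df$slice_index %in% slice_index, , drop = FALSE]
  if (nrow(df) == 0) return(list())
  sp <- split(df, interaction(df$label, df$timeframe, df$slice_index,
                              df$polygon_id, drop = TRUE))
  lapply(sp, function(d) {
    d <- d[order(d$vertex_index), ]
    list(label = d$label[1], timeframe = d$timeframe[1],
         slice_index = d$slice_index[1], polygon_id = d$polygon_id[1],
         xy = cbind(d$x_mm, d$y_mm), z = d$z_mm[1])
  })
}

# assemble a contour_set from a list of polygon entries (as contour_polygons)
contours_from_polygons <- function(polys, slice_thickness = 8) {
  if (length(polys) == 0) return(contour_set(slice_thickness = slice_thickness))
  df <- do.call(rbind, lapply(polys, function(p) {
    n <- nrow(p$xy)
    data.frame(label = p$label, timeframe = p$timeframe,
               slice_index = p$slice_index, polygon_id = p$polygon_id,
               vertex_index = seq_len(n) - 1L,
               x_mm = p$xy[, 1], y_mm = p$xy[, 2],
               z_mm = if (length(p$z) == 1) rep(p$z, n) else p$z)
  }))
  rownames(df) <- NULL
  contour_set(df, slice_thickness = slice_thickness)
}

#' Write / read contour sets as CSV
#'
#' Plain CSV with one row per vertex and a `#`-prefixed header line carrying
#' the slice thickness; loss-free up to the printed precision (15 significant
#' digits).
#'
#' @param x a `contour_set`.
#' @param path output file.
#' @return `write_contours`: the path, invisibly. `read_contours`: a
#'   `contour_set`.
#' @export
write_contours <- function(x, path) {
  stopifnot(inherits(x, "contour_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vortexlcs contours; slice_thickness_mm=%.6f", attr(x, "slice_thickness")), con)
  df <- as.data.frame(x)
  for (col in c("x_mm", "y_mm", "z_mm")) df[[col]] <- sprintf("%.9f", df[[col]])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty contour file: ", path)
  thick <- 8
  if (startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("slice_thickness_mm=([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) thick <- as.numeric(m[2])
  }
  df <- tryCatch(
    read.csv(text = lines, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed contour file '", path, "': ", conditionMessage(e))
  )
  need <- c("label", "timeframe", "slice_index", "polygon_id", "vertex_index",
            "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("contour file '", path, "' lacks required columns")
  for (col in c("x_mm", "y_mm", "z_mm")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("contour file '", path, "': non-numeric ", col, " at data line ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  contour_set(df, slice_thickness = thick)
}

# ---------------------------------------------------------------------------
# velocity field I/O: two open dialects

#' Write / read velocity fields
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{archive}{a single RDS file holding the 5-D array plus all metadata;
#'     bit-exact round trip.}
#'   \item{nifti}{one NIfTI volume per velocity component
#'     (`<prefix>_vx.nii.gz`, `_vy`, `_vz`; each `nx x ny x nz x nt`) plus a
#'     JSON sidecar `<prefix>.json` declaring spacing, origin, timing, VENC
#'     and velocity units.}
#' }
#' Velocities are converted to cm/s on read according to the sidecar's
#' declared units (`cm/s`, `m/s` or `mm/s`).
#'
#' @param field a `velocity_field`.
#' @param path archive file path (`.rds`) or NIfTI path prefix.
#' @param format `"archive"` or `"nifti"`.
#' @return `write_velocity_field`: the path(s), invisibly.
#'   `read_velocity_field`: a validated `velocity_field`.
#' @export
write_velocity_field <- function(field, path, format = c("archive", "nifti")) {
  format <- match.arg(format)
  validate_velocity_field(field)
  if (format == "archive") {
    saveRDS(list(dialect = "vortexlcs-archive-v1", v = field$v,
                 spacing = field$spacing, origin = field$origin,
                 time_points = field$time_points, venc = field$venc,
                 cycle_length = field$cycle_length), path)
    return(invisible(path))
  }
  comp <- c("vx", "vy", "vz")
  files <- sprintf("%s_%s.nii.gz", path, comp)
  for (c in 1:3) {
    img <- RNifti::asNifti(field$v[, , , , c, drop = TRUE],
                           pixdim = c(field$spacing, 1))
    RNifti::writeNifti(img, files[c], datatype = "double")
  }
  sidecar <- sprintf("%s.json", path)
  jsonlite::write_json(list(spacing_mm = field$spacing, origin_mm = field$origin,
                            time_points_ms = field$time_points,
                            venc_cm_s = field$venc,
                            cycle_length_ms = field$cycle_length,
                            velocity_units = "cm/s"),
                       sidecar, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(c(files, sidecar))
}

#' @rdname write_velocity_field
#' @param components for `format = "nifti"`, optional explicit character
#'   vector of the three component files (x, y, z order); defaults to
#'   `<prefix>_vx.nii.gz` etc.
#' @param sidecar optional explicit sidecar path.
#' @export
read_velocity_field <- function(path, format = c("archive", "nifti"),
                                components = NULL, sidecar = NULL) {
  format <- match.arg(format)
  if (format == "archive") {
    obj <- readRDS(path)
    if (!identical(obj$dialect, "vortexlcs-archive-v1"))
      stop("not a vortexlcs archive: ", path)
    return(velocity_field(obj$v, obj$spacing, obj$origin, obj$time_points,
                          obj$venc, obj$cycle_length))
  }
  if (is.null(components))
    components <- sprintf("%s_%s.nii.gz", path, c("vx", "vy", "vz"))
  if (is.null(sidecar)) sidecar <- sprintf("%s.json", path)
  if (!all(file.exists(components)))
    stop("missing component file(s): ",
         paste(components[!file.exists(components)], collapse = ", "))
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$time_points_ms) || is.null(meta$spacing_mm))
    stop("sidecar lacks timing or spacing metadata: ", sidecar)
  vols <- lapply(components, function(f) {
    a <- as.array(RNifti::readNifti(f))
    if (length(dim(a)) == 3L) a <- array(a, dim = c(dim(a), 1L))
    a
  })
  dims <- vapply(vols, function(a) paste(dim(a), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    stop("component volumes have mismatched dimensions: ",
         paste(dims, collapse = " vs "))
  d <- dim(vols[[1]])
  v <- array(0, dim = c(d, 3L))
  for (c in 1:3) v[, , , , c] <- vols[[c]]
  units <- if (is.null(meta$velocity_units)) "cm/s" else meta$velocity_units
  scale <- switch(units, "cm/s" = 1, "m/s" = 100, "mm/s" = 0.1,
                  stop("unknown velocity units in sidecar: ", units))
  v <- v * scale
  venc <- meta$venc_cm_s
  if (length(venc) == 0) venc <- NULL
  cl <- meta$cycle_length_ms
  if (length(cl) == 0) cl <- NULL
  origin <- if (is.null(meta$origin_mm)) c(0, 0, 0) else meta$origin_mm
  velocity_field(v, meta$spacing_mm, origin, meta$time_points_ms, venc, cl)
}
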