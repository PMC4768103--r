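# Pipeline orchestration: synth -> preprocess -> ftle/delineate -> metrics
# -> stats, driven by a YAML config, with plain-file stage outputs so any
# intermediate (e.g. contours) can be inspected or edited and re-run.

#' Compute LCS vortex contours and volumes across frames and slices
#'
#' The package's main analysis loop: for every analyzed timeframe and every
#' short-axis slice, seeds a particle grid over the endocardial extent,
#' advects it backwards to `t_origin`, computes the FTLE field, extracts and
#' delineates the LCS ridge, crops it to the endocardium, and accumulates
#' slice-summation volumes.
#'
#' @param field a `velocity_field`.
#' @param endo endocardial `contour_set` (label `"endocardium"`, slice
#'   indices matching `slice_z`).
#' @param t_origin backward-integration origin, ms (e.g. the E-wave onset
#'   from [detect_e_wave_onset()]).
#' @param slice_z short-axis slice positions, mm (indexed as in `endo`).
#' @param frames timeframe indices to analyze; default: all frames strictly
#'   after `t_origin`.
#' @param seed_spacing particle spacing, mm (default 0.8).
#' @param step RK4 step, ms (default 5).
#' @param threshold_fraction,percentile LCS extraction parameters (defaults
#'   0.5 and 0.95).
#' @param area_floor minimum retained polygon area, mm^2.
#' @param margin seeding margin beyond the endocardial bounding box, mm.
#' @return list with `lcs_contours` (cropped `contour_set`), and per analyzed
#'   frame `lv_volume_ml`, `vortex_volume_ml`, `vv_percent`,
#'   `wall_distance_mm`, `frames`, `time_ms`.
#' @export
analyze_vortex_ring <- function(field, endo, t_origin, slice_z, frames = NULL,
                                seed_spacing = 0.8, step = 5,
                                threshold_fraction = 0.5, percentile = 0.95,
                                area_floor = 50, margin = 4) {
  validate_velocity_field(field)
  stopifnot(inherits(endo, "contour_set"))
  times <- field$time_points
  if (is.null(frames)) frames <- which(times > t_origin + 1e-9)
  if (length(frames) == 0) stop("no timeframe after t_origin to analyze")
  thick <- attr(endo, "slice_thickness")

  xr <- range(endo$x_mm) + c(-margin, margin)
  yr <- range(endo$y_mm) + c(-margin, margin)
  extent <- c(diff(xr), diff(yr))

  all_lcs <- list()
  for (ti in frames) {
    t_seed <- times[ti]
    # FTLE on every slice of this time phase first: the normalization value
    # is the pooled percentile over the whole seeded stack of the phase.
    # Seeds outside the endocardial contour are flagged so that the
    # normalization reflects the ventricular flow, not the static
    # surroundings of the chamber.
    ftles <- list()
    for (si in seq_along(slice_z)) {
      ep <- contour_polygons(endo, label = "endocardium", timeframe = ti,
                             slice_index = si)
      if (length(ep) == 0) next
      plane <- seed_plane(c(xr[1], yr[1], slice_z[si]),
                          c(1, 0, 0), c(0, 1, 0), extent)
      grid <- seed_grid(plane, seed_spacing, t_seed = t_seed)
      fmap <- advect_backward(grid, field, t_origin = t_origin, step = step)
      ftle <- compute_ftle(fmap, grid)
      in_lv <- point_in_polygon(grid$positions[, 1:2], ep[[1]]$xy)
      ftle$flagged <- ftle$flagged | matrix(!in_lv, grid$n1, grid$n2)
      if (all(ftle$flagged)) next
      ftles[[as.character(si)]] <- list(grid = grid, ftle = ftle)
    }
    if (length(ftles) == 0) next
    pooled <- unlist(lapply(ftles, function(e) e$ftle$values[!e$ftle$flagged]))
    p95 <- as.numeric(quantile(pooled, percentile, type = 7, names = FALSE))
    if (!is.finite(p95) || p95 <= 0) next
    for (si in names(ftles)) {
      e <- ftles[[si]]
      lcs <- suppressWarnings(
        extract_lcs(e$ftle, threshold_fraction = threshold_fraction,
                    percentile = percentile, norm_value = p95))
      if (!any(lcs$mask)) next
      cs <- suppressWarnings(
        delineate_vortex(lcs, e$grid, timeframe = ti,
                         slice_index = as.integer(si),
                         area_floor = area_floor))
      if (nrow(cs) > 0) all_lcs[[length(all_lcs) + 1]] <- cs
    }
  }
  lcs_cs <- if (length(all_lcs) == 0) contour_set(slice_thickness = thick)
            else {
    df <- do.call(rbind, lapply(all_lcs, as.data.frame))
    contour_set(df, slice_thickness = thick)
  }
  cropped <- if (nrow(lcs_cs) > 0) crop_to_endocardium(lcs_cs, endo) else lcs_cs

  lv_all <- slice_summation_volume(endo, label = "endocardium")
  vortex_all <- slice_summation_volume(cropped, label = "lcs")
  lv <- lv_all[as.character(frames)]
  vortex <- rep(0, length(frames))
  hit <- match(names(vortex_all), as.character(frames))
  vortex[hit[!is.na(hit)]] <- vortex_all[!is.na(hit)]
  vortex <- pmin(vortex, lv)
  list(lcs_contours = cropped,
       frames = frames, time_ms = times[frames],
       lv_volume_ml = unname(lv), vortex_volume_ml = unname(vortex),
       vv_percent = unname(vortex_volume_fraction(vortex, lv)),
       wall_distance_mm = unname(vortex_wall_distance(lv, vortex)))
}

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: 0.8 mm seed spacing,
#' 5 ms RK4 step, 95th-percentile FTLE normalization with a 50% threshold,
#' 10 cm/s flow-profile threshold, alpha 0.05 over a 32-test battery.
#'
#' @return nested list, the same shape as the YAML config file.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    synth = list(enabled = TRUE, model = "synthetic_ventricle", params = list()),
    preprocess = list(background = FALSE, unwrap = FALSE,
                      unwrap_max_iters = 10L, noise_sigma = 0),
    ftle = list(seed_spacing = 0.8, step = 5, threshold = 0.5,
                percentile = 0.95, t_origin = "auto", area_floor = 50),
    metrics = list(flow_threshold = 10),
    stats = list(alpha = 0.05, n_tests = 32L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_pipeline_config(), user)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic dataset (or inputs
#' already on disk), writing per-stage plain-file outputs plus a manifest
#' (config, seed, package version, content hashes) into `out_dir`. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config nested config list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir run directory (created).
#' @return the run directory, invisibly; outputs: `field.rds`,
#'   `endo_contours.csv`, `lcs_contours.csv`, `metrics.csv`,
#'   `manifest.json`, `log.txt`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  logmsg <- function(...) cat(sprintf("[%s] %s\n", "vortexlcs", sprintf(...)),
                              file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  set.seed(config$seed)

  # --- synth ---------------------------------------------------------------
  if (!isTRUE(config$synth$enabled))
    stop("run_pipeline currently requires the synth stage ",
         "(external inputs are read with read_velocity_field/read_contours ",
         "and analyzed with analyze_vortex_ring directly)")
  sv <- stage("synth", do.call(synthetic_ventricle,
                               c(config$synth$params, list(seed = config$seed))))
  field <- sv$field
  truth <- sv$truth
  write_velocity_field(field, file.path(out_dir, "field.rds"))
  write_contours(truth$endo_contours, file.path(out_dir, "endo_contours.csv"))
  logmsg("synth: %d frames, grid %s", length(field$time_points),
         paste(dim(field$v)[1:3], collapse = "x"))

  # --- preprocess ----------------------------------------------------------
  pp <- config$preprocess
  if (!is.null(pp$noise_sigma) && pp$noise_sigma > 0)
    field <- stage("preprocess", inject_noise(field, pp$noise_sigma))
  if (isTRUE(pp$background)) {
    mask <- stationary_mask_from_sd(field)
    field <- stage("preprocess", correct_background_phase(field, mask))$field
    logmsg("preprocess: background plane removed")
  }
  if (isTRUE(pp$unwrap)) {
    field <- stage("preprocess",
                   unwrap_velocity(field, max_iters = pp$unwrap_max_iters))
    logmsg("preprocess: unwrap changed %s voxels",
           paste(attr(field, "n_changed"), collapse = "+"))
  }

  # --- ftle + delineate ----------------------------------------------------
  fc <- config$ftle
  profile <- through_plane_flow_profile(field, truth$orifice$slice_z,
                                        truth$orifice$roi)
  t_origin <- if (identical(fc$t_origin, "auto")) detect_e_wave_onset(profile)
              else as.numeric(fc$t_origin)
  res <- stage("ftle", analyze_vortex_ring(
    field, truth$endo_contours, t_origin = t_origin, slice_z = truth$slice_z,
    seed_spacing = fc$seed_spacing, step = fc$step,
    threshold_fraction = fc$threshold, percentile = fc$percentile,
    area_floor = fc$area_floor))
  write_contours(res$lcs_contours, file.path(out_dir, "lcs_contours.csv"))
  logmsg("ftle: t_origin %.1f ms, %d frames analyzed", t_origin,
         length(res$frames))

  # --- metrics -------------------------------------------------------------
  mc <- config$metrics
  annulus <- stage("metrics", tryCatch(
    mitral_effective_diameter(field, truth$orifice$slice_z, truth$orifice$roi,
                              flow_threshold = mc$flow_threshold),
    error = function(e) list(area_mm2 = NA_real_, diameter_mm = NA_real_)))
  dia <- field$time_points > truth$systole_ms
  inflow_ml <- sum(pmax(-profile$flow_ml_s[dia], 0) *
                   c(diff(field$time_points[dia]), 0)) / 1000
  scalars <- list(
    mitral_area_mm2 = annulus$area_mm2,
    mitral_diameter_mm = annulus$diameter_mm,
    max_lcs_diameter_mm = if (nrow(res$lcs_contours) > 0)
      max_lcs_diameter(res$lcs_contours) else NA_real_,
    e_peak_velocity_cm_s = max(abs(profile$peak_velocity_cm_s)),
    vfr = if (is.finite(annulus$diameter_mm))
      vortex_formation_ratio(inflow_ml, annulus$diameter_mm) else NA_real_)
  scalars$diameter_ratio <- if (is.finite(annulus$diameter_mm) &&
                                !is.na(scalars$max_lcs_diameter_mm))
    diameter_ratio(scalars$max_lcs_diameter_mm, annulus$diameter_mm)
    else NA_real_
  lvfull <- slice_summation_volume(truth$endo_contours, label = "endocardium")
  scalars$peak_filling_rate_ml_s <- peak_filling_rate(
    unname(lvfull), field$time_points[as.integer(names(lvfull))])
  mt <- metrics_table("synthetic", res$lv_volume_ml, res$vortex_volume_ml,
                      res$time_ms, scalars = scalars)
  write.csv(mt, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  logmsg("metrics: end-diastolic VV%% %.1f", tail(mt$vv_percent, 1))

  # --- manifest ------------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json", "log.txt")]
  manifest <- list(
    package = "vortexlcs",
    version = as.character(utils::packageVersion("vortexlcs")),
    seed = config$seed, config = config,
    t_origin_ms = t_origin,
    hashes = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
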