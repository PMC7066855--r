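#' Pipeline configuration
#'
#' Bundles the per-stage configurations. The recorded `seed` drives scene
#' generation, rendering noise, and plate simulation through derived
#' sub-streams, and is echoed into every provenance record.
#'
#' @param scene a [scene_config()]
#' @param imaging an [imaging_config()]
#' @param segmentation a [segmentation_params()]
#' @param n_plates plates to simulate in [run_simulate()]
#' @param alpha significance level for capture tests
#' @param span,degree LOESS trend-surface settings
#' @param distance_mode planarity distance mode; see [point_plane_distance()]
#' @param seed integer master seed
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(scene = scene_config(), imaging = imaging_config(),
                            segmentation = segmentation_params(),
                            n_plates = 6L, alpha = 0.01,
                            span = 0.5, degree = 2,
                            distance_mode = "perpendicular", seed = 1L) {
  stopifnot(inherits(scene, "scene_config"), inherits(imaging, "imaging_config"),
            inherits(segmentation, "segmentation_params"))
  scene$rng_seed <- as.integer(seed)
  structure(list(scene = scene, imaging = imaging, segmentation = segmentation,
                 n_plates = as.integer(n_plates), alpha = alpha,
                 span = span, degree = degree,
                 distance_mode = distance_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Demo pipeline configuration
#'
#' A self-consistent desk-scale configuration: the full 8 x 12 array laid
#' out inside the ~2.5 x 1.5 cm scanned region (the stated funnel-outlet
#' pitch of 3800 um would not fit 12 columns into that region, so the
#' deposited-array pitch is set to 2000 x 1800 um; see the vignette), with
#' a tilted deposition plane of reported slope magnitude.
#'
#' @param seed integer master seed
#' @param voxel_xy xy voxel spacing, um (coarser than the 10 um default to
#'   keep the demo fast)
#' @return a [pipeline_config()]
#' @export
demo_config <- function(seed = 1L, voxel_xy = 20) {
  scene <- scene_config(pitch = c(2000, 1800),
                        plane_p0 = 600, plane_px = -0.006, plane_py = -0.01,
                        z_noise_sd = 60, capture_prob = 0.8, rng_seed = seed)
  pipeline_config(scene = scene,
                  imaging = imaging_config(voxel_xy = voxel_xy),
                  seed = seed)
}

config_to_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path
#' @param config a [pipeline_config()]
#' @return a [pipeline_config()] (read) or `path` (write)
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # NULL fields serialize as {}, and Inf as the string "Inf"; undo both
  sanitize <- function(l) {
    l <- l[vapply(l, length, integer(1)) > 0]
    lapply(l, function(x)
      if (is.character(x) && all(x %in% c("Inf", "-Inf", "NA"))) as.numeric(x) else x)
  }
  raw[c("scene", "imaging", "segmentation")] <-
    lapply(raw[c("scene", "imaging", "segmentation")],
           function(x) if (is.null(x)) list() else sanitize(as.list(x)))
  sc <- raw$scene %||% list()
  if (!is.null(sc$capture_prob) && is.matrix(sc$capture_prob) == FALSE &&
      length(sc$capture_prob) == 96L)
    sc$capture_prob <- matrix(unlist(sc$capture_prob), 8, 12)
  scene <- do.call(scene_config, sc)
  imaging <- do.call(imaging_config, raw$imaging %||% list())
  segmentation <- do.call(segmentation_params, raw$segmentation %||% list())
  pipeline_config(scene = scene, imaging = imaging, segmentation = segmentation,
                  n_plates = raw$n_plates %||% 6L, alpha = raw$alpha %||% 0.01,
                  span = raw$span %||% 0.5, degree = raw$degree %||% 2,
                  distance_mode = raw$distance_mode %||% "perpendicular",
                  seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a full experiment to disk
#'
#' Generates a ground-truth scene, renders it to a multi-page TIFF stack,
#' simulates a series of capture plate maps, and writes all artifacts plus
#' a provenance JSON (configuration, seed, package version) to `outdir`.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory (created if missing)
#' @return invisibly, a list with the scene, stack path, scene CSV path,
#'   and plate map paths
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stopf("output directory is not writable: %s", outdir)

  scene <- generate_block_scene(config$scene)
  stack <- render_stack(scene, config$imaging)
  stack_path <- file.path(outdir, "stack.tif")
  write_stack(stack, stack_path, format = "float32")
  scene_path <- file.path(outdir, "scene.csv")
  write_scene_csv(scene, scene_path)

  plates <- generate_plate_series(config$n_plates, config$scene$capture_prob,
                                  rng_seed = derive_seed(config$seed, 104729L))
  plate_paths <- vapply(seq_along(plates), function(k) {
    p <- file.path(outdir, sprintf("plate_%02d.csv", k))
    write_plate_map(plates[[k]], p)
    p
  }, character(1))

  prov <- list(stage = "simulate", seed = config$seed,
               package_version = as.character(packageVersion("spheroplane")),
               config = config_to_list(config))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scene = scene, stack_path = stack_path,
                 scene_path = scene_path, plate_paths = plate_paths))
}

#' Analyze a stack and plate maps
#'
#' Runs segment -> well assignment -> planarity -> capture statistics ->
#' trend surface, writing per-stage reports to `outdir`:
#' `spheroids.csv` (label, well_id, centroid, mean radius, volume),
#' `planarity.csv` (one row: p0, px, py, mean, median, max),
#' `planarity.json` (per-spheroid records), `capture_per_well.csv`,
#' `capture_row_stats.csv`, `capture_col_stats.csv`, `trend.csv`
#' (fitted surface values and R^2), and `provenance.json`. If no plate
#' maps are supplied the capture stage is skipped with a warning and the
#' planarity report is still produced.
#'
#' @param stack an [image_stack()] or path to a multi-page TIFF
#' @param plate_paths character vector of plate-map CSV paths (may be
#'   empty)
#' @param config a [pipeline_config()]
#' @param outdir output directory
#' @return invisibly, a list: spheroids, planarity (a `planarity_report`),
#'   capture (a `capture_summary` or NULL), trend (a `trend_surface`)
#' @export
run_analyze <- function(stack, plate_paths = character(), config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (is.character(stack))
    stack <- read_stack(stack, spacing = c(config$imaging$section_thickness,
                                           config$imaging$voxel_xy,
                                           config$imaging$voxel_xy))
  stopifnot(inherits(stack, "image_stack"))

  spheroids <- segment_spheroids(stack, config$segmentation)
  message(sprintf("segment: %d spheroid(s) (threshold %.4g)",
                  length(spheroids), attr(spheroids, "threshold")))
  spheroids <- assign_wells(spheroids,
                            grid_origin = config$scene$grid_origin,
                            pitch = config$scene$pitch,
                            tolerance = config$segmentation$well_assign_tolerance,
                            grid_rows = config$scene$grid_rows,
                            grid_cols = config$scene$grid_cols)
  sp_df <- spheroids_to_df(spheroids)
  write.csv(sp_df, file.path(outdir, "spheroids.csv"), row.names = FALSE, quote = FALSE)

  planarity <- tryCatch(
    planarity_report(sp_df, distance_mode = config$distance_mode),
    error = function(e) stopf("planarity stage failed: %s", conditionMessage(e)))
  plane_row <- data.frame(p0_um = planarity$plane$p0, px = planarity$plane$px,
                          py = planarity$plane$py,
                          mean_norm_dist = planarity$mean,
                          median_norm_dist = planarity$median,
                          max_norm_dist = planarity$max,
                          n_spheroids = planarity$plane$n_points)
  write.csv(plane_row, file.path(outdir, "planarity.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(plane = unclass(planarity$plane),
                            distance_mode = planarity$distance_mode,
                            mean = planarity$mean, median = planarity$median,
                            max = planarity$max, records = planarity$records),
                       file.path(outdir, "planarity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("planarity: mean d/r = %.4f over %d spheroids",
                  planarity$mean, planarity$plane$n_points))

  capture <- NULL
  if (length(plate_paths) > 0) {
    maps <- lapply(plate_paths, read_plate_map)
    capture <- tryCatch(capture_summary(maps, alpha = config$alpha),
                        error = function(e) stopf("capture stage failed: %s",
                                                  conditionMessage(e)))
    write_plate_map(capture$per_well_mean, file.path(outdir, "capture_per_well.csv"))
    write.csv(capture$row_stats, file.path(outdir, "capture_row_stats.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(capture$col_stats, file.path(outdir, "capture_col_stats.csv"),
              row.names = FALSE, quote = FALSE)
    message(sprintf("capture: grand mean %.1f%% over %d plates",
                    100 * capture$grand_mean, capture$n_plates))
  } else {
    warning("no plate maps supplied: capture stage skipped", call. = FALSE)
  }

  trend <- tryCatch(
    loess_surface(cbind(sp_df$cx_um, sp_df$cy_um, sp_df$cz_um),
                  span = config$span, degree = config$degree),
    error = function(e) stopf("trend stage failed: %s", conditionMessage(e)))
  trend_df <- data.frame(well_id = sp_df$well_id,
                         cx_um = sp_df$cx_um, cy_um = sp_df$cy_um,
                         cz_um = sp_df$cz_um, fitted_z_um = trend$fitted_z,
                         r_squared = trend$r_squared)
  write.csv(trend_df, file.path(outdir, "trend.csv"), row.names = FALSE, quote = FALSE)
  message(sprintf("trend: LOESS R^2 = %s",
                  if (trend$r_squared_defined) sprintf("%.4f", trend$r_squared) else "undefined"))

  prov <- list(stage = "analyze", seed = config$seed,
               package_version = as.character(packageVersion("spheroplane")),
               config = config_to_list(config))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(spheroids = spheroids, planarity = planarity,
                 capture = capture, trend = trend))
}
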