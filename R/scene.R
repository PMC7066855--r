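#' Configuration for a synthetic spheroid microarray scene
#'
#' Describes the ground-truth world the phantom generator draws from: an
#' 8 x 12 grid of deposition sites (matching a 96-well plate transferred
#' into an agar receiver block), spheroid size and shape variability, the
#' plane the centroids scatter about, optional parabolic bowing of the
#' block, and the per-well probability that a spheroid was captured.
#'
#' Defaults reflect the device geometry and outcomes reported for the
#' centrifugal funnel array: 3800 um centre-to-centre funnel spacing,
#' ~500 um mean spheroid diameter, ~80% capture success. `pitch` may be a
#' scalar or a length-2 vector (x-pitch, y-pitch); the imaged block region
#' (~2.5 x 1.5 cm) implies a tighter deposited-array pitch than the funnel
#' outlets, so pipeline demo configurations override it (see the vignette).
#'
#' @param grid_rows,grid_cols grid dimensions (8 x 12 for a 96-well plate)
#' @param pitch centre-to-centre spacing in um; scalar or (x, y)
#' @param grid_origin xy position of the A1 node in um; default half a pitch
#'   in from the block corner
#' @param mean_diameter mean spheroid diameter, um
#' @param diameter_cv coefficient of variation of spheroid diameter
#' @param axis_ratio_range interval the ellipsoid semi-axis ratios are drawn
#'   from (1 = sphere); the three ratios are renormalised to preserve the
#'   volume-equivalent radius
#' @param plane_p0,plane_px,plane_py deposition plane z = p0 + px x + py y
#'   (p0 in um from the block bottom; slopes dimensionless)
#' @param bowl_coeff parabolic bowing curvature in 1/um, applied along x
#'   only (z += bowl_coeff * (x - x_centre)^2); 0 disables
#' @param z_noise_sd Gaussian scatter of centroid z about the surface, um
#' @param capture_prob per-well capture probability; scalar or 8 x 12 matrix
#' @param field_z imaging depth the scene must fit inside, um
#' @param rng_seed integer master seed; all scene randomness derives from it
#' @return an object of class `scene_config`
#' @export
scene_config <- function(grid_rows = 8L, grid_cols = 12L,
                         pitch = 3800, grid_origin = NULL,
                         mean_diameter = 500, diameter_cv = 0.1,
                         axis_ratio_range = c(0.8, 1.2),
                         plane_p0 = 500, plane_px = 0, plane_py = 0,
                         bowl_coeff = 0, z_noise_sd = 60,
                         capture_prob = 0.8, field_z = 1000,
                         rng_seed = 1L) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- c(pitch, pitch)
  if (length(pitch) != 2L || any(pitch <= 0)) stopf("pitch must be 1 or 2 positive values")
  if (is.null(grid_origin)) grid_origin <- pitch / 2
  if (min(pitch) <= mean_diameter)
    stopf("pitch (%g um) must exceed mean_diameter (%g um)", min(pitch), mean_diameter)
  if (diameter_cv < 0) stopf("diameter_cv must be >= 0")
  if (z_noise_sd < 0) stopf("z_noise_sd must be >= 0")
  if (length(axis_ratio_range) != 2L || any(axis_ratio_range <= 0) ||
      axis_ratio_range[1] > axis_ratio_range[2])
    stopf("axis_ratio_range must be a positive non-decreasing interval")
  if (is.matrix(capture_prob)) {
    if (!all(dim(capture_prob) == c(grid_rows, grid_cols)))
      stopf("capture_prob matrix must be %d x %d", grid_rows, grid_cols)
  } else if (length(capture_prob) != 1L) {
    stopf("capture_prob must be a scalar or a grid-shaped matrix")
  }
  if (any(capture_prob < 0 | capture_prob > 1))
    stopf("capture_prob must be in [0, 1] elementwise")
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 pitch = pitch, grid_origin = as.numeric(grid_origin),
                 mean_diameter = mean_diameter, diameter_cv = diameter_cv,
                 axis_ratio_range = as.numeric(axis_ratio_range),
                 plane_p0 = plane_p0, plane_px = plane_px, plane_py = plane_py,
                 bowl_coeff = bowl_coeff, z_noise_sd = z_noise_sd,
                 capture_prob = capture_prob, field_z = field_z,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Configuration for synthetic CLSM stack rendering
#'
#' Voxel geometry and optical parameters of the simulated confocal
#' acquisition. The default field matches the ~2.5 cm x 1.5 cm x 1 mm
#' region scanned in 30 um optical sections; xy sampling defaults to 10 um.
#' Depth attenuation is modelled as exponential decay along the tissue path
#' between a voxel and the objective (located on the +z side), reproducing
#' the dimming of structures seated deeper under spheroid tissue.
#'
#' @param voxel_xy xy voxel spacing, um
#' @param section_thickness optical section thickness = z spacing, um
#' @param field_x,field_y,field_z scanned region extent, um
#' @param attenuation_length 1/e tissue path length of the signal, um;
#'   `Inf` disables attenuation
#' @param background_noise_sd Gaussian background noise SD, intensity units
#' @param foreground_intensity unattenuated intensity inside a spheroid
#' @return an object of class `imaging_config`
#' @export
imaging_config <- function(voxel_xy = 10, section_thickness = 30,
                           field_x = 25000, field_y = 15000, field_z = 1000,
                           attenuation_length = 1000,
                           background_noise_sd = 2,
                           foreground_intensity = 100) {
  if (voxel_xy <= 0) stopf("voxel_xy must be > 0")
  if (section_thickness <= 0) stopf("section_thickness must be > 0")
  if (field_x <= 0 || field_y <= 0 || field_z <= 0) stopf("field dimensions must be positive")
  if (attenuation_length <= 0) stopf("attenuation_length must be > 0 (use Inf to disable)")
  if (background_noise_sd < 0) stopf("background_noise_sd must be >= 0")
  structure(list(voxel_xy = voxel_xy, section_thickness = section_thickness,
                 field_x = field_x, field_y = field_y, field_z = field_z,
                 attenuation_length = attenuation_length,
                 background_noise_sd = background_noise_sd,
                 foreground_intensity = foreground_intensity),
            class = "imaging_config")
}

well_name <- function(row, col) paste0(LETTERS[row], col)

#' Generate a ground-truth spheroid scene
#'
#' Draws one realisation of the stated world: a Bernoulli capture outcome
#' per well; for each captured well one ellipsoidal spheroid whose centroid
#' sits at the grid node in xy and, in z, on the configured plane plus
#' optional parabolic bowing plus Gaussian noise. Deterministic given
#' `config$rng_seed`.
#'
#' @param config a [scene_config()]
#' @return an object of class `ground_truth_scene`: a `spheroids` data
#'   frame (well_id, row, col, cx, cy, cz, a, b, c), a list of 3x3
#'   orientation matrices, the 8 x 12 logical `captured` matrix, and the
#'   generating plane
#' @export
generate_block_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  p <- config$capture_prob
  if (!is.matrix(p)) p <- matrix(p, nr, nc)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  # capture outcomes first, in fixed row-major well order
  captured <- matrix(FALSE, nr, nc, dimnames = list(LETTERS[seq_len(nr)], seq_len(nc)))
  for (r in seq_len(nr)) for (cc in seq_len(nc))
    captured[r, cc] <- runif(1) < p[r, cc]

  x_nodes <- config$grid_origin[1] + (seq_len(nc) - 1) * config$pitch[1]
  y_nodes <- config$grid_origin[2] + (seq_len(nr) - 1) * config$pitch[2]
  x_centre <- mean(range(x_nodes))

  rows <- list(); orients <- list(); k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!captured[r, cc]) next
    k <- k + 1L
    cx <- x_nodes[cc]; cy <- y_nodes[r]
    cz <- config$plane_p0 + config$plane_px * cx + config$plane_py * cy +
      config$bowl_coeff * (cx - x_centre)^2 +
      if (config$z_noise_sd > 0) rnorm(1, 0, config$z_noise_sd) else 0
    radius <- config$mean_diameter / 2 *
      max(0.1, 1 + if (config$diameter_cv > 0) rnorm(1, 0, config$diameter_cv) else 0)
    ratios <- runif(3, config$axis_ratio_range[1], config$axis_ratio_range[2])
    semi <- radius * ratios / prod(ratios)^(1 / 3)  # preserve equivalent-volume radius
    rot <- random_rotation()
    rows[[k]] <- data.frame(well_id = well_name(r, cc), row = r, col = cc,
                            cx = cx, cy = cy, cz = cz,
                            a = semi[1], b = semi[2], c = semi[3],
                            stringsAsFactors = FALSE)
    orients[[k]] <- rot
  }
  spheroids <- if (k > 0) do.call(rbind, rows) else
    data.frame(well_id = character(), row = integer(), col = integer(),
               cx = numeric(), cy = numeric(), cz = numeric(),
               a = numeric(), b = numeric(), c = numeric(), stringsAsFactors = FALSE)

  if (k > 0) {
    reach <- apply(spheroids[, c("a", "b", "c")], 1, max)
    bad <- spheroids$cz - reach < 0 | spheroids$cz + reach > config$field_z
    if (any(bad))
      stopf("scene geometry incompatible with field_z = %g um: spheroid(s) %s protrude outside the imaging depth",
            config$field_z, paste(spheroids$well_id[bad], collapse = ", "))
  }

  structure(list(spheroids = spheroids, orientations = orients,
                 captured = captured,
                 true_plane = list(p0 = config$plane_p0, px = config$plane_px,
                                   py = config$plane_py,
                                   bowl_coeff = config$bowl_coeff),
                 config = config),
            class = "ground_truth_scene")
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("ground_truth_scene: %d/%d wells captured, plane z = %.4g %+.4g x %+.4g y\n",
              sum(x$captured), length(x$captured),
              x$true_plane$p0, x$true_plane$px, x$true_plane$py))
  invisible(x)
}

#' Serialize / read a ground-truth scene as CSV
#'
#' One row per spheroid (well_id, row, col, cx, cy, cz, a, b, c), for use
#' as a test oracle. Ellipsoid orientation is not serialized.
#'
#' @param scene a `ground_truth_scene`
#' @param path CSV path
#' @return `path` (write) or a data frame (read)
#' @export
write_scene_csv <- function(scene, path) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  write.csv(scene$spheroids, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate a series of capture plate maps
#'
#' Independent Bernoulli capture draws per plate per well, emulating a
#' multi-plate transfer experiment. Each plate uses a sub-stream derived
#' from `rng_seed`, so plate k is reproducible independently of how many
#' plates are generated.
#'
#' @param n_plates number of plates (>= 1)
#' @param capture_prob scalar or 8 x 12 matrix of capture probabilities
#' @param rng_seed integer master seed
#' @return a list of [plate_map()] objects with logical (0/1) values
#' @export
generate_plate_series <- function(n_plates, capture_prob = 0.8, rng_seed = 1L) {
  if (n_plates < 1) stopf("n_plates must be >= 1")
  p <- if (is.matrix(capture_prob)) capture_prob else matrix(capture_prob, 8, 12)
  if (!all(dim(p) == c(8, 12))) stopf("capture_prob matrix must be 8 x 12")
  if (any(p < 0 | p > 1)) stopf("capture_prob must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(seq_len(n_plates), function(k) {
    set.seed(derive_seed(rng_seed, k))
    plate_map(matrix(runif(96) < p, 8, 12))
  })
}
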