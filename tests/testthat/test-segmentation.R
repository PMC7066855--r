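test_that("a rendered full grid of well-separated spheres yields exactly 96 objects", {
  scene <- generate_block_scene(tiny_scene_config())
  stack <- render_stack(scene, tiny_imaging_config())
  sp <- segment_spheroids(stack, segmentation_params())
  expect_length(sp, 96L)
  expect_false(attr(sp, "all_foreground"))
})

test_that("an all-background stack yields an empty list, not an error", {
  stack <- image_stack(array(0, c(5, 10, 10)), spacing = c(30, 20, 20))
  sp <- segment_spheroids(stack, segmentation_params(threshold_mode = "fixed",
                                                     fixed_threshold = 0.5))
  expect_length(sp, 0L)
})

test_that("a degenerate all-foreground threshold warns and is flagged", {
  stack <- image_stack(array(10, c(3, 4, 4)), spacing = c(30, 20, 20))
  expect_warning(
    sp <- segment_spheroids(stack, segmentation_params(threshold_mode = "fixed",
                                                       fixed_threshold = 1,
                                                       min_volume = 0)),
    "foreground")
  expect_true(attr(sp, "all_foreground"))
})

test_that("segmentation recovers the captured-well matrix well-for-well", {
  cp <- matrix(1, 8, 12)
  cp[cbind(c(2, 4, 5, 7, 8), c(3, 6, 9, 1, 12))] <- 0  # 91 captured
  scene <- generate_block_scene(tiny_scene_config(capture_prob = cp))
  expect_equal(nrow(scene$spheroids), 91L)
  stack <- render_stack(scene, tiny_imaging_config())
  sp <- segment_spheroids(stack, segmentation_params())
  expect_length(sp, 91L)
  sp <- assign_wells(sp, grid_origin = scene$config$grid_origin,
                     pitch = scene$config$pitch)
  got <- matrix(FALSE, 8, 12)
  for (o in sp) {
    w <- o$well_id
    expect_false(is.na(w))
    got[match(substr(w, 1, 1), LETTERS), as.integer(substring(w, 2))] <- TRUE
  }
  expect_equal(got, unname(scene$captured))
})

test_that("recovered centroids and radii are close to ground truth", {
  scene <- generate_block_scene(tiny_scene_config(plane_px = 0.005, plane_py = -0.01,
                                                  plane_p0 = 420))
  im <- tiny_imaging_config()
  stack <- render_stack(scene, im)
  sp <- segment_spheroids(stack, segmentation_params())
  df <- spheroids_to_df(assign_wells(sp, scene$config$grid_origin, scene$config$pitch))
  truth <- scene$spheroids
  m <- match(df$well_id, truth$well_id)
  expect_false(anyNA(m))
  voxel_diag <- sqrt(sum(stack$spacing^2))
  err <- sqrt((df$cx_um - truth$cx[m])^2 + (df$cy_um - truth$cy[m])^2 +
              (df$cz_um - truth$cz[m])^2)
  expect_lt(max(err), voxel_diag)
  expect_lt(max(abs(df$mean_radius_um - 150) / 150), 0.10)
})

test_that("extract_surface matches brute-force boundary enumeration", {
  # single voxel: its own surface
  one <- matrix(c(3L, 3L, 3L), 1)
  expect_equal(nrow(extract_surface(one)), 1L)
  # 3x3x3 solid cube: 26 surface voxels (all but the centre)
  cube <- as.matrix(expand.grid(iz = 2:4, iy = 2:4, ix = 2:4))
  surf <- extract_surface(cube)
  expect_equal(nrow(surf), 26L)
  centre_phys <- c(x = 2.5, y = 2.5, z = 2.5)
  expect_false(any(surf[, "x"] == 2.5 & surf[, "y"] == 2.5 & surf[, "z"] == 2.5))
  # digital balls: exact agreement with the oracle
  for (r in c(3, 5)) {
    ball <- digital_ball(r)
    got <- sort(attr(extract_surface(ball), "surface_rows"))
    expect_equal(got, sort(surface_rows_oracle(ball)))
  }
})

test_that("mean_radius is the arithmetic mean of surface distances in physical units", {
  # two surface points at distances 2 and 4
  pts <- rbind(c(2, 0, 0), c(0, 4, 0))
  expect_equal(mean_radius(pts, c(0, 0, 0)), 3)
  # dense analytic sphere sampling converges to the radius
  set.seed(1)
  u <- matrix(rnorm(3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 7.5
  expect_equal(mean_radius(u, c(0, 0, 0)), 7.5, tolerance = 1e-9)
  # digital ball, isotropic spacing 1: match brute force within 1e-9
  ball <- digital_ball(10)
  centroid_idx <- colMeans(ball)  # (iz, iy, ix)
  centroid <- c(centroid_idx[3] - 0.5, centroid_idx[2] - 0.5, centroid_idx[1] - 0.5)
  rows <- surface_rows_oracle(ball)
  brute <- mean(sqrt((ball[rows, 3] - 0.5 - centroid[1])^2 +
                     (ball[rows, 2] - 0.5 - centroid[2])^2 +
                     (ball[rows, 1] - 0.5 - centroid[3])^2))
  surf <- extract_surface(ball)
  cent <- colMeans(cbind(ball[, 3] - 0.5, ball[, 2] - 0.5, ball[, 1] - 0.5))
  expect_equal(mean_radius(surf, cent), brute, tolerance = 1e-9)
})

test_that("well assignment follows the nearest-node-within-tolerance contract", {
  mk <- function(x, y, label) structure(list(label = label, centroid = c(x = x, y = y, z = 0),
                                             mean_radius = 1, volume = 1,
                                             well_id = NA_character_),
                                        class = "spheroid_object")
  origin <- c(1000, 800); pitch <- c(2000, 1800)
  # exactly on node A1
  sp <- assign_wells(list(mk(1000, 800, 1L)), origin, pitch)
  expect_equal(sp[[1]]$well_id, "A1")
  # offset 100 um, tolerance 1000 um (device-pitch grid so tolerance <= pitch/2)
  sp <- assign_wells(list(mk(1000 + 3800 + 100, 800, 1L)), origin, c(3800, 3800),
                     tolerance = 1000)
  expect_equal(sp[[1]]$well_id, "A2")
  # two centroids nearest the same node: nearer wins, loser unassigned
  sp <- assign_wells(list(mk(1050, 800, 1L), mk(1200, 800, 2L)), origin, pitch)
  expect_equal(sp[[1]]$well_id, "A1")
  expect_true(is.na(sp[[2]]$well_id))
  expect_equal(attr(sp, "unassigned"), 2L)
  # tolerance above pitch/2 violates the params invariant
  expect_error(assign_wells(list(mk(0, 0, 1L)), origin, pitch, tolerance = 1500),
               "tolerance")
})

test_that("Otsu separates a clear bimodal mixture", {
  set.seed(2)
  x <- c(rnorm(5000, 5, 1), rnorm(500, 60, 5))
  truth <- rep(c(FALSE, TRUE), c(5000, 500))
  thr <- otsu_threshold(x)
  expect_lt(mean((x > thr) != truth), 0.01)  # near-perfect class separation
  expect_equal(otsu_threshold(rep(3, 100)), 3)  # constant input degenerates safely
})
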