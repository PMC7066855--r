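#' Render a ground-truth scene into a synthetic CLSM stack
#'
#' Voxelizes each ellipsoidal spheroid onto the imaging grid. Inside a
#' spheroid the intensity is `foreground_intensity * exp(-t /
#' attenuation_length)`, where t is the tissue path length from the voxel
#' towards the objective (the +z side): signal from voxels seated deeper
#' under spheroid tissue is dimmed, as in the real acquisitions. Gaussian
#' background noise is added everywhere. Deterministic given the scene and
#' `noise_seed`.
#'
#' @param scene a `ground_truth_scene` from [generate_block_scene()]
#' @param imaging an [imaging_config()]
#' @param noise_seed integer seed for the background noise; defaults to a
#'   sub-stream of the scene's master seed
#' @return an [image_stack()] with spacing (section_thickness, voxel_xy,
#'   voxel_xy)
#' @export
render_stack <- function(scene, imaging, noise_seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"), inherits(imaging, "imaging_config"))
  nz <- as.integer(round(imaging$field_z / imaging$section_thickness))
  ny <- as.integer(round(imaging$field_y / imaging$voxel_xy))
  nx <- as.integer(round(imaging$field_x / imaging$voxel_xy))
  if (nz < 1L || ny < 1L || nx < 1L)
    stopf("voxel grid is empty in at least one axis (%d x %d x %d)", nz, ny, nx)
  dz <- imaging$section_thickness; dxy <- imaging$voxel_xy
  sp <- scene$spheroids

  if (nrow(sp) > 0) {
    reach <- apply(sp[, c("a", "b", "c")], 1, max)
    if (any(sp$cx - reach < 0 | sp$cx + reach > imaging$field_x |
            sp$cy - reach < 0 | sp$cy + reach > imaging$field_y |
            sp$cz - reach < 0 | sp$cz + reach > imaging$field_z))
      stopf("scene does not fit inside the imaging field (%g x %g x %g um); spheroids extend outside it",
            imaging$field_x, imaging$field_y, imaging$field_z)
  }

  if (is.null(noise_seed)) noise_seed <- derive_seed(scene$config$rng_seed, 7919L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise_seed)

  n_vox <- as.numeric(nz) * ny * nx
  vox <- if (imaging$background_noise_sd > 0)
    rnorm(n_vox, 0, imaging$background_noise_sd) else numeric(n_vox)
  dim(vox) <- c(nz, ny, nx)  # in place, avoids a gigabyte-scale copy

  # voxel centre coordinates along each axis
  zc <- (seq_len(nz) - 0.5) * dz
  yc <- (seq_len(ny) - 0.5) * dxy
  xc <- (seq_len(nx) - 0.5) * dxy

  for (i in seq_len(nrow(sp))) {
    centre <- c(sp$cx[i], sp$cy[i], sp$cz[i])
    semi <- c(sp$a[i], sp$b[i], sp$c[i])
    rot <- scene$orientations[[i]]
    reach_i <- max(semi)
    iz <- which(zc >= centre[3] - reach_i - dz & zc <= centre[3] + reach_i + dz)
    iy <- which(yc >= centre[2] - reach_i - dxy & yc <= centre[2] + reach_i + dxy)
    ix <- which(xc >= centre[1] - reach_i - dxy & xc <= centre[1] + reach_i + dxy)
    if (!length(iz) || !length(iy) || !length(ix)) next
    # local coordinates of all bbox voxel centres, rotated into the
    # ellipsoid frame; mask where the quadratic form is <= 1
    g <- expand.grid(z = zc[iz], y = yc[iy], x = xc[ix])  # z fastest: matches array order
    pts <- cbind(g$x - centre[1], g$y - centre[2], g$z - centre[3]) %*% rot
    q <- (pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 + (pts[, 3] / semi[3])^2
    mask <- array(q <= 1, dim = c(length(iz), length(iy), length(ix)))
    if (!any(mask)) next
    # tissue path above each voxel (towards the objective on the +z side),
    # accumulated column-wise from the top of the bounding box
    nzb <- length(iz)
    t_above <- array(0, dim = dim(mask))
    above <- matrix(0, length(iy), length(ix))
    for (k in nzb:1) {
      t_above[k, , ] <- above * dz
      above <- above + matrix(mask[k, , ], length(iy), length(ix))
    }
    contrib <- imaging$foreground_intensity *
      (if (is.finite(imaging$attenuation_length))
         exp(-t_above / imaging$attenuation_length) else 1) * mask
    vox[iz, iy, ix] <- vox[iz, iy, ix] + contrib
  }

  image_stack(vox, spacing = c(dz, dxy, dxy))
}
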