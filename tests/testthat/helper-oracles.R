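# Independent oracles and small fixture builders shared across test files.

# Brute-force boundary enumeration: a voxel is on the surface iff one of its
# six face neighbours is absent from the set. Returns row indices into idx.
surface_rows_oracle <- function(idx) {
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  vapply(seq_len(nrow(idx)), function(i) {
    nb <- sweep(offs, 2, as.numeric(idx[i, ]), `+`)
    any(!(paste(nb[, 1], nb[, 2], nb[, 3]) %in% key))
  }, logical(1)) |> which()
}

# Digital ball of radius r (in voxels) centred in a cube, as (iz, iy, ix)
# index triplets.
digital_ball <- function(r, centre = r + 2) {
  rng <- seq_len(2 * (r + 2))
  g <- expand.grid(iz = rng, iy = rng, ix = rng)
  keep <- (g$iz - centre)^2 + (g$iy - centre)^2 + (g$ix - centre)^2 <= r^2
  as.matrix(g[keep, ])
}

# Coarse-to-fine grid search minimizing vertical squared residuals over
# (p0, px, py). Independent of fit_plane's linear algebra. Returns the best
# grid point and the final grid step per coefficient.
plane_grid_oracle <- function(pts, iters = 10, n_grid = 11) {
  z <- pts[, 3]
  centre <- c(mean(z), 0, 0)
  half <- c(max(abs(z - mean(z))) + 1e-6, 1, 1)
  X <- cbind(1, pts[, 1], pts[, 2])
  for (it in seq_len(iters)) {
    axes <- lapply(1:3, function(k)
      seq(centre[k] - half[k], centre[k] + half[k], length.out = n_grid))
    g <- as.matrix(expand.grid(p0 = axes[[1]], px = axes[[2]], py = axes[[3]]))
    rss <- colSums((z - X %*% t(g))^2)
    centre <- g[which.min(rss), ]
    step <- 2 * half / (n_grid - 1)
    half <- 2 * step  # keep the optimum inside the refined window
  }
  list(coef = unname(centre), step = 2 * half / (n_grid - 1))
}

# Small self-consistent scene/imaging fixtures: full 8 x 12 grid, 300 um
# spheroids, coarse voxels, desk-scale volume (~2M voxels).
tiny_scene_config <- function(seed = 1L, ...) {
  defaults <- list(pitch = c(600, 500), mean_diameter = 300, diameter_cv = 0,
                   axis_ratio_range = c(1, 1), plane_p0 = 400,
                   plane_px = 0, plane_py = 0, z_noise_sd = 0,
                   capture_prob = 1, field_z = 800, rng_seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

tiny_imaging_config <- function(...) {
  defaults <- list(voxel_xy = 20, section_thickness = 30,
                   field_x = 7200, field_y = 4000, field_z = 800,
                   attenuation_length = Inf, background_noise_sd = 0,
                   foreground_intensity = 100)
  args <- utils::modifyList(defaults, list(...))
  do.call(imaging_config, args)
}

# One-off sphere scene (single captured well) for rendering-level checks.
single_sphere_scene <- function(radius = 150, centre = c(600, 500, 400),
                                seed = 1L) {
  cp <- matrix(0, 8, 12); cp[1, 1] <- 1
  sc <- tiny_scene_config(seed = seed, capture_prob = cp,
                          mean_diameter = 2 * radius,
                          grid_origin = centre[1:2], plane_p0 = centre[3])
  generate_block_scene(sc)
}
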