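#' Segmentation parameters
#'
#' @param threshold_mode "otsu" (global Otsu threshold on the full volume;
#'   appropriate for the high-contrast whole-cell stain) or "fixed"
#' @param fixed_threshold intensity threshold when `threshold_mode = "fixed"`
#' @param connectivity component connectivity, 6 or 26 (default 26)
#' @param min_volume minimum object volume in um^3; defaults to the volume
#'   of a 150 um diameter sphere, rejecting debris
#' @param well_assign_tolerance maximum xy distance (um) from a grid node
#'   for well assignment; `NULL` means pitch/2 at assignment time
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold_mode = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                connectivity = 26L,
                                min_volume = 4 / 3 * pi * 75^3,
                                well_assign_tolerance = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold))
    stopf("fixed_threshold is required when threshold_mode = 'fixed'")
  if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
  if (min_volume < 0) stopf("min_volume must be >= 0")
  structure(list(threshold_mode = threshold_mode, fixed_threshold = fixed_threshold,
                 connectivity = as.integer(connectivity), min_volume = min_volume,
                 well_assign_tolerance = well_assign_tolerance),
            class = "segmentation_params")
}

#' Otsu's threshold
#'
#' Global histogram-based threshold maximising between-class variance;
#' suited to bimodal foreground/background intensity distributions.
#'
#' @param x numeric vector or array of intensities
#' @param n_bins number of histogram bins
#' @return the threshold intensity (foreground is `> threshold`)
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  if (!is.double(x)) x <- as.double(x)
  rng <- range(x, finite = TRUE)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  # histogram in chunks to cap temporary allocations on gigavoxel volumes
  n <- length(x)
  chunk <- 2e7
  counts <- integer(n_bins)
  for (start in seq(1, n, by = chunk)) {
    xi <- x[start:min(n, start + chunk - 1)]
    counts <- counts + tabulate(.bincode(xi, breaks, include.lowest = TRUE),
                                nbins = n_bins)
  }
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

# convert (iz, iy, ix) index triplets to linear indices and back
idx_to_linear <- function(idx, dims) {
  (idx[, 1] - 1) + as.numeric(dims[1]) * ((idx[, 2] - 1) + as.numeric(dims[2]) * (idx[, 3] - 1)) + 1
}

#' Extract surface voxels of a voxel set
#'
#' A voxel belongs to the external surface if at least one of its
#' neighbours (6-connected by default, i.e. face neighbours) lies outside
#' the set. Returned as physical-coordinate points (x, y, z) of the voxel
#' centres.
#'
#' @param voxel_idx integer matrix, one row per voxel, columns (iz, iy, ix)
#'   1-based voxel indices
#' @param spacing (dz, dy, dx) in um
#' @param origin (z0, y0, x0) in um
#' @param connectivity neighbourhood defining "outside contact": 6 or 26
#' @return a numeric matrix with columns (x, y, z); attribute
#'   `surface_rows` gives the rows of `voxel_idx` selected
#' @export
extract_surface <- function(voxel_idx, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            connectivity = 6L) {
  voxel_idx <- as.matrix(voxel_idx)
  dimnames(voxel_idx) <- NULL
  if (nrow(voxel_idx) == 0L) stopf("voxel set is empty")
  if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  # embed in a virtual grid large enough to avoid wrap-around
  dims <- apply(voxel_idx, 2, max) + 2L
  lin <- idx_to_linear(voxel_idx, dims)
  is_surface <- rep(FALSE, nrow(voxel_idx))
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(voxel_idx[, 1] + offs$dz[o],
                voxel_idx[, 2] + offs$dy[o],
                voxel_idx[, 3] + offs$dx[o])
    outside_grid <- nb[, 1] < 1 | nb[, 2] < 1 | nb[, 3] < 1
    nb_lin <- idx_to_linear(pmax(nb, 1L), dims)
    missing_nb <- outside_grid | is.na(match(nb_lin, lin))
    is_surface <- is_surface | missing_nb
    if (all(is_surface)) break
  }
  rows <- which(is_surface)
  pts <- cbind(x = (voxel_idx[rows, 3] - 0.5) * spacing[3] + origin[3],
               y = (voxel_idx[rows, 2] - 0.5) * spacing[2] + origin[2],
               z = (voxel_idx[rows, 1] - 0.5) * spacing[1] + origin[1])
  attr(pts, "surface_rows") <- rows
  pts
}

#' Mean radius of a spheroid
#'
#' Arithmetic mean of the Euclidean distances from the surface points to
#' the centroid, in physical units. This is the normaliser r_bar_i of the
#' planarity statistic.
#'
#' @param surface_points numeric matrix with columns (x, y, z), um
#' @param centroid numeric length-3 (x, y, z), um
#' @return mean radius in um
#' @export
mean_radius <- function(surface_points, centroid) {
  surface_points <- as.matrix(surface_points)
  if (nrow(surface_points) < 1L) stopf("at least one surface point is required")
  d <- sqrt((surface_points[, 1] - centroid[1])^2 +
            (surface_points[, 2] - centroid[2])^2 +
            (surface_points[, 3] - centroid[3])^2)
  mean(d)
}

#' Segment spheroids from an image stack
#'
#' Thresholds the volume (global Otsu by default), labels 3D connected
#' foreground components, discards components below `min_volume`, and for
#' each remaining object computes the unweighted volume centroid (physical
#' um), the 6-connectivity surface points, the mean radius r_bar, and the
#' volume. The volume centroid is used rather than an intensity-weighted
#' one because depth-dependent attenuation would bias the latter towards
#' the objective. Objects are ordered by centroid y, then x.
#'
#' @param stack an [image_stack()]
#' @param params a [segmentation_params()]
#' @return a list of `spheroid_object`s (label, voxel_idx, voxel_coords,
#'   surface_points, centroid, mean_radius, volume, well_id). Attributes:
#'   `threshold` (intensity used), `all_foreground` (TRUE when the
#'   threshold left no background -- a degenerate-threshold warning
#'   condition), `n_components_raw` (components before size filtering).
#' @export
segment_spheroids <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  dims <- dim(v)
  thr <- if (params$threshold_mode == "otsu") otsu_threshold(v) else params$fixed_threshold
  mask <- v > thr
  all_fg <- all(mask)
  if (all_fg)
    warning("degenerate threshold: entire volume is foreground", call. = FALSE)
  result <- list()
  n_raw <- 0L
  if (any(mask)) {
    labels <- cc_label3d(mask, as.integer(dims), params$connectivity)
    rm(mask)
    fg <- which(labels > 0L)
    lab <- labels[fg]
    n_raw <- max(lab)
    voxel_volume <- prod(stack$spacing)
    groups <- split(fg, lab)
    spacing <- stack$spacing; origin <- stack$origin
    objs <- lapply(groups, function(g) {
      # linear index -> (iz, iy, ix), 1-based
      g0 <- g - 1
      iz <- g0 %% dims[1] + 1
      rest <- g0 %/% dims[1]
      iy <- rest %% dims[2] + 1
      ix <- rest %/% dims[2] + 1
      idx <- cbind(iz = iz, iy = iy, ix = ix)
      vol <- nrow(idx) * voxel_volume
      if (vol < params$min_volume) return(NULL)
      coords <- cbind(x = (ix - 0.5) * spacing[3] + origin[3],
                      y = (iy - 0.5) * spacing[2] + origin[2],
                      z = (iz - 0.5) * spacing[1] + origin[1])
      centroid <- colMeans(coords)
      surf <- extract_surface(idx, spacing = spacing, origin = origin, connectivity = 6L)
      structure(list(label = NA_integer_, voxel_idx = idx, voxel_coords = coords,
                     surface_points = surf, centroid = centroid,
                     mean_radius = mean_radius(surf, centroid),
                     volume = vol, well_id = NA_character_),
                class = "spheroid_object")
    })
    objs <- Filter(Negate(is.null), objs)
    if (length(objs) > 0) {
      cy <- vapply(objs, function(o) o$centroid[["y"]], numeric(1))
      cx <- vapply(objs, function(o) o$centroid[["x"]], numeric(1))
      ord <- order(cy, cx)
      objs <- objs[ord]
      for (i in seq_along(objs)) objs[[i]]$label <- i
    }
    result <- objs
  }
  attr(result, "threshold") <- thr
  attr(result, "all_foreground") <- all_fg
  attr(result, "n_components_raw") <- n_raw
  result
}

#' @export
print.spheroid_object <- function(x, ...) {
  cat(sprintf("spheroid_object %s (label %d): centroid (%.1f, %.1f, %.1f) um, r_bar %.1f um, volume %.3g um^3\n",
              ifelse(is.na(x$well_id), "<unassigned>", x$well_id), x$label,
              x$centroid[1], x$centroid[2], x$centroid[3], x$mean_radius, x$volume))
  invisible(x)
}

#' Assign segmented spheroids to plate wells
#'
#' Each spheroid is assigned to the nearest grid node within `tolerance`
#' in the xy-plane. At most one spheroid per well: the nearest wins and
#' any other candidate is left unassigned (and reported in the
#' `unassigned` attribute).
#'
#' @param spheroids list of `spheroid_object`s
#' @param grid_origin xy position of node A1, um
#' @param pitch centre-to-centre spacing, scalar or (x, y), um
#' @param tolerance maximum xy distance to a node, um; default pitch/2
#' @param grid_rows,grid_cols grid dimensions
#' @return the spheroid list with `well_id` filled in; attribute
#'   `unassigned` holds labels that found no free well within tolerance
#' @export
assign_wells <- function(spheroids, grid_origin, pitch, tolerance = NULL,
                         grid_rows = 8L, grid_cols = 12L) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- c(pitch, pitch)
  if (is.null(tolerance)) tolerance <- min(pitch) / 2
  if (tolerance > min(pitch) / 2)
    stopf("tolerance (%g) must be <= pitch/2 (%g)", tolerance, min(pitch) / 2)
  if (length(spheroids) == 0L) {
    attr(spheroids, "unassigned") <- integer(0)
    return(spheroids)
  }
  cx <- vapply(spheroids, function(o) o$centroid[["x"]], numeric(1))
  cy <- vapply(spheroids, function(o) o$centroid[["y"]], numeric(1))
  col_idx <- round((cx - grid_origin[1]) / pitch[1]) + 1
  row_idx <- round((cy - grid_origin[2]) / pitch[2]) + 1
  node_x <- grid_origin[1] + (col_idx - 1) * pitch[1]
  node_y <- grid_origin[2] + (row_idx - 1) * pitch[2]
  dist_xy <- sqrt((cx - node_x)^2 + (cy - node_y)^2)
  in_grid <- col_idx >= 1 & col_idx <= grid_cols & row_idx >= 1 & row_idx <= grid_rows
  candidate <- in_grid & dist_xy <= tolerance
  well <- ifelse(candidate, well_name(pmax(row_idx, 1), col_idx), NA_character_)
  # nearest wins per well
  assigned <- rep(NA_character_, length(spheroids))
  for (w in unique(well[!is.na(well)])) {
    idx <- which(!is.na(well) & well == w)
    winner <- idx[which.min(dist_xy[idx])]
    assigned[winner] <- w
  }
  for (i in seq_along(spheroids)) spheroids[[i]]$well_id <- assigned[i]
  attr(spheroids, "unassigned") <-
    vapply(spheroids[is.na(assigned)], function(o) o$label, integer(1))
  spheroids
}

#' Tabulate segmented spheroids
#'
#' @param spheroids list of `spheroid_object`s
#' @return a data frame: label, well_id, cx_um, cy_um, cz_um,
#'   mean_radius_um, volume_um3
#' @export
spheroids_to_df <- function(spheroids) {
  if (length(spheroids) == 0L)
    return(data.frame(label = integer(), well_id = character(),
                      cx_um = numeric(), cy_um = numeric(), cz_um = numeric(),
                      mean_radius_um = numeric(), volume_um3 = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(label = vapply(spheroids, function(o) o$label, integer(1)),
             well_id = vapply(spheroids, function(o) o$well_id, character(1)),
             cx_um = vapply(spheroids, function(o) o$centroid[["x"]], numeric(1)),
             cy_um = vapply(spheroids, function(o) o$centroid[["y"]], numeric(1)),
             cz_um = vapply(spheroids, function(o) o$centroid[["z"]], numeric(1)),
             mean_radius_um = vapply(spheroids, function(o) o$mean_radius, numeric(1)),
             volume_um3 = vapply(spheroids, function(o) o$volume, numeric(1)),
             stringsAsFactors = FALSE)
}
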