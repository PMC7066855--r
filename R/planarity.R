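#' Fit a least-squares plane z = p0 + px x + py y to centroids
#'
#' Ordinary least squares of z on (x, y), minimising vertical residuals.
#' This matches the reporting parameterisation directly: p0 is the plane's
#' z-height (um) above the block bottom at the coordinate origin, px and
#' py are dimensionless slopes.
#'
#' @param centroids numeric matrix or data frame with columns (x, y, z) in
#'   um; at least 3 non-collinear points
#' @return an object of class `plane_fit`: p0, px, py, n_points, rss (um^2)
#' @export
fit_plane <- function(centroids) {
  m <- as.matrix(centroids[, 1:3])
  colnames(m) <- c("x", "y", "z")
  n <- nrow(m)
  if (n < 3L) stopf("plane fit requires at least 3 points (got %d)", n)
  X <- cbind(1, m[, "x"], m[, "y"])
  qr_dec <- qr(X)
  if (qr_dec$rank < 3L)
    stopf("degenerate xy configuration (collinear points): plane fit is singular")
  beta <- qr.coef(qr_dec, m[, "z"])
  res <- m[, "z"] - X %*% beta
  structure(list(p0 = unname(beta[1]), px = unname(beta[2]), py = unname(beta[3]),
                 n_points = n, rss = sum(res^2)),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane_fit: z = %.6g %+.6g x %+.6g y (um), n = %d, RSS = %.4g um^2\n",
              x$p0, x$px, x$py, x$n_points, x$rss))
  invisible(x)
}

#' Distance from a point to a fitted plane
#'
#' Default is the perpendicular Euclidean distance
#' |z - (p0 + px x + py y)| / sqrt(1 + px^2 + py^2). At the slope
#' magnitudes typical of deposited arrays (|p| <= 0.02) this differs from
#' the vertical residual |z - (p0 + px x + py y)| by under 0.02%; the
#' vertical mode is provided for comparison.
#'
#' @param points numeric vector (x, y, z) or matrix with such columns, um
#' @param plane a [fit_plane()] result (or list with p0, px, py)
#' @param mode "perpendicular" (default) or "vertical"
#' @return distance(s) in um, >= 0
#' @export
point_plane_distance <- function(points, plane, mode = c("perpendicular", "vertical")) {
  mode <- match.arg(mode)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  resid <- abs(points[, 3] - (plane$p0 + plane$px * points[, 1] + plane$py * points[, 2]))
  if (mode == "vertical") resid
  else resid / sqrt(1 + plane$px^2 + plane$py^2)
}

#' Planarity report for a set of spheroids
#'
#' Fits the least-squares plane to all centroids, computes each spheroid's
#' distance d_i to the plane and the normalized distance d_i / r_bar_i,
#' and summarises the normalized values with mean, median and max. A
#' normalized distance of 0 means the plane passes through the centroid;
#' a value above 1 indicates the plane likely misses the spheroid
#' entirely, and such records are flagged.
#'
#' @param spheroids a list of `spheroid_object`s or a data frame with
#'   columns cx_um, cy_um, cz_um, mean_radius_um (optionally well_id)
#' @param distance_mode "perpendicular" or "vertical"; see
#'   [point_plane_distance()]
#' @return an object of class `planarity_report`: `plane` (a `plane_fit`),
#'   `records` (well_id, d_um, r_bar_um, normalized, misses_plane),
#'   `mean`, `median`, `max` of the normalized values
#' @export
planarity_report <- function(spheroids, distance_mode = c("perpendicular", "vertical")) {
  distance_mode <- match.arg(distance_mode)
  df <- if (is.data.frame(spheroids)) spheroids else spheroids_to_df(spheroids)
  if (nrow(df) < 3L) stopf("planarity report requires at least 3 spheroids")
  cent <- cbind(df$cx_um, df$cy_um, df$cz_um)
  plane <- fit_plane(cent)
  d <- point_plane_distance(cent, plane, mode = distance_mode)
  r_bar <- df$mean_radius_um
  if (any(r_bar <= 0)) stopf("all mean radii must be positive")
  normalized <- d / r_bar
  records <- data.frame(well_id = df$well_id %||% NA_character_,
                        d_um = d, r_bar_um = r_bar, normalized = normalized,
                        misses_plane = normalized > 1,
                        stringsAsFactors = FALSE)
  structure(list(plane = plane, records = records,
                 mean = mean(normalized), median = median(normalized),
                 max = max(normalized), distance_mode = distance_mode),
            class = "planarity_report")
}

#' @export
print.planarity_report <- function(x, ...) {
  print(x$plane)
  cat(sprintf("normalized distance d_i/r_bar_i over %d spheroids: mean %.4f, median %.4f, max %.4f\n",
              nrow(x$records), x$mean, x$median, x$max))
  n_miss <- sum(x$records$misses_plane)
  if (n_miss > 0)
    cat(sprintf("%d spheroid(s) with normalized distance > 1 (plane likely misses them)\n", n_miss))
  invisible(x)
}

#' Summarise per-sample means as mean +/- SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of per-sample summary values, the convention used to aggregate
#' per-block planarity means across replicate blocks.
#'
#' @param sample_means numeric vector, length >= 2
#' @return a list with `mean` and `sd`
#' @export
summarize_samples <- function(sample_means) {
  sample_means <- as.numeric(sample_means)
  if (length(sample_means) < 2L)
    stopf("at least 2 values are required for a mean +/- SD summary")
  list(mean = mean(sample_means), sd = sd(sample_means))
}
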