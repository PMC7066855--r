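#' LOESS trend surface through spheroid centroids
#'
#' Fits a locally weighted polynomial regression of centroid z on (x, y)
#' to visualise non-planar deposition trends (e.g. a parabolic depression
#' of the agar block). Each local fit uses the `span` fraction of nearest
#' neighbours with tricube weights. The coefficient of determination is
#' computed at the observed centroids: R^2 = 1 - RSS/TSS.
#'
#' Defaults span = 0.5, degree = 2: a local quadratic is the smallest
#' local model able to follow a parabolic depression.
#'
#' @param centroids matrix or data frame with columns (x, y, z), um
#' @param span fraction of points used in each local fit, in (0, 1]
#' @param degree local polynomial degree, 1 or 2
#' @return an object of class `trend_surface`: `fitted_z` at each input
#'   centroid, `r_squared` (NA with `r_squared_defined = FALSE` when the
#'   input z is constant), `span`, `degree`, and the underlying `loess`
#'   model
#' @export
loess_surface <- function(centroids, span = 0.5, degree = 2) {
  if (!(span > 0 && span <= 1)) stopf("span must be in (0, 1]")
  if (!degree %in% c(1, 2)) stopf("degree must be 1 or 2")
  m <- as.matrix(centroids[, 1:3])
  df <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
  n_min <- (degree + 1) * (degree + 2) / 2
  if (ceiling(span * nrow(df)) < n_min)
    stopf("span * n (%g) too small for a degree-%d local fit (needs >= %g points)",
          span * nrow(df), degree, n_min)
  model <- tryCatch(
    loess(z ~ x + y, data = df, span = span, degree = degree,
          family = "gaussian", surface = "direct",
          control = loess.control(iterations = 1)),
    error = function(e) stopf("degenerate LOESS neighbourhood: %s", conditionMessage(e)))
  fitted_z <- as.numeric(predict(model, df))
  tss <- sum((df$z - mean(df$z))^2)
  if (tss == 0) {
    r2 <- NA_real_; defined <- FALSE
  } else {
    r2 <- 1 - sum((df$z - fitted_z)^2) / tss; defined <- TRUE
  }
  structure(list(fitted_z = fitted_z, r_squared = r2,
                 r_squared_defined = defined,
                 span = span, degree = degree, model = model),
            class = "trend_surface")
}

#' @export
print.trend_surface <- function(x, ...) {
  cat(sprintf("trend_surface: LOESS span %.2f, degree %d, R^2 = %s\n",
              x$span, x$degree,
              if (x$r_squared_defined) sprintf("%.4f", x$r_squared)
              else "undefined (constant z)"))
  invisible(x)
}

#' Predict the trend surface at new xy positions
#'
#' @param object a `trend_surface`
#' @param newdata matrix or data frame with columns (x, y)
#' @param ... unused
#' @return predicted z values, um
#' @export
predict.trend_surface <- function(object, newdata, ...) {
  nd <- as.data.frame(as.matrix(newdata)[, 1:2, drop = FALSE])
  names(nd) <- c("x", "y")
  as.numeric(predict(object$model, nd))
}
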