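#' Published planarity statistics for four reference blocks
#'
#' Plane-fit coefficients (z = p0 + px x + py y, um) and normalized
#' distance summaries (mean, median, max of d_i / r_bar_i) published for
#' four CLSM-imaged spheroid microarray blocks produced with a
#' centrifugal funnel-array transfer device. These printed values serve as inputs
#' for reference calculations (e.g. aggregating the per-block means to
#' 0.27 +/- 0.064) and as generating parameters for synthetic scenes; the
#' underlying image data were not deposited.
#'
#' @return a data frame: sample, p0_um, px, py, mean_norm_dist,
#'   median_norm_dist, max_norm_dist
#' @export
reference_planarity <- function() {
  path <- system.file("extdata", "reference_planarity.csv", package = "spheroplane",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
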