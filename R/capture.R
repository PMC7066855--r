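#' Per-well capture success across plates
#'
#' Elementwise mean of boolean (or fractional) plate maps: the fraction of
#' plates in which each well's spheroid was captured.
#'
#' @param maps list of [plate_map()] objects with identical shape
#' @return a [plate_map()] of per-well success fractions
#' @export
per_well_success <- function(maps) {
  if (length(maps) < 1L) stopf("at least one plate map is required")
  stopifnot(all(vapply(maps, inherits, logical(1), "well_plate_map")))
  acc <- Reduce(`+`, lapply(maps, function(m) m$values))
  plate_map(acc / length(maps))
}

#' Grand capture summary across plates
#'
#' Per-plate success fraction (captured wells / 96), averaged across
#' plates, with the n - 1 sample standard deviation across plates.
#'
#' @param maps list of [plate_map()] objects
#' @return a list: `mean`, `sd`, `per_plate` (vector of plate fractions),
#'   `n_plates`
#' @export
grand_summary <- function(maps) {
  if (length(maps) < 2L) stopf("at least 2 plates are required for a mean +/- SD summary")
  fr <- vapply(maps, function(m) mean(m$values), numeric(1))
  list(mean = mean(fr), sd = sd(fr), per_plate = fr, n_plates = length(maps))
}

one_sample_t <- function(x, mu) {
  n <- length(x)
  xbar <- mean(x)
  s <- sd(x)
  if (s == 0) {
    if (xbar == mu) return(list(t = 0, df = n - 1, p = 1, sem = 0, infinite_t = FALSE))
    return(list(t = sign(xbar - mu) * Inf, df = n - 1, p = 0, sem = 0, infinite_t = TRUE))
  }
  tt <- (xbar - mu) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), sem = s / sqrt(n),
       infinite_t = FALSE)
}

#' Row and column capture-success tests
#'
#' For each plate row (and column), tests whether its mean capture success
#' differs from the grand mean success over all wells, using a two-sided
#' one-sample t-test. The default sample unit is the per-plate row (or
#' column) mean, n = number of plates, treating plates as the independent
#' replicates; `unit = "well"` instead uses the per-well mean fractions
#' within the row/column as the sample. The null value is the grand mean
#' computed from the same data. Significance uses strict p < alpha.
#'
#' @param maps list of [plate_map()] objects (>= 2)
#' @param alpha significance level (default 0.01)
#' @param unit "plate" (default) or "well"
#' @param bonferroni apply a Bonferroni correction within rows and within
#'   columns (default FALSE, matching uncorrected per-row/column reporting)
#' @return a list with data frames `row_stats` and `col_stats` (level,
#'   mean, sem, t, df, p, significant, infinite_t), plus `grand_mean` and
#'   `alpha`
#' @export
row_col_tests <- function(maps, alpha = 0.01, unit = c("plate", "well"),
                          bonferroni = FALSE) {
  unit <- match.arg(unit)
  if (length(maps) < 2L) stopf("at least 2 plates are required")
  vals <- lapply(maps, function(m) m$values)
  grand <- mean(vapply(vals, mean, numeric(1)))
  mean_map <- Reduce(`+`, vals) / length(vals)

  run <- function(levels, slice_fun, n_levels) {
    k <- if (bonferroni) n_levels else 1
    out <- lapply(seq_len(n_levels), function(i) {
      x <- slice_fun(i)
      tst <- one_sample_t(x, grand)
      p_adj <- min(1, tst$p * k)
      data.frame(level = levels[i], mean = mean(x), sem = tst$sem,
                 t = tst$t, df = tst$df, p = p_adj,
                 significant = p_adj < alpha, infinite_t = tst$infinite_t,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  if (unit == "plate") {
    row_stats <- run(LETTERS[1:8], function(r)
      vapply(vals, function(v) mean(v[r, ]), numeric(1)), 8L)
    col_stats <- run(as.character(1:12), function(cc)
      vapply(vals, function(v) mean(v[, cc]), numeric(1)), 12L)
  } else {
    row_stats <- run(LETTERS[1:8], function(r) mean_map[r, ], 8L)
    col_stats <- run(as.character(1:12), function(cc) mean_map[, cc], 12L)
  }
  list(row_stats = row_stats, col_stats = col_stats,
       grand_mean = grand, alpha = alpha, unit = unit,
       n_plates = length(maps))
}

#' Full capture-statistics summary
#'
#' Bundles the per-well mean map, the grand mean +/- SD across plates, and
#' the row/column t-tests.
#'
#' @inheritParams row_col_tests
#' @return an object of class `capture_summary`
#' @export
capture_summary <- function(maps, alpha = 0.01, unit = c("plate", "well"),
                            bonferroni = FALSE) {
  unit <- match.arg(unit)
  gs <- grand_summary(maps)
  tests <- row_col_tests(maps, alpha = alpha, unit = unit, bonferroni = bonferroni)
  structure(list(per_well_mean = per_well_success(maps),
                 grand_mean = gs$mean, grand_sd = gs$sd,
                 per_plate = gs$per_plate,
                 row_stats = tests$row_stats, col_stats = tests$col_stats,
                 alpha = alpha, n_plates = length(maps), unit = unit),
            class = "capture_summary")
}

#' @export
print.capture_summary <- function(x, ...) {
  cat(sprintf("capture_summary over %d plates: grand mean %.1f%% +/- %.1f%% (SD)\n",
              x$n_plates, 100 * x$grand_mean, 100 * x$grand_sd))
  sig_r <- x$row_stats$level[x$row_stats$significant]
  sig_c <- x$col_stats$level[x$col_stats$significant]
  cat(sprintf("rows differing from grand mean (p < %g): %s\n", x$alpha,
              if (length(sig_r)) paste(sig_r, collapse = ", ") else "none"))
  cat(sprintf("columns differing from grand mean (p < %g): %s\n", x$alpha,
              if (length(sig_c)) paste(sig_c, collapse = ", ") else "none"))
  invisible(x)
}
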