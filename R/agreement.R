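#' Paired angle measurements
#'
#' Container for two measurement series over the same participants; pairs
#' with any missing value are excluded from agreement statistics.
#'
#' @param ids participant labels.
#' @param a,b numeric vectors of angles (degrees), `NA` allowed.
#' @return Object of class `paired_measurements`.
#' @export
paired_measurements <- function(ids, a, b) {
  if (length(ids) != length(a) || length(a) != length(b))
    stop("paired_measurements: ids, a and b must have equal length", call. = FALSE)
  structure(list(ids = as.character(ids), a = as.numeric(a), b = as.numeric(b)),
            class = "paired_measurements")
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` over complete pairs; bias is their mean, SD the
#' population standard deviation (divisor n, the convention that reproduces
#' the published limits of agreement), limits of agreement
#' `bias +/- 1.96 * SD`, and the LoA confidence half-width
#' `1.96 * sqrt(3/n) * SD`. Pairs whose absolute difference exceeds
#' `outlier_threshold` (default 5 degrees, the clinically relevant difference
#' for volar tilt) are flagged.
#'
#' @param pairs a [paired_measurements()] (or a list with `ids`, `a`, `b`).
#' @param outlier_threshold degrees (default 5).
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return Object of class `bland_altman`: `n`, `bias`, `sd`, `loa_low`,
#'   `loa_high`, `loa_ci_halfwidth`, `outlier_ids`, `differences`, `means`.
#' @export
bland_altman <- function(pairs, outlier_threshold = 5,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(pairs$a) & !is.na(pairs$b)
  if (sum(ok) < 3L)
    stop("bland_altman: fewer than 3 complete pairs", call. = FALSE)
  d <- pairs$a[ok] - pairs$b[ok]
  m <- (pairs$a[ok] + pairs$b[ok]) / 2
  ids <- pairs$ids[ok]
  n <- length(d)
  bias <- mean(d)
  s <- if (sd_type == "population") sqrt(mean((d - bias)^2)) else stats::sd(d)
  structure(list(n = n, bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 loa_ci_halfwidth = 1.96 * sqrt(3 / n) * s,
                 outlier_threshold = outlier_threshold,
                 outlier_ids = ids[abs(d) > outlier_threshold],
                 differences = stats::setNames(d, ids),
                 means = stats::setNames(m, ids),
                 sd_type = sd_type),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d complete pairs, %s SD)\n", x$n, x$sd_type))
  cat(sprintf("  bias %.2f, SD %.2f, LoA [%.2f, %.2f]\n",
              x$bias, x$sd, x$loa_low, x$loa_high))
  cat(sprintf("  LoA 95%% CI half-width: %.2f (1.96*sqrt(3/n)*SD)\n",
              x$loa_ci_halfwidth))
  if (length(x$outlier_ids))
    cat(sprintf("  outliers (|diff| > %g): %s\n", x$outlier_threshold,
                paste(x$outlier_ids, collapse = ", ")))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference against mean with bias and limits-of-agreement lines and the
#' clinically relevant threshold marked.
#'
#' @param x a [bland_altman()] result.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(x, main = "Bland-Altman agreement", ...) {
  stopifnot(inherits(x, "bland_altman"))
  ylim <- range(c(x$differences, x$loa_low, x$loa_high,
                  x$outlier_threshold, -x$outlier_threshold))
  graphics::plot(x$means, x$differences, pch = 19,
                 xlab = "mean of methods (deg)",
                 ylab = "difference (deg)", ylim = ylim, main = main, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  graphics::abline(h = c(-1, 1) * x$outlier_threshold, lty = 3, col = "purple")
  invisible(x)
}

#' Mean of two raters' measurements
#'
#' Element-wise mean; missing values propagate, so a participant missing
#' either rater is excluded downstream.
#'
#' @param r1,r2 numeric vectors of equal length.
#' @return Numeric vector of means.
#' @export
mean_rater <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop("mean_rater: length mismatch", call. = FALSE)
  (r1 + r2) / 2
}

#' Euclidean landmark placement discrepancy
#'
#' Distance, per corresponding landmark, between two landmark sets expressed
#' in the same frame (typically each method's anatomical CS coordinates).
#'
#' @param set_a,set_b named lists of length-3 points; names are matched.
#' @return Named numeric vector of distances (mm).
#' @export
landmark_discrepancy <- function(set_a, set_b) {
  keys <- intersect(names(set_a), names(set_b))
  keys <- keys[vapply(keys, function(k)
    length(set_a[[k]]) == 3L && length(set_b[[k]]) == 3L, TRUE)]
  if (length(keys) == 0L)
    stop("landmark_discrepancy: no comparable landmarks", call. = FALSE)
  vapply(keys, function(k) sqrt(sum((set_a[[k]] - set_b[[k]])^2)), 0)
}

#' Angle between two longitudinal axes
#'
#' Undirected comparison: the result is `min(theta, 180 - theta)`, in
#' \[0, 90\] degrees.
#'
#' @param z_a,z_b axis vectors.
#' @return Angle in degrees.
#' @export
axis_angle_difference <- function(z_a, z_b) {
  th <- angle_between(z_a, z_b)
  min(th, 180 - th)
}

#' Load a packaged measurement table
#'
#' The per-participant volar tilt and radial inclination tables of the
#' validation study, shipped as CSV: `"malunited"` (2D consensus, automatic,
#' and two manual 3D raters, n = 16 with one missing 2D row) and `"healthy"`
#' (2D, automatic, one manual 3D rater; three missing 2D rows). `NA` entries
#' are preserved.
#'
#' @param table `"malunited"` or `"healthy"`.
#' @return A data.frame.
#' @export
measurement_table <- function(table = c("malunited", "healthy")) {
  table <- match.arg(table)
  file <- system.file("extdata",
                      if (table == "malunited") "table1_malunited.csv"
                      else "table2_healthy.csv",
                      package = "radtilt", mustWork = TRUE)
  utils::read.csv(file)
}

#' Summary rows of a measurement table
#'
#' Per-column mean and sample SD (divisor n - 1, the descriptive convention
#' of the tables' Mean (SD) row) plus, for every 3D method column, the
#' signed mean difference from the 2D column with its population SD (the
#' bias convention of the agreement analysis). Missing values are excluded
#' pairwise.
#'
#' @param table `"malunited"` or `"healthy"`, or a data.frame in the fixture
#'   layout.
#' @return A list with `mean_sd` (data.frame: column, n, mean, sd) and
#'   `delta_2d` (data.frame: column, n, bias, sd).
#' @export
summarize_table <- function(table = c("malunited", "healthy")) {
  df <- if (is.data.frame(table)) table else measurement_table(table)
  num <- df[, setdiff(names(df), "id"), drop = FALSE]
  mean_sd <- data.frame(
    column = names(num),
    n = vapply(num, function(x) sum(!is.na(x)), 0L),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), 0),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), 0),
    row.names = NULL)
  delta <- NULL
  for (angle in c("vt", "ri")) {
    ref <- paste0(angle, "_2d")
    if (!ref %in% names(num)) next
    for (col in grep(paste0("^", angle, "_"), names(num), value = TRUE)) {
      if (col == ref) next
      ok <- !is.na(num[[col]]) & !is.na(num[[ref]])
      d <- num[[col]][ok] - num[[ref]][ok]
      delta <- rbind(delta, data.frame(
        column = col, n = length(d), bias = mean(d),
        sd = sqrt(mean((d - mean(d))^2))))
    }
  }
  list(mean_sd = mean_sd, delta_2d = delta)
}
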