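# Log-log (allometry-style) machinery: paired-feature fits, slope-ratio
# rates, the time ruler, additive complexity, and factor-of-two jumps.

#' Per-group log-log fits of one feature against another
#'
#' OLS of `log(y)` on `log(x)` within each group. The slope of such a plot
#' is the ratio of the two features' complexity growth rates with time
#' removed, which is what makes it usable as a power-law exponent and as
#' the first operand of the slope-ratio method.
#'
#' @param x_values,y_values strictly positive feature values.
#' @param groups optional vector of group labels (e.g. prokaryote /
#'   eukaryote); a single group when omitted. Groups with fewer than two
#'   points are skipped with a warning.
#' @param log_base log base; default 10.
#' @return a named list of `loglog_fit` objects, one per retained group,
#'   each with `slope`, `intercept`, `pearson_r`, `slope_se`, `group`, `n`,
#'   `x_log_range`, `log_base`.
#' @export
fit_loglog <- function(x_values, y_values, groups = NULL, log_base = 10) {
  stopifnot(length(x_values) == length(y_values))
  if (is.null(groups)) groups <- rep("all", length(x_values))
  lx <- complexity_transform(x_values, log_base)
  ly <- complexity_transform(y_values, log_base)
  out <- list()
  for (g in unique(as.character(groups))) {
    i <- which(groups == g)
    if (length(i) < 2L || length(unique(lx[i])) < 2L) {
      warning(sprintf("group '%s' has fewer than 2 distinct points; skipped", g))
      next
    }
    f <- .wols(lx[i], ly[i])
    out[[g]] <- structure(
      list(slope = f$slope, intercept = f$intercept, pearson_r = f$pearson_r,
           slope_se = f$slope_se, group = g, n = f$n,
           x_log_range = range(lx[i]), log_base = log_base),
      class = "loglog_fit")
  }
  if (!length(out)) .stop_domain("no group had >= 2 distinct points")
  out
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("Log-log fit [%s]: slope %.3f, intercept %.3f, r = %.3f (n = %d)\n",
              x$group, x$slope, x$intercept, x$pearson_r, x$n))
  invisible(x)
}

#' Complexity growth rate by the slope-ratio method
#'
#' A log-log slope between features y and x equals the ratio of their
#' time-growth rates, so multiplying it by x's calibrated rate (Gyr^-1)
#' yields y's rate. Rounding is left to the caller / reporting layer.
#'
#' @param loglog_slope dimensionless log-log slope.
#' @param base_rate calibrated complexity growth rate of the x feature
#'   (Gyr^-1).
#' @return the derived rate in Gyr^-1 (plain product, full precision).
#' @examples
#' slope_ratio_rate(0.96, 0.81)  # gene-number rate from the DNA-length rate
#' @export
slope_ratio_rate <- function(loglog_slope, base_rate) {
  if (!is.finite(loglog_slope) || !is.finite(base_rate)) {
    .stop_domain("slope_ratio_rate arguments must be finite")
  }
  loglog_slope * base_rate
}

#' Metabolic-rate growth rate from the allometric exponent
#'
#' Metabolic rate scales allometrically with mass (exponent ~0.75), so its
#' complexity growth rate is that exponent times the mass (cell volume)
#' growth rate.
#'
#' @param allometric_exponent metabolic-rate-vs-mass scaling exponent (> 0);
#'   conventionally 0.75.
#' @param mass_rate mass complexity growth rate in Gyr^-1 (> 0).
#' @return derived metabolic complexity growth rate (Gyr^-1).
#' @export
metabolic_rate_from_allometry <- function(allometric_exponent = 0.75,
                                          mass_rate) {
  if (!is.finite(allometric_exponent) || allometric_exponent <= 0 ||
      !is.finite(mass_rate) || mass_rate <= 0) {
    .stop_domain("both arguments must be finite and > 0")
  }
  allometric_exponent * mass_rate
}

#' Build a time ruler for a log-log plot
#'
#' Least-squares affine map from an abscissa coordinate of a log-log plot
#' (log units of the x feature) to time in Gyr before present, constructed
#' from anchor pairs with known times (e.g. present-day organisms, the
#' prokaryote-to-eukaryote transition at ~2.2 Gyr BP, a minimal cell at
#' ~3.75 Gyr BP). The map may be evaluated beyond its anchors to date
#' earlier, simpler feature values.
#'
#' @param coordinates numeric ruler coordinates (log units); must be
#'   distinct.
#' @param times_bp times in Gyr BP, strictly monotone in the coordinate.
#' @return an object of class `time_ruler` with the affine coefficients
#'   (`slope`, `intercept`, time = intercept + slope * coordinate), the
#'   anchors, their coordinate range and residuals.
#' @export
build_time_ruler <- function(coordinates, times_bp) {
  coordinates <- as.numeric(coordinates); times_bp <- as.numeric(times_bp)
  stopifnot(length(coordinates) == length(times_bp))
  if (length(coordinates) < 2L) .stop_domain("a ruler needs >= 2 anchors")
  if (anyDuplicated(coordinates)) .stop_domain("ruler coordinates must be distinct")
  o <- order(coordinates)
  dt <- diff(times_bp[o])
  if (!(all(dt > 0) || all(dt < 0))) {
    .stop_domain("anchor times must be strictly monotone in the coordinate")
  }
  f <- .wols(coordinates, times_bp)
  structure(list(slope = f$slope, intercept = f$intercept,
                 anchors = data.frame(coordinate = coordinates[o],
                                      time_bp = times_bp[o]),
                 coordinate_range = range(coordinates),
                 residuals = times_bp - (f$intercept + f$slope * coordinates)),
            class = "time_ruler")
}

#' @export
print.time_ruler <- function(x, ...) {
  cat(sprintf("Time ruler: time_bp = %.4g %+.4g * coordinate (%d anchors)\n",
              x$intercept, x$slope, nrow(x$anchors)))
  invisible(x)
}

#' Read a time off a ruler
#'
#' @param ruler a [build_time_ruler()] result.
#' @param coordinate log-unit coordinate(s) to date.
#' @return numeric time(s) in Gyr BP, with an `extrapolated` attribute
#'   (logical vector) marking queries outside the anchor range.
#' @export
ruler_time_at <- function(ruler, coordinate) {
  stopifnot(inherits(ruler, "time_ruler"))
  t <- ruler$intercept + ruler$slope * coordinate
  attr(t, "extrapolated") <- coordinate < ruler$coordinate_range[1L] |
    coordinate > ruler$coordinate_range[2L]
  t
}

#' Invert a time ruler
#'
#' Exact inverse of the affine ruler map: the coordinate whose ruler time
#' is `time_bp`.
#'
#' @param ruler a [build_time_ruler()] result.
#' @param time_bp time(s) in Gyr BP.
#' @return numeric coordinate(s) in log units.
#' @export
ruler_coordinate_at <- function(ruler, time_bp) {
  stopifnot(inherits(ruler, "time_ruler"))
  (time_bp - ruler$intercept) / ruler$slope
}

#' Additive combination of two complexities
#'
#' Complexity is additive over orthogonal components: the combined
#' complexity of two features is the sum of their log values (e.g.
#' log(genes) + log(cell types) for multicellular organisms, which places
#' eukaryotes back on the prokaryote gene-vs-genome line).
#'
#' @param log_a,log_b finite log-unit values (vectorised).
#' @return element-wise sum.
#' @export
combine_complexities <- function(log_a, log_b) {
  if (any(!is.finite(log_a)) || any(!is.finite(log_b))) {
    .stop_domain("combine_complexities requires finite log values")
  }
  log_a + log_b
}

#' Factor-of-two jump analysis between group lines
#'
#' Measures the vertical offset between two groups' log-log regression
#' lines at the midpoint of their shared abscissa range and expresses it as
#' a multiplicative factor, together with the nearest power of two.
#' Hierarchical transitions (e.g. prokaryote to eukaryote in disordered
#' binding sites) appear as jumps by factors of ~2^k.
#'
#' @param fits list of at least two `loglog_fit` objects (from
#'   [fit_loglog()]); the first two groups are compared, second over first.
#' @return an object of class `jump_analysis` with `jump_factor`
#'   (continuous), `nearest_power_of_2`, `log2_offsets` (each group's line
#'   level at the evaluation point, in log2 units), and
#'   `eval_coordinate`.
#' @export
jump_analysis <- function(fits) {
  if (length(fits) < 2L) .stop_domain("jump analysis needs >= 2 group fits")
  f1 <- fits[[1L]]; f2 <- fits[[2L]]
  stopifnot(inherits(f1, "loglog_fit"), inherits(f2, "loglog_fit"))
  lo <- max(f1$x_log_range[1L], f2$x_log_range[1L])
  hi <- min(f1$x_log_range[2L], f2$x_log_range[2L])
  if (lo > hi) {
    warning("group abscissa ranges do not overlap; evaluating at the boundary between them")
    xm <- (min(f1$x_log_range[2L], f2$x_log_range[2L]) +
             max(f1$x_log_range[1L], f2$x_log_range[1L])) / 2
  } else {
    xm <- (lo + hi) / 2
  }
  l1 <- f1$intercept + f1$slope * xm
  l2 <- f2$intercept + f2$slope * xm
  base <- f1$log_base
  factor <- base^(l2 - l1)
  to_log2 <- log2(base)
  structure(list(
    jump_factor = factor,
    nearest_power_of_2 = 2^round(log2(factor)),
    log2_offsets = setNames(c(l1, l2) * to_log2, c(f1$group, f2$group)),
    eval_coordinate = xm,
    groups = c(f1$group, f2$group)),
    class = "jump_analysis")
}

#' @export
print.jump_analysis <- function(x, ...) {
  cat(sprintf("Jump %s -> %s: factor %.3g (nearest power of two: %g)\n",
              x$groups[1L], x$groups[2L], x$jump_factor,
              x$nearest_power_of_2))
  invisible(x)
}
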