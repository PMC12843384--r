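# Log-linear complexity regression: fits of log(feature) vs origin time,
# anchor intersections, the Earth-only scenario, and the summary table.

# Closed-form weighted OLS of y on x.  Kept as plain arithmetic (not lm())
# so the Monte Carlo engine can call it cheaply and so the test suite can
# check it against an independent normal-equations / lm() oracle.
.wols <- function(x, y, w = NULL) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) return(NULL)
  sxy <- sum(w * (x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  df <- n - 2L
  s2 <- if (df > 0) sum(w * res^2) / df else NA_real_
  syy <- sum(w * (y - yb)^2)
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  list(slope = slope, intercept = intercept, pearson_r = r,
       slope_se = if (df > 0) sqrt(s2 / sxx) else NA_real_,
       intercept_se = if (df > 0) sqrt(s2 * (1 / sw + xb^2 / sxx)) else NA_real_,
       n = n)
}

# sd of log(value) from a raw-scale mean +/- sd interval: transform the two
# bounds and halve the log-range; one-sided if mean - sd is not positive.
.log_sd <- function(mean, sd, log_base) {
  upper <- log(mean + sd, base = log_base)
  lower <- ifelse(mean - sd > 0, log(mean - sd, base = log_base), NA_real_)
  ifelse(is.na(lower), upper - log(mean, base = log_base), (upper - lower) / 2)
}

#' Fit a log-linear complexity trend
#'
#' Ordinary (or weighted) least squares of `log_base(value)` on origin time
#' in Gyr before present. Because time runs positive into the past, the
#' fitted slope on that axis is negative for a growing feature; the returned
#' `slope_a` is its magnitude, the complexity growth rate in Gyr^-1.
#'
#' @param series a [feature_series].
#' @param weighted logical; if `TRUE`, weight each taxon by the inverse
#'   variance of its log-value (log-sd derived from the raw mean +/- sd
#'   bounds, half the log-range).
#' @param weight_rule `"inverse_log_variance"` (default when `weighted`) or
#'   `"equal"`; equal weights reproduce the unweighted fit exactly.
#' @param excluded_taxa character vector of taxa to drop before fitting.
#' @param log_base log base; defaults to the series' own.
#' @return an object of class `complexity_fit` with elements `slope_a`
#'   (magnitude, Gyr^-1), `slope_bp` (signed slope on the BP axis),
#'   `intercept_b` (log units at present), `pearson_r`, `slope_se`,
#'   `intercept_se`, `n_points`, `time_range`, `weighted`, `excluded_taxa`,
#'   `feature_id`, `log_base`.
#' @examples
#' s <- feature_series("toy", data.frame(taxon = c("a", "b"),
#'                                       time_gyr_bp = c(1, 3),
#'                                       value = c(10, 1)))
#' fit_loglinear(s)$slope_a  # 0.5
#' @export
fit_loglinear <- function(series, weighted = FALSE,
                          weight_rule = c("inverse_log_variance", "equal"),
                          excluded_taxa = character(),
                          log_base = series$log_base) {
  stopifnot(inherits(series, "feature_series"))
  weight_rule <- match.arg(weight_rule)
  obs <- series$observations
  if (length(excluded_taxa)) obs <- obs[!(obs$taxon %in% excluded_taxa), ]
  if (nrow(obs) < 2L || length(unique(obs$time_gyr_bp)) < 2L) {
    .stop_domain("need >= 2 observations with >= 2 distinct origin times to fit")
  }
  y <- complexity_transform(obs$value, log_base, labels = obs$taxon)
  w <- NULL
  if (weighted && weight_rule == "inverse_log_variance") {
    if (any(is.na(obs$sd))) {
      .stop_domain("inverse-variance weighting requires `sd` for all included taxa (missing for %s)",
                   obs$taxon[which(is.na(obs$sd))[1L]])
    }
    if (any(obs$sd <= 0)) {
      .stop_domain("inverse-variance weighting requires strictly positive `sd` (taxon %s)",
                   obs$taxon[which(obs$sd <= 0)[1L]])
    }
    w <- 1 / .log_sd(obs$value, obs$sd, log_base)^2
  }
  f <- .wols(obs$time_gyr_bp, y, w)
  if (is.null(f)) .stop_domain("zero variance in origin times; cannot fit")
  structure(list(feature_id = series$feature_id,
                 slope_a = abs(f$slope), slope_bp = f$slope,
                 intercept_b = f$intercept, pearson_r = f$pearson_r,
                 slope_se = f$slope_se, intercept_se = f$intercept_se,
                 n_points = f$n,
                 time_range = range(obs$time_gyr_bp),
                 weighted = isTRUE(weighted) && weight_rule != "equal",
                 weight_rule = if (weighted) weight_rule else "equal",
                 excluded_taxa = excluded_taxa,
                 log_base = log_base),
            class = "complexity_fit")
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat(sprintf("Complexity fit [%s]%s: slope %.3f Gyr^-1, intercept %.3f, r = %.3f (n = %d)\n",
              x$feature_id, if (x$weighted) " (weighted)" else "",
              x$slope_a, x$intercept_b, x$pearson_r, x$n_points))
  invisible(x)
}

# Evaluate a fitted line at a time (Gyr BP), in log units.
.fit_value_at <- function(fit, time_bp) {
  fit$intercept_b + fit$slope_bp * time_bp
}

#' Intersect a fitted complexity trend with an early anchor
#'
#' Solves the fitted line `log(x) = b + slope_bp * t` for the time at which
#' it reaches the anchor's log value: the era when the feature could have
#' been at its minimal-complexity form under continued linear growth.
#'
#' @param fit a `complexity_fit` with non-zero slope.
#' @param anchor an [early_anchor].
#' @return an object of class `intersection_result` with `time_bp` (Gyr
#'   before present), `anchor`, and `extrapolated` (TRUE when the time lies
#'   outside the fitted data's time range, which it essentially always does
#'   for the shipped anchors).
#' @export
intersect_with_anchor <- function(fit, anchor) {
  stopifnot(inherits(fit, "complexity_fit"), inherits(anchor, "early_anchor"))
  if (!is.finite(fit$slope_bp) || fit$slope_bp == 0) {
    .stop_domain("fitted slope is zero; the trend never reaches the anchor")
  }
  la <- log(anchor$value, base = fit$log_base)
  time_bp <- (la - fit$intercept_b) / fit$slope_bp
  stopifnot(abs(.fit_value_at(fit, time_bp) - la) <= 1e-9)
  structure(list(time_bp = time_bp, anchor = anchor,
                 extrapolated = time_bp < fit$time_range[1L] ||
                   time_bp > fit$time_range[2L],
                 feature_id = fit$feature_id),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("Intersection [%s]: %.2f Gyr BP at anchor '%s'%s\n",
              x$feature_id, x$time_bp, x$anchor$label,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Earth-only complexity growth scenario
#'
#' If all pre-biotic complexity growth happened on Earth, complexity had to
#' climb from the early anchor (placed at the time liquid water appeared) to
#' the LUCA-level value in the short interval before the first organisms.
#' This returns the pre-life growth rate that requires and its ratio to the
#' observed evolutionary rate.
#'
#' @param anchor an [early_anchor] (the starting complexity).
#' @param luca_time_bp,luca_value time (Gyr BP) and raw feature value of the
#'   LUCA-level point; `luca_value` must exceed the anchor value.
#' @param water_time_bp time liquid water appeared (Gyr BP); must be older
#'   than `luca_time_bp`.
#' @param evolutionary_slope observed complexity growth rate (Gyr^-1) to
#'   compare against.
#' @param log_base log base; default 10.
#' @return list with `required_slope` (Gyr^-1) and `ratio`
#'   (`required_slope / evolutionary_slope`).
#' @export
earth_only_scenario <- function(anchor, luca_time_bp, luca_value,
                                water_time_bp, evolutionary_slope,
                                log_base = 10) {
  stopifnot(inherits(anchor, "early_anchor"))
  if (water_time_bp <= luca_time_bp) {
    .stop_domain("`water_time_bp` must be older (larger) than `luca_time_bp`")
  }
  if (luca_value <= anchor$value) {
    .stop_domain("`luca_value` must exceed the anchor value")
  }
  dlog <- complexity_transform(luca_value, log_base) -
    complexity_transform(anchor$value, log_base)
  required <- dlog / (water_time_bp - luca_time_bp)
  list(required_slope = required, ratio = required / evolutionary_slope)
}

#' One row of the complexity summary table
#'
#' @param feature_id feature identifier.
#' @param slope complexity growth rate magnitude (Gyr^-1), > 0.
#' @param intersection intersection time with the early anchor (Gyr BP), or
#'   `NA` for features without a usable anchor (metabolic rate).
#' @param anchor_label label of the early feature.
#' @return a one-row data frame.
#' @export
summary_row <- function(feature_id, slope, intersection = NA_real_,
                        anchor_label = NA_character_) {
  if (!is.na(slope) && slope <= 0) .stop_domain("summary slope must be > 0")
  data.frame(feature_id = feature_id, complexity_slope = slope,
             intersection_time = intersection, anchor_label = anchor_label,
             stringsAsFactors = FALSE)
}

#' Aggregate per-feature fits into a summary table
#'
#' Computes the mean and sample (n-1) standard deviation of the complexity
#' slopes over all rows that carry a slope, and of the intersection times
#' over all rows that carry one. Features without an intersection (the
#' metabolic rate, whose anchor is undefined) simply do not contribute to
#' the intersection aggregate.
#'
#' @param rows a data frame with columns `feature_id`, `complexity_slope`,
#'   `intersection_time`, `anchor_label` (e.g. built by rbind-ing
#'   [summary_row()] calls), or a list of such data frames.
#' @return an object of class `complexity_summary`: the rows plus
#'   `slope_mean`, `slope_sd`, `intersection_mean`, `intersection_sd` and
#'   the counts they are based on. Standard deviations are `NA` when fewer
#'   than two values are defined.
#' @examples
#' rows <- rbind(summary_row("dna_length", 0.89, 8.4),
#'               summary_row("gene_number", 0.78, 7.2))
#' summarize_complexity(rows)
#' @export
summarize_complexity <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) .stop_domain("summary needs at least one row")
  slopes <- rows$complexity_slope[!is.na(rows$complexity_slope)]
  inters <- rows$intersection_time[!is.na(rows$intersection_time)]
  structure(list(
    rows = rows,
    slope_mean = if (length(slopes)) mean(slopes) else NA_real_,
    slope_sd = if (length(slopes) > 1L) sd(slopes) else NA_real_,
    slope_n = length(slopes),
    intersection_mean = if (length(inters)) mean(inters) else NA_real_,
    intersection_sd = if (length(inters) > 1L) sd(inters) else NA_real_,
    intersection_n = length(inters)),
    class = "complexity_summary")
}

#' @export
print.complexity_summary <- function(x, ...) {
  print(x$rows, ...)
  cat(sprintf("slopes: mean %.2f, sd %s Gyr^-1 (n = %d)\n", x$slope_mean,
              if (is.na(x$slope_sd)) "NA" else sprintf("%.2f", x$slope_sd),
              x$slope_n))
  cat(sprintf("intersections: mean %.1f, sd %s Gyr BP (n = %d)\n",
              x$intersection_mean,
              if (is.na(x$intersection_sd)) "NA" else sprintf("%.1f", x$intersection_sd),
              x$intersection_n))
  invisible(x)
}
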