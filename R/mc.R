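# Monte Carlo propagation of bivariate noise (per-taxon feature sd, fractional
# time uncertainty) into slope / intercept / intersection distributions.

#' Monte Carlo configuration
#'
#' @param n_reps number of replicates (>= 1); default 1000.
#' @param time_cv fractional one-sigma uncertainty on each origin time
#'   (times are redrawn as Normal(t, time_cv * t)); default 0.20, i.e. the
#'   "+/-20 percent" convention read as one standard deviation.
#' @param seed integer seed; replicates are bit-identical for a fixed seed.
#' @param value_noise optional per-taxon sd on the raw feature scale, used
#'   for taxa whose series carries no `sd`; recycled to the number of
#'   observations.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(n_reps = 1000, time_cv = 0.20, seed = NULL,
                      value_noise = NULL) {
  if (n_reps < 1) .stop_domain("`n_reps` must be >= 1")
  if (time_cv < 0) .stop_domain("`time_cv` must be >= 0")
  structure(list(n_reps = as.integer(n_reps), time_cv = time_cv,
                 seed = seed, value_noise = value_noise),
            class = "mc_config")
}

# Draw value matrix (n_obs x n_reps) on the raw scale, redrawing non-positive
# values (values must stay positive for the log transform); max 100 rounds.
.draw_values <- function(mean, sd, n_reps) {
  n <- length(mean)
  m <- matrix(rnorm(n * n_reps, mean = mean, sd = sd), nrow = n)
  for (i in seq_len(100L)) {
    bad <- which(m <= 0)
    if (!length(bad)) return(m)
    mm <- matrix(mean, nrow = n, ncol = n_reps)
    ss <- matrix(sd, nrow = n, ncol = n_reps)
    m[bad] <- rnorm(length(bad), mean = mm[bad], sd = ss[bad])
  }
  if (any(m <= 0)) {
    .stop_domain("could not draw positive feature values after 100 attempts; sd too large relative to mean")
  }
  m
}

# Core replicate engine: returns per-rep slope (BP axis), intercept, and
# optionally intersection time with an anchor.  Vectorised over replicates.
.mc_run <- function(series, config, anchor = NULL) {
  stopifnot(inherits(series, "feature_series"), inherits(config, "mc_config"))
  obs <- series$observations
  n <- nrow(obs)
  if (n < 2L) .stop_domain("series must be fittable (>= 2 observations)")
  sds <- obs$sd
  if (any(is.na(sds))) {
    if (is.null(config$value_noise)) {
      .stop_domain("all observations need `sd`, or supply `value_noise` in the config")
    }
    vn <- rep_len(config$value_noise, n)
    sds[is.na(sds)] <- vn[is.na(sds)]
  }
  run <- function() {
    vals <- .draw_values(obs$value, sds, config$n_reps)
    times <- matrix(rnorm(n * config$n_reps, mean = obs$time_gyr_bp,
                          sd = config$time_cv * obs$time_gyr_bp), nrow = n)
    y <- log(vals, base = series$log_base)
    tb <- colMeans(times)
    yb <- colMeans(y)
    tc <- times - rep(tb, each = n)
    sxx <- colSums(tc^2)
    slope <- colSums(tc * (y - rep(yb, each = n))) / sxx
    ok <- sxx > 0 & is.finite(slope)
    intercept <- yb - slope * tb
    out <- list(slope_bp = slope[ok], intercept = intercept[ok],
                n_discarded = sum(!ok))
    if (!is.null(anchor)) {
      la <- log(anchor$value, base = series$log_base)
      neg <- out$slope_bp < 0  # growing feature: negative slope on BP axis
      out$n_discarded <- out$n_discarded + sum(!neg)
      out$intersection <- (la - out$intercept[neg]) / out$slope_bp[neg]
      out$slope_bp <- out$slope_bp[neg]
      out$intercept <- out$intercept[neg]
    }
    out
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

.cv <- function(x) if (length(x) && mean(x) != 0) sd(x) / abs(mean(x)) else NA_real_

#' Monte Carlo distribution of a complexity fit
#'
#' For each replicate, redraws every taxon's feature value from
#' Normal(mean, sd) on the raw scale (redrawing non-positive values) and
#' every origin time from Normal(t, time_cv * t), refits the log-linear
#' trend, and summarises the slope and intercept distributions.
#'
#' @param series a [feature_series]; every observation needs an `sd`, or
#'   `config$value_noise` must be supplied.
#' @param config an [mc_config].
#' @return an object of class `mc_result`: `slope_mean`, `slope_sd`,
#'   `slope_cv` (slope magnitudes, Gyr^-1), the same for the intercept,
#'   `n_effective` (replicates surviving validity filters), `n_reps`,
#'   `seed`.
#' @export
mc_fit <- function(series, config = mc_config()) {
  r <- .mc_run(series, config)
  a <- abs(r$slope_bp)
  structure(list(
    slope_mean = mean(a), slope_sd = sd(a), slope_cv = .cv(a),
    intercept_mean = mean(r$intercept), intercept_sd = sd(r$intercept),
    intercept_cv = .cv(r$intercept),
    n_effective = length(a), n_reps = config$n_reps, seed = config$seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC fit (%d/%d reps): slope %.3f +/- %.3f (CV %.1f%%), intercept %.3f +/- %.3f (CV %.1f%%)\n",
              x$n_effective, x$n_reps, x$slope_mean, x$slope_sd,
              100 * x$slope_cv, x$intercept_mean, x$intercept_sd,
              100 * x$intercept_cv))
  invisible(x)
}

#' Monte Carlo distribution of an anchor intersection time
#'
#' As [mc_fit()], but additionally intersects each replicate's fitted line
#' with the anchor. Replicates whose fitted slope on the before-present
#' axis is non-negative (a non-growing feature, which never reaches the
#' anchor in the past) are discarded and counted. Because extrapolated
#' intersections are right-skewed, quantiles are reported alongside the
#' mean and sd.
#'
#' @param series a [feature_series].
#' @param anchor an [early_anchor]; defaults to the series' own.
#' @param config an [mc_config].
#' @param probs quantile probabilities; default 2.5, 50, 97.5 percent.
#' @return an object of class `mc_intersection`: `mean`, `sd`, `cv`,
#'   `quantiles`, `n_effective`, `n_reps`, `seed`.
#' @export
mc_intersection <- function(series, anchor = series$anchor,
                            config = mc_config(),
                            probs = c(0.025, 0.5, 0.975)) {
  if (is.null(anchor)) .stop_domain("series has no anchor and none was supplied")
  r <- .mc_run(series, config, anchor = anchor)
  ti <- r$intersection
  if (!length(ti)) .stop_domain("no replicate produced a growing-feature fit")
  structure(list(
    mean = mean(ti), sd = sd(ti), cv = .cv(ti),
    quantiles = quantile(ti, probs = probs, names = TRUE),
    n_effective = length(ti), n_reps = config$n_reps, seed = config$seed),
    class = "mc_intersection")
}

#' @export
print.mc_intersection <- function(x, ...) {
  q <- paste(sprintf("%.2f", x$quantiles), collapse = ", ")
  cat(sprintf("MC intersection (%d/%d reps): %.2f +/- %.2f Gyr BP, quantiles [%s]\n",
              x$n_effective, x$n_reps, x$mean, x$sd, q))
  invisible(x)
}
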