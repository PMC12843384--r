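# Cosmic context: flat Lambda-CDM lookback times, the star-formation-rate
# history (quartic rise + exponential decay), and alignment of its peak
# with the complexity-intersection era.

# Hubble time in Gyr for H0 in km/s/Mpc: (1 Mpc / 1 km) s -> Gyr.
.hubble_time_gyr <- function(h0) 977.79222 / h0

#' Flat Lambda-CDM cosmology
#'
#' Defaults match the documented defaults of the standard online
#' cosmology calculator (H0 = 69.6 km/s/Mpc, Omega_m = 0.286, flat), with
#' a universe age of 13.721 Gyr used for before-present conversions.
#'
#' @param hubble_h0 Hubble constant in km/s/Mpc (> 0).
#' @param omega_m matter density parameter.
#' @param omega_lambda dark-energy density parameter; must complement
#'   `omega_m` to 1 (flat).
#' @param universe_age age of the universe in Gyr.
#' @return an object of class `cosmology`.
#' @export
cosmology <- function(hubble_h0 = 69.6, omega_m = 0.286,
                      omega_lambda = 1 - omega_m, universe_age = 13.721) {
  if (hubble_h0 <= 0) .stop_domain("`hubble_h0` must be > 0")
  if (abs(omega_m + omega_lambda - 1) > 1e-9) {
    .stop_domain("cosmology must be flat: omega_m + omega_lambda = 1")
  }
  structure(list(hubble_h0 = hubble_h0, omega_m = omega_m,
                 omega_lambda = omega_lambda, universe_age = universe_age),
            class = "cosmology")
}

#' Lookback time under flat Lambda-CDM
#'
#' Numerical quadrature of the standard lookback integral
#' t_L(z) = t_H * Integral_0^z dz' / ((1+z') E(z')) with
#' E(z) = sqrt(Omega_m (1+z)^3 + Omega_Lambda). Strictly increasing in z,
#' zero at z = 0, and clipped at the configured universe age (the clip can
#' only bind at z of several hundred, beyond the matter+Lambda model's
#' validity).
#'
#' @param z redshift(s), >= 0.
#' @param cosmo a [cosmology].
#' @return lookback time(s) in Gyr.
#' @examples
#' lookback_time(c(0.5, 1, 3))
#' @export
lookback_time <- function(z, cosmo = cosmology()) {
  stopifnot(inherits(cosmo, "cosmology"))
  z <- as.numeric(z)
  if (any(!is.finite(z) | z < 0)) .stop_domain("redshift must be >= 0")
  integrand <- function(zz) {
    1 / ((1 + zz) * sqrt(cosmo$omega_m * (1 + zz)^3 + cosmo$omega_lambda))
  }
  th <- .hubble_time_gyr(cosmo$hubble_h0)
  tl <- vapply(z, function(zi) {
    if (zi == 0) return(0)
    th * integrate(integrand, 0, zi, rel.tol = 1e-10)$value
  }, numeric(1))
  pmin(tl, cosmo$universe_age)
}

# Redshift at a given lookback time (inverse of lookback_time), used by the
# synthetic SFR generator.
.redshift_at_lookback <- function(t_gyr, cosmo = cosmology()) {
  vapply(t_gyr, function(t) {
    if (t <= 0) return(0)
    uniroot(function(z) lookback_time(z, cosmo) - t, c(1e-8, 50),
            tol = 1e-10)$root
  }, numeric(1))
}

# Truth used by the synthetic SFR generator: quartic rise
# A * (t (2 tp - t))^2 / tp^4 peaking at t = tp (time after big bang),
# exponential decay A exp(-k (t - tp)) afterwards.
.sfr_truth <- function(t_abb, peak_abb, peak_rate, decay_k) {
  ifelse(t_abb <= peak_abb,
         peak_rate * (t_abb * (2 * peak_abb - t_abb))^2 / peak_abb^4,
         peak_rate * exp(-decay_k * (t_abb - peak_abb)))
}

#' Generate a synthetic redshift vs star-formation-rate table
#'
#' Stand-in for a gamma-ray-attenuation-derived SFR table (redshift, rate
#' in 0.02 x solar masses / yr / Mpc^3): a quartic rise from the big bang
#' to the peak and an exponential decay after it, sampled at redshifts
#' spanning both segments, with optional multiplicative noise. The default
#' peak sits ~10.3 Gyr before present (z ~ 2), near the observed cosmic
#' star-formation peak.
#'
#' @param peak_time_bp peak position in Gyr before present.
#' @param peak_rate rate at the peak (arbitrary SFR units).
#' @param decay_k exponential decay constant (1/Gyr) after the peak.
#' @param n number of table rows.
#' @param noise_cv multiplicative lognormal noise CV (0 = noiseless).
#' @param cosmo a [cosmology].
#' @param seed integer seed.
#' @return data frame with columns `z`, `rate`; the truth parameters are
#'   attached as the `"truth"` attribute.
#' @export
gen_sfr_table <- function(peak_time_bp = 10.3, peak_rate = 1,
                          decay_k = 0.25, n = 30L, noise_cv = 0,
                          cosmo = cosmology(), seed = 1L) {
  peak_abb <- cosmo$universe_age - peak_time_bp
  if (peak_abb <= 0) .stop_domain("peak must lie after the big bang")
  gen <- function() {
    t_abb <- seq(0.4, cosmo$universe_age - 0.2, length.out = n)
    rate <- .sfr_truth(t_abb, peak_abb, peak_rate, decay_k)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rate <- rate * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    }
    z <- .redshift_at_lookback(cosmo$universe_age - t_abb, cosmo)
    data.frame(z = z, rate = rate)
  }
  tab <- withr::with_seed(seed, gen())
  attr(tab, "truth") <- list(peak_time_bp = peak_time_bp,
                             peak_abb = peak_abb, peak_rate = peak_rate,
                             decay_k = decay_k)
  tab
}

#' Fit the star-formation-rate history
#'
#' Converts redshifts to time after the big bang, locates the peak at the
#' input point of maximum rate, fits a degree-4 polynomial to the pre-peak
#' side and an exponential decay to the post-peak side (independently, no
#' continuity constraint), and samples the combined curve on a regular
#' time grid.
#'
#' @param z_rate_table data frame with columns `z` and `rate` (>= 6 rows
#'   spanning the peak).
#' @param cosmo a [cosmology].
#' @param sample_step grid spacing in Gyr; default 0.2.
#' @return an object of class `sfr_curve`: `samples` (data frame with
#'   `time_abb`, `time_bp`, `rate`, ordered in time after big bang),
#'   `peak_time_bp`, `peak_time_abb`, `poly_coefs` (ascending powers),
#'   `poly_degree`, `exp_coefs` (`log_rate_at_peak`, `decay_k`),
#'   `degenerate` flag.
#' @export
fit_sfr <- function(z_rate_table, cosmo = cosmology(), sample_step = 0.2) {
  stopifnot(is.data.frame(z_rate_table),
            all(c("z", "rate") %in% names(z_rate_table)))
  if (nrow(z_rate_table) < 6L) .stop_domain("need >= 6 points spanning the peak")
  t_abb <- cosmo$universe_age - lookback_time(z_rate_table$z, cosmo)
  rate <- as.numeric(z_rate_table$rate)
  o <- order(t_abb)
  t_abb <- t_abb[o]; rate <- rate[o]
  degenerate <- var(rate) == 0
  if (degenerate) warning("rates are constant; peak is degenerate")
  ipk <- which.max(rate)
  t_peak <- t_abb[ipk]

  pre <- which(t_abb <= t_peak)
  degree <- 4L
  if (length(pre) < degree + 1L) {
    degree <- max(1L, length(pre) - 1L)
    warning(sprintf("only %d pre-peak points; polynomial degree reduced to %d",
                    length(pre), degree))
  }
  pf <- lm(rate[pre] ~ poly(t_abb[pre], degree, raw = TRUE))
  poly_coefs <- unname(coef(pf))

  post <- which(t_abb >= t_peak)
  pos <- post[rate[post] > 0]
  if (length(pos) < length(post)) {
    warning(sprintf("excluded %d non-positive rate(s) from the exponential fit",
                    length(post) - length(pos)))
  }
  if (length(pos) < 2L) .stop_domain("need >= 2 positive post-peak points")
  ef <- .wols(t_abb[pos] - t_peak, log(rate[pos]))
  exp_coefs <- c(log_rate_at_peak = ef$intercept, decay_k = -ef$slope)

  grid <- seq(t_abb[1L], t_abb[length(t_abb)], by = sample_step)
  eval_poly <- function(t) {
    drop(outer(t, 0:degree, `^`) %*% poly_coefs)
  }
  r <- ifelse(grid <= t_peak, eval_poly(grid),
              exp(ef$intercept + ef$slope * (grid - t_peak)))
  r <- pmax(r, 0)
  structure(list(
    samples = data.frame(time_abb = grid,
                         time_bp = cosmo$universe_age - grid, rate = r),
    peak_time_abb = t_peak, peak_time_bp = cosmo$universe_age - t_peak,
    peak_rate = rate[ipk],
    poly_coefs = poly_coefs, poly_degree = degree, exp_coefs = exp_coefs,
    degenerate = degenerate, sample_step = sample_step,
    cosmology = cosmo),
    class = "sfr_curve")
}

#' @export
print.sfr_curve <- function(x, ...) {
  cat(sprintf("SFR curve: peak %.2f Gyr BP, %d samples every %g Gyr, decay %.3g /Gyr%s\n",
              x$peak_time_bp, nrow(x$samples), x$sample_step,
              x$exp_coefs[["decay_k"]],
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Align the star-formation peak with complexity intersections
#'
#' Reports the fitted SFR peak time, the mean complexity-intersection time,
#' their difference, and whether the intersection era falls inside the
#' high-SFR window (times where the sampled rate is at least half the peak
#' rate). A concordance report only; no causal claim is encoded.
#'
#' @param sfr an [fit_sfr()] result.
#' @param summary a [summarize_complexity()] result (or a number, taken as
#'   the intersection mean in Gyr BP).
#' @return list with `peak_time_bp`, `intersection_mean`, `difference`
#'   (peak minus intersections), `in_high_sfr_window`, and `window`
#'   (Gyr BP range of the half-maximum window).
#' @export
align_with_intercepts <- function(sfr, summary) {
  stopifnot(inherits(sfr, "sfr_curve"))
  im <- if (inherits(summary, "complexity_summary")) {
    summary$intersection_mean
  } else {
    as.numeric(summary)
  }
  smp <- sfr$samples
  hi <- smp$time_bp[smp$rate >= max(smp$rate) / 2]
  window <- range(hi)
  list(peak_time_bp = sfr$peak_time_bp, intersection_mean = im,
       difference = sfr$peak_time_bp - im,
       in_high_sfr_window = im >= window[1L] && im <= window[2L],
       window = window)
}
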