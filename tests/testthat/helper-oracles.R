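# Independent oracles and fixture builders shared across tests.

# Brute-force (weighted) least squares via explicit normal equations:
# solve (X' W X) beta = X' W y.  Deliberately a different route from the
# package's centered closed form.
oracle_ols <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  X <- cbind(1, x)
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  list(intercept = beta[1L], slope = beta[2L])
}

# Composite-Simpson quadrature of the flat Lambda-CDM lookback integral.
oracle_lookback <- function(z, h0 = 69.6, om = 0.286, n = 4000L) {
  ol <- 1 - om
  f <- function(zz) 1 / ((1 + zz) * sqrt(om * (1 + zz)^3 + ol))
  if (n %% 2L) n <- n + 1L
  zz <- seq(0, z, length.out = n + 1L)
  h <- z / n
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  (977.79222 / h0) * h / 3 * sum(w * f(zz))
}

# A feature series whose per-taxon values sit exactly on a log10-linear
# trend through (anchor_time, anchor_value) with the given slope magnitude.
exact_series <- function(slope, anchor_time, anchor_value,
                         times = c(0.3, 0.5, 1.46, 3.2, 3.42, 3.75),
                         sd_frac = NA, feature_id = "exact") {
  values <- 10^(log10(anchor_value) + slope * (anchor_time - times))
  obs <- data.frame(taxon = paste0("t", seq_along(times)),
                    time_gyr_bp = times, value = values)
  if (!is.na(sd_frac)) obs$sd <- sd_frac * values
  feature_series(feature_id, obs,
                 anchor = early_anchor("truth", anchor_value),
                 units = "")
}

# Generator configuration for a published-compilation feature row.
config_for_feature <- function(fid, seed = 1L) {
  ref <- table4_reference()
  r <- ref[ref$feature_id == fid, ]
  generator_config(true_slope = r$complexity_slope,
                   true_anchor_time = r$intersection_time,
                   anchor_value = builtin_anchor(fid)$value,
                   seed = seed)
}
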