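test_that("two-point series gives the exact line", {
  s <- feature_series("toy", data.frame(taxon = c("a", "b"),
                                        time_gyr_bp = c(1, 3),
                                        value = c(10, 1)))
  f <- fit_loglinear(s)
  expect_equal(f$slope_a, 0.5)
  expect_equal(f$slope_bp, -0.5)
  expect_equal(f$pearson_r, -1)
  expect_equal(f$intercept_b, 1.5)
})

test_that("the in-paper cell-volume series reproduces the published fit", {
  s <- load_builtin("cell_volume")
  expect_equal(nrow(s$observations), 6)
  f <- fit_loglinear(s)
  expect_equal(round(f$slope_a, 2), 1.27)
  expect_equal(round(abs(f$pearson_r), 2), 0.97)
  i <- intersect_with_anchor(f, s$anchor)
  expect_true(i$time_bp > 8 && i$time_bp < 9)
  expect_true(i$extrapolated)
})

test_that("fits match the normal-equations oracle on random inputs", {
  withr::with_seed(21, {
    for (k in 1:25) {
      n <- sample(3:10, 1)
      t <- runif(n, 0, 4)
      v <- 10^(runif(1, 1, 6) - runif(1, 0.2, 1.5) * t + rnorm(n, 0, 0.3))
      s <- feature_series("rand", data.frame(taxon = paste0("x", 1:n),
                                             time_gyr_bp = t, value = v))
      f <- fit_loglinear(s)
      o <- oracle_ols(t, log10(v))
      expect_equal(f$slope_bp, o$slope, tolerance = 1e-10)
      expect_equal(f$intercept_b, o$intercept, tolerance = 1e-10)
    }
  })
})

test_that("weighting: equal weights match unweighted; sd is required", {
  withr::with_seed(22, {
    n <- 6
    t <- runif(n, 0.2, 4)
    v <- 10^(5 - t + rnorm(n, 0, 0.2))
    obs <- data.frame(taxon = paste0("x", 1:n), time_gyr_bp = t, value = v,
                      sd = 0.3 * v)
    s <- feature_series("w", obs)
    f_eq <- fit_loglinear(s, weighted = TRUE, weight_rule = "equal")
    f_un <- fit_loglinear(s)
    expect_identical(f_eq$slope_bp, f_un$slope_bp)
    expect_identical(f_eq$intercept_b, f_un$intercept_b)
    # inverse-variance fit matches a weighted normal-equations oracle
    f_w <- fit_loglinear(s, weighted = TRUE)
    lw <- 1 / ((log10(v + obs$sd) - log10(v - obs$sd)) / 2)^2
    o <- oracle_ols(t, log10(v), lw)
    expect_equal(f_w$slope_bp, o$slope, tolerance = 1e-10)
    # dropping sd from one taxon breaks inverse-variance weighting
    obs2 <- obs; obs2$sd[2] <- NA
    s2 <- feature_series("w", obs2)
    expect_error(fit_loglinear(s2, weighted = TRUE), "x2")
    expect_error(fit_loglinear(s2, weighted = TRUE, excluded_taxa = "x2"), NA)
  })
})

test_that("fit errors on degenerate time structure", {
  s <- feature_series("flat", data.frame(taxon = c("a", "b"),
                                         time_gyr_bp = c(2, 2),
                                         value = c(10, 100)))
  expect_error(fit_loglinear(s), "distinct")
  s1 <- feature_series("one", data.frame(taxon = "a", time_gyr_bp = 1,
                                         value = 10))
  expect_error(fit_loglinear(s1), "2 observations")
})

test_that("anchor intersection solves the fitted line", {
  # hand-solvable: log(x) = 1.5 - 0.5 t; anchor 10^-0.5 -> t = 4
  s <- feature_series("toy", data.frame(taxon = c("a", "b"),
                                        time_gyr_bp = c(1, 3),
                                        value = c(10, 1)))
  f <- fit_loglinear(s)
  i <- intersect_with_anchor(f, early_anchor("hand", 10^(-0.5)))
  expect_equal(i$time_bp, 4)
  expect_true(i$extrapolated)
  # anchor equal to the fitted present-day value -> t = 0
  i0 <- intersect_with_anchor(f, early_anchor("now", 10^f$intercept_b))
  expect_equal(i0$time_bp, 0)
})

test_that("intersection consistency and shift invariance hold on random fits", {
  withr::with_seed(23, {
    for (k in 1:10) {
      n <- sample(4:8, 1)
      t <- runif(n, 0.2, 4)
      v <- 10^(6 - runif(1, 0.5, 1.5) * t + rnorm(n, 0, 0.2))
      s <- feature_series("rand", data.frame(taxon = paste0("x", 1:n),
                                             time_gyr_bp = t, value = v))
      f <- fit_loglinear(s)
      a <- early_anchor("a", 10^runif(1, -2, 1))
      i <- intersect_with_anchor(f, a)
      expect_equal(f$intercept_b + f$slope_bp * i$time_bp,
                   log10(a$value), tolerance = 1e-9)
      # shifting all times by delta shifts the intersection by delta exactly
      delta <- 1.25
      s2 <- feature_series("rand", data.frame(taxon = paste0("x", 1:n),
                                              time_gyr_bp = t + delta,
                                              value = v))
      f2 <- fit_loglinear(s2)
      expect_equal(f2$slope_bp, f$slope_bp, tolerance = 1e-9)
      expect_equal(intersect_with_anchor(f2, a)$time_bp, i$time_bp + delta,
                   tolerance = 1e-8)
    }
  })
})

test_that("zero slope yields a no-intersection error", {
  s <- feature_series("const", data.frame(taxon = c("a", "b"),
                                          time_gyr_bp = c(1, 3),
                                          value = c(10, 10)))
  f <- fit_loglinear(s)
  expect_error(intersect_with_anchor(f, early_anchor("a", 1)), "zero")
})

test_that("earth-only scenario returns the required pre-life slope and ratio", {
  a <- early_anchor("100 nt", 100)  # log10 = 2
  r <- earth_only_scenario(a, luca_time_bp = 4.0, luca_value = 10^5.73,
                           water_time_bp = 4.5, evolutionary_slope = 0.89)
  expect_equal(r$required_slope, (5.73 - 2) / 0.5, tolerance = 1e-12)
  expect_equal(r$ratio, 7.46 / 0.89, tolerance = 1e-12)
  same <- earth_only_scenario(a, 4.0, 10^5.73, 4.5,
                              evolutionary_slope = (5.73 - 2) / 0.5)
  expect_equal(same$ratio, 1)
  expect_error(earth_only_scenario(a, 4.5, 10^5.73, 4.0, 1), "older")
  expect_error(earth_only_scenario(a, 4.0, 50, 4.5, 1), "exceed")
})

test_that("summarize_complexity aggregates defined quantities only", {
  rows <- rbind(summary_row("a", 1.0, 8.0, "x"),
                summary_row("b", 0.8, NA, "y"),
                summary_row("c", 1.2, 9.0, "z"))
  sm <- summarize_complexity(rows)
  expect_equal(sm$slope_mean, 1.0)
  expect_equal(sm$slope_sd, sd(c(1.0, 0.8, 1.2)))
  expect_equal(sm$intersection_mean, 8.5)
  expect_equal(sm$intersection_n, 2)
  one <- summarize_complexity(summary_row("solo", 0.9, 8.0))
  expect_equal(one$slope_mean, 0.9)
  expect_true(is.na(one$slope_sd))
  expect_error(summarize_complexity(rows[0, ]), "one row")
  expect_error(summary_row("bad", -1), "> 0")
})
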