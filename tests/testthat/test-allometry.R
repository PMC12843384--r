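test_that("log-log fit recovers the identity relation and skips small groups", {
  x <- c(1, 10, 100, 1000)
  f <- fit_loglog(x, x)
  expect_equal(f$all$slope, 1, tolerance = 1e-12)
  expect_equal(f$all$pearson_r, 1, tolerance = 1e-12)
  expect_warning(
    f2 <- fit_loglog(c(x, 5), c(x, 5), groups = c(rep("big", 4), "tiny")),
    "tiny")
  expect_named(f2, "big")
  expect_error(suppressWarnings(fit_loglog(c(1, 1), c(2, 3))), "2 distinct")
})

test_that("log-log exponent recovery on generator output is within 2 SE", {
  cfg <- generator_config(seed = 31)
  tab <- gen_gene_genome_table(cfg)
  p <- tab[tab$group == "prokaryote", ]
  f <- fit_loglog(p$genome_length, p$gene_count)$all
  expect_lt(abs(f$slope - cfg$gene_exponent_prok), 2 * f$slope_se)
  expect_gt(f$pearson_r, 0.95)
})

test_that("slope-ratio products match the published arithmetic", {
  expect_equal(round(slope_ratio_rate(0.96, 0.81), 2), 0.78)
  expect_equal(round(slope_ratio_rate(1.04, 0.78), 2), 0.81)
  expect_equal(slope_ratio_rate(1, 0.63), 0.63)
  expect_error(slope_ratio_rate(NA, 1), "finite")
  expect_equal(metabolic_rate_from_allometry(0.75, 1.2), 0.9)
  expect_equal(metabolic_rate_from_allometry(1, 0.77), 0.77)
  expect_equal(metabolic_rate_from_allometry(0.75, 1.27), 0.9525)
})

test_that("time ruler: exact two-anchor map, extrapolation, inversion", {
  r <- build_time_ruler(c(0, 10), c(0, 10))
  t5 <- ruler_time_at(r, 5)
  expect_equal(as.numeric(t5), 5)
  expect_false(attr(t5, "extrapolated"))
  t15 <- ruler_time_at(r, 15)
  expect_equal(as.numeric(t15), 15)  # linear extrapolation
  expect_true(attr(t15, "extrapolated"))
  # anchors reproduce their own times exactly in the 2-anchor case
  expect_equal(as.numeric(ruler_time_at(r, c(0, 10))), c(0, 10))
  # three exactly-affine anchors leave zero residual
  r3 <- build_time_ruler(c(1, 2, 4), 10 - 2 * c(1, 2, 4))
  expect_equal(max(abs(r3$residuals)), 0, tolerance = 1e-12)
  # round trip coordinate -> time -> coordinate is identity
  withr::with_seed(32, {
    co <- runif(5, -3, 8)
    expect_equal(ruler_coordinate_at(r3, as.numeric(ruler_time_at(r3, co))),
                 co, tolerance = 1e-12)
  })
  expect_error(build_time_ruler(c(1, 1), c(0, 2)), "distinct")
  expect_error(build_time_ruler(c(1, 2, 3), c(0, 5, 2)), "monotone")
  expect_error(build_time_ruler(1, 2), ">= 2")
})

test_that("time-removal identity: log-log slope equals ratio of time slopes", {
  # two exactly log-linear features sharing time points
  times <- c(0.3, 0.8, 1.5, 2.4, 3.4, 3.75)
  ax <- 0.81; ay <- 0.96 * 0.81
  x <- 10^(6 - ax * times)
  y <- 10^(3.5 - ay * times)
  sx <- feature_series("x", data.frame(taxon = paste0("t", 1:6),
                                       time_gyr_bp = times, value = x))
  sy <- feature_series("y", data.frame(taxon = paste0("t", 1:6),
                                       time_gyr_bp = times, value = y))
  fx <- fit_loglinear(sx); fy <- fit_loglinear(sy)
  fxy <- fit_loglog(x, y)$all
  expect_equal(fxy$slope, fy$slope_a / fx$slope_a, tolerance = 1e-9)
  expect_equal(fxy$slope, ay / ax, tolerance = 1e-9)
})

test_that("combine_complexities is additive, commutative, associative", {
  expect_equal(combine_complexities(2, 1), 3)
  expect_equal(combine_complexities(3.7, 0), 3.7)  # unicellular: one cell type
  withr::with_seed(33, {
    a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
    expect_equal(combine_complexities(a, b), combine_complexities(b, a))
    expect_equal(combine_complexities(combine_complexities(a, b), c),
                 combine_complexities(a, combine_complexities(b, c)))
  })
  expect_error(combine_complexities(Inf, 1), "finite")
})

test_that("combined eukaryote complexity falls back on the prokaryote line", {
  cfg <- generator_config(seed = 34)
  tab <- gen_gene_genome_table(cfg)
  p <- tab[tab$group == "prokaryote", ]
  e <- tab[tab$group == "eukaryote", ]
  fp <- fit_loglog(p$genome_length, p$gene_count)$all
  combined <- combine_complexities(log10(e$gene_count),
                                   log10(e$cell_type_count))
  fc <- fit_loglog(e$genome_length, 10^combined)$all
  expect_lt(abs(fc$slope - fp$slope),
            2 * sqrt(fc$slope_se^2 + fp$slope_se^2) + 1e-9)
})

test_that("jump analysis detects factor-of-two structure", {
  # two parallel lines offset by 2 in log2 units -> factor 4
  x <- 10^seq(1, 3, length.out = 6)
  y1 <- x^1.04
  y2 <- y1 * 4
  fits <- fit_loglog(c(x, x), c(y1, y2),
                     groups = rep(c("prok", "euk"), each = 6))
  j <- jump_analysis(fits)
  expect_equal(j$jump_factor, 4, tolerance = 1e-9)
  expect_equal(j$nearest_power_of_2, 4)
  expect_equal(diff(j$log2_offsets), 2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical lines -> factor 1
  fits_id <- fit_loglog(c(x, x), c(y1, y1),
                        groups = rep(c("a", "b"), each = 6))
  expect_equal(jump_analysis(fits_id)$jump_factor, 1, tolerance = 1e-9)
  # non-overlapping abscissa ranges -> boundary evaluation with warning
  x2 <- 10^seq(4, 5, length.out = 6)
  fits_no <- fit_loglog(c(x, x2), c(y1, x2^1.04 * 4),
                        groups = rep(c("lo", "hi"), each = 6))
  expect_warning(j2 <- jump_analysis(fits_no), "overlap")
  expect_equal(j2$jump_factor, 4, tolerance = 1e-6)
  expect_error(jump_analysis(fits["prok"]), ">= 2")
})

test_that("synthetic binding data round-trips the configured jump", {
  j <- jump_analysis(with(gen_binding_table(generator_config(seed = 35)),
                          fit_loglog(reduced_proteome_size,
                                     disordered_binding_sites, group)))
  expect_gt(j$jump_factor, 3.5)
  expect_lt(j$jump_factor, 4.5)
  expect_equal(j$nearest_power_of_2, 4)
  j1 <- jump_analysis(with(gen_binding_table(generator_config(jump_factor = 1,
                                                              seed = 35)),
                           fit_loglog(reduced_proteome_size,
                                      disordered_binding_sites, group)))
  expect_equal(j1$jump_factor, 1, tolerance = 0.15)
})

test_that("ruler dates the minimal peptide era on a gene-genome fixture", {
  # anchors per the shipped placements: present at the largest eukaryote
  # abscissa, the eukaryote transition at the group boundary (~1e7 nt),
  # and the minimal cell at the small-genome end (~5e5 nt).
  ruler <- build_time_ruler(c(10, 7, log10(5.8e5)), c(0, 2.2, 3.75))
  t100 <- as.numeric(ruler_time_at(ruler, 2))  # coordinate of a 100 nt string
  expect_gt(t100, 6); expect_lt(t100, 9)
  # binding-fixture ruler: [2 proteins, 2 sites] lands in the 8-9 Gyr range
  rb <- build_time_ruler(c(log10(4e4), log10(6e3), log10(500)),
                         c(0, 2.2, 3.75))
  t2p <- as.numeric(ruler_time_at(rb, log10(2)))
  expect_gt(t2p, 8); expect_lt(t2p, 9)
})
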