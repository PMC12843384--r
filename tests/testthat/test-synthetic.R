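test_that("noiseless generation puts every taxon exactly on the line", {
  taxa <- data.frame(name = c("a", "b", "c"), origin_time = c(0.5, 2, 3.5),
                     n_records = 5L, raw_cv = 0)
  cfg <- generator_config(true_slope = 0.89, true_anchor_time = 8.4,
                          anchor_value = 100, taxa = taxa, seed = 61)
  s <- gen_feature_series(cfg)
  expected <- 10^(log10(100) + 0.89 * (8.4 - taxa$origin_time))
  expect_equal(sort(s$observations$value), sort(expected), tolerance = 1e-12)
  expect_equal(s$observations$sd, rep(0, 3))
  f <- fit_loglinear(s)
  expect_equal(f$slope_a, 0.89, tolerance = 1e-10)
  expect_equal(intersect_with_anchor(f, s$anchor)$time_bp, 8.4,
               tolerance = 1e-8)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- generator_config(seed = 62)
  expect_identical(gen_feature_series(cfg)$observations,
                   gen_feature_series(cfg)$observations)
  expect_identical(gen_gene_genome_table(cfg), gen_gene_genome_table(cfg))
  expect_identical(gen_binding_table(cfg), gen_binding_table(cfg))
  cfg2 <- generator_config(seed = 63)
  expect_false(identical(gen_feature_series(cfg)$observations$value,
                         gen_feature_series(cfg2)$observations$value))
})

test_that("default configuration recovers slope and intersection", {
  # averaged over seeds: the estimator agrees with truth within its own SE
  fits <- lapply(1:20, function(k) {
    cfg <- generator_config(seed = 640L + k)
    s <- gen_feature_series(cfg)
    f <- fit_loglinear(s)
    list(slope = f$slope_a, se = f$slope_se,
         t = intersect_with_anchor(f, s$anchor)$time_bp)
  })
  slope_bar <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  se_bar <- mean(vapply(fits, `[[`, numeric(1), "se"))
  expect_lt(abs(slope_bar - 0.89), 2 * se_bar)
  t_bar <- mean(vapply(fits, `[[`, numeric(1), "t"))
  expect_lt(abs(t_bar - 8.4), 0.5)
})

test_that("doubling the true slope doubles the recovered slope (noiseless)", {
  taxa <- data.frame(name = letters[1:4], origin_time = c(0.5, 1.5, 2.5, 3.4),
                     n_records = 3L, raw_cv = 0)
  f1 <- fit_loglinear(gen_feature_series(
    generator_config(true_slope = 0.5, true_anchor_time = 8, anchor_value = 10,
                     taxa = taxa, seed = 65)))
  f2 <- fit_loglinear(gen_feature_series(
    generator_config(true_slope = 1.0, true_anchor_time = 8, anchor_value = 10,
                     taxa = taxa, seed = 65)))
  expect_equal(f2$slope_a, 2 * f1$slope_a, tolerance = 1e-10)
})

test_that("config validation rejects impossible worlds", {
  expect_error(generator_config(true_anchor_time = 2), "predate")
  expect_error(generator_config(anchor_value = 0), "> 0")
  taxa <- data.frame(name = "a", origin_time = 1,
                     n_records = 0L, raw_cv = 0.5)
  expect_error(generator_config(taxa = taxa), "n_records")
})

test_that("noiseless gene-genome table has the exact configured exponents", {
  cfg <- generator_config(noise_log10_prok = 0, noise_log10_euk = 0,
                          seed = 66)
  tab <- gen_gene_genome_table(cfg, n_prok = 40, n_euk = 40)
  f <- with(tab, fit_loglog(genome_length, gene_count, group))
  expect_equal(f$prokaryote$slope, 0.96, tolerance = 1e-9)
  expect_equal(f$eukaryote$slope, 0.32, tolerance = 1e-9)
  expect_equal(abs(f$prokaryote$pearson_r), 1, tolerance = 1e-12)
  # combined eukaryote complexity sits exactly on the prokaryote line
  e <- tab[tab$group == "eukaryote", ]
  combined <- combine_complexities(log10(e$gene_count),
                                   log10(e$cell_type_count))
  fc <- fit_loglog(e$genome_length, 10^combined)$all
  expect_equal(fc$slope, f$prokaryote$slope, tolerance = 1e-9)
  expect_equal(fc$intercept, f$prokaryote$intercept, tolerance = 1e-9)
})

test_that("more noise does not sharpen the gene-genome correlation", {
  r_at <- function(noise) {
    mean(vapply(1:4, function(k) {
      cfg <- generator_config(noise_log10_euk = noise, seed = 670L + k)
      tab <- gen_gene_genome_table(cfg)
      abs(with(tab[tab$group == "eukaryote", ],
               fit_loglog(genome_length, gene_count)$all$pearson_r))
    }, numeric(1)))
  }
  expect_gte(r_at(0.15), r_at(0.30))
})

test_that("binding generator carries exponent and jump round-trip", {
  cfg <- generator_config(seed = 68)
  tab <- gen_binding_table(cfg, n_per_group = 80)
  f <- with(tab, fit_loglog(reduced_proteome_size, disordered_binding_sites,
                            group))
  expect_lt(abs(f$prokaryote$slope - cfg$binding_exponent),
            2 * f$prokaryote$slope_se)
  expect_lt(abs(f$eukaryote$slope - cfg$binding_exponent),
            2 * f$eukaryote$slope_se)
})

test_that("provenance travels with generated objects", {
  cfg <- generator_config(seed = 69)
  s <- gen_feature_series(cfg)
  expect_equal(attr(s, "provenance")$seed, 69L)
  expect_equal(attr(gen_binding_table(cfg), "provenance")$config$jump_factor, 4)
})
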