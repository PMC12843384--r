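# Synthetic data with the statistical structure the analyses assume:
# per-taxon lognormal feature values whose log-means follow a linear trend
# in origin time, gene-genome power laws, and a prokaryote-to-eukaryote
# jump in binding sites.  Everything is deterministic under a fixed seed.

.default_taxa <- function() {
  data.frame(
    name = c("archaea", "bacteria", "cyanobacteria", "fungi", "land_plants",
             "invertebrates", "vertebrates", "mammals"),
    origin_time = c(3.4, 3.42, 3.2, 1.46, 0.47, 0.6, 0.5, 0.3),
    n_records = c(40L, 200L, 60L, 80L, 60L, 60L, 100L, 50L),
    raw_cv = 0.5,
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Parameters of the synthetic world: a log-linear complexity trend
#' anchored at (`true_anchor_time`, `anchor_value`), per-taxon record
#' counts and raw-scale coefficients of variation, power-law exponents for
#' the gene-genome and binding-proteome relations, and the
#' prokaryote-to-eukaryote jump factor. Defaults follow the published
#' DNA-length trend (slope 0.89 Gyr^-1 through 100 nt at 8.4 Gyr BP),
#' power-law exponents 0.96 (prokaryote) / 0.32 (eukaryote) / 1.04
#' (binding), a 4x binding jump, and desk-scale record counts (20-200 per
#' taxon) with a wide, database-like raw CV of 0.5.
#'
#' @param true_slope complexity growth rate in log10 units per Gyr.
#' @param true_anchor_time time (Gyr BP) at which the trend passes through
#'   `anchor_value`.
#' @param anchor_value feature value at the anchor time (> 0).
#' @param taxa data frame with columns `name`, `origin_time`, `n_records`,
#'   `raw_cv`; all origin times must predate `true_anchor_time`.
#' @param gene_exponent_prok,gene_exponent_euk gene-vs-genome log-log
#'   slopes for the two groups.
#' @param binding_exponent binding-sites-vs-proteome log-log slope.
#' @param jump_factor multiplicative eukaryote offset in binding sites.
#' @param noise_log10_prok,noise_log10_euk log10-scale sd of the power-law
#'   scatter per group.
#' @param seed integer seed; all generators are bit-identical under a
#'   fixed seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(true_slope = 0.89, true_anchor_time = 8.4,
                             anchor_value = 100, taxa = .default_taxa(),
                             gene_exponent_prok = 0.96,
                             gene_exponent_euk = 0.32,
                             binding_exponent = 1.04, jump_factor = 4,
                             noise_log10_prok = 0.05,
                             noise_log10_euk = 0.25, seed = 1L) {
  stopifnot(is.data.frame(taxa),
            all(c("name", "origin_time", "n_records", "raw_cv") %in% names(taxa)))
  if (anchor_value <= 0 || true_slope <= 0) {
    .stop_domain("`anchor_value` and `true_slope` must be > 0")
  }
  if (any(taxa$origin_time >= true_anchor_time)) {
    .stop_domain("all taxa origin times must predate (be smaller than) `true_anchor_time`")
  }
  if (any(taxa$raw_cv < 0) || any(taxa$n_records < 1L)) {
    .stop_domain("taxa need raw_cv >= 0 and n_records >= 1")
  }
  structure(list(true_slope = true_slope, true_anchor_time = true_anchor_time,
                 anchor_value = anchor_value, taxa = taxa,
                 gene_exponent_prok = gene_exponent_prok,
                 gene_exponent_euk = gene_exponent_euk,
                 binding_exponent = binding_exponent,
                 jump_factor = jump_factor,
                 noise_log10_prok = noise_log10_prok,
                 noise_log10_euk = noise_log10_euk,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# log10 of the true trend line at a time before present.
.true_line_log10 <- function(config, time_bp) {
  log10(config$anchor_value) +
    config$true_slope * (config$true_anchor_time - time_bp)
}

.provenance <- function(config) {
  list(seed = config$seed, config = unclass(config)[setdiff(names(config), "taxa")])
}

#' Generate a synthetic feature series
#'
#' Draws `n_records` lognormal values per taxon whose raw-scale mean sits
#' exactly on the configured trend line (the lognormal meanlog is offset by
#' -sigma^2/2 so the expectation, not the median, follows the line), then
#' aggregates to per-taxon mean / sd / n as the analysis pipeline expects.
#' With `raw_cv = 0` every value lies exactly on the line.
#'
#' @param config a [generator_config].
#' @param feature_id,units metadata for the returned series.
#' @return a [feature_series] with a synthetic anchor attached and the
#'   generator provenance in the `"provenance"` attribute.
#' @export
gen_feature_series <- function(config = generator_config(),
                               feature_id = "synthetic", units = "") {
  stopifnot(inherits(config, "generator_config"))
  gen <- function() {
    obs <- do.call(rbind, lapply(seq_len(nrow(config$taxa)), function(i) {
      tx <- config$taxa[i, ]
      mu10 <- .true_line_log10(config, tx$origin_time)
      sdlog <- sqrt(log(1 + tx$raw_cv^2))
      meanlog <- mu10 * log(10) - sdlog^2 / 2
      v <- exp(rnorm(tx$n_records, meanlog, sdlog))
      data.frame(taxon = tx$name, time_gyr_bp = tx$origin_time,
                 value = mean(v),
                 sd = if (tx$n_records > 1L) sd(v) else 0,
                 n = tx$n_records, stringsAsFactors = FALSE)
    }))
    feature_series(feature_id, obs,
                   anchor = early_anchor("synthetic anchor", config$anchor_value,
                                         sprintf("generator truth at %g Gyr BP",
                                                 config$true_anchor_time)),
                   units = units)
  }
  s <- withr::with_seed(config$seed, gen())
  attr(s, "provenance") <- .provenance(config)
  s
}

# Prokaryote gene-genome line: calibrated so a 1e6 nt genome carries 1000
# genes (one gene per kilobase), matching real prokaryote gene density.
.prok_gene_intercept <- function(config) 3 - config$gene_exponent_prok * 6

#' Generate a synthetic gene-vs-genome table
#'
#' Prokaryote rows follow `gene_count ~ genome_length^exponent_prok` with
#' tight multiplicative scatter; eukaryote rows follow the shallower
#' `^exponent_euk` law with wide scatter. Each eukaryote row carries a
#' `cell_type_count` constructed so that log10(genes) + log10(cell types)
#' falls back on the prokaryote line, mirroring the additive-complexity
#' construction.
#'
#' @param config a [generator_config].
#' @param n_prok,n_euk rows per group.
#' @return data frame with columns `organism`, `group`, `genome_length`,
#'   `gene_count`, `cell_type_count` (NA for prokaryotes), plus generator
#'   provenance in the `"provenance"` attribute.
#' @export
gen_gene_genome_table <- function(config = generator_config(),
                                  n_prok = 200L, n_euk = 100L) {
  stopifnot(inherits(config, "generator_config"))
  gen <- function() {
    # prokaryote genomes 0.5-12 Mb; eukaryote genomes 10 Mb - 10 Gb
    lp <- runif(n_prok, log10(5e5), log10(1.2e7))
    gp <- .prok_gene_intercept(config) + config$gene_exponent_prok * lp +
      rnorm(n_prok, 0, config$noise_log10_prok)
    le <- runif(n_euk, 7, 10)
    # eukaryote line pinned to the prokaryote line at the 1e7 nt boundary
    euk_intercept <- (.prok_gene_intercept(config) + config$gene_exponent_prok * 7) -
      config$gene_exponent_euk * 7
    ge <- euk_intercept + config$gene_exponent_euk * le +
      rnorm(n_euk, 0, config$noise_log10_euk)
    ct <- (.prok_gene_intercept(config) + config$gene_exponent_prok * le) - ge
    data.frame(
      organism = c(sprintf("prok_%03d", seq_len(n_prok)),
                   sprintf("euk_%03d", seq_len(n_euk))),
      group = rep(c("prokaryote", "eukaryote"), c(n_prok, n_euk)),
      # continuous values: rounding to integer counts would inject extra
      # noise and break exact noiseless recovery of the set exponents
      genome_length = 10^c(lp, le),
      gene_count = 10^c(gp, ge),
      cell_type_count = c(rep(NA_real_, n_prok), 10^ct),
      stringsAsFactors = FALSE)
  }
  tab <- withr::with_seed(config$seed, gen())
  attr(tab, "provenance") <- .provenance(config)
  tab
}

#' Generate a synthetic binding-sites-vs-proteome table
#'
#' Two groups with a common power-law exponent linking disordered binding
#' sites to reduced proteome size; the eukaryote level is multiplied by
#' `jump_factor` (default 4, i.e. two factor-of-two jumps).
#'
#' @param config a [generator_config].
#' @param n_per_group rows per group.
#' @return data frame with columns `organism`, `group`,
#'   `reduced_proteome_size`, `disordered_binding_sites`, plus provenance.
#' @export
gen_binding_table <- function(config = generator_config(),
                              n_per_group = 60L) {
  stopifnot(inherits(config, "generator_config"))
  gen <- function() {
    # proteomes: prokaryotes ~500-6000 proteins, eukaryotes ~5000-40000
    lp <- runif(n_per_group, log10(500), log10(6000))
    le <- runif(n_per_group, log10(5000), log10(4e4))
    # one binding site per two proteins at the low end of prokaryotes
    b0 <- log10(250) - config$binding_exponent * log10(500)
    bp <- b0 + config$binding_exponent * lp +
      rnorm(n_per_group, 0, config$noise_log10_prok)
    be <- b0 + log10(config$jump_factor) + config$binding_exponent * le +
      rnorm(n_per_group, 0, config$noise_log10_prok)
    data.frame(
      organism = c(sprintf("prok_%03d", seq_len(n_per_group)),
                   sprintf("euk_%03d", seq_len(n_per_group))),
      group = rep(c("prokaryote", "eukaryote"), each = n_per_group),
      reduced_proteome_size = 10^c(lp, le),
      disordered_binding_sites = 10^c(bp, be),
      stringsAsFactors = FALSE)
  }
  tab <- withr::with_seed(config$seed, gen())
  attr(tab, "provenance") <- .provenance(config)
  tab
}
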