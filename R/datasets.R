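# Built-in datasets (origin times, canonical cell values, reference
# compilation) and readers/aggregators for user-supplied tables.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "complexitrend")
  if (!nzchar(path)) .stop_domain("bundled data file '%s' not found", file)
  path
}

#' Taxon origin times
#'
#' The bundled compilation of crude origin-time estimates (Gyr before
#' present) for major taxa, with the minimal cell JCVI-syn3A positioned at
#' 3.75 Gyr BP (midpoint of the 3.5-4 range; the DNA-length analysis uses
#' 4.0).
#'
#' @return data frame with columns `taxon`, `gyr_bp_range`, `time_gyr_bp`,
#'   `note`.
#' @export
origin_times <- function() {
  read.csv(.extdata("origin_times.csv"), stringsAsFactors = FALSE)
}

#' Reference compilation of complexity growth rates and intersections
#'
#' The published per-feature complexity slopes (Gyr^-1) and early-anchor
#' intersection times (Gyr BP) used as offline fixtures for the features
#' whose raw data come from external database extractions. The metabolic
#' rate carries a slope but no intersection.
#'
#' @return data frame with columns `feature_id`, `complexity_slope`,
#'   `intersection_time`, `anchor_label`.
#' @export
table4_reference <- function() {
  read.csv(.extdata("table4_reference.csv"), stringsAsFactors = FALSE,
           na.strings = c("NA", ""))
}

#' Built-in early anchors for every feature
#'
#' Constructs the early-feature anchor of each built-in feature from module
#' constants (no downloads): 100 nt string, single 33-aa peptide gene, one
#' bound protein pair (2 sites), the 33-residue synthesis energy, the 8 nm
#' micelle volume, the abiotic synthesis rate, and the mean mcbit of a
#' 100 nt RNA. The metabolic rate has no usable anchor and returns `NULL`.
#'
#' @param feature_id one of the built-in feature ids.
#' @return an [early_anchor] or `NULL` (metabolic rate).
#' @export
builtin_anchor <- function(feature_id) {
  switch(feature_id,
    dna_length = early_anchor("100 nt DNA string", 100,
                              "minimal memory chunk coding a 33 aa peptide"),
    gene_number = early_anchor("one 33 aa peptide (single gene)", 1,
                               "one gene product from a 100 nt string"),
    pp_binding = early_anchor("one pair of bound proteins", 2,
                              "two proteins with two disordered binding sites"),
    build_energy = energy_anchor(),
    cell_volume = micelle_anchor(),
    volume_per_doubling = strecker_anchor(),
    mcbit = early_anchor("average mcbit of a 100 nt RNA string", 42500,
                         "mean molecular-complexity index over 100 nt RNAs"),
    metabolic_rate = NULL,
    .stop_domain("unknown feature '%s'; available: %s", feature_id,
                 paste(.feature_ids, collapse = ", ")))
}

#' Load a built-in feature series
#'
#' Returns a ready-to-analyse [feature_series] for a built-in feature. The
#' cell-volume and volume-per-doubling series are fully populated from the
#' bundled canonical cell values and origin times; the remaining features
#' derive from external database extractions that are not redistributable,
#' so their series carry the early anchor plus the reference slope /
#' intersection (as a `"reference"` attribute) but no raw observations.
#'
#' @param feature_id built-in feature id.
#' @param jcvi_time_bp origin time assigned to JCVI-syn3A; default 3.75
#'   Gyr BP (volume and kinetics analyses). The DNA-length analysis uses
#'   4.0.
#' @return a [feature_series]; for data-backed features, with observations.
#' @examples
#' load_builtin("cell_volume")
#' @export
load_builtin <- function(feature_id, jcvi_time_bp = 3.75) {
  if (!feature_id %in% .feature_ids) {
    .stop_domain("unknown feature '%s'; available: %s", feature_id,
                 paste(.feature_ids, collapse = ", "))
  }
  cells <- read.csv(.extdata("cell_values.csv"), stringsAsFactors = FALSE,
                    na.strings = "NA")
  times <- origin_times()
  cells$time_gyr_bp <- times$time_gyr_bp[match(cells$taxon, times$taxon)]
  cells$time_gyr_bp[cells$taxon == "jcvi_syn3a"] <- jcvi_time_bp
  cells$volume_um3[cells$taxon == "jcvi_syn3a"] <- sphere_volume(0.4)
  anchor <- builtin_anchor(feature_id)
  ref <- table4_reference()
  ref <- ref[ref$feature_id == feature_id, ]

  series <- switch(feature_id,
    cell_volume = feature_series(
      "cell_volume",
      data.frame(taxon = cells$taxon, time_gyr_bp = cells$time_gyr_bp,
                 value = cells$volume_um3),
      anchor = anchor, units = "um^3"),
    volume_per_doubling = {
      ok <- !is.na(cells$doubling_h)
      feature_series(
        "volume_per_doubling",
        data.frame(taxon = cells$taxon[ok],
                   time_gyr_bp = cells$time_gyr_bp[ok],
                   value = cells$volume_um3[ok] / (cells$doubling_h[ok] * 60)),
        anchor = anchor, units = "um^3/min")
    },
    feature_series(feature_id,
                   data.frame(taxon = character(), time_gyr_bp = numeric(),
                              value = numeric()),
                   anchor = anchor, units = ""))
  attr(series, "reference") <- ref
  series
}

#' Read a genome-summary table
#'
#' Reads a comma- or tab-separated table of per-organism genome summaries
#' (NCBI-dump style) and validates it into records with columns `organism`,
#' `taxon_group`, `genome_length`, `gene_count`. Malformed rows
#' (non-positive genome length, negative gene count, missing taxon) are
#' dropped with a warning giving counts. Gzip-compressed files are read
#' transparently.
#'
#' @param path path to a CSV/TSV file (optionally `.gz`).
#' @param column_map named character vector mapping the required record
#'   fields to the file's column names.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return data frame of validated records.
#' @export
read_genome_table <- function(path,
                              column_map = c(organism = "organism",
                                             taxon_group = "taxon_group",
                                             genome_length = "genome_length",
                                             gene_count = "gene_count"),
                              sep = NULL) {
  if (is.null(sep)) {
    base <- sub("\\.gz$", "", path)
    sep <- if (grepl("\\.(tsv|txt)$", base)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("organism", "taxon_group", "genome_length", "gene_count")
  cols <- column_map[need]
  miss <- need[is.na(cols) | !(cols %in% names(raw))]
  if (length(miss)) {
    .stop_domain("input lacks mapped column(s) for: %s", paste(miss, collapse = ", "))
  }
  rec <- data.frame(organism = as.character(raw[[cols[["organism"]]]]),
                    taxon_group = as.character(raw[[cols[["taxon_group"]]]]),
                    genome_length = suppressWarnings(as.numeric(raw[[cols[["genome_length"]]]])),
                    gene_count = suppressWarnings(as.numeric(raw[[cols[["gene_count"]]]])),
                    stringsAsFactors = FALSE)
  ok <- is.finite(rec$genome_length) & rec$genome_length > 0 &
    is.finite(rec$gene_count) & rec$gene_count >= 0 &
    nzchar(rec$taxon_group)
  if (any(!ok)) {
    warning(sprintf("dropped %d malformed row(s) of %d", sum(!ok), nrow(rec)))
  }
  rec[ok, , drop = FALSE]
}

#' Aggregate per-organism records into a feature series
#'
#' Collapses per-organism records to per-taxon mean, sd and n on the raw
#' scale and attaches each taxon's origin time, producing a series ready
#' for [fit_loglinear()] / [mc_fit()].
#'
#' @param records data frame with columns `taxon_group` and the value
#'   column named by `value_col`.
#' @param origin data frame with columns `taxon`, `time_gyr_bp`; defaults
#'   to the bundled [origin_times()].
#' @param feature_id,units passed to [feature_series()].
#' @param value_col name of the value column; default `"genome_length"`.
#' @param anchor optional [early_anchor]; defaults to the built-in anchor
#'   when `feature_id` is a built-in feature.
#' @return a [feature_series] ordered by origin time.
#' @export
aggregate_by_taxon <- function(records, origin = origin_times(),
                               feature_id = "dna_length", units = "nt",
                               value_col = "genome_length",
                               anchor = NULL) {
  stopifnot(is.data.frame(records), value_col %in% names(records))
  groups <- unique(records$taxon_group)
  missing_t <- setdiff(groups, origin$taxon)
  if (length(missing_t)) {
    .stop_domain("no origin time for taxon group(s): %s",
                 paste(missing_t, collapse = ", "))
  }
  agg <- do.call(rbind, lapply(groups, function(g) {
    v <- records[[value_col]][records$taxon_group == g]
    data.frame(taxon = g,
               time_gyr_bp = origin$time_gyr_bp[match(g, origin$taxon)],
               value = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  if (is.null(anchor) && feature_id %in% .feature_ids) {
    anchor <- builtin_anchor(feature_id)
  }
  feature_series(feature_id, agg, anchor = anchor, units = units)
}

#' Write / read a feature series as CSV
#'
#' Round-trippable plain-text representation of a series' observations
#' (columns `taxon`, `time_gyr_bp`, `value`, `sd`, `n`).
#'
#' @param series a [feature_series].
#' @param path output path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a [feature_series].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "feature_series"))
  write.csv(series$observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param feature_id,units,anchor,log_base metadata for the reconstructed
#'   series (CSV carries observations only).
#' @export
read_series_csv <- function(path, feature_id = "user_feature", units = "",
                            anchor = NULL, log_base = 10) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  feature_series(feature_id, obs, anchor = anchor, units = units,
                 log_base = log_base)
}
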