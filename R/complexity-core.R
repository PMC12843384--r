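# Core complexity model: log transform, early-feature anchors, containers.

#' Relative complexity of feature values
#'
#' Element-wise logarithm of strictly positive feature values in a chosen
#' base. The log of a feature value is used throughout as its relative
#' complexity: because feature growth is taken as proportional to current
#' value, complexity grows linearly when the feature grows exponentially.
#' The output is unitless, which is what allows complexities from features
#' with different units to be compared and summed.
#'
#' @param values numeric vector of strictly positive feature values.
#' @param log_base base of the logarithm; default 10 (the convention used
#'   for all shipped analyses). Must be positive and not 1.
#' @param labels optional character vector (e.g. taxon names) used to name
#'   the offending entry in error messages.
#' @return numeric vector of logarithms, same length as `values`.
#' @examples
#' complexity_transform(c(1, 100, 1000))
#' complexity_transform(8, log_base = 2)
#' @export
complexity_transform <- function(values, log_base = 10, labels = NULL) {
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 0 ||
      log_base == 1) {
    .stop_domain("`log_base` must be a single positive number != 1")
  }
  values <- as.numeric(values)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    who <- if (!is.null(labels)) labels[bad[1L]] else paste0("#", bad[1L])
    .stop_domain(
      "non-positive feature value for %s (%.6g): complexity is defined only for positive values",
      who, values[bad[1L]])
  }
  log(values, base = log_base)
}

#' Volume of a sphere from its diameter
#'
#' @param diameter strictly positive diameter (any length unit).
#' @return volume `(pi/6) * d^3` in the cubed unit of `diameter`.
#' @examples
#' sphere_volume(0.4)   # a 0.4 um cell, in um^3
#' @export
sphere_volume <- function(diameter) {
  diameter <- as.numeric(diameter)
  if (any(!is.finite(diameter) | diameter <= 0)) {
    .stop_domain("`diameter` must be strictly positive")
  }
  (pi / 6) * diameter^3
}

#' Early-feature anchor
#'
#' An anchor is the minimal-complexity instance of a feature (e.g. a 100 nt
#' string for genome length) whose log value a fitted complexity trend is
#' extrapolated to intersect.
#'
#' @param label short human-readable description.
#' @param value strictly positive anchor value, in the feature's units.
#' @param derivation free text recording how the value was obtained.
#' @return an object of class `early_anchor`.
#' @export
early_anchor <- function(label, value, derivation = "") {
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value) || value <= 0) {
    .stop_domain("anchor `value` must be a single strictly positive number")
  }
  structure(list(label = as.character(label), value = value,
                 derivation = as.character(derivation)),
            class = "early_anchor")
}

#' @export
print.early_anchor <- function(x, ...) {
  cat(sprintf("Early anchor: %s = %.4g\n", x$label, x$value))
  if (nzchar(x$derivation)) cat("  derivation:", x$derivation, "\n")
  invisible(x)
}

#' Micelle anchor for the cell-volume feature
#'
#' Volume of the smallest lipid enclosure around a minimal peptide: a sphere
#' whose diameter is the peptide diameter plus twice the micelle wall
#' thickness. With the defaults (2 nm peptide, 3 nm wall) the enclosure is
#' an 8 nm sphere of volume 2.68e-7 um^3.
#'
#' @param peptide_diameter_nm peptide diameter in nm (> 0); default 2, the
#'   calculated diameter of a 33-residue peptide.
#' @param wall_thickness_nm micelle wall thickness in nm (>= 0); default 3.
#' @return an [early_anchor] whose value is a volume in um^3.
#' @export
micelle_anchor <- function(peptide_diameter_nm = 2, wall_thickness_nm = 3) {
  if (!is.finite(peptide_diameter_nm) || peptide_diameter_nm <= 0) {
    .stop_domain("`peptide_diameter_nm` must be strictly positive")
  }
  if (!is.finite(wall_thickness_nm) || wall_thickness_nm < 0) {
    .stop_domain("`wall_thickness_nm` must be non-negative")
  }
  d_nm <- peptide_diameter_nm + 2 * wall_thickness_nm
  vol_um3 <- sphere_volume(d_nm * 1e-3)
  early_anchor(
    label = sprintf("33 aa peptide in lipid micelle (%g nm sphere)", d_nm),
    value = vol_um3,
    derivation = sprintf(
      "(pi/6) * d^3 with d = %g nm peptide + 2 x %g nm wall = %g nm",
      peptide_diameter_nm, wall_thickness_nm, d_nm))
}

#' Energy anchor for the cell-construction-energy feature
#'
#' Energy in joules to synthesise a minimal peptide: residues x ATP per
#' residue x joules per ATP. The default ATP-per-residue value (11.65) is
#' the average cost of amino-acid synthesis for an H2-dependent methanogen
#' across NH4+ and N2 nitrogen sources; the J/ATP conversion defaults to
#' 5.0e-20 J (about 30.5 kJ/mol hydrolysis free energy) and is configurable
#' because downstream intersections do not depend on it strongly.
#'
#' @param n_residues number of residues (> 0); default 33.
#' @param atp_per_residue mean ATP cost per residue (> 0); default 11.65.
#' @param joules_per_atp J released per ATP (> 0); default 5.0e-20.
#' @return an [early_anchor] whose value is an energy in J.
#' @export
energy_anchor <- function(n_residues = 33, atp_per_residue = 11.65,
                          joules_per_atp = 5.0e-20) {
  args <- c(n_residues = n_residues, atp_per_residue = atp_per_residue,
            joules_per_atp = joules_per_atp)
  if (any(!is.finite(args) | args <= 0)) {
    .stop_domain("all energy_anchor arguments must be strictly positive")
  }
  early_anchor(
    label = sprintf("energy to build %g amino acids", n_residues),
    value = n_residues * atp_per_residue * joules_per_atp,
    derivation = sprintf("%g residues x %g ATP/residue x %.3g J/ATP",
                         n_residues, atp_per_residue, joules_per_atp))
}

# Printed constant for the abiotic amino-acid synthesis rate anchor.  The
# published figure value (2.56e-11 um^3/min) is not reconstructible from the
# published residue volume (~4.6e-11 um^3) and half-time (0.3^-1 min) by any
# identifiable arithmetic, so the constant is stored verbatim.
.strecker_printed_value <- 2.56e-11
.strecker_alanine_volume <- 4.6e-11

#' Strecker-reaction anchor for the volume-per-doubling feature
#'
#' Anchor for the mass-growth-rate feature: the volume-per-time equivalent
#' of abiotic (Strecker) synthesis of a minimal 33-residue sequence. Called
#' with no arguments it returns the published constant 2.56e-11 um^3/min,
#' whose derivation from the published inputs is not reconstructible and is
#' therefore recorded verbatim. With explicit arguments it returns the plain
#' product `rate_per_min * n_residues * residue_volume`, so that a unit rate
#' and single residue return the residue volume per minute.
#'
#' @param rate_per_min reaction rate in 1/min (> 0).
#' @param n_residues residue count (> 0).
#' @param residue_volume residue volume in um^3 (> 0); the published alanine
#'   volume is ~4.6e-11 um^3.
#' @return an [early_anchor] whose value is in um^3/min.
#' @export
strecker_anchor <- function(rate_per_min = 0.3, n_residues = 33,
                            residue_volume = .strecker_alanine_volume) {
  args <- c(rate_per_min = rate_per_min, n_residues = n_residues,
            residue_volume = residue_volume)
  if (any(!is.finite(args) | args <= 0)) {
    .stop_domain("all strecker_anchor arguments must be strictly positive")
  }
  if (missing(rate_per_min) && missing(n_residues) && missing(residue_volume)) {
    return(early_anchor(
      label = "Strecker synthesis of 33 amino acids",
      value = .strecker_printed_value,
      derivation = paste("published constant 2.56e-11 um^3/min;",
                         "not derivable from the published residue volume",
                         "(4.6e-11 um^3) and half-time (0.3^-1 min)")))
  }
  early_anchor(
    label = sprintf("abiotic synthesis of %g residues", n_residues),
    value = rate_per_min * n_residues * residue_volume,
    derivation = sprintf("%g /min x %g residues x %.3g um^3/residue",
                         rate_per_min, n_residues, residue_volume))
}

#' Per-taxon feature observations with an early anchor
#'
#' Container for one complexity feature: per-taxon observations (taxon name,
#' origin time in Gyr BP, raw-scale mean value, optional raw-scale sd and
#' record count) plus the feature's early anchor and log base.
#'
#' @param feature_id feature identifier; the built-in analyses use
#'   `dna_length`, `gene_number`, `pp_binding`, `build_energy`,
#'   `cell_volume`, `metabolic_rate`, `volume_per_doubling`, `mcbit`, but
#'   any user-chosen id is accepted.
#' @param observations data frame with columns `taxon`, `time_gyr_bp`,
#'   `value` and optionally `sd`, `n`. Times are Gyr before present
#'   (positive into the past); values must be strictly positive.
#' @param anchor optional [early_anchor].
#' @param units free-text units of the raw feature values.
#' @param log_base log base used when fitting; default 10.
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(feature_id, observations, anchor = NULL,
                           units = "", log_base = 10) {
  stopifnot(is.data.frame(observations))
  need <- c("taxon", "time_gyr_bp", "value")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    .stop_domain("observations lack column(s): %s", paste(miss, collapse = ", "))
  }
  obs <- observations
  obs$taxon <- as.character(obs$taxon)
  obs$time_gyr_bp <- as.numeric(obs$time_gyr_bp)
  obs$value <- as.numeric(obs$value)
  if (is.null(obs$sd)) obs$sd <- rep(NA_real_, nrow(obs))
  if (is.null(obs$n)) obs$n <- rep(NA_integer_, nrow(obs))
  if (any(!is.finite(obs$time_gyr_bp) | obs$time_gyr_bp < 0)) {
    .stop_domain("origin times must be finite and >= 0 Gyr BP")
  }
  bad <- which(!is.finite(obs$value) | obs$value <= 0)
  if (length(bad)) {
    .stop_domain("non-positive value for taxon %s", obs$taxon[bad[1L]])
  }
  if (any(!is.na(obs$sd) & obs$sd < 0)) {
    .stop_domain("value sd must be >= 0")
  }
  if (!is.null(anchor) && !inherits(anchor, "early_anchor")) {
    .stop_domain("`anchor` must be an early_anchor object")
  }
  obs <- obs[order(obs$time_gyr_bp), c("taxon", "time_gyr_bp", "value", "sd", "n")]
  rownames(obs) <- NULL
  structure(list(feature_id = as.character(feature_id), units = units,
                 observations = obs, anchor = anchor,
                 log_base = log_base),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("Feature series '%s' (%s): %d observation(s), log base %g\n",
              x$feature_id, x$units, nrow(x$observations), x$log_base))
  if (nrow(x$observations)) print(x$observations, ...)
  if (!is.null(x$anchor)) print(x$anchor)
  invisible(x)
}
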