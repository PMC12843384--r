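---
title: "Methods: log-linear complexity growth and origin-time extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: log-linear complexity growth and origin-time extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexitrend)
```

## The model

For a countable or measurable biological feature $x$ (genome length in
nucleotides, gene number, disordered protein binding sites, cell volume,
...), the working assumption is that the feature's rate of change is
proportional to its current value, the way populations and cumulative
innovations grow. Integrating that assumption makes the *logarithm* of
the feature a linear function of time,

$$C(x) = a\,\log(x) + b,$$

and $C(x)$ is used as a relative, unitless complexity value. Fitting
$\log_{10}(x_i)$ against taxon origin times $t_i$ (in Gyr before present,
positive into the past) gives a complexity growth rate $a$ in Gyr$^{-1}$:
a rate of 1 Gyr$^{-1}$ means the feature grows tenfold per billion years.
Because time runs into the past, the fitted slope on that axis is
negative for a growing feature; the package always reports the magnitude,
matching the convention of the published compilation.

Each feature has an *early anchor*: the minimal-complexity instance of
the feature (a 100 nt string; one 33-residue peptide; one pair of bound
proteins; the energy, micelle volume, or abiotic synthesis rate of a
33-residue construct; the mean molecular-complexity index of a 100 nt
RNA). Solving the fitted line for the time at which it reaches the
anchor's log value estimates the era when that feature's growth could
have begun, under the strong assumption that the linear trend continues
unchanged into pre-biotic chemistry. Every such intersection is an
extrapolation far beyond the data and is flagged as such; the package
computes the quantity and makes no causal claim for it.

```{r volume}
series <- load_builtin("cell_volume")
fit <- fit_loglinear(series)
fit
intersect_with_anchor(fit, series$anchor)
```

## Parameters that matter

* **Log base** (`log_base`, default 10). Changing base rescales all log
  values by a constant, so slopes scale but anchor intersection *times*
  do not. Base 2 is the natural view for factor-of-two jump analysis and
  is used there via a fixed $\log_2(10)$ conversion.
* **JCVI-syn3A origin time** (`jcvi_time_bp`). The minimal cell is a
  LUCA surrogate placed at 3.5-4 Gyr BP. The volume and kinetics
  analyses use the 3.75 midpoint, which reproduces the published volume
  slope of 1.27; the DNA-length analysis used 4.0. Both are arguments,
  never hard-coded into the fit.
* **Weighting** (`weighted`, `weight_rule`). The weighted variant uses
  inverse variance of the log values, with the log-sd taken as half the
  log-range of the raw mean ± sd interval (one-sided when mean − sd is
  not positive). This is a choice: the source analysis converts ± one sd
  "to logarithms" without stating the rule. Equal weights reproduce the
  unweighted fit exactly, which is tested.
* **Monte Carlo noise** (`mc_config`). "±20%" time uncertainty is
  interpreted as a *normal* standard deviation of $0.2\,t$, not a
  uniform bound. Feature values are redrawn on the raw scale from
  Normal(mean, sd) and redrawn while non-positive (at most 100 rounds,
  then an error), because the log transform requires positivity. Only
  the data points are jittered, never the anchor. Quantiles are reported
  alongside mean/sd because extrapolated intersection times are
  right-skewed.
* **Energy conversion** (`joules_per_atp`, default 5.0e-20 J ≈ 30.5
  kJ/mol). The source never states its J/ATP factor; the default is the
  standard hydrolysis free energy. Anchor-intersection *times* for the
  shipped analyses do not depend on it.
* **Metabolic-rate operands** (`allometric_exponent` = 0.75,
  `mass_rate` = 1.2). The metabolic complexity rate is the allometric
  exponent times a mass growth rate. The published 0.9 Gyr$^{-1}$ is
  consistent only with a mass rate of 1.2 (not the printed volume slopes
  1.27 or 1.32); 1.2 is therefore the default and both operands are
  exposed.

## Slope ratios, the time ruler, and jumps

A log-log (allometry-style) plot of two features has slope equal to the
ratio of their time slopes — time is removed, not gone. Two consequences
are implemented:

1. **Slope-ratio rates**: multiplying a log-log slope by the calibrated
   rate of its abscissa feature yields the ordinate feature's rate
   (`slope_ratio_rate`). Chaining is done on values rounded to reporting
   precision, matching the published arithmetic (0.96 × 0.81 = 0.78,
   then 1.04 × 0.78 = 0.81).
2. **Time ruler**: an affine least-squares map from an abscissa
   coordinate to Gyr BP, built from anchor pairs with known times
   (`build_time_ruler`). The package uses the *abscissa* of the log-log
   plot as the ruler coordinate — the published figures draw the ruler as
   vertical gridlines — rather than projecting onto the regression line;
   projection was a genuinely open design and the abscissa convention is
   simpler and matches the figures. Default anchor placements (present at
   the largest observed eukaryote abscissa, the eukaryote transition at
   2.2 Gyr BP at the group boundary, the minimal cell at 3.75 Gyr BP)
   approximate positions read off published figures and are overridable;
   they are approximations, not recovered values.

Jump analysis (`jump_analysis`) measures the vertical offset between two
group lines at the midpoint of their shared abscissa range and reports it
as a continuous factor plus the nearest power of two. Evaluation at a
single shared point is a choice; for non-parallel lines the factor
depends on where you evaluate, and midpoint-of-overlap is the least
arbitrary single point.

## The synthetic world

`gen_feature_series()` draws per-taxon lognormal values whose raw-scale
*mean* sits exactly on a configured trend line (the lognormal meanlog is
offset by $-\sigma^2/2$), with taxa, record counts (20-200) and a wide
raw CV of 0.5 mimicking a public-database extraction at desk scale.
`gen_gene_genome_table()` and `gen_binding_table()` produce power-law
pairs with configured exponents (0.96 / 0.32 / 1.04), a 4× eukaryote
binding offset, and eukaryote cell-type counts constructed so that
log(genes) + log(cell types) falls back on the prokaryote line. Values
are kept continuous (not rounded to integer counts) so that noiseless
configurations recover their exponents exactly — integerisation would
inject noise the tests would have to absorb.

What a green parameter-recovery test establishes: the pipeline is an
unbiased, correctly-calibrated estimator *for data with exactly the
generated structure*. It does not establish that real genome databases
have that structure — real extractions carry taxonomic correlation,
endosymbiont outliers, ascertainment bias and ploidy effects that the
generator deliberately omits.

The Monte Carlo CVs under these defaults are ~16% (slope) and ~2%
(intercept), computed by simulation and frozen into the tests with that
provenance. The published 8.5%/8.0% CVs came from the unpublished
database extraction and are not reproduced.

## Star-formation context

`lookback_time()` integrates the flat ΛCDM lookback integral
(`stats::integrate`, checked against an independent Simpson-rule oracle);
defaults H₀ = 69.6 km/s/Mpc, Ωₘ = 0.286 match the documented defaults of
the online calculator the source analysis used, with 13.721 Gyr as the
before-present zero point. The returned value is clipped at the
configured universe age; the clip can bind only beyond z ≈ 300, outside
the matter+Λ model's validity (no radiation term). `fit_sfr()` locates
the peak at the input point of maximum rate, fits a degree-4 polynomial
to the pre-peak side and an exponential decay to the post-peak side —
independently, with no continuity constraint at the peak, matching the
source's description — and samples the combined curve every 0.2 Gyr.
The redshift-rate fixture shipped with the package is *synthetic*
(generated by `gen_sfr_table()`, labelled as such); the real
gamma-ray-attenuation table is user-supplied. `align_with_intercepts()`
reports the peak time, the mean complexity intersection, their
difference, and whether the intersection era falls inside the
half-maximum SFR window — a concordance report, nothing more.

## Numerical choices and degenerate inputs

* Fits use a centered closed-form weighted least squares (needed in
  vectorised form by the Monte Carlo engine); tests verify it against an
  explicit normal-equations oracle at 1e-10 relative tolerance.
* "Coefficient of regression" is reported as |Pearson r| (this
  reproduces the published 0.97 for the volume fit; $r^2$ would give
  0.94).
* Fewer than two distinct origin times, zero time variance, non-positive
  feature values, zero fitted slope at intersection, non-monotone or
  duplicated ruler anchors, and constant SFR tables are all hard errors
  or flagged degeneracies, never silent results.
* Reporting rounds slopes to two decimals and intersections to one
  (`format_summary()`), the published precision; internal objects keep
  full precision, and chained slope-ratio arithmetic rounds between
  steps because that is how the published chain was computed.

## Known limitations and documented discrepancies

* The volume-per-doubling series as shipped (canonical volumes, doubling
  times 30/20/3/2.2/2 h, JCVI at 3.75 Gyr BP) yields slope 0.98, |r|
  0.97, intersection 11.6 Gyr BP, not the published 0.93/0.95/10.5; no
  variant of the stated inputs reproduces those numbers. `run_table4()`
  therefore defaults to the published compilation values for the
  data-dependent rows (so the offline aggregate reproduces the published
  0.96/0.20 and 8.6/1.0) and recomputes volume and kinetics from data,
  reporting what it computes.
* The published volume slope appears as 1.27 in the running text and
  1.32 in the compilation table; the pipeline computes 1.27 and the
  fixture table carries 1.32.
* The abiotic-synthesis anchor constant 2.56e-11 µm³/min is stored
  verbatim because no arithmetic reconstructs it from the published
  residue volume and half-time; the residue is named glycine in one
  place and alanine in another in the source, and the anchor label keeps
  the construction generic.
* The "five clustered intercepts" statistic of the source (mean 8.6, sd
  0.23) is not reproducible from the published rounded values and is not
  computed.
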