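#' Shapiro-Wilk normality check
#'
#' Gate used to choose between Pearson and Spearman correlation: a sample
#' passes when the Shapiro-Wilk test does not reject normality at
#' `alpha`.
#'
#' @param x numeric sample, `3 <= n <= 5000`, non-constant.
#' @param alpha significance level.
#' @return list with `pass` (logical), `statistic` (W), `p_value`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0) stop("constant vector")
  sw <- shapiro.test(x)
  list(pass = sw$p.value >= alpha, statistic = unname(sw$statistic),
       p_value = sw$p.value)
}

#' Correlation between volume irregularity and absorption deviation
#'
#' Tests the statistical relationship between the per-sample deviation of
#' the true volume from the perfect cylinder (absolute mm^3 or relative
#' percent) and the per-sample deviation of the estimated absorption
#' coefficient from the theoretical mixture reference. Pearson's
#' correlation is used when both variables pass [normality_check()],
#' otherwise Spearman's rank correlation.
#'
#' @param volume_diff per-sample volume deviation.
#' @param mu_a_diff per-sample absorption deviation (percent).
#' @param mode `"absolute"` or `"relative"` (label carried into output).
#' @return A `CorrelationResult`: `phi`, `p_value`, `method`, `n`, `mode`.
#' @export
volume_correlation <- function(volume_diff, mu_a_diff,
                               mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  volume_diff <- as.numeric(volume_diff)
  mu_a_diff <- as.numeric(mu_a_diff)
  if (length(volume_diff) != length(mu_a_diff)) stop("unequal lengths")
  if (length(volume_diff) < 3L) stop("need at least 3 pairs")
  if (sd(volume_diff) == 0 || sd(mu_a_diff) == 0) stop("zero variance input")
  method <- if (normality_check(volume_diff)$pass &&
                normality_check(mu_a_diff)$pass) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(volume_diff, mu_a_diff, method = method,
                                  exact = FALSE))
  structure(list(phi = unname(ct$estimate), p_value = ct$p.value,
                 method = method, n = length(volume_diff), mode = mode),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("<CorrelationResult> phi=%.4f p=%.4g (%s, n=%d, %s)\n",
              x$phi, x$p_value, x$method, x$n, x$mode))
  invisible(x)
}

# summarize per-sample relative-difference spectra into a report
sensitivity_report <- function(rel_diff_spectra, factor, levels) {
  qb <- quartile_band(rel_diff_spectra)
  structure(list(axis = qb$median$wavelengths,
                 rel_diff_median = qb$median$values,
                 rel_diff_q1 = qb$q1$values,
                 rel_diff_q3 = qb$q3$values,
                 factor = factor, levels = levels),
            class = "SensitivityReport")
}

#' @export
print.SensitivityReport <- function(x, ...) {
  cat(sprintf(
    "<SensitivityReport> factor %s (%s), %d wavelengths, median of medians %.3g%%\n",
    x$factor, paste(x$levels, collapse = " vs "), length(x$axis),
    median(x$rel_diff_median)))
  invisible(x)
}

#' Export a sensitivity report as delimited text
#' @param report a `SensitivityReport`.
#' @param path output path (tab-separated).
#' @return Invisibly, the data frame written.
#' @export
write_sensitivity_report <- function(report, path) {
  df <- data.frame(wavelength_nm = report$axis,
                   rel_diff_median = report$rel_diff_median,
                   rel_diff_q1 = report$rel_diff_q1,
                   rel_diff_q3 = report$rel_diff_q3)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

# correlation of two property spectra, Pearson/Spearman gated on normality
spectra_correlation <- function(a, b) {
  shared_axis(a, b)
  volume_correlation(a$values, b$values, mode = "absolute")
}

#' Anisotropy-factor sensitivity of the recovered properties
#'
#' Inverts the same measurement record(s) with lookup tables built at
#' different anisotropy factors and reports, for each non-baseline `g`,
#' the per-wavelength relative difference of the recovered `mu_a` and
#' `mu_s'` from the baseline-`g` arm (quartile bands across records),
#' plus the correlation between each property spectrum and its baseline.
#'
#' @param records a [measurement_record()] or list of them.
#' @param luts_by_g named list of `LookupTable`s; names are the `g`
#'   values (e.g. `"0.8"`, `"0.9"`, `"0.99"`), sharing grid and geometry.
#' @param baseline name of the baseline level (default `"0.9"`).
#' @return list keyed by non-baseline level; each element has
#'   `mu_a_report`, `mu_s_report` (`SensitivityReport`s) and
#'   `mu_a_correlation`, `mu_s_correlation` (`CorrelationResult`s for the
#'   first record).
#' @export
g_sensitivity <- function(records, luts_by_g, baseline = "0.9") {
  if (inherits(records, "MeasurementRecord")) records <- list(records)
  if (is.null(names(luts_by_g)) || !(baseline %in% names(luts_by_g))) {
    stop(sprintf("missing baseline g level '%s'", baseline))
  }
  inv <- lapply(luts_by_g, function(lut) {
    lapply(records, invert_spectrum, luts = lut)
  })
  base <- inv[[baseline]]
  out <- list()
  for (lev in setdiff(names(luts_by_g), baseline)) {
    arm <- inv[[lev]]
    rd_a <- Map(function(t, r) relative_difference(t$mu_a, r$mu_a), arm, base)
    rd_s <- Map(function(t, r) relative_difference(t$mu_s_prime, r$mu_s_prime),
                arm, base)
    out[[lev]] <- list(
      mu_a_report = sensitivity_report(rd_a, "g", c(lev, baseline)),
      mu_s_report = sensitivity_report(rd_s, "g", c(lev, baseline)),
      mu_a_correlation = spectra_correlation(arm[[1L]]$mu_a, base[[1L]]$mu_a),
      mu_s_correlation = spectra_correlation(arm[[1L]]$mu_s_prime,
                                             base[[1L]]$mu_s_prime))
  }
  out
}

#' Surrounding-medium sensitivity of the recovered absorption coefficient
#'
#' Inverts the record(s) under the air-gap and water-gap lookup tables
#' and reports, per medium, the relative difference of the recovered
#' `mu_a` from the theoretical mixture reference.
#'
#' @param records a [measurement_record()] or list of them.
#' @param lut_air,lut_water `LookupTable`s differing only in gap medium.
#' @param mu_a_theoretical reference `Spectrum` on the records' axis.
#' @return list with `air` and `water` `SensitivityReport`s.
#' @export
medium_sensitivity <- function(records, lut_air, lut_water, mu_a_theoretical) {
  if (inherits(records, "MeasurementRecord")) records <- list(records)
  per_medium <- function(lut, label) {
    rd <- lapply(records, function(rec) {
      est <- invert_spectrum(rec, lut)
      relative_difference(est$mu_a, mu_a_theoretical)
    })
    sensitivity_report(rd, "medium", c(label, "theoretical"))
  }
  list(air = per_medium(lut_air, "air"),
       water = per_medium(lut_water, "water"))
}

#' Refractive-index sensitivity of the recovered properties
#'
#' Inverts the same record with lookup tables built at different assumed
#' sample refractive indices and reports the relative change of the
#' recovered properties against the baseline-`n` arm.
#'
#' @param record a [measurement_record()].
#' @param luts_by_n named list of `LookupTable`s; names are the `n`
#'   values (e.g. `"1.3"`, `"1.358"`, `"1.5"`).
#' @param baseline baseline level name (default `"1.358"`).
#' @return list keyed by non-baseline level with `mu_a_rel_diff` and
#'   `mu_s_rel_diff` percent `Spectrum`s.
#' @export
n_sensitivity <- function(record, luts_by_n, baseline = "1.358") {
  stopifnot(inherits(record, "MeasurementRecord"))
  if (is.null(names(luts_by_n)) || !(baseline %in% names(luts_by_n))) {
    stop(sprintf("missing baseline n level '%s'", baseline))
  }
  inv <- lapply(luts_by_n, invert_spectrum, record = record)
  base <- inv[[baseline]]
  out <- list()
  for (lev in setdiff(names(luts_by_n), baseline)) {
    out[[lev]] <- list(
      mu_a_rel_diff = relative_difference(inv[[lev]]$mu_a, base$mu_a),
      mu_s_rel_diff = relative_difference(inv[[lev]]$mu_s_prime,
                                          base$mu_s_prime))
  }
  out
}

#' Surface-roughness experiment: smooth vs maximally rough bottom
#'
#' Forward-simulates the same sample with a smooth and with a fully
#' Lambertian (maximally rough) bottom interface, inverts both arms
#' against the smooth-geometry lookup table, and reports the relative
#' change of the recovered properties (rough vs smooth arm) per
#' wavelength.
#'
#' @param props_by_wavelength list of [optical_properties()] objects, one
#'   per wavelength.
#' @param wavelengths wavelength axis, nm.
#' @param construct a [sample_construct()] with `bottom_roughness`
#'   `"smooth"` (the rough arm is derived from it).
#' @param lut_smooth `LookupTable` built for the smooth geometry.
#' @param n_photons photons per forward simulation.
#' @param seed seed shared by both arms (common random numbers).
#' @return list with `mu_a_change`, `mu_s_change` (percent `Spectrum`s)
#'   and the two inversions.
#' @export
roughness_experiment <- function(props_by_wavelength, wavelengths, construct,
                                 lut_smooth, n_photons = 1e5, seed = 1) {
  stopifnot(inherits(construct, "SampleConstruct"),
            inherits(lut_smooth, "LookupTable"))
  rough <- construct
  rough$bottom_roughness <- "lambertian"
  run_arm <- function(con) {
    rt <- lapply(props_by_wavelength, simulate_rt, construct = con,
                 n_photons = n_photons, seed = seed)
    rec <- measurement_record(
      spectrum_new(wavelengths, vapply(rt, `[[`, numeric(1), "R_diffuse"),
                   "fraction"),
      spectrum_new(wavelengths, vapply(rt, `[[`, numeric(1), "T_total"),
                   "fraction"))
    invert_spectrum(rec, lut_smooth)
  }
  sm <- run_arm(construct)
  rg <- run_arm(rough)
  list(mu_a_change = relative_difference(rg$mu_a, sm$mu_a),
       mu_s_change = relative_difference(rg$mu_s_prime, sm$mu_s_prime),
       smooth = sm, rough = rg)
}
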