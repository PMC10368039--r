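#' Component absorption library
#'
#' Absorption spectra of the four cartilage constituents (water, collagen,
#' elastin, lipid) on one wavelength axis, together with their volume
#' fractions. The default fractions 0.68 / 0.30 / 0.01 / 0.01 represent
#' the articular cartilage matrix.
#'
#' @param spectra named list of four `Spectrum` objects (mm^-1) sharing
#'   one axis, names `water`, `collagen`, `elastin`, `lipid`.
#' @param fractions named numeric volume fractions, each in `[0, 1]`,
#'   summing to 1.
#' @return A `ComponentLibrary` list.
#' @export
component_library <- function(spectra,
                              fractions = c(water = 0.68, collagen = 0.30,
                                            elastin = 0.01, lipid = 0.01)) {
  comp <- c("water", "collagen", "elastin", "lipid")
  if (!setequal(names(spectra), comp) || !setequal(names(fractions), comp)) {
    stop("spectra and fractions must be named water, collagen, elastin, lipid")
  }
  spectra <- spectra[comp]
  fractions <- fractions[comp]
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  do.call(shared_axis, unname(spectra))
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must lie in [0, 1] and sum to 1")
  }
  structure(list(spectra = spectra, fractions = fractions),
            class = "ComponentLibrary")
}

#' @export
print.ComponentLibrary <- function(x, ...) {
  cat(sprintf("<ComponentLibrary> %d wavelengths; fractions %s\n",
              length(x$spectra$water$wavelengths),
              paste(sprintf("%s=%.2f", names(x$fractions), x$fractions),
                    collapse = " ")))
  invisible(x)
}

#' Synthetic component absorption spectra
#'
#' Generates a stand-in library of the four constituent absorption
#' spectra on an arbitrary wavelength axis: a water-like curve with
#' absorption bands near 970, 1200 and 1400 nm rising steeply into the
#' short-wave infrared, and smooth, monotonically decreasing collagen /
#' elastin / lipid stand-ins. These are synthetic curves with realistic
#' magnitudes (mm^-1), not digitized literature spectra; real spectra can
#' be supplied as delimited text via [read_component_library()].
#'
#' @param wavelengths wavelength axis, nm, strictly increasing.
#' @param fractions volume fractions passed to [component_library()].
#' @return A `ComponentLibrary`.
#' @examples
#' lib <- synthetic_component_library(seq(500, 1300, by = 50))
#' mixture_absorption(lib)
#' @export
synthetic_component_library <- function(wavelengths,
                                        fractions = c(water = 0.68,
                                                      collagen = 0.30,
                                                      elastin = 0.01,
                                                      lipid = 0.01)) {
  wl <- as.numeric(wavelengths)
  gauss <- function(center, width, height) height * exp(-0.5 * ((wl - center) / width)^2)
  water <- 5e-4 +
    gauss(740, 25, 0.002) +
    gauss(970, 35, 0.045) +
    gauss(1200, 55, 0.10) +
    gauss(1450, 60, 2.9)          # deep-SWIR water band shoulder
  collagen <- 0.012 * (wl / 500)^-1.6 + 0.002
  elastin  <- 0.020 * (wl / 500)^-1.8 + 0.001
  lipid    <- 0.006 * (wl / 500)^-1.2 + 0.001
  component_library(
    spectra = list(water = spectrum_new(wl, water, "mm^-1"),
                   collagen = spectrum_new(wl, collagen, "mm^-1"),
                   elastin = spectrum_new(wl, elastin, "mm^-1"),
                   lipid = spectrum_new(wl, lipid, "mm^-1")),
    fractions = fractions)
}

#' Theoretical absorption coefficient of the constituent mixture
#'
#' Volume-fraction-weighted sum of the component absorption spectra:
#' \deqn{\mu_{a,theoretical}(\lambda) = \sum_c \mu_{a,c}(\lambda)\, V_c,}
#' the reference against which estimated cartilage absorption spectra are
#' judged.
#'
#' @param lib a [component_library()].
#' @return A `Spectrum` (mm^-1) on the library's axis.
#' @export
mixture_absorption <- function(lib) {
  stopifnot(inherits(lib, "ComponentLibrary"))
  ax <- do.call(shared_axis, unname(lib$spectra))
  v <- Reduce(`+`, Map(function(s, f) s$values * f,
                       lib$spectra, as.list(lib$fractions)))
  spectrum_new(ax, v, "mm^-1")
}

#' Observation-removal quality filter for estimated absorption spectra
#'
#' Flags an estimated absorption spectrum as signal distortion when it
#' shows any of: values at or below the absorption floor (`<= 1e-5`
#' mm^-1); signal flattening (coefficient of variation over the band
#' below `cv_min`); or lack of the spectral features of the theoretical
#' mixture reference (Pearson correlation with it over the feature band,
#' default 900-1400 nm, below `r_min`).
#'
#' @param mu_a_est estimated absorption `Spectrum` (mm^-1).
#' @param mu_a_theoretical reference mixture `Spectrum` on the same axis.
#' @param floor absorption floor, mm^-1.
#' @param cv_min minimal coefficient of variation.
#' @param r_min minimal feature-band Pearson correlation.
#' @param feature_band wavelength window (nm) for the correlation check.
#' @return A `QCDecision`: `keep` flag and `reasons` (subset of
#'   `flat_signal`, `below_floor`, `missing_features`).
#' @export
qc_filter <- function(mu_a_est, mu_a_theoretical,
                      floor = 1e-5, cv_min = 0.05, r_min = 0.5,
                      feature_band = c(900, 1400)) {
  stopifnot(is_spectrum(mu_a_est), is_spectrum(mu_a_theoretical))
  shared_axis(mu_a_est, mu_a_theoretical)
  if (length(mu_a_est$values) < 3L) stop("band shorter than 3 points")
  reasons <- character(0)
  if (any(mu_a_est$values <= floor)) reasons <- c(reasons, "below_floor")
  cv <- sd(mu_a_est$values) / mean(mu_a_est$values)
  if (!is.finite(cv) || cv < cv_min) reasons <- c(reasons, "flat_signal")
  est_b <- spectrum_band(mu_a_est, feature_band)
  ref_b <- spectrum_band(mu_a_theoretical, feature_band)
  if (length(est_b$values) >= 3L) {
    r <- suppressWarnings(stats::cor(est_b$values, ref_b$values,
                                     method = "pearson"))
    if (!is.finite(r) || r < r_min) reasons <- c(reasons, "missing_features")
  }
  structure(list(keep = length(reasons) == 0L, reasons = reasons),
            class = "QCDecision")
}

#' @export
print.QCDecision <- function(x, ...) {
  if (x$keep) cat("<QCDecision> keep\n")
  else cat("<QCDecision> remove:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
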