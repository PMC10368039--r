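#' Paired reflectance/transmittance measurement record
#'
#' Holds the calibrated diffuse reflectance and total transmittance
#' spectra of one sample (fractions, shared wavelength axis), together
#' with a site label and free-form acquisition metadata.
#'
#' @param R,T `Spectrum` objects in `"fraction"` units on one axis.
#' @param site site label (e.g. one of FL, FM, PL, PM, TL, TM).
#' @param meta named list of acquisition metadata (seeds, photon counts,
#'   noise settings, ...).
#' @return A `MeasurementRecord` list.
#' @export
measurement_record <- function(R, T, site = "NA", meta = list()) {
  stopifnot(is_spectrum(R), is_spectrum(T))
  shared_axis(R, T)
  if (length(R$values) && (any(R$values < 0) || any(T$values < 0))) {
    stop("R and T must be nonnegative fractions")
  }
  structure(list(R = R, T = T, site = site, meta = meta),
            class = "MeasurementRecord")
}

#' @export
print.MeasurementRecord <- function(x, ...) {
  cat(sprintf("<MeasurementRecord> site %s, %d wavelengths\n",
              x$site, length(x$R$wavelengths)))
  invisible(x)
}

# deterministic sub-seed derivation (stays below 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 69621 + as.numeric(k) * 30011 + 1) %% 2147483629
}
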