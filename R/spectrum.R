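#' Wavelength-resolved spectrum
#'
#' A `Spectrum` pairs a strictly increasing wavelength axis (nm) with one
#' scalar value per wavelength, tagged with its unit. It is the common
#' currency of the package: measured reflectance/transmittance curves,
#' absorption and reduced scattering coefficient spectra, and relative
#' difference traces are all `Spectrum` objects.
#'
#' @param wavelengths numeric, nm, strictly increasing.
#' @param values numeric, same length as `wavelengths`, all finite.
#' @param units one of `"mm^-1"`, `"fraction"`, `"percent"`,
#'   `"dimensionless"`.
#' @return An object of class `Spectrum`: a list with elements
#'   `wavelengths`, `values`, `units`.
#' @examples
#' s <- spectrum_new(c(500, 600, 700), c(0.1, 0.2, 0.3), "mm^-1")
#' s$values
#' @export
spectrum_new <- function(wavelengths, values,
                         units = c("dimensionless", "mm^-1", "fraction", "percent")) {
  units <- match.arg(units)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (length(values) && any(!is.finite(values))) {
    stop("values must be finite")
  }
  structure(list(wavelengths = wavelengths, values = values, units = units),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  n <- length(x$wavelengths)
  cat(sprintf("<Spectrum> %d points", n))
  if (n) {
    cat(sprintf(", %g-%g nm, units %s\n", min(x$wavelengths),
                max(x$wavelengths), x$units))
  } else {
    cat(sprintf(", units %s\n", x$units))
  }
  invisible(x)
}

#' @export
as.data.frame.Spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths, value = x$values)
}

#' @export
length.Spectrum <- function(x) length(x$wavelengths)

#' @export
plot.Spectrum <- function(x, ...) {
  graphics::plot(x$wavelengths, x$values, type = "l",
                 xlab = "wavelength (nm)", ylab = x$units, ...)
}

is_spectrum <- function(x) inherits(x, "Spectrum")

#' Check that spectra share one wavelength axis
#'
#' @param ... `Spectrum` objects.
#' @return Invisibly, the shared wavelength axis; errors on any mismatch.
#' @keywords internal
shared_axis <- function(...) {
  xs <- list(...)
  ax <- xs[[1L]]$wavelengths
  for (s in xs[-1L]) {
    if (length(s$wavelengths) != length(ax) ||
        (length(ax) && any(abs(s$wavelengths - ax) > 1e-9))) {
      stop("spectra do not share a wavelength axis")
    }
  }
  invisible(ax)
}

#' Restrict a spectrum to a wavelength band
#'
#' @param x a `Spectrum`.
#' @param band numeric length 2, inclusive band limits in nm.
#' @return The `Spectrum` restricted to `band`.
#' @export
spectrum_band <- function(x, band) {
  stopifnot(is_spectrum(x), length(band) == 2L)
  keep <- x$wavelengths >= min(band) & x$wavelengths <= max(band)
  spectrum_new(x$wavelengths[keep], x$values[keep], x$units)
}

#' Pointwise median and quartile bands of a set of spectra
#'
#' Summarises a group of spectra sharing one wavelength axis the way
#' per-site cohorts are presented: the pointwise median with first and
#' third quartile bands. Quantiles use the linear-interpolation definition
#' (type 7).
#'
#' @param spectra list of `Spectrum` objects on one axis (at least one).
#' @return list with `median`, `q1`, `q3` (`Spectrum`s sharing the axis).
#' @examples
#' sp <- lapply(1:3, function(k) spectrum_new(c(500, 600), c(k, k)))
#' quartile_band(sp)$median$values
#' @export
quartile_band <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  ax <- do.call(shared_axis, spectra)
  m <- do.call(rbind, lapply(spectra, function(s) s$values))
  units <- spectra[[1L]]$units
  qs <- apply(m, 2L, quantile, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 3L)
  list(median = spectrum_new(ax, qs[2L, ], units),
       q1 = spectrum_new(ax, qs[1L, ], units),
       q3 = spectrum_new(ax, qs[3L, ], units))
}

#' Pointwise relative difference between two spectra, in percent
#'
#' Computes `100 * (test - reference) / reference` at each wavelength, so
#' underestimation relative to the reference is negative. The reference is
#' always the second argument.
#'
#' @param test,reference `Spectrum` objects on a shared axis; `reference`
#'   must be nonzero at every wavelength.
#' @return A percent-unit `Spectrum` of relative differences.
#' @examples
#' a <- spectrum_new(c(500, 600), c(1, 2))
#' b <- spectrum_new(c(500, 600), c(2, 2))
#' relative_difference(a, b)$values  # -50, 0
#' @export
relative_difference <- function(test, reference) {
  stopifnot(is_spectrum(test), is_spectrum(reference))
  ax <- shared_axis(test, reference)
  if (any(reference$values == 0)) {
    bad <- ax[reference$values == 0][1L]
    stop(sprintf("reference spectrum is zero at %g nm", bad))
  }
  spectrum_new(ax, 100 * (test$values - reference$values) / reference$values,
               "percent")
}
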