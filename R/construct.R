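#' Lateral gap medium of the sample holder
#'
#' The annular gap between the cartilage cylinder and the holder wall is
#' filled with either air or water (PBS). Air is index-matched to the
#' ambient (n = 1, no absorption or scattering); water has n = 1.33 and a
#' wavelength-dependent absorption coefficient that the caller supplies
#' per-run (scattering is negligible).
#'
#' @param name `"air"` or `"water"`, or `"custom"` with explicit values.
#' @param mu_a absorption coefficient of the medium, mm^-1.
#' @param mu_s scattering coefficient of the medium, mm^-1.
#' @param g anisotropy factor of the medium.
#' @param n refractive index of the medium.
#' @return A `GapMedium` list.
#' @examples
#' gap_medium("air")
#' gap_medium("water", mu_a = 0.05)
#' @export
gap_medium <- function(name = c("air", "water", "custom"),
                       mu_a = NULL, mu_s = NULL, g = NULL, n = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    air    = list(mu_a = 0, mu_s = 0, g = 0, n = 1.0),
    water  = list(mu_a = 0, mu_s = 0, g = 0, n = 1.33),
    custom = list(mu_a = 0, mu_s = 0, g = 0, n = 1.0))
  out <- list(name = name,
              mu_a = if (is.null(mu_a)) defaults$mu_a else mu_a,
              mu_s = if (is.null(mu_s)) defaults$mu_s else mu_s,
              g = if (is.null(g)) defaults$g else g,
              n = if (is.null(n)) defaults$n else n)
  if (out$mu_a < 0 || out$mu_s < 0 || out$n < 1) {
    stop("gap medium properties must be nonnegative with n >= 1")
  }
  structure(out, class = "GapMedium")
}

#' Cylinder-in-holder sample geometry
#'
#' Describes the measurement construct: a cartilage cylinder held between
#' two glass windows inside a cylindrical holder, with the lateral annular
#' gap filled by air or water. The sample's bottom face can carry an
#' oblique planar cut (emulating the irregular cartilage-bone detachment
#' surface) and can be flagged as maximally rough, in which case photons
#' crossing it are redirected with a Lambertian (cosine-weighted) law.
#'
#' Default dimensions follow the 14 mm drill-bit plug in a slightly wider
#' holder with 1 mm glass windows; all are overridable.
#'
#' @param sample_radius cartilage cylinder radius, mm.
#' @param sample_thickness cartilage cylinder thickness, mm.
#' @param window_thickness glass window thickness, mm (0 = no windows).
#' @param window_n glass refractive index.
#' @param gap_medium a [gap_medium()] object.
#' @param holder_radius inner holder radius, mm (>= `sample_radius`).
#' @param bottom_roughness `"smooth"` or `"lambertian"`.
#' @param beam_radius radius of the collimated incident beam, mm.
#' @param cut_depth maximal depth of the oblique bottom cut, mm (0 = flat
#'   bottom). The cut plane passes through the nominal bottom rim on one
#'   side and `cut_depth` above it on the other, removing a volume
#'   fraction `cut_depth / (2 * sample_thickness)`.
#' @return A `SampleConstruct` list.
#' @examples
#' sample_construct(sample_thickness = 2)
#' @export
sample_construct <- function(sample_radius = 7,
                             sample_thickness = 2,
                             window_thickness = 1,
                             window_n = 1.52,
                             gap_medium = opticart::gap_medium("air"),
                             holder_radius = 9,
                             bottom_roughness = c("smooth", "lambertian"),
                             beam_radius = 1,
                             cut_depth = 0) {
  bottom_roughness <- match.arg(bottom_roughness)
  stopifnot(sample_radius > 0, sample_thickness > 0, window_thickness >= 0,
            beam_radius > 0, cut_depth >= 0)
  if (holder_radius < sample_radius) {
    stop("holder_radius must be >= sample_radius")
  }
  if (window_thickness > 0 && window_n < 1) stop("window_n must be >= 1")
  if (cut_depth >= sample_thickness) {
    stop("cut_depth must be smaller than sample_thickness")
  }
  if (!inherits(gap_medium, "GapMedium")) stop("gap_medium must be a GapMedium")
  structure(list(sample_radius = sample_radius,
                 sample_thickness = sample_thickness,
                 window_thickness = window_thickness,
                 window_n = window_n,
                 gap_medium = gap_medium,
                 holder_radius = holder_radius,
                 bottom_roughness = bottom_roughness,
                 beam_radius = beam_radius,
                 cut_depth = cut_depth),
            class = "SampleConstruct")
}

#' @export
print.SampleConstruct <- function(x, ...) {
  cat(sprintf(
    "<SampleConstruct> r=%g mm, d=%g mm, windows %g mm (n=%g), gap=%s, holder r=%g mm, bottom=%s%s\n",
    x$sample_radius, x$sample_thickness, x$window_thickness, x$window_n,
    x$gap_medium$name, x$holder_radius, x$bottom_roughness,
    if (x$cut_depth > 0) sprintf(", cut %.3g mm", x$cut_depth) else ""))
  invisible(x)
}

#' Nominal cylinder volume of a construct, mm^3
#' @param construct a `SampleConstruct`.
#' @return Volume of the perfect cylinder, mm^3.
#' @export
nominal_volume <- function(construct) {
  pi * construct$sample_radius^2 * construct$sample_thickness
}

#' True sample volume accounting for the oblique bottom cut, mm^3
#' @param construct a `SampleConstruct`.
#' @return Volume of the cut cylinder, mm^3.
#' @export
true_volume <- function(construct) {
  nominal_volume(construct) * (1 - construct$cut_depth / (2 * construct$sample_thickness))
}
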