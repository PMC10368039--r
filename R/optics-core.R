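#' Bundle of optical properties for one homogeneous medium
#'
#' Collects the wavelength-independent transport parameters of a medium:
#' absorption coefficient `mu_a` (mm^-1), single scattering coefficient
#' `mu_s` (mm^-1), scattering anisotropy factor `g` (mean cosine of the
#' deflection angle) and refractive index `n`. The derived reduced
#' scattering coefficient `mu_s_prime = mu_s * (1 - g)` and attenuation
#' coefficient `mu_t = mu_a + mu_s` are attached.
#'
#' @param mu_a absorption coefficient, mm^-1, >= 0.
#' @param mu_s single scattering coefficient, mm^-1, >= 0.
#' @param g anisotropy factor, -1 < g < 1.
#' @param n refractive index, >= 1.
#' @return An `OpticalProperties` object (list with the four fields plus
#'   derived `mu_s_prime` and `mu_t`).
#' @examples
#' optical_properties(mu_a = 0.01, mu_s = 10, g = 0.9, n = 1.358)$mu_s_prime
#' @export
optical_properties <- function(mu_a, mu_s, g = 0.9, n = 1.358) {
  stopifnot(length(mu_a) == 1L, length(mu_s) == 1L, length(g) == 1L,
            length(n) == 1L)
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be >= 0")
  if (!is.finite(mu_s) || mu_s < 0) stop("mu_s must be >= 0")
  if (!is.finite(g) || abs(g) >= 1) stop("g must satisfy -1 < g < 1")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
                 mu_s_prime = mu_s * (1 - g), mu_t = mu_a + mu_s),
            class = "OpticalProperties")
}

#' @export
print.OpticalProperties <- function(x, ...) {
  cat(sprintf(
    "<OpticalProperties> mu_a=%.4g mu_s=%.4g (mu_s'=%.4g) g=%.3g n=%.4g [mm^-1]\n",
    x$mu_a, x$mu_s, x$mu_s_prime, x$g, x$n))
  invisible(x)
}

#' Henyey-Greenstein phase function
#'
#' Per-steradian probability density of scattering through deflection angle
#' `theta` for anisotropy factor `g`:
#' \deqn{p(\theta, g) = \frac{1}{4\pi}\frac{1-g^2}{(1+g^2-2g\cos\theta)^{3/2}}.}
#' It integrates to 1 over the unit sphere and has mean cosine `g`.
#'
#' @param theta deflection angle in radians, in `[0, pi]`; vectorised.
#' @param g anisotropy factor, -1 < g < 1.
#' @return The density value(s), per steradian.
#' @examples
#' hg_phase(1.0, 0)        # isotropic: 1/(4*pi)
#' hg_phase(0, 0.9)        # strong forward peak
#' @export
hg_phase <- function(theta, g) {
  if (!is.finite(g) || abs(g) >= 1) stop("g must satisfy -1 < g < 1")
  if (any(theta < 0 | theta > pi)) stop("theta must be in [0, pi]")
  (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * cos(theta))^1.5
}

#' Sample the cosine of the Henyey-Greenstein deflection angle
#'
#' Closed-form inverse-CDF sampler for the Henyey-Greenstein phase
#' function. For `g = 0` the cosine is uniform on `[-1, 1]`; otherwise
#' \deqn{\cos\theta = \frac{1}{2g}\left[1+g^2-\left(\frac{1-g^2}{1-g+2gu}\right)^2\right].}
#'
#' @param g anisotropy factor, -1 < g < 1.
#' @param u uniform variate(s) in (0, 1); vectorised.
#' @return `cos(theta)` value(s) in `[-1, 1]`; deterministic in `(g, u)`.
#' @examples
#' sample_hg_cosine(0, 0.25)   # -0.5
#' mean(sample_hg_cosine(0.9, runif(1e4)))  # close to 0.9
#' @export
sample_hg_cosine <- function(g, u) {
  if (!is.finite(g) || abs(g) >= 1) stop("g must satisfy -1 < g < 1")
  if (any(u <= 0 | u >= 1)) stop("u must be in (0, 1)")
  if (g == 0) {
    return(2 * u - 1)
  }
  s <- (1 - g^2) / (1 - g + 2 * g * u)
  ct <- (1 + g^2 - s^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Reduced scattering coefficient
#'
#' `mu_s' = mu_s * (1 - g)`: the effective isotropic-equivalent scattering
#' rate of a forward-scattering medium.
#'
#' @param mu_s single scattering coefficient, mm^-1, >= 0; vectorised.
#' @param g anisotropy factor, -1 < g < 1.
#' @return Reduced scattering coefficient(s), mm^-1.
#' @examples
#' reduced_scattering(10, 0.9)  # 1
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(!is.finite(mu_s)) || any(mu_s < 0)) stop("mu_s must be >= 0")
  if (!is.finite(g) || abs(g) >= 1) stop("g must satisfy -1 < g < 1")
  mu_s * (1 - g)
}

#' Unpolarized Fresnel reflectance at a planar dielectric interface
#'
#' Average of the s- and p-polarized Fresnel power reflectances for a ray
#' hitting the interface from the `n_in` side with incidence cosine
#' `cos_incident`. Beyond the critical angle (when `n_in > n_out`) the
#' reflectance is 1 (total internal reflection).
#'
#' @param n_in refractive index of the incidence medium, >= 1.
#' @param n_out refractive index of the far medium, >= 1.
#' @param cos_incident cosine of the incidence angle, in `[0, 1]`;
#'   vectorised.
#' @return Reflectance fraction(s) in `[0, 1]`.
#' @examples
#' fresnel_unpolarized(1, 1.358, 1)            # normal incidence, ~0.023
#' fresnel_unpolarized(1.358, 1, cos(pi / 3))  # beyond critical angle: 1
#' @export
fresnel_unpolarized <- function(n_in, n_out, cos_incident) {
  if (!is.finite(n_in) || n_in < 1 || !is.finite(n_out) || n_out < 1) {
    stop("refractive indices must be >= 1")
  }
  if (any(cos_incident < 0 | cos_incident > 1)) {
    stop("cos_incident must be in [0, 1]")
  }
  if (n_in == n_out) {
    return(rep(0, length(cos_incident)))
  }
  ci <- cos_incident
  sin_t2 <- (n_in / n_out)^2 * (1 - ci^2)
  r <- numeric(length(ci))
  tir <- sin_t2 >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    ct <- sqrt(1 - sin_t2[ok])
    cio <- ci[ok]
    rs <- ((n_in * cio - n_out * ct) / (n_in * cio + n_out * ct))^2
    rp <- ((n_in * ct - n_out * cio) / (n_in * ct + n_out * cio))^2
    r[ok] <- 0.5 * (rs + rp)
  }
  pmin(1, pmax(0, r))
}

#' Cosine-weighted (Lambertian) hemisphere direction
#'
#' Maps two uniform variates to a unit direction with polar cosine density
#' proportional to `cos(theta)`, as leaves a maximally rough (Lambertian)
#' interface. The polar angle is `asin(sqrt(u1))` and the azimuth
#' `2*pi*u2`.
#'
#' @param u1,u2 uniform variates in (0, 1).
#' @return Numeric length 3: unit direction `(x, y, z)` with `z > 0`
#'   (pointing into the hemisphere).
#' @examples
#' lambertian_exit_direction(0.25, 0.5)  # polar angle 30 degrees
#' @export
lambertian_exit_direction <- function(u1, u2) {
  if (any(c(u1, u2) <= 0) || any(c(u1, u2) >= 1)) stop("u1, u2 must be in (0, 1)")
  sin_t <- sqrt(u1)
  cos_t <- sqrt(1 - u1)
  phi <- 2 * pi * u2
  c(sin_t * cos(phi), sin_t * sin(phi), cos_t)
}

#' Exponential free-path sample
#'
#' Inverse-CDF sample of the distance to the next photon-medium
#' interaction: `-log(u) / mu_t`.
#'
#' @param mu_t attenuation coefficient `mu_a + mu_s`, mm^-1, > 0.
#' @param u uniform variate(s) in (0, 1); vectorised.
#' @return Step length(s), mm.
#' @examples
#' sample_free_path(1, exp(-1))  # 1 mm
#' @export
sample_free_path <- function(mu_t, u) {
  if (!is.finite(mu_t) || mu_t <= 0) stop("mu_t must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must be in (0, 1)")
  -log(u) / mu_t
}
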