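# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Henyey-Greenstein cosine by brute-force inversion of the CDF built from
# quadrature of the phase function (never uses sample_hg_cosine).
hg_cosine_cdf_oracle <- function(g, u) {
  dens <- function(ct) {
    2 * pi * (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
  }
  cdf <- function(ct) integrate(dens, -1, ct, rel.tol = 1e-12)$value
  vapply(u, function(ui) {
    uniroot(function(ct) cdf(ct) - ui, c(-1 + 1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  }, numeric(1))
}

# Total diffuse reflectance of a thick (effectively semi-infinite) medium
# under normal incidence: diffusion approximation with extrapolated
# boundary, isotropic source at one transport mean free path, internal
# reflection through the Groenhuis polynomial for the effective
# reflection coefficient. Integrating the image-dipole radial solution
# over the surface gives the closed form below. The incident specular
# loss at the air-tissue boundary is removed to match a tally that is
# per incident photon and excludes the specular return.
diffusion_thick_slab_R <- function(mu_a, mu_s_prime, n_rel) {
  D <- 1 / (3 * (mu_a + mu_s_prime))
  mu_eff <- sqrt(mu_a / D)
  z0 <- 1 / (mu_a + mu_s_prime)
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + r_eff) / (1 - r_eff)
  zb <- 2 * A * D
  R_d <- 0.5 * (exp(-mu_eff * z0) + exp(-mu_eff * (z0 + 2 * zb)))
  R_sp <- ((n_rel - 1) / (n_rel + 1))^2
  (1 - R_sp) * R_d
}

# Smooth analytic (R, T) surfaces with a known closed form, used to test
# interpolation and inversion independently of the Monte Carlo engine.
# Monotone in both arguments the way physical surfaces are.
analytic_surface <- function(mu_a, mu_s_prime) {
  la <- log10(mu_a); ls <- log10(mu_s_prime)
  list(R = 0.12 + 0.25 * plogis(1.2 * ls) - 0.03 * la,
       T = 0.75 * plogis(-0.9 * ls - 0.8 * la - 1))
}

analytic_lut <- function(n_a = 12, n_s = 12,
                         mu_a_range = c(1e-3, 1), mu_s_range = c(0.1, 5)) {
  ga <- 10^seq(log10(mu_a_range[1]), log10(mu_a_range[2]), length.out = n_a)
  gs <- 10^seq(log10(mu_s_range[1]), log10(mu_s_range[2]), length.out = n_s)
  R <- outer(ga, gs, function(a, s) analytic_surface(a, s)$R)
  T_ <- outer(ga, gs, function(a, s) analytic_surface(a, s)$T)
  lut_from_surfaces(ga, gs, R, T_)
}
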