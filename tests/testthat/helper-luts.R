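# Shared, lazily built Monte Carlo fixtures. The expensive lookup tables
# are built once per test run and reused across files; everything is
# seeded, so reruns are bit-identical.

.fixtures <- new.env(parent = emptyenv())

fix_seed <- 42L

# 2 mm air-gap construct used throughout the sensitivity experiments
fix_construct <- function() sample_construct(sample_thickness = 2)

# local refined grid covering the synthetic cartilage conditions
fix_grids <- function() {
  list(mu_a = 10^seq(log10(2e-4), log10(0.5), length.out = 12),
       mu_s_prime = 10^seq(log10(0.2), log10(4), length.out = 10))
}

fix_wavelengths <- function() seq(500, 1300, length.out = 17)

# true spectra of the cartilage-like reference sample (mixture mu_a with
# canonical fractions, mu_s' = 1.5 * (lambda/500)^-1, g = 0.9, n = 1.358)
fix_truth <- function() {
  wl <- fix_wavelengths()
  list(wl = wl,
       mu_a = mixture_absorption(synthetic_component_library(wl)),
       mu_s_prime = 1.5 * (wl / 500)^-1)
}

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fix_lut <- function(g = 0.9, n_sample = 1.358, n_photons = 4e4,
                    construct = fix_construct()) {
  key <- sprintf("lut_g%s_n%s_p%g", format(g), format(n_sample), n_photons)
  cached(key, function() {
    gr <- fix_grids()
    build_lut(gr$mu_a, gr$mu_s_prime, construct, g = g, n_sample = n_sample,
              n_photons = n_photons, seed = fix_seed)
  })
}

# forward-simulated record of the reference sample (no measurement noise)
fix_record <- function(n_photons = 1e5) {
  key <- sprintf("record_p%g", n_photons)
  cached(key, function() {
    tr <- fix_truth()
    con <- fix_construct()
    R <- T_ <- numeric(length(tr$wl))
    for (k in seq_along(tr$wl)) {
      props <- optical_properties(tr$mu_a$values[k],
                                  tr$mu_s_prime[k] / (1 - 0.9),
                                  g = 0.9, n = 1.358)
      rt <- simulate_rt(props, con, n_photons, fix_seed)
      R[k] <- rt$R_diffuse
      T_[k] <- rt$T_total
    }
    measurement_record(spectrum_new(tr$wl, R, "fraction"),
                       spectrum_new(tr$wl, T_, "fraction"))
  })
}
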