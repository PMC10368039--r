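#' Configuration for a synthetic cartilage cohort
#'
#' Defines the study conditions the generator emulates: per-site cohorts
#' of cylindrical cartilage plugs (14 mm drill-bit diameter, thickness
#' 0.5-3 mm), constituent-mixture absorption with jittered volume
#' fractions, power-law reduced scattering, bottom-face volume
#' irregularity of up to 18%, and multiplicative measurement noise.
#'
#' @param sites character vector of site labels.
#' @param n_per_site samples per site.
#' @param thickness_range cylinder thickness range, mm.
#' @param diameter cylinder diameter, mm.
#' @param volume_irregularity_max maximal relative volume deficit (the
#'   bottom face carries an oblique planar cut removing up to this
#'   fraction of the nominal cylinder volume).
#' @param fraction_jitter_sd SD of the additive jitter on the volume
#'   fractions (renormalized; negative draws are resampled).
#' @param scatter_amplitude_range range of `a` in
#'   `mu_s'(lambda) = a * (lambda/500)^(-b)`, mm^-1.
#' @param scatter_power_range range of the scattering power `b`.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise on R and T.
#' @param g_true,n_true true anisotropy factor and refractive index.
#' @param gap `"air"` or `"water"` lateral gap medium.
#' @param wavelengths measurement wavelength grid, nm.
#' @param seed root seed; all per-sample randomness is split from it.
#' @return A `SyntheticCohortConfig` list.
#' @export
cohort_config <- function(sites = c("FL", "FM", "PL", "PM", "TL", "TM"),
                          n_per_site = 2,
                          thickness_range = c(0.5, 3),
                          diameter = 14,
                          volume_irregularity_max = 0.18,
                          fraction_jitter_sd = 0.02,
                          scatter_amplitude_range = c(1.0, 2.5),
                          scatter_power_range = c(0.5, 1.5),
                          noise_cv = 0.02,
                          g_true = 0.9,
                          n_true = 1.358,
                          gap = c("air", "water"),
                          wavelengths = seq(400, 1400, by = 50),
                          seed = 1) {
  gap <- match.arg(gap)
  stopifnot(n_per_site >= 1, diff(thickness_range) >= 0, diameter > 0,
            volume_irregularity_max >= 0, volume_irregularity_max < 1,
            fraction_jitter_sd >= 0, noise_cv >= 0,
            diff(scatter_amplitude_range) >= 0,
            diff(scatter_power_range) >= 0,
            abs(g_true) < 1, n_true >= 1)
  structure(list(sites = sites, n_per_site = n_per_site,
                 thickness_range = thickness_range, diameter = diameter,
                 volume_irregularity_max = volume_irregularity_max,
                 fraction_jitter_sd = fraction_jitter_sd,
                 scatter_amplitude_range = scatter_amplitude_range,
                 scatter_power_range = scatter_power_range,
                 noise_cv = noise_cv, g_true = g_true, n_true = n_true,
                 gap = gap, wavelengths = as.numeric(wavelengths),
                 seed = seed),
            class = "SyntheticCohortConfig")
}

#' True optical-property spectra of one synthetic sample
#'
#' Absorption is the constituent mixture with volume fractions jittered
#' around (0.68, 0.30, 0.01, 0.01) (additive Gaussian jitter, negative
#' draws resampled, renormalized to sum 1); reduced scattering follows
#' the power law `a * (lambda/500)^(-b)` with `a`, `b` drawn uniformly
#' from the configured ranges.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for this sample's draws.
#' @return list with `mu_a`, `mu_s_prime` (`Spectrum`s, mm^-1),
#'   `fractions`, `a`, `b`, `g`, `n`.
#' @export
generate_true_spectra <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  set.seed(derive_seed(seed, 101))
  base <- c(water = 0.68, collagen = 0.30, elastin = 0.01, lipid = 0.01)
  repeat {
    fr <- base + stats::rnorm(4, 0, config$fraction_jitter_sd)
    if (all(fr >= 0)) break
  }
  fr <- fr / sum(fr)
  a <- runif(1, config$scatter_amplitude_range[1L],
             config$scatter_amplitude_range[2L])
  b <- runif(1, config$scatter_power_range[1L], config$scatter_power_range[2L])
  lib <- synthetic_component_library(config$wavelengths, fractions = fr)
  mu_a <- mixture_absorption(lib)
  mu_s_prime <- spectrum_new(config$wavelengths,
                             a * (config$wavelengths / 500)^(-b), "mm^-1")
  list(mu_a = mu_a, mu_s_prime = mu_s_prime, fractions = fr, a = a, b = b,
       g = config$g_true, n = config$n_true)
}

#' Geometry of one synthetic sample
#'
#' Draws the cylinder thickness uniformly from the configured range and a
#' relative volume deficit uniformly from
#' `[-volume_irregularity_max, 0]`, realized as an oblique planar cut of
#' the bottom face (cut depth `2 * |deficit| * thickness`), so the
#' geometry itself — not just the volume bookkeeping — is irregular.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for this sample's draws.
#' @return list with `construct` ([sample_construct()]),
#'   `nominal_volume`, `true_volume` (mm^3).
#' @export
generate_geometry <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  set.seed(derive_seed(seed, 202))
  thick <- runif(1, config$thickness_range[1L], config$thickness_range[2L])
  deficit <- runif(1, -config$volume_irregularity_max, 0)
  con <- sample_construct(sample_radius = config$diameter / 2,
                          sample_thickness = thick,
                          gap_medium = gap_medium(config$gap),
                          cut_depth = -2 * deficit * thick)
  list(construct = con,
       nominal_volume = nominal_volume(con),
       true_volume = true_volume(con))
}

#' Forward-simulate the noisy measurement of one synthetic sample
#'
#' Runs the Monte Carlo forward model at every wavelength of the sample's
#' property spectra (water-gap constructs pick up the water absorption at
#' each wavelength) and applies independent multiplicative log-normal
#' noise with coefficient of variation `noise_cv` to R and T.
#'
#' @param truth output of [generate_true_spectra()].
#' @param construct the sample's [sample_construct()].
#' @param config the [cohort_config()] (noise level, gap medium).
#' @param n_photons photons per wavelength.
#' @param seed integer seed driving the photon transport.
#' @param noise_seed integer seed driving the multiplicative noise
#'   (defaults to a stream split from `seed`).
#' @return A [measurement_record()] with simulation metadata.
#' @export
simulate_measurement <- function(truth, construct, config,
                                 n_photons = 2e4, seed = config$seed,
                                 noise_seed = derive_seed(seed, 303)) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  wl <- truth$mu_a$wavelengths
  g <- truth$g
  water_mu_a <- if (config$gap == "water") {
    synthetic_component_library(wl)$spectra$water$values
  } else NULL
  R <- T_ <- numeric(length(wl))
  for (k in seq_along(wl)) {
    con <- construct
    if (!is.null(water_mu_a)) con$gap_medium$mu_a <- water_mu_a[k]
    props <- optical_properties(mu_a = truth$mu_a$values[k],
                                mu_s = truth$mu_s_prime$values[k] / (1 - g),
                                g = g, n = truth$n)
    rt <- simulate_rt(props, con, n_photons, seed)
    R[k] <- rt$R_diffuse
    T_[k] <- rt$T_total
  }
  if (config$noise_cv > 0) {
    set.seed(noise_seed)
    sig <- sqrt(log(1 + config$noise_cv^2))
    R <- R * exp(stats::rnorm(length(wl), 0, sig) - sig^2 / 2)
    T_ <- T_ * exp(stats::rnorm(length(wl), 0, sig) - sig^2 / 2)
  }
  measurement_record(spectrum_new(wl, pmin(1, R), "fraction"),
                     spectrum_new(wl, pmin(1, T_), "fraction"),
                     meta = list(n_photons = n_photons, seed = seed,
                                 noise_cv = config$noise_cv))
}

#' Generate a full synthetic cohort
#'
#' Draws every sample of every site: true spectra, irregular geometry and
#' a forward-simulated noisy measurement record. Site labels influence
#' nothing but the labels themselves.
#'
#' @param config a [cohort_config()].
#' @param n_photons photons per wavelength and sample.
#' @return list of `SyntheticSample` lists (`site`, `truth`, `construct`,
#'   `nominal_volume`, `true_volume`, `record`, `seed`).
#' @export
generate_cohort <- function(config, n_photons = 2e4) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  samples <- list()
  k <- 0L
  for (site in config$sites) {
    for (i in seq_len(config$n_per_site)) {
      k <- k + 1L
      s_seed <- derive_seed(config$seed, k)
      truth <- generate_true_spectra(config, seed = s_seed)
      geo <- generate_geometry(config, seed = s_seed)
      rec <- simulate_measurement(truth, geo$construct, config,
                                  n_photons = n_photons, seed = s_seed)
      rec$site <- site
      samples[[k]] <- structure(
        list(site = site, truth = truth, construct = geo$construct,
             nominal_volume = geo$nominal_volume,
             true_volume = geo$true_volume, record = rec, seed = s_seed),
        class = "SyntheticSample")
    }
  }
  samples
}

#' Write a cohort manifest as delimited text
#'
#' @param cohort list of `SyntheticSample`s from [generate_cohort()].
#' @param path output path (tab-separated).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_manifest <- function(cohort, path) {
  df <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    data.frame(sample_id = i, site = s$site,
               thickness_mm = s$construct$sample_thickness,
               nominal_volume_mm3 = s$nominal_volume,
               true_volume_mm3 = s$true_volume,
               seed = s$seed)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
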