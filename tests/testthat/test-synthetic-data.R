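test_that("true spectra follow the mixture model and power-law scattering", {
  cfg <- cohort_config(fraction_jitter_sd = 0, scatter_amplitude_range = c(1.5, 1.5),
                       scatter_power_range = c(1, 1), seed = 3)
  tr <- generate_true_spectra(cfg)
  ref <- mixture_absorption(synthetic_component_library(cfg$wavelengths))
  expect_equal(tr$mu_a$values, ref$values, tolerance = 1e-12)
  expect_equal(tr$mu_s_prime$values, 1.5 * (cfg$wavelengths / 500)^-1,
               tolerance = 1e-12)
  expect_equal(tr$n, 1.358)   # default refractive index
  expect_equal(tr$g, 0.9)
  # determinism
  tr2 <- generate_true_spectra(cfg)
  expect_identical(tr, tr2)
})

test_that("jittered volume fractions stay nonnegative and sum to one", {
  cfg <- cohort_config(fraction_jitter_sd = 0.05,
                       wavelengths = c(500, 600, 700), seed = 8)
  sums <- vapply(1:200, function(k) {
    tr <- generate_true_spectra(cfg, seed = k)
    expect_true(all(tr$fractions >= 0))
    sum(tr$fractions)
  }, numeric(1))
  expect_equal(sums, rep(1, 200), tolerance = 1e-12)
})

test_that("geometry honors the drill-bit diameter and irregularity bound", {
  cfg0 <- cohort_config(volume_irregularity_max = 0, seed = 5)
  g0 <- generate_geometry(cfg0)
  expect_equal(g0$construct$sample_radius, 7)   # 14 mm plug
  expect_equal(g0$true_volume, g0$nominal_volume)
  expect_equal(g0$nominal_volume,
               pi * 7^2 * g0$construct$sample_thickness)

  cfg <- cohort_config(volume_irregularity_max = 0.18, seed = 5)
  deficits <- vapply(1:500, function(k) {
    g <- generate_geometry(cfg, seed = k)
    1 - g$true_volume / g$nominal_volume
  }, numeric(1))
  expect_true(all(deficits >= 0 & deficits <= 0.18))
  expect_gt(max(deficits), 0.10)   # the bound is actually explored
})

test_that("measurement simulation is deterministic and noise-calibrated", {
  cfg <- cohort_config(wavelengths = c(700, 900), noise_cv = 0,
                       thickness_range = c(2, 2),
                       volume_irregularity_max = 0, seed = 12)
  tr <- generate_true_spectra(cfg)
  geo <- generate_geometry(cfg)
  rec0 <- simulate_measurement(tr, geo$construct, cfg, n_photons = 2000)
  # noise_cv = 0 equals the raw forward tallies with the same seed
  p1 <- optical_properties(tr$mu_a$values[1], tr$mu_s_prime$values[1] / 0.1,
                           g = 0.9, n = 1.358)
  rt1 <- simulate_rt(p1, geo$construct, 2000, cfg$seed)
  expect_identical(rec0$R$values[1], rt1$R_diffuse)
  # same config and seed twice: identical records
  rec0b <- simulate_measurement(tr, geo$construct, cfg, n_photons = 2000)
  expect_identical(rec0$R$values, rec0b$R$values)

  # multiplicative noise calibration at one wavelength: the empirical CV
  # over independent noise draws matches noise_cv (transport fixed)
  cfg2 <- cohort_config(wavelengths = 800, noise_cv = 0.02,
                        thickness_range = c(2, 2),
                        volume_irregularity_max = 0, seed = 12)
  tr2 <- generate_true_spectra(cfg2)
  geo2 <- generate_geometry(cfg2)
  Rs <- vapply(1:200, function(k) {
    simulate_measurement(tr2, geo2$construct, cfg2, n_photons = 500,
                         noise_seed = k)$R$values
  }, numeric(1))
  cv <- sd(Rs) / mean(Rs)
  expect_gt(cv, 0.015)
  expect_lt(cv, 0.025)
})

test_that("site labels are inert in cohort generation", {
  base <- list(n_per_site = 1, wavelengths = c(700, 900), noise_cv = 0.01,
               seed = 21)
  a <- generate_cohort(do.call(cohort_config, c(base, list(sites = c("FL", "TM")))),
                       n_photons = 500)
  b <- generate_cohort(do.call(cohort_config, c(base, list(sites = c("TM", "FL")))),
                       n_photons = 500)
  for (k in 1:2) {
    expect_identical(a[[k]]$truth, b[[k]]$truth)
    expect_identical(a[[k]]$record$R$values, b[[k]]$record$R$values)
  }
  expect_identical(a[[1]]$site, b[[2]]$site)
})

test_that("a low-noise cohort is identifiable end to end", {
  # fixed 2 mm geometry so one matched lookup table serves all samples
  cfg <- cohort_config(sites = "FL", n_per_site = 3,
                       thickness_range = c(2, 2),
                       volume_irregularity_max = 0,
                       noise_cv = 0.01,
                       wavelengths = seq(500, 1300, length.out = 9),
                       seed = 31)
  cohort <- generate_cohort(cfg, n_photons = 1e4)
  lut <- fix_lut(g = 0.9, n_photons = 4e4)
  err_a <- err_s <- c()
  for (s in cohort) {
    est <- invert_spectrum(s$record, lut)
    err_a <- c(err_a, abs(est$mu_a$values / s$truth$mu_a$values - 1))
    err_s <- c(err_s, abs(est$mu_s_prime$values / s$truth$mu_s_prime$values - 1))
  }
  expect_lt(median(err_s), 0.05)
  expect_lt(median(err_a), 0.15)
})

test_that("cohort manifests list every sample with its volumes", {
  cfg <- cohort_config(sites = c("FL", "PM"), n_per_site = 1,
                       wavelengths = c(700, 900), seed = 2)
  cohort <- generate_cohort(cfg, n_photons = 200)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_cohort_manifest(cohort, path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$site, c("FL", "PM"))
  expect_true(all(df$true_volume_mm3 <= df$nominal_volume_mm3))
})
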