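# Lookup-table interpolation and inversion, tested on analytic surfaces
# with known closed form wherever the Monte Carlo engine is not the point.

test_that("lookup-table constructor validates grids and surfaces", {
  ok <- analytic_lut()
  expect_s3_class(ok, "LookupTable")
  g <- ok$mu_a_grid; s <- ok$mu_s_prime_grid
  expect_error(lut_from_surfaces(g[1:3], s, ok$R_surface, ok$T_surface),
               "4 nodes")
  expect_error(lut_from_surfaces(-g, s, ok$R_surface, ok$T_surface))
  bad <- ok$R_surface; bad[1, 1] <- 1.5
  expect_error(lut_from_surfaces(g, s, bad, ok$T_surface), "fractions")
  expect_error(lut_from_surfaces(g, s, ok$R_surface[, 1:5], ok$T_surface),
               "dimensions")
})

test_that("bicubic interpolation is exact at nodes and accurate off-grid", {
  lut <- analytic_lut(14, 14)
  # node exactness
  q <- lut_interp(lut, lut$mu_a_grid[5], lut$mu_s_prime_grid[8])
  expect_equal(q$R, lut$R_surface[5, 8], tolerance = 1e-12)
  expect_equal(q$T, lut$T_surface[5, 8], tolerance = 1e-12)
  # off-grid error against the closed form, interior points
  set.seed(11)
  for (i in 1:25) {
    mu_a <- 10^runif(1, log10(2e-3), log10(0.5))
    mu_s <- 10^runif(1, log10(0.2), log10(3))
    truth <- analytic_surface(mu_a, mu_s)
    q <- lut_interp(lut, mu_a, mu_s)
    expect_lt(abs(q$R - truth$R), 1e-4)
    expect_lt(abs(q$T - truth$T), 1e-4)
  }
})

test_that("inversion recovers node and off-node values on an analytic surface", {
  lut <- analytic_lut(12, 12)
  # round trip at a node
  inv <- invert_rt(lut$R_surface[6, 7], lut$T_surface[6, 7], lut)
  expect_lt(abs(inv$mu_a_hat / lut$mu_a_grid[6] - 1), 1e-6)
  expect_lt(abs(inv$mu_s_prime_hat / lut$mu_s_prime_grid[7] - 1), 1e-6)
  expect_false(inv$on_boundary)
  expect_true(inv$converged)
  # off-node closed-form pair
  truth <- analytic_surface(0.05, 1.3)
  inv <- invert_rt(truth$R, truth$T, lut)
  expect_lt(abs(inv$mu_a_hat / 0.05 - 1), 1e-4)
  expect_lt(abs(inv$mu_s_prime_hat / 1.3 - 1), 1e-4)
})

test_that("degenerate and unphysical measurement pairs are flagged", {
  lut <- analytic_lut()
  inv <- invert_rt(0, 0, lut)
  expect_true(inv$on_boundary)
  expect_warning(invert_rt(0.7, 0.7, lut), "R_meas \\+ T_meas")
  expect_error(invert_rt(NA_real_, 0.1, lut), "finite")
  expect_error(invert_rt(1.2, 0.1, lut), "0, 1")
})

test_that("inversion is monotone-consistent in T on a noise-free surface", {
  lut <- analytic_lut(12, 12)
  R0 <- 0.35
  T_vals <- seq(0.10, 0.30, by = 0.05)
  mu_a_hats <- vapply(T_vals, function(Tm) {
    invert_rt(R0, Tm, lut)$mu_a_hat
  }, numeric(1))
  # raising measured T at fixed R never raises the absorption estimate
  expect_true(all(diff(mu_a_hats) <= 1e-9))
})

test_that("Monte Carlo lookup tables are deterministic and node-consistent", {
  con <- sample_construct(sample_thickness = 2)
  ga <- 10^seq(-3, -0.5, length.out = 4)
  gs <- 10^seq(-0.5, 0.5, length.out = 4)
  lut1 <- build_lut(ga, gs, con, g = 0.9, n_photons = 500, seed = 77)
  lut2 <- build_lut(ga, gs, con, g = 0.9, n_photons = 500, seed = 77)
  expect_identical(lut1$R_surface, lut2$R_surface)
  expect_identical(lut1$T_surface, lut2$T_surface)
  # any node equals a direct forward call with the same seed
  p <- optical_properties(ga[2], gs[3] / (1 - 0.9), g = 0.9, n = 1.358)
  direct <- simulate_rt(p, con, 500, seed = 77)
  expect_identical(lut1$R_surface[2, 3], direct$R_diffuse)
  expect_identical(lut1$T_surface[2, 3], direct$T_total)
  expect_error(build_lut(-ga, gs, con), "nonnegative")
})

test_that("spectrum inversion maps node-exact records to node-exact spectra", {
  lut <- analytic_lut(12, 12)
  idx_a <- c(3, 5, 8); idx_s <- c(4, 6, 9)
  wl <- c(500, 700, 900)
  rec <- measurement_record(
    spectrum_new(wl, lut$R_surface[cbind(idx_a, idx_s)], "fraction"),
    spectrum_new(wl, lut$T_surface[cbind(idx_a, idx_s)], "fraction"))
  est <- invert_spectrum(rec, lut)
  expect_equal(est$mu_a$values, lut$mu_a_grid[idx_a], tolerance = 1e-5)
  expect_equal(est$mu_s_prime$values, lut$mu_s_prime_grid[idx_s],
               tolerance = 1e-5)
  expect_false(any(est$flags$on_boundary))

  # empty record inverts to empty spectra without error
  empty <- measurement_record(spectrum_new(numeric(0), numeric(0), "fraction"),
                              spectrum_new(numeric(0), numeric(0), "fraction"))
  out <- invert_spectrum(empty, lut)
  expect_equal(length(out$mu_a), 0L)

  # per-wavelength table set: a missing wavelength is named
  luts <- list("500" = lut)
  expect_error(invert_spectrum(rec, luts), "700")
})

test_that("substitution calibration scales and clips raw counts", {
  expect_equal(calibrate_substitution(500, 1000, 0.99)$value, 0.495)
  expect_equal(calibrate_substitution(1000, 1000, 0.99)$value, 0.99)
  expect_false(calibrate_substitution(1000, 1000, 0.99)$clipped)
  over <- calibrate_substitution(2000, 1000, 0.99)
  expect_equal(over$value, 1)     # 1.98 is unphysical for a fraction
  expect_true(over$clipped)
  expect_error(calibrate_substitution(500, 0, 0.99), "raw_reference")
  expect_error(calibrate_substitution(500, 1000, 1.2), "rho_reference")
})

test_that("lookup tables persist losslessly", {
  lut <- analytic_lut(6, 6)
  path <- withr::local_tempfile(fileext = ".rds")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_identical(back, lut)
})
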