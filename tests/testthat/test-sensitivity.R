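# Sensitivity machinery. Small dedicated lookup tables are built here at
# modest photon counts; the full-scale experiments live in the
# acceptance suite.

test_that("normality gate passes Gaussians and rejects exponentials", {
  pass_g <- vapply(1:100, function(i) {
    set.seed(i)
    normality_check(rnorm(500))$pass
  }, logical(1))
  expect_gte(mean(pass_g), 0.90)
  pass_e <- vapply(1:100, function(i) {
    set.seed(i)
    normality_check(rexp(500))$pass
  }, logical(1))
  expect_gte(mean(!pass_e), 0.90)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("volume correlation picks its method and matches a rank oracle", {
  # perfectly linear pair
  res <- volume_correlation(1:20, 2 * (1:20) + 3)
  expect_equal(res$phi, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  # rank-based brute force for a small permutation pair: with rank data,
  # Pearson and Spearman coincide, so the choice of method cannot matter
  x <- c(1, 2, 3, 4, 5); y <- c(5, 1, 4, 2, 3)
  brute <- 1 - 6 * sum((rank(x) - rank(y))^2) / (5 * (5^2 - 1))
  expect_equal(volume_correlation(x, y)$phi, brute, tolerance = 1e-12)
  # errors
  expect_error(volume_correlation(1:5, rep(2, 5)), "zero variance")
  expect_error(volume_correlation(1:2, 1:2), "at least 3")
})

test_that("null volume correlations are small with uniform p-values", {
  set.seed(99)
  phis <- ps <- numeric(1000)
  for (i in 1:1000) {
    x <- rnorm(60); y <- rnorm(60)
    r <- volume_correlation(x, y)
    phis[i] <- r$phi; ps[i] <- r$p_value
  }
  expect_lt(median(abs(phis)), 0.15)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("g-sensitivity is zero for identical tables and errors on missing levels", {
  lut <- analytic_lut(10, 10)
  wl <- c(600, 800, 1000)
  rec <- measurement_record(
    spectrum_new(wl, lut$R_surface[cbind(4:6, 5:7)], "fraction"),
    spectrum_new(wl, lut$T_surface[cbind(4:6, 5:7)], "fraction"))
  sens <- g_sensitivity(rec, list("0.8" = lut, "0.9" = lut, "0.99" = lut))
  for (lev in c("0.8", "0.99")) {
    expect_equal(sens[[lev]]$mu_a_report$rel_diff_median, rep(0, 3),
                 tolerance = 1e-6)
    expect_equal(sens[[lev]]$mu_s_report$rel_diff_median, rep(0, 3),
                 tolerance = 1e-6)
    expect_equal(sens[[lev]]$mu_a_correlation$phi, 1, tolerance = 1e-6)
  }
  expect_error(g_sensitivity(rec, list("0.8" = lut), baseline = "0.9"),
               "baseline")
})

test_that("g-sensitivity shrinks as the tested level approaches the truth", {
  con <- fix_construct()
  ga <- 10^seq(log10(2e-3), log10(0.3), length.out = 6)
  gs <- 10^seq(log10(0.5), log10(2.5), length.out = 6)
  luts <- lapply(c(0.8, 0.85, 0.9), function(g) {
    build_lut(ga, gs, con, g = g, n_photons = 1e4, seed = fix_seed)
  })
  names(luts) <- c("0.8", "0.85", "0.9")
  wl <- seq(600, 1000, by = 100)
  R <- T_ <- numeric(length(wl))
  mu_a_true <- c(0.004, 0.003, 0.003, 0.01, 0.03)
  mu_s_true <- 1.5 * (wl / 500)^-1
  for (k in seq_along(wl)) {
    p <- optical_properties(mu_a_true[k], mu_s_true[k] / 0.1, g = 0.9,
                            n = 1.358)
    rt <- simulate_rt(p, con, 4e4, fix_seed)
    R[k] <- rt$R_diffuse; T_[k] <- rt$T_total
  }
  rec <- measurement_record(spectrum_new(wl, R, "fraction"),
                            spectrum_new(wl, T_, "fraction"))
  sens <- g_sensitivity(rec, luts, baseline = "0.9")
  med <- function(lev, what) {
    median(abs(sens[[lev]][[what]]$rel_diff_median))
  }
  # nearer g level, smaller deviation (common random numbers throughout)
  expect_lte(med("0.85", "mu_s_report"), med("0.8", "mu_s_report"))
  # reduced scattering is the more robust property
  expect_lt(med("0.8", "mu_s_report"), med("0.8", "mu_a_report"))
})

test_that("an air-gap assumption inflates recovered absorption for a water-gap sample", {
  wl <- seq(500, 1100, length.out = 6)
  lib <- synthetic_component_library(wl)
  mu_a_th <- mixture_absorption(lib)
  con_air <- fix_construct()
  con_wat <- sample_construct(sample_thickness = 2,
                              gap_medium = gap_medium("water"))
  ga <- 10^seq(log10(5e-4), log10(0.5), length.out = 8)
  gs <- 10^seq(log10(0.3), log10(4), length.out = 8)
  lut_air <- build_lut(ga, gs, con_air, g = 0.9, n_photons = 8e3,
                       seed = fix_seed)
  lut_wat <- build_lut(ga, gs, con_wat, g = 0.9, n_photons = 8e3,
                       seed = fix_seed)
  # truth: water in the gap
  R <- T_ <- numeric(length(wl))
  for (k in seq_along(wl)) {
    cw <- con_wat
    cw$gap_medium$mu_a <- lib$spectra$water$values[k]
    p <- optical_properties(mu_a_th$values[k], 1.5 * (wl[k] / 500)^-1 / 0.1,
                            g = 0.9, n = 1.358)
    rt <- simulate_rt(p, cw, 2e4, fix_seed)
    R[k] <- rt$R_diffuse; T_[k] <- rt$T_total
  }
  rec <- measurement_record(spectrum_new(wl, R, "fraction"),
                            spectrum_new(wl, T_, "fraction"))
  ms <- medium_sensitivity(rec, lut_air, lut_wat, mu_a_th)
  # assuming air for a water-gap sample overestimates mu_a (500-1135 nm)
  expect_gt(median(ms$air$rel_diff_median), 0)
  # identical tables give numerically identical reports
  ms2 <- medium_sensitivity(rec, lut_air, lut_air, mu_a_th)
  expect_identical(ms2$air$rel_diff_median, ms2$water$rel_diff_median)
  expect_identical(ms2$air$rel_diff_q1, ms2$water$rel_diff_q1)
  expect_identical(ms2$air$rel_diff_q3, ms2$water$rel_diff_q3)
})

test_that("sensitivity reports keep ordered quartile bands and export cleanly", {
  wl <- c(500, 600)
  sp <- lapply(c(-3, 1, 5), function(k) {
    spectrum_new(wl, c(k, k), "percent")
  })
  rep_ <- opticart:::sensitivity_report(sp, "medium", c("air", "theoretical"))
  expect_true(all(rep_$rel_diff_q1 <= rep_$rel_diff_median))
  expect_true(all(rep_$rel_diff_median <= rep_$rel_diff_q3))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_sensitivity_report(rep_, path)
  expect_equal(read.table(path, header = TRUE, sep = "\t"), df,
               tolerance = 1e-12)
})

test_that("the roughness experiment is null when both arms are smooth", {
  lut <- analytic_lut(10, 10)
  con <- fix_construct()
  wl <- c(600, 800)
  props <- lapply(c(0.01, 0.02), function(mua) {
    optical_properties(mua, 15, g = 0.9, n = 1.358)
  })
  con2 <- con
  res <- roughness_experiment(props, wl, con2, lut, n_photons = 3000,
                              seed = fix_seed)
  # with the flag honored, arms differ; force both smooth via the helper:
  smooth_only <- function() {
    rt <- lapply(props, simulate_rt, construct = con, n_photons = 3000,
                 seed = fix_seed)
    rec <- measurement_record(
      spectrum_new(wl, vapply(rt, `[[`, numeric(1), "R_diffuse"), "fraction"),
      spectrum_new(wl, vapply(rt, `[[`, numeric(1), "T_total"), "fraction"))
    invert_spectrum(rec, lut)
  }
  a <- smooth_only(); b <- smooth_only()
  expect_equal(relative_difference(a$mu_a, b$mu_a)$values, c(0, 0))
  # the Lambertian arm genuinely moves the recovered properties
  expect_true(any(abs(res$mu_a_change$values) > 0))
})
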