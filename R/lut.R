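#' Construct a lookup table from explicit surfaces
#'
#' Low-level constructor pairing `(mu_a, mu_s')` grids with forward-model
#' reflectance/transmittance surfaces. [build_lut()] fills the surfaces by
#' Monte Carlo; this constructor also accepts analytic surfaces, which is
#' useful for testing the inversion machinery on noise-free closed forms.
#'
#' @param mu_a_grid,mu_s_prime_grid strictly increasing positive grids,
#'   mm^-1, at least 4 nodes each.
#' @param R_surface,T_surface matrices `[i, j]` of fractions: node
#'   `(mu_a_grid[i], mu_s_prime_grid[j])`.
#' @param se_R,se_T matrices of Monte Carlo standard errors (0 for
#'   analytic surfaces).
#' @param g,n_sample anisotropy factor and sample refractive index the
#'   surfaces were computed for.
#' @param construct the [sample_construct()] geometry, or `NULL`.
#' @param n_photons,seed Monte Carlo provenance (0 for analytic surfaces).
#' @return A `LookupTable` object.
#' @export
lut_from_surfaces <- function(mu_a_grid, mu_s_prime_grid, R_surface, T_surface,
                              se_R = NULL, se_T = NULL,
                              g = 0.9, n_sample = 1.358, construct = NULL,
                              n_photons = 0, seed = 0) {
  mu_a_grid <- as.numeric(mu_a_grid)
  mu_s_prime_grid <- as.numeric(mu_s_prime_grid)
  if (length(mu_a_grid) < 4L || length(mu_s_prime_grid) < 4L) {
    stop("grids must have at least 4 nodes each")
  }
  if (any(mu_a_grid < 0) || any(mu_s_prime_grid < 0)) {
    stop("grids must be nonnegative")
  }
  if (any(diff(mu_a_grid) <= 0) || any(diff(mu_s_prime_grid) <= 0)) {
    stop("grids must be strictly increasing")
  }
  dims <- c(length(mu_a_grid), length(mu_s_prime_grid))
  for (m in list(R_surface, T_surface)) {
    if (!is.matrix(m) || !all(dim(m) == dims)) {
      stop("surface dimensions must match the grids")
    }
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
      stop("surfaces must be finite fractions in [0, 1]")
    }
  }
  if (is.null(se_R)) se_R <- matrix(0, dims[1L], dims[2L])
  if (is.null(se_T)) se_T <- matrix(0, dims[1L], dims[2L])
  structure(list(mu_a_grid = mu_a_grid, mu_s_prime_grid = mu_s_prime_grid,
                 R_surface = R_surface, T_surface = T_surface,
                 se_R = se_R, se_T = se_T,
                 g = g, n_sample = n_sample, construct = construct,
                 n_photons = n_photons, seed = seed),
            class = "LookupTable")
}

#' Default lookup-table grids
#'
#' Log-spaced 20-node grids spanning the literature range of cartilage
#' optical properties: `mu_a` over `[1e-4, 5]` mm^-1 and `mu_s'` over
#' `[0.05, 10]` mm^-1.
#'
#' @param n_mu_a,n_mu_s number of nodes per axis.
#' @param mu_a_range,mu_s_range axis ranges, mm^-1.
#' @return list with `mu_a` and `mu_s_prime` grid vectors.
#' @export
default_grids <- function(n_mu_a = 20, n_mu_s = 20,
                          mu_a_range = c(1e-4, 5), mu_s_range = c(0.05, 10)) {
  list(mu_a = 10^seq(log10(mu_a_range[1L]), log10(mu_a_range[2L]),
                     length.out = n_mu_a),
       mu_s_prime = 10^seq(log10(mu_s_range[1L]), log10(mu_s_range[2L]),
                           length.out = n_mu_s))
}

#' Build a forward-model lookup table by Monte Carlo
#'
#' Simulates reflectance and transmittance at every node of a
#' `(mu_a, mu_s')` grid for a fixed geometry, anisotropy factor and sample
#' refractive index. Each node uses the single scattering coefficient
#' `mu_s = mu_s' / (1 - g)` and the *same* seed, so every node (and every
#' table rebuilt with the same seed at another `g` or `n`) sees common
#' random numbers: surface differences across nodes and arms are not
#' contaminated by independent Monte Carlo noise.
#'
#' @inheritParams lut_from_surfaces
#' @param construct a [sample_construct()] geometry.
#' @param n_photons photons per node.
#' @param seed integer seed shared by all nodes.
#' @return A `LookupTable`.
#' @export
build_lut <- function(mu_a_grid, mu_s_prime_grid, construct,
                      g = 0.9, n_sample = 1.358,
                      n_photons = 2e4, seed = 1) {
  stopifnot(inherits(construct, "SampleConstruct"))
  if (any(mu_a_grid < 0) || any(mu_s_prime_grid < 0)) {
    stop("grids must be nonnegative")
  }
  na <- length(mu_a_grid); ns <- length(mu_s_prime_grid)
  R <- T_ <- sR <- sT <- matrix(NA_real_, na, ns)
  for (j in seq_len(ns)) {
    for (i in seq_len(na)) {
      props <- optical_properties(mu_a = mu_a_grid[i],
                                  mu_s = mu_s_prime_grid[j] / (1 - g),
                                  g = g, n = n_sample)
      res <- simulate_rt(props, construct, n_photons, seed)
      R[i, j] <- res$R_diffuse
      T_[i, j] <- res$T_total
      sR[i, j] <- res$se_R
      sT[i, j] <- res$se_T
    }
  }
  lut_from_surfaces(mu_a_grid, mu_s_prime_grid, R, T_, sR, sT,
                    g = g, n_sample = n_sample, construct = construct,
                    n_photons = n_photons, seed = seed)
}

#' @export
print.LookupTable <- function(x, ...) {
  cat(sprintf(
    "<LookupTable> %dx%d nodes, mu_a [%g, %g], mu_s' [%g, %g] mm^-1, g=%g, n=%g, %g photons/node, seed %s\n",
    length(x$mu_a_grid), length(x$mu_s_prime_grid),
    min(x$mu_a_grid), max(x$mu_a_grid),
    min(x$mu_s_prime_grid), max(x$mu_s_prime_grid),
    x$g, x$n_sample, x$n_photons, format(x$seed)))
  invisible(x)
}

# separable cubic-spline ("bicubic") interpolation of one surface on
# log10-parameter axes; la/ls are log10(mu_a), log10(mu_s')
interp_surface <- function(la_grid, ls_grid, surface, la, ls) {
  col_vals <- vapply(seq_along(la_grid), function(i) {
    spline(ls_grid, surface[i, ], xout = ls, method = "natural")$y
  }, numeric(1L))
  spline(la_grid, col_vals, xout = la, method = "natural")$y
}

#' Interpolate lookup-table surfaces at arbitrary (mu_a, mu_s')
#'
#' Separable cubic-spline (bicubic) interpolation on log10-parameter axes.
#'
#' @param lut a `LookupTable`.
#' @param mu_a,mu_s_prime query values, mm^-1, inside the grid hull.
#' @return list with interpolated `R` and `T` fractions.
#' @export
lut_interp <- function(lut, mu_a, mu_s_prime) {
  stopifnot(inherits(lut, "LookupTable"))
  if (mu_a <= 0 || mu_s_prime <= 0) stop("query must be positive")
  la_grid <- log10(lut$mu_a_grid); ls_grid <- log10(lut$mu_s_prime_grid)
  la <- log10(mu_a); ls <- log10(mu_s_prime)
  list(R = interp_surface(la_grid, ls_grid, lut$R_surface, la, ls),
       T = interp_surface(la_grid, ls_grid, lut$T_surface, la, ls))
}

#' Invert one (R, T) pair to (mu_a, mu_s')
#'
#' Minimizes the standard-error-weighted squared residual
#' `((R(mu_a, mu_s') - R_meas)/sigma_R)^2 + ((T(...) - T_meas)/sigma_T)^2`
#' over the bicubic-interpolated lookup-table surfaces, searching in
#' log10-parameter space by Nelder-Mead from the best grid node. The
#' residual weights are the Monte Carlo standard errors at the nearest
#' node, floored at `se_floor`.
#'
#' @param R_meas,T_meas measured fractions in `[0, 1]`.
#' @param lut a `LookupTable`.
#' @param se_floor lower bound on the residual weights.
#' @return An `InversionResult`: `mu_a_hat`, `mu_s_prime_hat`, `residual`,
#'   `converged`, `on_boundary`.
#' @export
invert_rt <- function(R_meas, T_meas, lut, se_floor = 1e-4) {
  stopifnot(inherits(lut, "LookupTable"))
  if (!is.finite(R_meas) || !is.finite(T_meas)) stop("non-finite input")
  if (R_meas < 0 || T_meas < 0 || R_meas > 1 || T_meas > 1) {
    stop("R_meas and T_meas must be in [0, 1]")
  }
  if (R_meas + T_meas > 1) {
    warning("R_meas + T_meas > 1: unphysical pair, attempting inversion anyway")
  }
  la_grid <- log10(lut$mu_a_grid); ls_grid <- log10(lut$mu_s_prime_grid)

  # best starting node and local SE weights
  node_obj <- outer(seq_along(la_grid), seq_along(ls_grid),
                    Vectorize(function(i, j) {
                      (lut$R_surface[i, j] - R_meas)^2 +
                        (lut$T_surface[i, j] - T_meas)^2
                    }))
  idx <- which(node_obj == min(node_obj), arr.ind = TRUE)[1L, ]
  sig_R <- max(lut$se_R[idx[1L], idx[2L]], se_floor)
  sig_T <- max(lut$se_T[idx[1L], idx[2L]], se_floor)

  lo <- c(la_grid[1L], ls_grid[1L])
  hi <- c(la_grid[length(la_grid)], ls_grid[length(ls_grid)])

  objective <- function(z) {
    zc <- pmin(hi, pmax(lo, z))
    pen <- sum((z - zc)^2) * 1e6
    R <- interp_surface(la_grid, ls_grid, lut$R_surface, zc[1L], zc[2L])
    T_ <- interp_surface(la_grid, ls_grid, lut$T_surface, zc[1L], zc[2L])
    ((R - R_meas) / sig_R)^2 + ((T_ - T_meas) / sig_T)^2 + pen
  }

  start <- c(la_grid[idx[1L]], ls_grid[idx[2L]])
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-12))
  z <- pmin(hi, pmax(lo, fit$par))
  edge_tol <- 1e-3 * (hi - lo)
  on_boundary <- any(z - lo < edge_tol) || any(hi - z < edge_tol)
  structure(list(mu_a_hat = 10^z[1L], mu_s_prime_hat = 10^z[2L],
                 residual = max(0, fit$value),
                 converged = fit$convergence == 0L,
                 on_boundary = on_boundary),
            class = "InversionResult")
}

#' @export
print.InversionResult <- function(x, ...) {
  cat(sprintf(
    "<InversionResult> mu_a=%.4g mu_s'=%.4g mm^-1 (residual %.3g%s%s)\n",
    x$mu_a_hat, x$mu_s_prime_hat, x$residual,
    if (!x$converged) ", not converged" else "",
    if (x$on_boundary) ", on grid boundary" else ""))
  invisible(x)
}

#' Invert a full measurement record wavelength by wavelength
#'
#' Applies [invert_rt()] at each wavelength of the record. `luts` is
#' either a single `LookupTable` (used at all wavelengths — the table
#' depends only on geometry, `g` and `n`, not on wavelength) or a list
#' named by wavelength (nm); a missing wavelength raises an error naming
#' it.
#'
#' @param record a [measurement_record()].
#' @param luts a `LookupTable` or a named list of them.
#' @param se_floor passed to [invert_rt()].
#' @return list with `mu_a` and `mu_s_prime` spectra (mm^-1) on the
#'   record's axis and a `flags` data frame (wavelength, residual,
#'   converged, on_boundary).
#' @export
invert_spectrum <- function(record, luts, se_floor = 1e-4) {
  stopifnot(inherits(record, "MeasurementRecord"))
  wl <- record$R$wavelengths
  lut_for <- function(w) {
    if (inherits(luts, "LookupTable")) return(luts)
    key <- format(w)
    if (is.null(luts[[key]])) stop(sprintf("no lookup table for %g nm", w))
    luts[[key]]
  }
  n <- length(wl)
  mu_a <- mu_s <- res <- numeric(n)
  conv <- bound <- logical(n)
  for (k in seq_len(n)) {
    inv <- invert_rt(record$R$values[k], record$T$values[k], lut_for(wl[k]),
                     se_floor = se_floor)
    mu_a[k] <- inv$mu_a_hat
    mu_s[k] <- inv$mu_s_prime_hat
    res[k] <- inv$residual
    conv[k] <- inv$converged
    bound[k] <- inv$on_boundary
  }
  list(mu_a = spectrum_new(wl, mu_a, "mm^-1"),
       mu_s_prime = spectrum_new(wl, mu_s, "mm^-1"),
       flags = data.frame(wavelength_nm = wl, residual = res,
                          converged = conv, on_boundary = bound))
}

#' Substitution calibration of raw detector counts
#'
#' Converts raw sample counts to a reflectance (or transmittance)
#' fraction by substitution against a reference standard of known
#' reflectivity: `rho_reference * raw_sample / raw_reference`, clipped to
#' `[0, 1]`.
#'
#' @param raw_sample raw counts with the sample in place (vectorised).
#' @param raw_reference raw counts with the reference standard, > 0.
#' @param rho_reference known reflectivity of the standard, in `(0, 1]`.
#' @return list with `value` (clipped fraction) and `clipped` (logical).
#' @examples
#' calibrate_substitution(500, 1000, 0.99)$value  # 0.495
#' @export
calibrate_substitution <- function(raw_sample, raw_reference, rho_reference) {
  if (any(raw_reference <= 0)) stop("raw_reference must be > 0")
  if (rho_reference <= 0 || rho_reference > 1) {
    stop("rho_reference must be in (0, 1]")
  }
  v <- rho_reference * raw_sample / raw_reference
  clipped <- v < 0 | v > 1
  list(value = pmin(1, pmax(0, v)), clipped = clipped)
}

#' Persist / load a lookup table
#'
#' Writes the full `LookupTable` (grids, surfaces, standard errors and
#' provenance) to a single serialized container file at run time.
#'
#' @param lut a `LookupTable`.
#' @param path file path.
#' @return `write_lut`: invisibly, `path`; `read_lut`: the `LookupTable`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "LookupTable"))
  saveRDS(lut, path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lut <- readRDS(path)
  if (!inherits(lut, "LookupTable")) stop("file does not contain a LookupTable")
  lut
}
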