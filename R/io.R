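#' Read / write spectrum tables
#'
#' Delimited text with a `wavelength_nm` header column followed by one or
#' more value columns; comma- and tab-delimited dialects are detected
#' automatically. Rows are sorted by wavelength on write; duplicated or
#' non-monotone wavelengths on read raise an error naming the offending
#' row.
#'
#' @param path file path.
#' @param units unit tag attached to the spectra read.
#' @return `read_spectrum_table`: named list of `Spectrum` objects, one
#'   per value column. `write_spectrum_table`: invisibly, `path`.
#' @export
read_spectrum_table <- function(path, units = "dimensionless") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    stop("missing 'wavelength_nm' header column")
  }
  wl <- df$wavelength_nm
  if (anyDuplicated(wl)) {
    stop(sprintf("duplicated wavelength at row %d", anyDuplicated(wl)))
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  cols <- setdiff(names(df), "wavelength_nm")
  if (!length(cols)) stop("no value columns")
  setNames(lapply(cols, function(cn) spectrum_new(wl, df[[cn]], units)), cols)
}

#' @rdname read_spectrum_table
#' @param spectra named list of `Spectrum` objects on one axis, or a
#'   single `Spectrum`.
#' @param sep delimiter, `","` (default) or `"\t"`.
#' @export
write_spectrum_table <- function(spectra, path, sep = ",") {
  if (is_spectrum(spectra)) spectra <- list(value = spectra)
  stopifnot(all(vapply(spectra, is_spectrum, logical(1))))
  ax <- do.call(shared_axis, unname(spectra))
  ord <- order(ax)
  df <- data.frame(wavelength_nm = ax[ord])
  for (cn in names(spectra)) df[[cn]] <- spectra[[cn]]$values[ord]
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a component absorption library from delimited text
#'
#' Expects columns `wavelength_nm, water, collagen, elastin, lipid`
#' (mm^-1).
#'
#' @param path file path.
#' @param fractions volume fractions passed to [component_library()].
#' @return A `ComponentLibrary`.
#' @export
read_component_library <- function(path,
                                   fractions = c(water = 0.68, collagen = 0.30,
                                                 elastin = 0.01, lipid = 0.01)) {
  sp <- read_spectrum_table(path, units = "mm^-1")
  component_library(sp[c("water", "collagen", "elastin", "lipid")], fractions)
}

#' Read a pipeline run configuration (YAML)
#'
#' Any subset of the [cohort_config()] fields plus `photons`,
#' `grids` (`n_mu_a`, `n_mu_s`, `mu_a_range`, `mu_s_range`) and
#' `g_levels` may be given; the rest fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `RunConfig` list with `cohort`, `grids`, `g_levels`,
#'   `photons`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  cohort <- do.call(cohort_config, raw[intersect(names(raw), known)])
  grids <- do.call(default_grids, if (is.null(raw$grids)) list() else raw$grids)
  structure(list(cohort = cohort, grids = grids,
                 g_levels = if (is.null(raw$g_levels)) c(0.8, 0.9, 0.99) else raw$g_levels,
                 photons = if (is.null(raw$photons)) 2e4 else raw$photons,
                 seed = cohort$seed),
            class = "RunConfig")
}

config_hash <- function(config) {
  # cheap stable fingerprint of the configuration for artifact provenance
  s <- paste(deparse(unclass(config)), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Pipeline command dispatcher
#'
#' Thin driver tying the stages together for scripted use:
#' `synth` writes a cohort manifest and per-sample spectra, `build-lut`
#' builds and stores a lookup table, `invert` recovers property spectra
#' for the cohort, `qc` writes the observation-removal decisions,
#' `sensitivity` runs the anisotropy-factor experiment, and `report`
#' writes a combined structured summary. Artifacts embed the config hash
#' and seed; exit status is 0 on success.
#'
#' @param command one of `"synth"`, `"build-lut"`, `"invert"`, `"qc"`,
#'   `"sensitivity"`, `"report"`.
#' @param config a `RunConfig` from [read_run_config()] (or `NULL` for
#'   defaults).
#' @param out_dir output directory (created if absent).
#' @return Integer exit status, invisibly; artifacts on disk.
#' @export
cli_dispatch <- function(command, config = NULL, out_dir = ".") {
  cmds <- c("synth", "build-lut", "invert", "qc", "sensitivity", "report")
  if (!command %in% cmds) {
    message("usage: opticart {", paste(cmds, collapse = "|"), "}")
    return(invisible(2L))
  }
  if (is.null(config)) config <- read_run_config(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- config$cohort
  hash <- config_hash(config)
  log_line <- function(stage, extra = "") {
    message(sprintf("[opticart] stage=%s seed=%s photons=%g %s",
                    stage, format(config$seed), config$photons, extra))
  }
  art <- function(...) file.path(out_dir, ...)

  cohort_path <- art("cohort.rds")
  lut_path <- art("lut.rds")

  if (command == "synth") {
    log_line("synth")
    cohort <- generate_cohort(cc, n_photons = config$photons)
    write_cohort_manifest(cohort, art("manifest.tsv"))
    for (i in seq_along(cohort)) {
      write_spectrum_table(list(R = cohort[[i]]$record$R,
                                T = cohort[[i]]$record$T),
                           art(sprintf("sample_%02d_rt.csv", i)))
    }
    saveRDS(cohort, cohort_path)
    writeLines(sprintf("config_hash: %s\nseed: %s", hash, format(config$seed)),
               art("provenance.txt"))
    return(invisible(0L))
  }

  if (command == "build-lut") {
    log_line("build-lut")
    con <- sample_construct(gap_medium = gap_medium(cc$gap))
    lut <- build_lut(config$grids$mu_a, config$grids$mu_s_prime, con,
                     g = cc$g_true, n_sample = cc$n_true,
                     n_photons = config$photons, seed = config$seed)
    write_lut(lut, lut_path)
    return(invisible(0L))
  }

  need <- function(path) {
    if (!file.exists(path)) {
      message("missing input: ", path)
      return(TRUE)
    }
    FALSE
  }

  if (command == "invert") {
    log_line("invert")
    if (need(cohort_path) || need(lut_path)) return(invisible(1L))
    cohort <- readRDS(cohort_path)
    lut <- read_lut(lut_path)
    for (i in seq_along(cohort)) {
      est <- invert_spectrum(cohort[[i]]$record, lut)
      write_spectrum_table(list(mu_a = est$mu_a, mu_s_prime = est$mu_s_prime),
                           art(sprintf("sample_%02d_props.csv", i)))
    }
    return(invisible(0L))
  }

  if (command == "qc") {
    log_line("qc")
    if (need(cohort_path) || need(lut_path)) return(invisible(1L))
    cohort <- readRDS(cohort_path)
    lut <- read_lut(lut_path)
    ref <- mixture_absorption(synthetic_component_library(cc$wavelengths))
    rows <- lapply(seq_along(cohort), function(i) {
      est <- invert_spectrum(cohort[[i]]$record, lut)
      dec <- qc_filter(est$mu_a, ref)
      data.frame(sample_id = i, keep = dec$keep,
                 reasons = paste(dec$reasons, collapse = ";"))
    })
    write.table(do.call(rbind, rows), art("qc.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    return(invisible(0L))
  }

  if (command == "sensitivity") {
    log_line("sensitivity")
    if (need(cohort_path)) return(invisible(1L))
    cohort <- readRDS(cohort_path)
    con <- sample_construct(gap_medium = gap_medium(cc$gap))
    luts <- lapply(config$g_levels, function(g) {
      build_lut(config$grids$mu_a, config$grids$mu_s_prime, con, g = g,
                n_sample = cc$n_true, n_photons = config$photons,
                seed = config$seed)
    })
    names(luts) <- format(config$g_levels)
    sens <- g_sensitivity(lapply(cohort, `[[`, "record"), luts,
                          baseline = format(cc$g_true))
    for (lev in names(sens)) {
      write_sensitivity_report(sens[[lev]]$mu_a_report,
                               art(sprintf("sens_mu_a_g%s.tsv", lev)))
      write_sensitivity_report(sens[[lev]]$mu_s_report,
                               art(sprintf("sens_mu_s_g%s.tsv", lev)))
    }
    return(invisible(0L))
  }

  # report
  log_line("report")
  summary <- list(config_hash = hash, seed = config$seed,
                  photons = config$photons,
                  artifacts = list.files(out_dir),
                  version = as.character(packageVersion("opticart")))
  jsonlite::write_json(summary, art("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(0L)
}
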