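#' Chromophore extinction records and libraries
#'
#' A `ChromophoreLibrary` holds one extinction spectrum per tissue
#' chromophore, on a wavelength grid covering 600--1100 nm, together with the
#' concentration unit each spectrum is expressed in. Absorption composes
#' linearly from the library via the Lambert--Beer law, so the units are
#' fixed by convention: extinction in cm^-1 per uM for the hemoglobins
#' (concentrations in uM) and cm^-1 per (mg/cm^3) for water, lipid and
#' collagen (concentrations in mg/cm^3). A sixth, wavelength-independent
#' "background" absorber with unit extinction (1 cm^-1 per unit
#' concentration) absorbs whatever residual spectrally-flat absorption the
#' five constituents cannot explain.
#'
#' @param chromophore_name One of `"HbO2"`, `"Hb"`, `"water"`, `"lipid"`,
#'   `"collagen"`, `"background"`.
#' @param wavelength_grid Strictly increasing numeric vector of wavelengths
#'   (nm) covering at least 600--1100 nm.
#' @param epsilon Non-negative extinction values, one per grid point.
#' @param provenance Free-text source citation for the spectrum.
#' @return `extinction_record()` returns an object of class
#'   `"tdb_extinction_record"`; `chromophore_library()` returns a
#'   `"tdb_chromophore_library"`.
#' @examples
#' rec <- extinction_record("background", c(600, 1100), c(1, 1), "definition")
#' lib <- default_chromophore_library()
#' get_extinction(lib, "water", c(900, 970, 1000))
#' @export
extinction_record <- function(chromophore_name, wavelength_grid, epsilon,
                              provenance = "unspecified") {
  chromophore_name <- match.arg(chromophore_name, tdb_chromophores())
  wavelength_grid <- as.numeric(wavelength_grid)
  epsilon <- as.numeric(epsilon)
  if (length(wavelength_grid) < 2 || any(diff(wavelength_grid) <= 0)) {
    abort("`wavelength_grid` must be strictly increasing with >= 2 points.")
  }
  if (length(epsilon) != length(wavelength_grid)) {
    abort("`epsilon` and `wavelength_grid` must have the same length.")
  }
  if (any(!is.finite(epsilon)) || any(epsilon < 0)) {
    abort("`epsilon` must be finite and non-negative everywhere.")
  }
  if (chromophore_name == "background" && any(epsilon != 1)) {
    abort("The background absorber must have epsilon identically 1.")
  }
  structure(
    list(
      chromophore_name = chromophore_name,
      wavelength_grid = wavelength_grid,
      epsilon = epsilon,
      provenance = provenance
    ),
    class = "tdb_extinction_record"
  )
}

#' @export
print.tdb_extinction_record <- function(x, ...) {
  cat(sprintf(
    "<extinction record: %s, %d points, %.0f-%.0f nm>\n  %s\n",
    x$chromophore_name, length(x$wavelength_grid),
    min(x$wavelength_grid), max(x$wavelength_grid), x$provenance
  ))
  invisible(x)
}

tdb_chromophores <- function() {
  c("HbO2", "Hb", "water", "lipid", "collagen", "background")
}

tdb_units <- function() {
  c(
    HbO2 = "uM", Hb = "uM",
    water = "mg/cm^3", lipid = "mg/cm^3", collagen = "mg/cm^3",
    background = "cm^-1"
  )
}

#' @param records A list of six `extinction_record()` objects, one per
#'   chromophore (any order; names taken from the records).
#' @rdname extinction_record
#' @export
chromophore_library <- function(records) {
  if (!all(vapply(records, inherits, logical(1), "tdb_extinction_record"))) {
    abort("`records` must all be extinction records.")
  }
  nms <- vapply(records, function(r) r$chromophore_name, character(1))
  if (anyDuplicated(nms)) abort("Duplicate chromophore names in library.")
  missing <- setdiff(tdb_chromophores(), nms)
  if (length(missing)) {
    abort(paste0("Library is missing chromophores: ",
                 paste(missing, collapse = ", ")))
  }
  spans <- vapply(records, function(r) range(r$wavelength_grid), numeric(2))
  if (any(spans[1, ] > 600) || any(spans[2, ] < 1100)) {
    abort("Every record must cover the 600-1100 nm range.")
  }
  names(records) <- nms
  structure(
    list(records = records[tdb_chromophores()], unit_registry = tdb_units()),
    class = "tdb_chromophore_library"
  )
}

#' @export
print.tdb_chromophore_library <- function(x, ...) {
  cat("<chromophore library>\n")
  for (r in x$records) {
    cat(sprintf("  %-10s [%s] %d points, %.0f-%.0f nm\n",
                r$chromophore_name, x$unit_registry[[r$chromophore_name]],
                length(r$wavelength_grid),
                min(r$wavelength_grid), max(r$wavelength_grid)))
  }
  invisible(x)
}

#' Evaluate an extinction spectrum at arbitrary wavelengths
#'
#' Linear interpolation on the stored grid. Extrapolation outside the grid
#' span is refused: extinction spectra are sharply structured and silent
#' extrapolation would corrupt downstream fits.
#'
#' @param library A `chromophore_library()`.
#' @param name Chromophore name.
#' @param wavelengths Wavelengths (nm) at which to evaluate, all within the
#'   record's grid span.
#' @return Numeric vector of extinction values, same length as `wavelengths`.
#' @export
get_extinction <- function(library, name, wavelengths) {
  stopifnot(inherits(library, "tdb_chromophore_library"))
  if (!name %in% names(library$records)) {
    abort(paste0("Unknown chromophore: '", name, "'."))
  }
  rec <- library$records[[name]]
  wavelengths <- as.numeric(wavelengths)
  rng <- range(rec$wavelength_grid)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    abort(sprintf(
      "Wavelength outside the %s grid span [%.0f, %.0f] nm; extrapolation refused.",
      name, rng[1], rng[2]
    ))
  }
  approx(rec$wavelength_grid, rec$epsilon, xout = wavelengths,
         method = "linear", ties = "ordered")$y
}

#' Compose absorption and reduced-scattering spectra from tissue parameters
#'
#' `compose_mua()` applies the Lambert--Beer law,
#' mu_a(lambda) = sum_i eps_i(lambda) C_i + B, over the five tissue
#' constituents plus the spectrally-flat background term B (cm^-1).
#' `compose_musp()` evaluates the empirical Mie power law
#' mu_s'(lambda) = a (lambda/lambda0)^-b with reference wavelength
#' lambda0 = 600 nm.
#'
#' @param composition A [tissue_composition()].
#' @param library A [chromophore_library()].
#' @param wavelengths Wavelengths (nm).
#' @return Numeric vector of mu_a (resp. mu_s') in cm^-1.
#' @examples
#' lib <- default_chromophore_library()
#' comp <- tissue_composition(c_hbo2 = 15, c_hb = 5, c_water = 300,
#'                            c_lipid = 600, c_collagen = 60,
#'                            background = 0.018, a = 12, b = 0.8)
#' mua <- compose_mua(comp, lib, seq(600, 1100, 10))
#' musp <- compose_musp(12, 0.8, seq(600, 1100, 10))
#' @export
compose_mua <- function(composition, library, wavelengths) {
  stopifnot(inherits(composition, "tdb_tissue_composition"))
  conc <- c(
    HbO2 = composition$c_hbo2, Hb = composition$c_hb,
    water = composition$c_water, lipid = composition$c_lipid,
    collagen = composition$c_collagen, background = composition$background
  )
  if (any(conc < 0)) abort("Concentrations and background must be >= 0.")
  mua <- numeric(length(wavelengths))
  for (nm in names(conc)) {
    if (conc[[nm]] != 0) {
      mua <- mua + conc[[nm]] * get_extinction(library, nm, wavelengths)
    }
  }
  mua
}

#' @param a Scattering amplitude (cm^-1), the value of mu_s' at `lambda0`.
#' @param b Scattering power (dimensionless).
#' @param lambda0 Reference wavelength (nm), 600 by convention.
#' @rdname compose_mua
#' @export
compose_musp <- function(a, b, wavelengths, lambda0 = 600) {
  if (!is.finite(a) || a <= 0) abort("`a` must be positive.")
  if (!is.finite(b)) abort("`b` must be finite.")
  if (!is.finite(lambda0) || lambda0 <= 0) abort("`lambda0` must be positive.")
  a * (wavelengths / lambda0)^(-b)
}

#' Read or write an extinction table as CSV
#'
#' The on-disk format is a plain CSV with columns `wavelength_nm,epsilon`,
#' preceded by `#`-prefixed header lines carrying the chromophore name and
#' provenance.
#'
#' @param path File path.
#' @return `read_extinction_csv()` returns an [extinction_record()].
#' @export
read_extinction_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  name <- sub("^#\\s*chromophore:\\s*", "", grep("^#\\s*chromophore:", hdr, value = TRUE)[1])
  prov <- sub("^#\\s*provenance:\\s*", "", grep("^#\\s*provenance:", hdr, value = TRUE)[1])
  if (is.na(name)) abort("Extinction CSV lacks a '# chromophore:' header.")
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("wavelength_nm", "epsilon") %in% names(df))) {
    abort("Extinction CSV must have columns wavelength_nm,epsilon.")
  }
  extinction_record(name, df$wavelength_nm, df$epsilon,
                    provenance = if (is.na(prov)) "unspecified" else prov)
}

#' @param record An [extinction_record()] to write.
#' @rdname read_extinction_csv
#' @export
write_extinction_csv <- function(record, path) {
  stopifnot(inherits(record, "tdb_extinction_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# chromophore: ", record$chromophore_name),
    paste0("# provenance: ", record$provenance),
    "wavelength_nm,epsilon"
  ), con)
  writeLines(sprintf("%g,%.8g", record$wavelength_grid, record$epsilon), con)
  invisible(path)
}

#' The bundled default chromophore library
#'
#' Returns the library of synthetic extinction spectra shipped under
#' `inst/extdata/extinction/`. These are smooth analytic stand-ins shaped to
#' the canonical near-infrared features of each chromophore (lipid peak at
#' 930 nm, water peak at 970 nm, deoxy-hemoglobin peak at 760 nm, the broad
#' oxy-hemoglobin maximum near 915 nm, collagen bumps near 910/1030 nm with a
#' rise towards 1180 nm); they are *not* a literature compilation, and
#' absolute concentrations retrieved with them are internally consistent but
#' not comparable to values retrieved with measured extinction data. The
#' library is swappable: any [chromophore_library()] can be passed wherever
#' this default is used.
#'
#' @param dir Directory holding one `<name>_synthetic.csv` per chromophore;
#'   defaults to the bundled data.
#' @return A [chromophore_library()].
#' @export
default_chromophore_library <- function(dir = system.file("extdata", "extinction",
                                                          package = "tdbreast")) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  recs <- lapply(files, read_extinction_csv)
  recs <- c(recs, list(background_record()))
  chromophore_library(recs)
}

background_record <- function() {
  extinction_record("background", c(600, 1100), c(1, 1),
                    provenance = "unit-extinction flat absorber (definition)")
}

#' Synthetic extinction spectra (analytic forms)
#'
#' Analytic generator behind the bundled library; exposed so tests and users
#' can rebuild the spectra on any grid.
#'
#' @param name Chromophore name (not `"background"`).
#' @param wavelengths Wavelengths (nm).
#' @return Extinction values (cm^-1 per uM for hemoglobins, cm^-1 per
#'   mg/cm^3 otherwise).
#' @export
synthetic_extinction <- function(name, wavelengths) {
  l <- wavelengths
  g <- function(mu, sig) exp(-(l - mu)^2 / (2 * sig^2))
  switch(match.arg(name, setdiff(tdb_chromophores(), "background")),
    water = (0.004 + 0.030 * g(740, 35) + 0.030 * g(836, 60) +
               0.450 * g(970, 42) + 0.200 * g(1150, 80)) / 1000,
    lipid = (0.002 + 0.012 * g(760, 15) + 0.115 * g(928, 18) +
               0.015 * g(890, 40) + 0.055 * g(1040, 30)) / 916,
    collagen = 1.5e-4 * exp(-(l - 600) / 120) + 0.8e-4 * g(910, 40) +
      1.2e-4 * g(1035, 40) + 2.5e-4 * g(1180, 60),
    HbO2 = 6e-4 + 7e-3 * exp(-(l - 600) / 25) + 2.4e-3 * g(915, 85),
    Hb = 3.3e-2 * exp(-(l - 600) / 35) + 1.8e-3 * g(758, 20) +
      2.5e-3 * exp(-(l - 700) / 280)
  )
}

#' Build the full synthetic library in memory (no files)
#' @param wavelengths Grid on which to tabulate the spectra (nm).
#' @rdname synthetic_extinction
#' @export
synthetic_chromophore_library <- function(wavelengths = seq(600, 1100, by = 1)) {
  recs <- lapply(setdiff(tdb_chromophores(), "background"), function(nm) {
    extinction_record(nm, wavelengths, synthetic_extinction(nm, wavelengths),
                      provenance = "synthetic analytic spectrum (tdbreast)")
  })
  chromophore_library(c(recs, list(background_record())))
}
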