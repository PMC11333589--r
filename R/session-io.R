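tdb_schema_version <- "1.0"

#' Write / read a measurement session on disk
#'
#' The on-disk container is a plain-text directory bundle: a
#' `manifest.json` (schema version, subject id, seed, time axis,
#' wavelength list, per-acquisition metadata and file names), an `irf.csv`
#' (one column, full-precision), and one counts CSV per acquisition
#' (`wavelength_nm` column followed by one integer column per time
#' channel). The round trip is lossless: `read_session(write_session(s))`
#' reproduces the session field-for-field with bit-exact counts.
#'
#' @param session A `"tdb_session"` (from [simulate_session()] or a
#'   previous [read_session()]).
#' @param path Directory to create/fill.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "tdb_session"))
  acqs <- session$acquisitions
  if (!length(acqs)) abort("Session has no acquisitions.")
  axis <- acqs[[1]]$time_axis
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  writeLines(sprintf("%.17g", acqs[[1]]$irf), file.path(path, "irf.csv"))

  acq_meta <- purrr::imap(acqs, function(a, i) {
    file <- sprintf("acq_%02d.csv", i)
    counts <- t(vapply(a$dtofs, function(d) d$counts,
                       numeric(axis$n_channels)))
    df <- data.frame(wavelength_nm = vapply(a$dtofs, function(d) d$wavelength,
                                            numeric(1)))
    df <- cbind(df, as.data.frame(counts))
    names(df) <- c("wavelength_nm",
                   sprintf("ch%04d", seq_len(axis$n_channels)))
    readr::write_csv(df, file.path(path, file), progress = FALSE)
    md <- a$metadata
    list(
      file = file, mode = a$geometry$mode,
      rho_cm = if (a$geometry$mode == "reflectance") a$geometry$rho else NULL,
      thickness_cm = if (a$geometry$mode == "transmittance") a$geometry$thickness else NULL,
      lateral_offset_cm = a$geometry$lateral_offset,
      breast = md$breast, posture = md$posture, position = md$position,
      distance_cm = md$distance_cm
    )
  })

  manifest <- list(
    schema_version = tdb_schema_version,
    subject_id = session$subject_id,
    seed = session$seed,
    time_axis = list(t0 = axis$t0, dt = axis$dt,
                     n_channels = axis$n_channels),
    wavelengths = vapply(acqs[[1]]$dtofs, function(d) d$wavelength,
                         numeric(1)),
    irf_file = "irf.csv",
    acquisitions = acq_meta
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) abort("No manifest.json in session directory.")
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (!identical(mf$schema_version, tdb_schema_version)) {
    abort(sprintf("Schema version mismatch: file has '%s', reader expects '%s'.",
                  mf$schema_version %||% "<missing>", tdb_schema_version))
  }
  if (is.null(mf$irf_file) || !file.exists(file.path(path, mf$irf_file))) {
    abort("Session is missing its IRF histogram.")
  }
  wl <- as.numeric(unlist(mf$wavelengths))
  if (!isTRUE(all.equal(wl, seq(600, 1100, 10)))) {
    abort("Wavelength list must be 600:10:1100 nm.")
  }
  ta <- mf$time_axis
  axis <- time_axis(as.numeric(ta$t0), as.numeric(ta$dt),
                    as.integer(ta$n_channels))
  irf <- as.numeric(readLines(file.path(path, mf$irf_file)))
  if (length(irf) != axis$n_channels) {
    abort("IRF length does not match the time axis.")
  }

  acqs <- lapply(mf$acquisitions, function(am) {
    df <- readr::read_csv(file.path(path, am$file), progress = FALSE,
                          show_col_types = FALSE)
    if (nrow(df) != length(wl)) {
      abort(sprintf(
        "Counts matrix in %s has %d rows for a %d-wavelength list.",
        am$file, nrow(df), length(wl)
      ))
    }
    if (ncol(df) - 1 != axis$n_channels) {
      abort(sprintf("Counts matrix in %s has %d channels; axis has %d.",
                    am$file, ncol(df) - 1, axis$n_channels))
    }
    counts <- as.matrix(df[, -1])
    if (any(counts < 0) || any(counts != round(counts))) {
      abort("Counts must be non-negative integers.")
    }
    geom <- if (am$mode == "transmittance") {
      geometry("transmittance", thickness = am$thickness_cm,
               lateral_offset = am$lateral_offset_cm %||% 0)
    } else {
      geometry("reflectance", rho = am$rho_cm)
    }
    dtofs <- lapply(seq_along(wl), function(k) {
      dtof(df$wavelength_nm[k], as.numeric(counts[k, ]), axis)
    })
    spectral_acquisition(
      dtofs, irf, geom,
      metadata = list(subject = mf$subject_id, breast = am$breast,
                      posture = am$posture, position = am$position,
                      distance_cm = am$distance_cm, mode = am$mode)
    )
  })
  structure(list(subject_id = mf$subject_id, seed = mf$seed,
                 acquisitions = acqs),
            class = "tdb_session")
}

#' Fit every acquisition of a session into a parameter table
#'
#' Runs the spectrally-constrained fit on each acquisition of a session and
#' assembles one parameter-table row per acquisition (composition columns
#' plus derived blood parameters and density indices), the tabular input of
#' the statistics layer.
#'
#' @param session A `"tdb_session"`.
#' @param library,medium Passed to [spectral_fit()].
#' @param ... Further arguments to [spectral_fit()] (e.g. `wavelengths`,
#'   `init`).
#' @return A tibble with one row per successfully fitted acquisition.
#' @export
fit_session <- function(session, library = default_chromophore_library(),
                        medium = medium_model(), ...) {
  stopifnot(inherits(session, "tdb_session"))
  rows <- purrr::map(session$acquisitions, function(a) {
    md <- a$metadata
    res <- tryCatch(spectral_fit(a, library, medium, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("Acquisition skipped (%s %s %s): %s",
                   md$posture %||% "?", md$position %||% "?",
                   md$mode %||% "?", conditionMessage(res)))
      return(NULL)
    }
    comp <- res$composition
    tibble(
      subject = md$subject %||% session$subject_id,
      breast = md$breast %||% NA_character_,
      posture = md$posture %||% NA_character_,
      position = md$position %||% NA_character_,
      distance_cm = md$distance_cm %||% NA_real_,
      mode = md$mode %||% a$geometry$mode,
      c_hbo2 = comp$c_hbo2, c_hb = comp$c_hb, c_water = comp$c_water,
      c_lipid = comp$c_lipid, c_collagen = comp$c_collagen,
      background = comp$background, a = comp$a, b = comp$b,
      objective_value = res$objective_value, converged = res$converged
    )
  })
  add_derived_indices(dplyr::bind_rows(purrr::compact(rows)))
}
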