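#' Tissue composition parameter vector
#'
#' The free-parameter vector of the spectrally-constrained fit: five
#' chromophore concentrations, the spectrally-flat background absorption,
#' and the two Mie scattering parameters of
#' mu_s'(lambda) = a (lambda/lambda0)^-b.
#'
#' @param c_hbo2,c_hb Oxy- / deoxy-hemoglobin concentration (uM).
#' @param c_water,c_lipid,c_collagen Constituent concentrations (mg/cm^3).
#' @param background Residual flat absorption B (cm^-1).
#' @param a Scattering amplitude (cm^-1 at `lambda0`).
#' @param b Scattering power (dimensionless).
#' @param lambda0 Reference wavelength (nm).
#' @export
tissue_composition <- function(c_hbo2, c_hb, c_water, c_lipid, c_collagen,
                               background = 0, a = 10, b = 1, lambda0 = 600) {
  vals <- c(c_hbo2 = c_hbo2, c_hb = c_hb, c_water = c_water,
            c_lipid = c_lipid, c_collagen = c_collagen,
            background = background)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("Concentrations and background must be finite and >= 0.")
  }
  if (!is.finite(a) || a <= 0) abort("`a` must be positive.")
  if (!is.finite(b)) abort("`b` must be finite.")
  structure(as.list(c(vals, a = a, b = b, lambda0 = lambda0)),
            class = "tdb_tissue_composition")
}

#' @export
print.tdb_tissue_composition <- function(x, ...) {
  cat(sprintf(
    paste0("<tissue composition>\n  HbO2 %.2f uM  Hb %.2f uM  water %.0f",
           "  lipid %.0f  collagen %.1f mg/cm^3\n",
           "  background %.4f cm^-1  a %.2f cm^-1  b %.3f (lambda0 %g nm)\n"),
    x$c_hbo2, x$c_hb, x$c_water, x$c_lipid, x$c_collagen,
    x$background, x$a, x$b, x$lambda0
  ))
  invisible(x)
}

#' @method as_tibble tdb_tissue_composition
#' @export
as_tibble.tdb_tissue_composition <- function(x, ...) {
  tibble(
    c_hbo2 = x$c_hbo2, c_hb = x$c_hb, c_water = x$c_water,
    c_lipid = x$c_lipid, c_collagen = x$c_collagen,
    background = x$background, a = x$a, b = x$b, lambda0 = x$lambda0
  )
}

# IRF-convolved forward curve for one wavelength
model_curve <- function(mua, musp, geom, medium, axis, irf) {
  convolve_with_irf(td_forward(mua, musp, geom, medium, axis), irf, axis)
}

# Profiled weighted-least-squares residual: amplitude solved in closed form.
# Weights 1/sqrt(max(counts, 1)) approximate Poisson counting statistics.
wls_residual <- function(model_win, counts_win) {
  w2 <- 1 / pmax(counts_win, 1)
  denom <- sum(w2 * model_win^2)
  amp <- if (denom > 0) sum(w2 * model_win * counts_win) / denom else 0
  list(residual = (amp * model_win - counts_win) * sqrt(w2), amplitude = amp)
}

#' Single-wavelength (standard) fit of a DTOF
#'
#' Fits the IRF-convolved diffusion-equation model, scaled by a free
#' multiplicative amplitude, to one measured DTOF by count-weighted least
#' squares restricted to the fit window (80% of the peak on the leading
#' edge to 5% on the falling edge). The absorption and reduced scattering
#' coefficients are the free parameters; the amplitude is profiled out in
#' closed form at every step. Bounded Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) with mu_a in [1e-4, 1] cm^-1 and mu_s' in
#' [1, 50] cm^-1.
#'
#' @param dtof A [dtof()].
#' @param irf IRF histogram on the same axis.
#' @param geometry A [geometry()].
#' @param medium A [medium_model()].
#' @param init Optional starting `c(mua, musp)`; default `c(0.1, 10)`.
#' @param lower,upper Parameter bounds `c(mua, musp)`.
#' @param snr_min Minimum total counts; below it the DTOF is excluded
#'   (result flagged, not an error).
#' @param min_window Minimum fit-window length in channels.
#' @param max_iter Iteration cap.
#' @return A `"tdb_standard_fit"` with fields `mua`, `musp`, `amplitude`,
#'   `objective_value`, `converged`, `n_iterations`, `excluded`,
#'   `fit_window`. Use [tidy()] / [glance()] for tabular access.
#' @export
standard_fit <- function(dtof, irf, geometry, medium = medium_model(),
                         init = NULL, lower = c(1e-4, 1), upper = c(1, 50),
                         snr_min = 1000, min_window = 10, max_iter = 500) {
  stopifnot(inherits(dtof, "tdb_dtof"))
  axis <- dtof$time_axis
  out <- structure(
    list(wavelength = dtof$wavelength, mua = NA_real_, musp = NA_real_,
         amplitude = NA_real_, objective_value = NA_real_, converged = FALSE,
         n_iterations = 0L, excluded = FALSE, exclusion_reason = NA_character_,
         fit_window = NULL),
    class = "tdb_standard_fit"
  )
  if (dtof$total_counts < snr_min) {
    out$excluded <- TRUE
    out$exclusion_reason <- "low_snr"
    return(out)
  }
  win <- determine_fit_window(dtof$counts, min_channels = min_window)
  idx <- win$start_index:win$end_index
  y <- dtof$counts[idx]

  fn <- function(p) {
    curve <- model_curve(p[1], p[2], geometry, medium, axis, irf)
    wls_residual(curve[idx], y)$residual
  }
  init <- init %||% c(0.1, 10)
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(init, lower), upper), lower = lower, upper = upper,
    fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-10, ptol = 1e-10
    )
  )
  curve <- model_curve(fit$par[1], fit$par[2], geometry, medium, axis, irf)
  prof <- wls_residual(curve[idx], y)
  out$mua <- fit$par[1]
  out$musp <- fit$par[2]
  out$amplitude <- prof$amplitude
  out$objective_value <- sum(prof$residual^2)
  out$converged <- fit$info %in% 1:4 && is.finite(out$objective_value)
  out$n_iterations <- fit$niter
  out$fit_window <- win
  out
}

#' @export
print.tdb_standard_fit <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<standard fit: excluded (%s)>\n", x$exclusion_reason))
  } else {
    cat(sprintf(
      "<standard fit @ %g nm: mua %.4f cm^-1, musp %.2f cm^-1, %s in %d iter>\n",
      x$wavelength %||% NA, x$mua, x$musp,
      if (x$converged) "converged" else "NOT converged", x$n_iterations
    ))
  }
  invisible(x)
}

#' @method tidy tdb_standard_fit
#' @export
tidy.tdb_standard_fit <- function(x, ...) {
  tibble(
    term = c("mua", "musp", "amplitude"),
    estimate = c(x$mua, x$musp, x$amplitude)
  )
}

#' @method glance tdb_standard_fit
#' @export
glance.tdb_standard_fit <- function(x, ...) {
  tibble(
    objective_value = x$objective_value, converged = x$converged,
    n_iterations = x$n_iterations, excluded = x$excluded
  )
}

#' Standard fit of every DTOF in an acquisition
#'
#' Runs [standard_fit()] independently at each of the 51 wavelengths and
#' returns a tibble of per-wavelength optical properties, the classical
#' "standard" analysis of a TD-DOS spectrum.
#'
#' @param acq A [spectral_acquisition()].
#' @inheritParams standard_fit
#' @param ... Passed to [standard_fit()].
#' @return Tibble with columns `wavelength`, `mua`, `musp`, `amplitude`,
#'   `objective_value`, `converged`, `excluded`.
#' @export
standard_fit_spectrum <- function(acq, medium = medium_model(), init = NULL, ...) {
  stopifnot(inherits(acq, "tdb_spectral_acquisition"))
  purrr::map_dfr(acq$dtofs, function(d) {
    f <- standard_fit(d, acq$irf, acq$geometry, medium = medium, init = init, ...)
    tibble(
      wavelength = d$wavelength, mua = f$mua, musp = f$musp,
      amplitude = f$amplitude, objective_value = f$objective_value,
      converged = f$converged, excluded = f$excluded
    )
  })
}

# Initial composition from per-wavelength standard fits: non-negative linear
# unmixing of the mua spectrum on the extinction spectra, and a log-log line
# through musp over 600-900 nm, where the power-law estimate is reliable.
spectral_init_from_standard <- function(std, library, lambda0 = 600) {
  ok <- std$converged & !std$excluded & is.finite(std$mua) & is.finite(std$musp)
  wl <- std$wavelength[ok]
  E <- vapply(tdb_chromophores(),
              function(nm) get_extinction(library, nm, wl),
              numeric(length(wl)))
  nn <- pracma::lsqnonneg(E, std$mua[ok])$x
  names(nn) <- tdb_chromophores()
  sc <- ok & std$wavelength <= 900
  lf <- stats::lm(log(std$musp[sc]) ~ log(std$wavelength[sc] / lambda0))
  a0 <- exp(stats::coef(lf)[[1]])
  b0 <- -stats::coef(lf)[[2]]
  tissue_composition(
    c_hbo2 = nn[["HbO2"]], c_hb = nn[["Hb"]], c_water = nn[["water"]],
    c_lipid = nn[["lipid"]], c_collagen = nn[["collagen"]],
    background = min(nn[["background"]], 0.2),
    a = min(max(a0, 1), 50), b = min(max(b0, 0), 4), lambda0 = lambda0
  )
}

#' Spectrally-constrained global fit of an acquisition
#'
#' Fits all 51 DTOFs of a spectrum at once: the Lambert-Beer law (five
#' chromophores plus the flat background) replaces mu_a and the Mie power
#' law replaces mu_s' inside the diffusion model, so the free parameters are
#' the tissue composition itself rather than per-wavelength optical
#' properties. Per-wavelength amplitudes remain free and are profiled out in
#' closed form. DTOFs below the SNR threshold are excluded (flagged with a
#' reason code); at least `min_wavelengths` usable wavelengths are required.
#' Initialization defaults to per-wavelength standard fits followed by
#' non-negative unmixing of the mu_a spectrum and a log-log line fit of the
#' mu_s' spectrum over 600-900 nm.
#'
#' @param acq A [spectral_acquisition()].
#' @param library A [chromophore_library()].
#' @param medium A [medium_model()].
#' @param init Optional starting [tissue_composition()]; if `NULL` the
#'   standard-fit initialization is used.
#' @param wavelengths Optional subset of wavelengths (nm) to fit on (the
#'   full 51-point grid by default).
#' @param snr_min Total-count threshold below which a DTOF is excluded.
#' @param min_wavelengths Minimum usable wavelengths.
#' @param max_iter Iteration cap.
#' @param bounds Named list overriding the default box bounds
#'   (`conc_max`, `background_max`, `a_range`, `b_range`).
#' @return A `"tdb_spectral_fit"` holding the recovered
#'   [tissue_composition()], per-wavelength amplitudes, objective value,
#'   convergence diagnostics, excluded wavelengths and fit windows.
#' @export
spectral_fit <- function(acq, library = default_chromophore_library(),
                         medium = medium_model(), init = NULL,
                         wavelengths = NULL, snr_min = 1000,
                         min_wavelengths = 20, max_iter = 500,
                         bounds = list()) {
  stopifnot(inherits(acq, "tdb_spectral_acquisition"))
  axis <- acq$time_axis
  b0 <- modifyList(
    list(conc_max = c(HbO2 = 500, Hb = 500, water = 1100, lipid = 1100,
                      collagen = 400),
         background_max = 0.2, a_range = c(1, 50), b_range = c(0, 4)),
    bounds
  )

  wl_all <- vapply(acq$dtofs, function(d) d$wavelength, numeric(1))
  keep <- if (is.null(wavelengths)) rep(TRUE, 51) else wl_all %in% wavelengths
  totals <- vapply(acq$dtofs, function(d) d$total_counts, numeric(1))
  usable <- keep & totals >= snr_min
  excluded <- tibble(
    wavelength = wl_all[keep & !usable],
    reason = rep("low_snr", sum(keep & !usable))
  )
  if (sum(usable) < min_wavelengths) {
    abort(sprintf("Only %d usable wavelengths (need >= %d).",
                  sum(usable), min_wavelengths))
  }
  idx_wl <- which(usable)
  wins <- lapply(idx_wl, function(i) {
    determine_fit_window(acq$dtofs[[i]]$counts)
  })
  chans <- lapply(wins, function(w) w$start_index:w$end_index)
  ys <- lapply(seq_along(idx_wl), function(k) {
    acq$dtofs[[idx_wl[k]]]$counts[chans[[k]]]
  })
  wl_fit <- wl_all[idx_wl]
  # extinction matrix, one column per chromophore incl. background
  E <- vapply(tdb_chromophores(),
              function(nm) get_extinction(library, nm, wl_fit),
              numeric(length(wl_fit)))

  if (is.null(init)) {
    std <- standard_fit_spectrum(acq, medium = medium, snr_min = snr_min)
    std <- std[std$wavelength %in% wl_fit, ]
    init <- spectral_init_from_standard(std, library)
  }
  stopifnot(inherits(init, "tdb_tissue_composition"))
  lambda0 <- init$lambda0

  lower <- c(rep(0, 6), b0$a_range[1], b0$b_range[1])
  upper <- c(b0$conc_max, b0$background_max, b0$a_range[2], b0$b_range[2])
  p0 <- c(init$c_hbo2, init$c_hb, init$c_water, init$c_lipid,
          init$c_collagen, init$background, init$a, init$b)
  p0 <- pmin(pmax(p0, lower), upper)

  fn <- function(p) {
    mua <- as.numeric(E %*% p[1:6])
    musp <- compose_musp(p[7], p[8], wl_fit, lambda0)
    res <- vector("list", length(wl_fit))
    for (k in seq_along(wl_fit)) {
      curve <- model_curve(mua[k], musp[k], acq$geometry, medium, axis, acq$irf)
      res[[k]] <- wls_residual(curve[chans[[k]]], ys[[k]])$residual
    }
    unlist(res, use.names = FALSE)
  }

  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-10, ptol = 1e-10
    )
  )
  p <- fit$par
  comp <- tissue_composition(
    c_hbo2 = p[1], c_hb = p[2], c_water = p[3], c_lipid = p[4],
    c_collagen = p[5], background = p[6], a = p[7], b = p[8],
    lambda0 = lambda0
  )
  mua <- as.numeric(E %*% p[1:6])
  musp <- compose_musp(p[7], p[8], wl_fit, lambda0)
  amps <- vapply(seq_along(wl_fit), function(k) {
    curve <- model_curve(mua[k], musp[k], acq$geometry, medium, axis, acq$irf)
    wls_residual(curve[chans[[k]]], ys[[k]])$amplitude
  }, numeric(1))

  structure(
    list(
      composition = comp,
      spectra = tibble(wavelength = wl_fit, mua = mua, musp = musp,
                       amplitude = amps),
      objective_value = fit$deviance, converged = fit$info %in% 1:4,
      n_iterations = fit$niter, excluded_wavelengths = excluded,
      fit_windows = wins, init = init
    ),
    class = "tdb_spectral_fit"
  )
}

#' @export
print.tdb_spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral fit: %s in %d iterations, objective %.3g>\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$objective_value))
  print(x$composition)
  if (nrow(x$excluded_wavelengths)) {
    cat(sprintf("  excluded wavelengths: %s\n",
                paste(x$excluded_wavelengths$wavelength, collapse = ", ")))
  }
  invisible(x)
}

#' @method tidy tdb_spectral_fit
#' @export
tidy.tdb_spectral_fit <- function(x, ...) {
  comp <- x$composition
  tibble(
    term = c("c_hbo2", "c_hb", "c_water", "c_lipid", "c_collagen",
             "background", "a", "b"),
    estimate = c(comp$c_hbo2, comp$c_hb, comp$c_water, comp$c_lipid,
                 comp$c_collagen, comp$background, comp$a, comp$b),
    unit = c("uM", "uM", "mg/cm^3", "mg/cm^3", "mg/cm^3", "cm^-1",
             "cm^-1", "1")
  )
}

#' @method glance tdb_spectral_fit
#' @export
glance.tdb_spectral_fit <- function(x, ...) {
  tibble(
    objective_value = x$objective_value, converged = x$converged,
    n_iterations = x$n_iterations,
    n_wavelengths = nrow(x$spectra),
    n_excluded = nrow(x$excluded_wavelengths)
  )
}
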