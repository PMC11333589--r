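#' Time axis for TCSPC histograms
#'
#' @param t0 Time origin (ns) of the first channel edge; photon injection is
#'   at t = 0, so any system delay is carried by the IRF, not by `t0`.
#' @param dt Channel width (ns).
#' @param n_channels Number of channels (>= 64).
#' @return A `"tdb_time_axis"` object. `axis_times()` returns the channel
#'   center times (ns). The default (4096 channels x 6.1 ps ~ 25 ns) mimics
#'   a TCSPC board running at a 40 MHz laser repetition rate.
#' @export
time_axis <- function(t0 = 0, dt = 25 / 4096, n_channels = 4096) {
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be positive.")
  if (n_channels < 64) abort("`n_channels` must be >= 64.")
  structure(list(t0 = t0, dt = dt, n_channels = as.integer(n_channels)),
            class = "tdb_time_axis")
}

#' @param axis A `time_axis()`.
#' @rdname time_axis
#' @export
axis_times <- function(axis) {
  axis$t0 + (seq_len(axis$n_channels) - 0.5) * axis$dt
}

same_axis <- function(a, b) {
  isTRUE(all.equal(a$t0, b$t0)) && isTRUE(all.equal(a$dt, b$dt)) &&
    a$n_channels == b$n_channels
}

#' Measurement geometry
#'
#' Reflectance places source and detector on the same surface of a
#' semi-infinite medium at inter-fiber distance `rho`; transmittance places
#' them on opposite faces of an infinite slab of the given `thickness`, with
#' an optional lateral offset between the injection and collection axes.
#'
#' @param mode `"reflectance"` or `"transmittance"`.
#' @param rho Source-detector distance (cm), required for reflectance
#'   (2 or 3 cm in the measurement protocol).
#' @param thickness Slab thickness (cm), required for transmittance. A finite
#'   thickness may also be given in reflectance mode to use the slab solution
#'   on the injection side.
#' @param lateral_offset Lateral source-detector offset (cm) in
#'   transmittance; 0 = coaxial.
#' @export
geometry <- function(mode = c("reflectance", "transmittance"),
                     rho = NULL, thickness = NULL, lateral_offset = 0) {
  mode <- match.arg(mode)
  if (mode == "reflectance") {
    if (is.null(rho) || !is.finite(rho) || rho <= 0) {
      abort("Reflectance geometry requires `rho` > 0.")
    }
    thickness <- thickness %||% Inf
    if (thickness <= 0) abort("`thickness` must be positive.")
  } else {
    if (is.null(thickness) || !is.finite(thickness) || thickness <= 0) {
      abort("Transmittance geometry requires finite `thickness` > 0.")
    }
    rho <- lateral_offset
  }
  structure(list(mode = mode, rho = rho, thickness = thickness,
                 lateral_offset = lateral_offset),
            class = "tdb_geometry")
}

#' Optical medium model
#'
#' Derived diffusion quantities for a homogeneous medium of refractive index
#' `n`: light speed v = c/n, boundary reflection factor A(n) from the
#' internal-reflection approximation r_d = -1.440/n^2 + 0.710/n + 0.668 +
#' 0.0636 n, A = (1+r_d)/(1-r_d). The diffusion coefficient D = 1/(3 mu_s')
#' is absorption-independent, which keeps the Beer-Lambert factorization of
#' the time-domain Green's function exact.
#'
#' @param n Tissue refractive index (default 1.4).
#' @param n_out Refractive index of the outer medium (default 1, air).
#' @export
medium_model <- function(n = 1.4, n_out = 1) {
  if (n <= 0 || n_out <= 0) abort("Refractive indices must be positive.")
  nr <- n / n_out
  rd <- -1.440 / nr^2 + 0.710 / nr + 0.668 + 0.0636 * nr
  structure(list(n = n, v = .c_cm_ns / n, A = (1 + rd) / (1 - rd)),
            class = "tdb_medium_model")
}

#' Time-resolved diffuse reflectance / transmittance forward model
#'
#' Method-of-images solution of the time-dependent diffusion equation with
#' extrapolated boundary conditions. For the semi-infinite half-space
#' (reflectance) a single dipole pair (source at depth z0 = 1/mu_s', image at
#' -(z0 + 2 ze), ze = 2 A D) is exact; for the slab (transmittance, or
#' reflectance off a finite slab) symmetric image pairs are added until the
#' last pair changes every channel by less than `tol` relative (cap
#' `max_pairs`). Absorption enters exactly as exp(-mu_a v t). The returned
#' curve is a per-channel photon-current density in arbitrary amplitude
#' units (amplitude is always a free parameter in fitting).
#'
#' @param mua Absorption coefficient (cm^-1), >= 0.
#' @param musp Reduced scattering coefficient (cm^-1), > 0.
#' @param geometry A [geometry()].
#' @param medium A [medium_model()].
#' @param axis A [time_axis()].
#' @param tol,max_pairs Image-series truncation control (slab only).
#' @return Numeric vector over channels; identically 0 for t <= 0.
#' @export
td_forward <- function(mua, musp, geometry, medium = medium_model(),
                       axis = time_axis(), tol = 1e-9, max_pairs = 50) {
  stopifnot(inherits(geometry, "tdb_geometry"),
            inherits(medium, "tdb_medium_model"),
            inherits(axis, "tdb_time_axis"))
  if (!is.finite(mua) || mua < 0) abort("`mua` must be >= 0.")
  if (!is.finite(musp) || musp <= 0) abort("`musp` must be > 0.")

  t <- axis_times(axis)
  pos <- t > 0
  out <- numeric(length(t))
  if (!any(pos)) return(out)
  tp <- t[pos]

  v <- medium$v
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  ze <- 2 * medium$A * D
  denom4 <- 4 * D * v * tp
  rho <- geometry$rho
  common <- exp(-mua * v * tp - rho^2 / denom4) /
    (2 * (4 * pi * D * v)^(3 / 2) * tp^(5 / 2))

  zterm <- function(z) z * exp(-z^2 / denom4)

  if (geometry$mode == "reflectance" && !is.finite(geometry$thickness)) {
    series <- zterm(z0) + zterm(z0 + 2 * ze)
  } else {
    s <- geometry$thickness
    series <- numeric(length(tp))
    add_m <- function(m) {
      if (geometry$mode == "transmittance") {
        z1 <- s * (1 - 2 * m) - 4 * m * ze - z0
        z2 <- s * (1 - 2 * m) - (4 * m - 2) * ze + z0
        zterm(z1) - zterm(z2)
      } else {
        z3 <- -2 * m * s - 4 * m * ze - z0
        z4 <- -2 * m * s - (4 * m - 2) * ze + z0
        zterm(z4) - zterm(z3)
      }
    }
    series <- add_m(0L)
    converged <- FALSE
    for (m in seq_len(max_pairs)) {
      incr <- add_m(m) + add_m(-m)
      series <- series + incr
      if (max(abs(incr) / pmax(abs(series), .Machine$double.xmin)) < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      abort(sprintf("Image series did not converge within %d pairs.", max_pairs))
    }
  }

  out[pos] <- pmax(common * series, 0)
  out
}

#' Steady-state (CW) diffuse reflectance closed form
#'
#' Time integral of the semi-infinite time-resolved reflectance: the
#' extrapolated-boundary dipole expression
#' R(rho) = (1/4pi) [ z0 (mueff + 1/r1) e^{-mueff r1}/r1^2 +
#' (z0+2ze)(mueff + 1/r2) e^{-mueff r2}/r2^2 ], mueff = sqrt(3 mua musp).
#' Used as an independent quadrature oracle for [td_forward()].
#'
#' @inheritParams td_forward
#' @param rho Source-detector distance (cm).
#' @export
cw_reflectance <- function(mua, musp, rho, medium = medium_model()) {
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  ze <- 2 * medium$A * D
  mueff <- sqrt(mua / D)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * ze)^2 + rho^2)
  (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
     (z0 + 2 * ze) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
}

#' Convolve a model curve with the instrument response function
#'
#' Discrete linear convolution scaled by the channel width, truncated
#' causally to the axis length, so that a unit-area IRF preserves the model's
#' area when no tail truncation occurs. Linear in both arguments.
#'
#' @param model Numeric model curve over the axis channels.
#' @param irf Numeric IRF histogram over the same axis.
#' @param axis The shared [time_axis()].
#' @return Numeric vector of length `axis$n_channels`.
#' @export
convolve_with_irf <- function(model, irf, axis) {
  n <- axis$n_channels
  if (length(model) != n || length(irf) != n) {
    abort("`model` and `irf` must both live on the shared time axis.")
  }
  np <- 2L * n
  full <- Re(fft(fft(c(model, numeric(n))) * fft(c(irf, numeric(n))),
                 inverse = TRUE)) / np
  full[seq_len(n)] * axis$dt
}

#' Determine the fit window of a histogram
#'
#' The fitting range runs from 80% of the pulse peak on the leading edge to
#' 5% of the peak on the falling edge: the start is the first channel at or
#' before the (first) peak with counts >= 0.8 max, the end the last channel
#' at or after the peak with counts >= 0.05 max (clamped to the last channel
#' when the histogram never falls below 5%).
#'
#' @param counts Non-negative histogram with a strictly positive maximum.
#' @param lead_frac,tail_frac Threshold fractions of the peak (defaults 0.8
#'   and 0.05).
#' @param min_channels Minimum admissible window length.
#' @return A list with integer `start_index` and `end_index` (inclusive,
#'   1-based), of class `"tdb_fit_window"`.
#' @export
determine_fit_window <- function(counts, lead_frac = 0.8, tail_frac = 0.05,
                                 min_channels = 10) {
  if (length(counts) == 0 || max(counts) <= 0) {
    abort("Histogram must have a strictly positive maximum.")
  }
  peak <- which.max(counts)  # first channel attaining the max
  lead <- which(counts[seq_len(peak)] >= lead_frac * counts[peak])
  start <- min(lead)
  tail_ok <- which(counts >= tail_frac * counts[peak])
  end <- max(tail_ok[tail_ok >= peak])
  if (end - start + 1 < min_channels) {
    abort(sprintf("Fit window has %d channels; at least %d required.",
                  end - start + 1, min_channels))
  }
  structure(list(start_index = start, end_index = end),
            class = "tdb_fit_window")
}

#' A single-wavelength photon time-of-flight histogram
#'
#' @param wavelength Wavelength (nm).
#' @param counts Non-negative integer photon counts per channel.
#' @param axis The [time_axis()] the counts live on.
#' @export
dtof <- function(wavelength, counts, axis) {
  stopifnot(inherits(axis, "tdb_time_axis"))
  if (length(counts) != axis$n_channels) {
    abort("`counts` length must equal the axis channel count.")
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  structure(list(wavelength = wavelength, counts = counts, time_axis = axis,
                 total_counts = sum(counts)),
            class = "tdb_dtof")
}

#' A 51-wavelength spectral acquisition
#'
#' One probing configuration's full spectrum: 51 DTOFs on the 600-1100 nm
#' grid (10 nm steps), the measured IRF, the geometry, and protocol metadata
#' (subject / breast / posture / position labels).
#'
#' @param dtofs List of 51 [dtof()]s, wavelengths 600, 610, ..., 1100 nm.
#' @param irf Numeric IRF histogram on the shared axis.
#' @param geometry A [geometry()].
#' @param metadata Named list of labels.
#' @export
spectral_acquisition <- function(dtofs, irf, geometry, metadata = list()) {
  wl <- vapply(dtofs, function(d) d$wavelength, numeric(1))
  if (length(dtofs) != 51 || !isTRUE(all.equal(wl, seq(600, 1100, 10)))) {
    abort("An acquisition needs exactly 51 DTOFs on the 600:10:1100 nm grid.")
  }
  axis <- dtofs[[1]]$time_axis
  if (!all(vapply(dtofs, function(d) same_axis(d$time_axis, axis), logical(1)))) {
    abort("All DTOFs must share one time axis.")
  }
  if (length(irf) != axis$n_channels) {
    abort("IRF must live on the shared time axis.")
  }
  structure(list(dtofs = dtofs, irf = irf, geometry = geometry,
                 metadata = metadata, time_axis = axis),
            class = "tdb_spectral_acquisition")
}

#' @export
print.tdb_spectral_acquisition <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<spectral acquisition: %s%s, %d x %d channels>\n",
    x$geometry$mode,
    if (x$geometry$mode == "reflectance") sprintf(" rho=%g cm", x$geometry$rho)
    else sprintf(" thickness=%g cm", x$geometry$thickness),
    length(x$dtofs), x$time_axis$n_channels
  ))
  if (length(md)) {
    cat("  ", paste(names(md), unlist(md), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Synthetic instrument response function
#'
#' A Gaussian pulse (default FWHM 150 ps) convolved with a single-exponential
#' detector tail (default tau 100 ps), delayed by `delay` ns and
#' area-normalized so that sum(irf) * dt = 1.
#'
#' @param axis A [time_axis()].
#' @param fwhm_ps Gaussian FWHM (ps).
#' @param tail_tau_ps Exponential tail time constant (ps).
#' @param delay Peak delay from the axis origin (ns).
#' @return Numeric vector over the axis channels.
#' @export
synthetic_irf <- function(axis, fwhm_ps = 150, tail_tau_ps = 100, delay = 1) {
  t <- axis_times(axis)
  sig <- fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
  gauss <- exp(-(t - delay)^2 / (2 * sig^2))
  tau <- tail_tau_ps / 1000
  tail <- exp(-pmax(t - t[1], 0) / tau)
  irf <- convolve_with_irf(gauss, tail, axis)
  irf / (sum(irf) * axis$dt)
}
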