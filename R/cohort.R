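#' Cohort calibration marginals
#'
#' Per-configuration marginal means and standard deviations of the tissue
#' constituents used by the synthetic cohort generator. The supine
#' rho = 3 cm quadrant marginals are the anchor (water 314/279/228, lipid
#' 602/653/711, collagen 67.2/64.8/52.2 mg/cm^3 across outer/lower/inner,
#' with their SDs); 2 cm marginals are obtained by scaling with the overall
#' 2 cm : 3 cm ratios (water 248:267, lipid 713:666, collagen 49.4:57.8,
#' SDs likewise), sitting reflectance reuses the inner-quadrant marginals
#' (the sitting configuration probes more adipose, inner-quadrant-like
#' tissue), and transmittance uses the position-averaged 3 cm marginals.
#' Blood and scattering truths, which have no printed per-configuration
#' values, default to tHb ~ N(15, 5) uM truncated above 2, SO2 ~
#' N(0.75, 0.08) in \[0.4, 1\], a ~ N(12, 3) cm^-1 truncated above 1;
#' compression reduces transmittance tHb by x0.7 and raises transmittance
#' a by x1.2.
#'
#' @return A tibble with columns `component`, `posture`, `position`,
#'   `distance_cm`, `mode`, `mean`, `sd`.
#' @export
cohort_calibration <- function() {
  quad3 <- tibble(
    component = rep(c("water", "lipid", "collagen"), each = 3),
    position = rep(c("O", "L", "I"), 3),
    mean = c(314, 279, 228, 602, 653, 711, 67.2, 64.8, 52.2),
    sd = c(189, 180, 145, 238, 227, 188, 30.5, 32.0, 32.6)
  )
  ratio <- tibble(
    component = c("water", "lipid", "collagen"),
    mean_ratio = c(248 / 267, 713 / 666, 49.4 / 57.8),
    sd_ratio = c(155 / 171, 166 / 216, 28.4 / 30.6)
  )
  quad2 <- dplyr::left_join(quad3, ratio, by = "component")
  quad2 <- dplyr::mutate(quad2, mean = .data$mean * .data$mean_ratio,
                         sd = .data$sd * .data$sd_ratio,
                         mean_ratio = NULL, sd_ratio = NULL)
  supine <- dplyr::bind_rows(
    dplyr::mutate(quad3, distance_cm = 3),
    dplyr::mutate(quad2, distance_cm = 2)
  )
  supine <- dplyr::mutate(supine, posture = "supine", mode = "reflectance")

  sit_base <- dplyr::filter(supine, .data$position == "I")
  sitting <- dplyr::mutate(sit_base, posture = "sitting", position = "CC")

  trans3 <- dplyr::summarise(dplyr::group_by(quad3, .data$component),
                             mean = mean(.data$mean), sd = mean(.data$sd),
                             .groups = "drop")
  trans <- dplyr::mutate(trans3, posture = "sitting", position = "CC",
                         distance_cm = NA_real_, mode = "transmittance")

  blood <- function(posture, position, distance_cm, mode, trans_scale = 1) {
    tibble(
      component = c("thb", "so2", "a"),
      posture = posture, position = position, distance_cm = distance_cm,
      mode = mode,
      mean = c(15, 0.75, 12) * c(trans_scale * 0.7 + (1 - trans_scale) * 1, 1,
                                 trans_scale * 1.2 + (1 - trans_scale) * 1),
      sd = c(5 * ifelse(trans_scale == 1, 0.7, 1), 0.08, 3)
    )
  }
  cfgs <- dplyr::distinct(
    dplyr::bind_rows(supine, sitting, trans),
    .data$posture, .data$position, .data$distance_cm, .data$mode
  )
  blood_all <- purrr::pmap_dfr(cfgs, function(posture, position, distance_cm, mode) {
    blood(posture, position, distance_cm, mode,
          trans_scale = as.numeric(mode == "transmittance"))
  })
  dplyr::bind_rows(supine, sitting, trans, blood_all)
}

# Moment-matched truncated normal: find pre-truncation (m, s) such that the
# N(m, s) truncated to [lower, upper] has the requested mean and sd.
truncnorm_solve <- function(mean, sd, lower = 0, upper = Inf) {
  moments <- function(m, s) {
    al <- (lower - m) / s
    au <- (upper - m) / s
    Z <- pnorm(au) - pnorm(al)
    phi_l <- stats::dnorm(al)
    phi_u <- stats::dnorm(au)
    mu <- m + s * (phi_l - phi_u) / Z
    al_t <- if (is.finite(al)) al * phi_l else 0
    au_t <- if (is.finite(au)) au * phi_u else 0
    v <- s^2 * (1 + (al_t - au_t) / Z - ((phi_l - phi_u) / Z)^2)
    c(mu, sqrt(v))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 / sd^2 + (mm[2] - sd)^2 / sd^2
  }
  sol <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(m = sol$par[1], s = exp(sol$par[2]))
}

# Inverse-CDF draw from the truncated normal through a standard-normal
# latent (Gaussian copula): preserves the latent correlation structure
# while matching the truncated marginal exactly.
truncnorm_from_latent <- function(x, m, s, lower = 0, upper = Inf) {
  pl <- pnorm((lower - m) / s)
  pu <- pnorm((upper - m) / s)
  u <- pnorm(x)
  m + s * qnorm(pl + u * (pu - pl))
}

#' Generator configuration
#'
#' Latent-factor loadings and moment-matched marginal parameters for the
#' cohort generator. Each component's per-configuration value is driven by a
#' subject density latent z (loading alpha), a component-specific subject
#' latent (beta), and a per-position residual (gamma), with
#' alpha^2 + beta^2 + gamma^2 = 1; a small jitter (tau = 0.15) decorrelates
#' breasts and the two inter-fiber distances. Quadrant-to-quadrant
#' correlation of one component is (1 - tau^2)(alpha^2 + beta^2) ~ 0.78.
#' Transmittance values load on the subject latents only (the compressed
#' whole-breast measurement averages out position structure).
#'
#' @param calibration Output of [cohort_calibration()].
#' @param tau Breast/distance jitter loading.
#' @return A list used by [sample_subject()] and [sample_cohort()].
#' @export
cohort_config <- function(calibration = cohort_calibration(), tau = 0.15) {
  loadings <- tibble(
    component = c("water", "lipid", "collagen", "thb", "so2", "a"),
    alpha2 = c(0.6, 0.6, 0.6, 0.3, 0, 0.2),
    beta2 = c(0.2, 0.2, 0.2, 0.5, 0.8, 0.6),
    sgn = c(1, -1, 1, 1, 1, 1)
  )
  loadings$gamma2 <- 1 - loadings$alpha2 - loadings$beta2
  lims <- tibble(
    component = c("water", "lipid", "collagen", "thb", "so2", "a"),
    lower = c(0, 0, 0, 2, 0.4, 1),
    upper = c(Inf, Inf, Inf, Inf, 1, Inf)
  )
  cal <- dplyr::left_join(calibration, lims, by = "component")
  ms <- purrr::pmap_dfr(
    cal[, c("mean", "sd", "lower", "upper")],
    function(mean, sd, lower, upper) {
      p <- truncnorm_solve(mean, sd, lower, upper)
      tibble(m = p[["m"]], s = p[["s"]])
    }
  )
  list(
    calibration = dplyr::bind_cols(cal, ms),
    loadings = loadings,
    tau = tau,
    # scattering-power model: b = b0 - k * lipid_fraction + noise
    # the -0.12 depth offset dominates the lipid-mediated +0.05 so the net
    # 2 cm -> 3 cm change in b is negative, as observed in vivo
    b0 = 1.6, b_k = 1.2, b_sd_subject = 0.06, b_sd_config = 0.05,
    b_offset_3cm = -0.12, b_range = c(0.2, 1.6),
    thickness = list(mean = 19.7, sd = 9.8, lower = 11, upper = 37,
                     compression = 0.85)
  )
}

with_preserved_seed <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Sample one synthetic subject
#'
#' Draws a subject's ground-truth tissue composition for every protocol
#' configuration (2 breasts x \{sitting reflectance at 2 and 3 cm,
#' compressed transmittance\} + \{supine outer/lower/inner x 2 and 3 cm\} =
#' 18 entries) from truncated normals calibrated to the cohort marginals,
#' through a latent Gaussian factor model (see [cohort_config()]). The
#' scattering power b is negatively coupled to the lipid fraction, and the
#' subject's compressed breast thickness is drawn once per subject.
#' Identical seed gives a bit-identical record.
#'
#' @param seed Integer seed.
#' @param archetype Optional `"adipose"`, `"mixed"` or `"dense"`; restricts
#'   the density latent to its lower / middle / upper tercile.
#' @param config A [cohort_config()].
#' @return A `"tdb_subject"`: list with `subject_id`, `archetype`, `seed`,
#'   `z` (density latent), `thickness_mm`, `compressed_thickness_cm`, and
#'   the 18-row `truth` tibble of [tissue_composition()] columns.
#' @export
sample_subject <- function(seed, archetype = NULL, config = cohort_config()) {
  if (!is.null(archetype)) {
    archetype <- match.arg(archetype, c("adipose", "mixed", "dense"))
  }
  with_preserved_seed({
    set.seed(seed)
    u <- switch(archetype %||% "any",
      adipose = runif(1, 0, 1 / 3),
      mixed = runif(1, 1 / 3, 2 / 3),
      dense = runif(1, 2 / 3, 1),
      any = runif(1)
    )
    z <- qnorm(u)

    comps <- config$loadings$component
    u_c <- stats::setNames(rnorm(length(comps)), comps)
    positions <- c("O", "L", "I", "CC")
    e_cp <- matrix(rnorm(length(comps) * length(positions)),
                   nrow = length(comps),
                   dimnames = list(comps, positions))

    cal <- config$calibration
    tau <- config$tau
    ld <- config$loadings

    rows <- dplyr::distinct(cal, .data$posture, .data$position,
                            .data$distance_cm, .data$mode)
    truth <- purrr::pmap_dfr(rows, function(posture, position, distance_cm, mode) {
      out <- tibble(breast = c("L", "R"), posture = posture,
                    position = position, distance_cm = distance_cm,
                    mode = mode)
      for (cc in comps) {
        li <- ld[ld$component == cc, ]
        core <- if (mode == "transmittance") {
          (sqrt(li$alpha2) * li$sgn * z + sqrt(li$beta2) * u_c[[cc]]) /
            sqrt(li$alpha2 + li$beta2)
        } else {
          sqrt(li$alpha2) * li$sgn * z + sqrt(li$beta2) * u_c[[cc]] +
            sqrt(li$gamma2) * e_cp[cc, position]
        }
        lat <- sqrt(1 - tau^2) * core + tau * rnorm(2)
        mrow <- cal[cal$component == cc & cal$posture == posture &
                      cal$position == position & cal$mode == mode &
                      (is.na(distance_cm) | cal$distance_cm %in% distance_cm), ]
        out[[cc]] <- truncnorm_from_latent(lat, mrow$m[1], mrow$s[1],
                                           mrow$lower[1], mrow$upper[1])
      }
      out
    })

    # scattering power from the lipid fraction, plus a per-subject and a
    # per-configuration noise term; small negative offset at rho = 3 cm
    # (deeper probing retrieves slightly lower b)
    b_subj <- rnorm(1, 0, config$b_sd_subject)
    truth$b <- config$b0 - config$b_k * truth$lipid / 1000 + b_subj +
      rnorm(nrow(truth), 0, config$b_sd_config) +
      ifelse(!is.na(truth$distance_cm) & truth$distance_cm == 3,
             config$b_offset_3cm, 0)
    truth$b <- pmin(pmax(truth$b, config$b_range[1]), config$b_range[2])

    th <- config$thickness
    x_th <- 0.5 * (-z) + sqrt(0.75) * rnorm(1)
    tp <- truncnorm_solve(th$mean, th$sd, th$lower, th$upper)
    thickness_mm <- truncnorm_from_latent(x_th, tp[["m"]], tp[["s"]],
                                          th$lower, th$upper)

    truth <- dplyr::mutate(
      truth,
      c_hbo2 = .data$thb * .data$so2,
      c_hb = .data$thb * (1 - .data$so2),
      c_water = .data$water, c_lipid = .data$lipid,
      c_collagen = .data$collagen,
      background = 0.018,
      thickness_cm = dplyr::if_else(.data$mode == "transmittance",
                                    th$compression * thickness_mm / 10,
                                    NA_real_)
    )
    truth <- dplyr::select(truth, "breast", "posture", "position",
                           "distance_cm", "mode", "thickness_cm",
                           "c_hbo2", "c_hb", "c_water", "c_lipid",
                           "c_collagen", "background", "a", "b",
                           "thb", "so2")

    structure(
      list(subject_id = sprintf("S%06d", seed), archetype = archetype,
           seed = seed, z = z, thickness_mm = thickness_mm,
           truth = truth),
      class = "tdb_subject"
    )
  })
}

#' @export
print.tdb_subject <- function(x, ...) {
  cat(sprintf("<synthetic subject %s (z = %.2f%s), %d truth entries>\n",
              x$subject_id, x$z,
              if (is.null(x$archetype)) "" else paste0(", ", x$archetype),
              nrow(x$truth)))
  invisible(x)
}

#' Sample a synthetic cohort
#'
#' @param n Number of subjects.
#' @param seed Master seed; per-subject seeds are derived from it, so one
#'   master seed reproduces the whole cohort bit-exactly.
#' @param archetype_mix Optional proportions `c(adipose, mixed, dense)`; by
#'   default the density latent is unrestricted standard normal.
#' @param config A [cohort_config()].
#' @return List of [sample_subject()] records.
#' @export
sample_cohort <- function(n, seed, archetype_mix = NULL,
                          config = cohort_config()) {
  with_preserved_seed({
    set.seed(seed)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    archetypes <- if (is.null(archetype_mix)) {
      rep(list(NULL), n)
    } else {
      as.list(sample(c("adipose", "mixed", "dense"), n, replace = TRUE,
                     prob = archetype_mix))
    }
    purrr::map2(sub_seeds, archetypes,
                function(s, a) sample_subject(s, a, config))
  })
}

#' Truth-level parameter table of a cohort
#'
#' Flattens the subjects' ground-truth composition tables into one
#' parameter table (one row per subject x breast x configuration) with the
#' derived blood parameters and density indices appended -- the same shape
#' the fitting pipeline produces, usable directly by the statistics layer.
#'
#' @param subjects List of [sample_subject()] records.
#' @return A tibble.
#' @export
cohort_parameter_table <- function(subjects) {
  tab <- purrr::map_dfr(subjects, function(s) {
    dplyr::mutate(s$truth, subject = s$subject_id, .before = 1)
  })
  add_derived_indices(tab)
}

#' Simulate a noisy DTOF from a tissue composition
#'
#' Full synthetic measurement chain for one wavelength: compose mu_a and
#' mu_s' from the composition, evaluate the time-resolved diffusion model,
#' convolve with the IRF, scale the curve to the target total count
#' (emulating a fixed integration time), and draw per-channel Poisson
#' counts.
#'
#' @param comp A [tissue_composition()].
#' @param wavelength Wavelength (nm).
#' @param geometry A [geometry()].
#' @param library A [chromophore_library()].
#' @param medium A [medium_model()].
#' @param axis A [time_axis()].
#' @param irf IRF histogram on `axis`.
#' @param counts_target Expected total counts (0 gives an all-zero DTOF).
#' @param seed Optional seed for the Poisson draw.
#' @param noiseless If `TRUE`, skip the Poisson draw and round the scaled
#'   curve deterministically (used by noiseless round-trip oracles).
#' @return A [dtof()].
#' @export
simulate_dtof <- function(comp, wavelength, geometry,
                          library = default_chromophore_library(),
                          medium = medium_model(), axis = time_axis(),
                          irf = synthetic_irf(axis), counts_target = 1e6,
                          seed = NULL, noiseless = FALSE) {
  if (counts_target < 0) abort("`counts_target` must be >= 0.")
  mua <- compose_mua(comp, library, wavelength)
  musp <- compose_musp(comp$a, comp$b, wavelength, comp$lambda0)
  # FFT convolution can leave O(eps) negative ringing in empty channels
  curve <- pmax(model_curve(mua, musp, geometry, medium, axis, irf), 0)
  tot <- sum(curve)
  lam <- if (tot > 0 && counts_target > 0) curve / tot * counts_target else 0 * curve
  counts <- if (noiseless) {
    lam
  } else if (is.null(seed)) {
    rpois(length(lam), lam)
  } else {
    with_preserved_seed({
      set.seed(seed)
      rpois(length(lam), lam)
    })
  }
  dtof(wavelength, counts, axis)
}

#' Simulate a full 51-wavelength acquisition
#'
#' @inheritParams simulate_dtof
#' @param metadata Metadata labels stored in the acquisition.
#' @return A [spectral_acquisition()].
#' @export
simulate_acquisition <- function(comp, geometry,
                                 library = default_chromophore_library(),
                                 medium = medium_model(), axis = time_axis(),
                                 irf = synthetic_irf(axis),
                                 counts_target = 1e6, seed = NULL,
                                 noiseless = FALSE, metadata = list()) {
  run <- function() {
    dtofs <- lapply(seq(600, 1100, 10), function(wl) {
      simulate_dtof(comp, wl, geometry, library, medium, axis, irf,
                    counts_target, seed = NULL, noiseless = noiseless)
    })
    spectral_acquisition(dtofs, irf, geometry, metadata)
  }
  if (is.null(seed)) run() else with_preserved_seed({
    set.seed(seed)
    run()
  })
}

#' Simulate a complete measurement session
#'
#' Emits the protocol's 18 acquisitions for one subject: per breast, the
#' sitting sequence (reflectance at 2 and 3 cm, then compressed
#' transmittance in cranio-caudal view) and the supine sequence
#' (outer/lower/inner quadrants at 2 and 3 cm). Transmittance uses the
#' subject's compressed thickness and its compression-reduced truth; dense
#' subjects get attenuated transmittance counts, emulating the SNR failures
#' seen for the densest breasts.
#'
#' @param subject A [sample_subject()] record.
#' @param library,medium,axis,irf Measurement chain pieces.
#' @param counts_reflectance,counts_transmittance Per-DTOF expected total
#'   counts.
#' @param noiseless Skip Poisson noise.
#' @return A `"tdb_session"`: list with `subject_id`, `seed`, and 18
#'   acquisitions.
#' @export
simulate_session <- function(subject,
                             library = default_chromophore_library(),
                             medium = medium_model(), axis = time_axis(),
                             irf = synthetic_irf(axis),
                             counts_reflectance = 1e6,
                             counts_transmittance = 1e5,
                             noiseless = FALSE) {
  stopifnot(inherits(subject, "tdb_subject"))
  truth <- subject$truth
  if (nrow(truth) != 18) abort("Subject truth table is incomplete.")
  # dense breasts attenuate the transmitted signal strongly
  trans_atten <- 10^(-1.5 * max(subject$z - 1, 0))
  acqs <- lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    comp <- tissue_composition(
      c_hbo2 = row$c_hbo2, c_hb = row$c_hb, c_water = row$c_water,
      c_lipid = row$c_lipid, c_collagen = row$c_collagen,
      background = row$background, a = row$a, b = row$b
    )
    geom <- if (row$mode == "transmittance") {
      geometry("transmittance", thickness = row$thickness_cm)
    } else {
      geometry("reflectance", rho = row$distance_cm)
    }
    target <- if (row$mode == "transmittance") {
      counts_transmittance * trans_atten
    } else {
      counts_reflectance
    }
    simulate_acquisition(
      comp, geom, library, medium, axis, irf, counts_target = target,
      seed = subject$seed + i, noiseless = noiseless,
      metadata = list(subject = subject$subject_id, breast = row$breast,
                      posture = row$posture, position = row$position,
                      distance_cm = row$distance_cm, mode = row$mode)
    )
  })
  structure(list(subject_id = subject$subject_id, seed = subject$seed,
                 acquisitions = acqs),
            class = "tdb_session")
}

#' @export
print.tdb_session <- function(x, ...) {
  cat(sprintf("<session %s: %d acquisitions>\n", x$subject_id,
              length(x$acquisitions)))
  invisible(x)
}
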