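# One mid-size cohort shared across the statistical checks of this file.
local_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sample_cohort(1000, seed = 20240819)
    }
    cache
  }
})

test_that("subject sampling is seed-deterministic and archetype-aware", {
  cfg <- cohort_config()
  s1 <- sample_subject(123, config = cfg)
  s2 <- sample_subject(123, config = cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$thickness_mm, s2$thickness_mm)
  expect_equal(nrow(s1$truth), 18)

  adipose <- sample_subject(5, "adipose", cfg)
  dense <- sample_subject(5, "dense", cfg)
  expect_lt(adipose$z, qnorm(1 / 3))
  expect_gt(dense$z, qnorm(2 / 3))
  expect_error(sample_subject(5, "fibrous", cfg))

  coh_a <- sample_cohort(4, seed = 9, config = cfg)
  coh_b <- sample_cohort(4, seed = 9, config = cfg)
  expect_identical(cohort_parameter_table(coh_a), cohort_parameter_table(coh_b))
})

test_that("cohort marginals reproduce the calibrated quadrant composition", {
  tab <- cohort_parameter_table(local_cohort())
  s3 <- dplyr::filter(tab, posture == "supine", distance_cm == 3)
  by_pos <- dplyr::summarise(
    dplyr::group_by(s3, position),
    water = mean(c_water), lipid = mean(c_lipid), collagen = mean(c_collagen),
    .groups = "drop"
  )
  outer <- dplyr::filter(by_pos, position == "O")
  # calibration targets with a +-15 mg/cm^3 allowance (a few standard
  # errors of the cohort mean at this size)
  expect_lt(abs(outer$water - 314), 15)
  expect_lt(abs(outer$lipid - 602), 18)
  expect_lt(abs(outer$collagen - 67.2), 3)

  inner <- dplyr::filter(by_pos, position == "I")
  expect_gt(outer$water, inner$water)
  expect_lt(outer$lipid, inner$lipid)

  by_dist <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tab, mode == "reflectance"), distance_cm),
    water = mean(c_water), lipid = mean(c_lipid), .groups = "drop"
  )
  expect_gt(by_dist$lipid[by_dist$distance_cm == 2],
            by_dist$lipid[by_dist$distance_cm == 3])
  expect_lt(by_dist$water[by_dist$distance_cm == 2],
            by_dist$water[by_dist$distance_cm == 3])
})

test_that("scattering power is negatively coupled to lipid content", {
  tab <- cohort_parameter_table(local_cohort())
  expect_lt(cor(tab$c_lipid, tab$b), -0.5)
})

test_that("DTOF simulation is seeded, Poisson-consistent and handles zero exposure", {
  lib <- test_library()
  ax <- test_axis_small()
  irf <- synthetic_irf(ax)
  comp <- typical_composition()
  geom <- geometry("reflectance", rho = 2)

  z <- simulate_dtof(comp, 800, geom, lib, axis = ax, irf = irf,
                     counts_target = 0, seed = 1)
  expect_true(all(z$counts == 0))

  d1 <- simulate_dtof(comp, 800, geom, lib, axis = ax, irf = irf,
                      counts_target = 1e5, seed = 77)
  d2 <- simulate_dtof(comp, 800, geom, lib, axis = ax, irf = irf,
                      counts_target = 1e5, seed = 77)
  expect_identical(d1$counts, d2$counts)

  # law of large numbers: replicate mean tracks the noiseless intensity
  noiseless <- simulate_dtof(comp, 800, geom, lib, axis = ax, irf = irf,
                             counts_target = 1e5, noiseless = TRUE)
  reps <- vapply(1:200, function(i) {
    simulate_dtof(comp, 800, geom, lib, axis = ax, irf = irf,
                  counts_target = 1e5, seed = 1000 + i)$counts
  }, numeric(ax$n_channels))
  lam <- noiseless$counts
  keep <- lam > 1
  zscore <- (rowMeans(reps)[keep] - lam[keep]) / sqrt(lam[keep] / 200)
  # channel-wise |z| < 3 up to the expected handful of random exceedances
  expect_lt(mean(abs(zscore) > 3), 0.02)
})

test_that("a session carries the full 18-acquisition protocol", {
  ax <- test_axis_small()
  sub <- sample_subject(42)
  ses <- simulate_session(sub, axis = ax, irf = synthetic_irf(ax),
                          counts_reflectance = 1e4, counts_transmittance = 1e3)
  expect_equal(length(ses$acquisitions), 18)
  expect_true(all(vapply(ses$acquisitions,
                         function(a) length(a$dtofs) == 51, logical(1))))
  md <- purrr::map_dfr(ses$acquisitions, function(a) {
    tibble::tibble(posture = a$metadata$posture, mode = a$geometry$mode)
  })
  expect_equal(sum(md$mode == "transmittance"), 2)
  expect_true(all(md$posture[md$mode == "transmittance"] == "sitting"))
  expect_true(all(md$mode[md$posture == "supine"] == "reflectance"))
  expect_equal(sum(md$posture == "supine"), 12)
})

test_that("the pipeline round-trips a sampled subject's composition (master oracle)", {
  lib <- test_library()
  ax <- test_axis()
  irf <- synthetic_irf(ax)
  sub <- sample_subject(314)
  row <- dplyr::filter(sub$truth, posture == "supine", position == "O",
                       distance_cm == 3, breast == "R")
  truth <- tissue_composition(row$c_hbo2, row$c_hb, row$c_water, row$c_lipid,
                              row$c_collagen, background = row$background,
                              a = row$a, b = row$b)
  acq <- simulate_acquisition(truth, geometry("reflectance", rho = 3), lib,
                              axis = ax, irf = irf, noiseless = TRUE)
  fit <- spectral_fit(acq, lib, wavelengths = seq(600, 1100, 20))
  comp <- fit$composition
  for (fld in c("c_hbo2", "c_hb", "c_water", "c_lipid", "a", "b")) {
    expect_equal(comp[[fld]], truth[[fld]], tolerance = 0.01)
  }
  expect_equal(comp$c_collagen, truth$c_collagen, tolerance = 0.05)
})
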