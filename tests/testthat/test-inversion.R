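test_that("standard fit recovers noiseless optical properties to 1e-3", {
  ax <- test_axis()
  geom <- geometry("reflectance", rho = 3)
  med <- medium_model()
  irf <- synthetic_irf(ax)

  truth <- convolve_with_irf(td_forward(0.10, 10, geom, med, ax), irf, ax)
  counts <- round(pmax(truth, 0) / sum(pmax(truth, 0)) * 1e6)
  f <- standard_fit(dtof(800, counts, ax), irf, geom, med,
                    init = c(0.05, 15))
  expect_true(f$converged)
  expect_equal(f$mua, 0.10, tolerance = 1e-3)
  expect_equal(f$musp, 10, tolerance = 1e-3)

  # tidy/glance expose the result in broom shape
  td <- tidy(f)
  expect_equal(td$term, c("mua", "musp", "amplitude"))
  expect_true(all(c("objective_value", "converged") %in% names(glance(f))))
})

test_that("a fit started at the generating truth stays there", {
  ax <- test_axis_small()
  geom <- geometry("reflectance", rho = 2)
  med <- medium_model()
  irf <- synthetic_irf(ax)
  truth <- convolve_with_irf(td_forward(0.05, 10, geom, med, ax), irf, ax)
  counts <- round(pmax(truth, 0) / sum(pmax(truth, 0)) * 1e6)
  f <- standard_fit(dtof(800, counts, ax), irf, geom, med, init = c(0.05, 10))
  expect_true(f$converged)
  expect_lte(f$n_iterations, 5)
  expect_equal(f$mua, 0.05, tolerance = 1e-4)
})

test_that("low-SNR DTOFs are excluded with a reason, not an error", {
  ax <- test_axis_small()
  f <- standard_fit(dtof(800, rep(1, ax$n_channels), ax),
                    synthetic_irf(ax), geometry("reflectance", rho = 2))
  expect_true(f$excluded)
  expect_equal(f$exclusion_reason, "low_snr")
  expect_false(f$converged)
})

test_that("recovered properties are invariant to exposure scaling", {
  ax <- test_axis()
  geom <- geometry("reflectance", rho = 2)
  med <- medium_model()
  irf <- synthetic_irf(ax)
  truth <- convolve_with_irf(td_forward(0.07, 12, geom, med, ax), irf, ax)
  base <- pmax(truth, 0) / sum(pmax(truth, 0))
  f1 <- standard_fit(dtof(800, round(base * 1e5), ax), irf, geom, med)
  f2 <- standard_fit(dtof(800, round(base * 1e7), ax), irf, geom, med)
  expect_equal(f1$mua, f2$mua, tolerance = 5e-3)
  expect_equal(f1$musp, f2$musp, tolerance = 5e-3)
  expect_equal(f2$amplitude / f1$amplitude, 100, tolerance = 0.01)
})

test_that("spectral fit recovers a noiseless protocol-typical composition", {
  lib <- test_library()
  ax <- test_axis()
  irf <- synthetic_irf(ax)
  truth <- typical_composition()
  acq <- simulate_acquisition(truth, geometry("reflectance", rho = 3), lib,
                              axis = ax, irf = irf, counts_target = 1e6,
                              noiseless = TRUE)
  fit <- spectral_fit(acq, lib)
  expect_true(fit$converged)
  comp <- fit$composition
  expect_equal(comp$c_water, truth$c_water, tolerance = 0.01)
  expect_equal(comp$c_lipid, truth$c_lipid, tolerance = 0.01)
  expect_equal(comp$c_hbo2, truth$c_hbo2, tolerance = 0.01)
  expect_equal(comp$c_hb, truth$c_hb, tolerance = 0.01)
  expect_equal(comp$a, truth$a, tolerance = 0.01)
  expect_equal(comp$b, truth$b, tolerance = 0.01)
  expect_equal(comp$c_collagen, truth$c_collagen, tolerance = 0.05)
})

test_that("zero-collagen truth pins the collagen estimate at its bound", {
  lib <- test_library()
  ax <- test_axis()
  truth <- tissue_composition(15, 5, 300, 600, 0, background = 0.018,
                              a = 12, b = 0.8)
  acq <- simulate_acquisition(truth, geometry("reflectance", rho = 3), lib,
                              axis = ax, counts_target = 1e6,
                              noiseless = TRUE)
  fit <- spectral_fit(acq, lib, wavelengths = seq(600, 1100, 20))
  expect_lte(fit$composition$c_collagen, 1)
})

test_that("a free background term barely moves water, lipid and HbO2 when truth has none", {
  lib <- test_library()
  ax <- test_axis()
  truth <- tissue_composition(15, 5, 300, 600, 60, background = 0,
                              a = 12, b = 0.8)
  acq <- simulate_acquisition(truth, geometry("reflectance", rho = 3), lib,
                              axis = ax, counts_target = 2e5, seed = 31)
  fit <- spectral_fit(acq, lib, wavelengths = seq(600, 1100, 20))
  comp <- fit$composition
  expect_equal(comp$c_water, truth$c_water, tolerance = 0.05)
  expect_equal(comp$c_lipid, truth$c_lipid, tolerance = 0.05)
  expect_equal(comp$c_hbo2, truth$c_hbo2, tolerance = 0.05)
})

test_that("spectral fit refuses to run on too few usable wavelengths", {
  lib <- test_library()
  ax <- test_axis_small()
  acq <- simulate_acquisition(typical_composition(),
                              geometry("reflectance", rho = 2), lib,
                              axis = ax, counts_target = 10, seed = 3)
  expect_error(spectral_fit(acq, lib), "usable wavelengths")
})

test_that("spectral and standard fits agree on the mua spectrum of one noisy acquisition", {
  lib <- test_library()
  ax <- test_axis()
  truth <- typical_composition()
  acq <- simulate_acquisition(truth, geometry("reflectance", rho = 3), lib,
                              axis = ax, counts_target = 1e6, seed = 99)
  std <- standard_fit_spectrum(acq)
  fit <- spectral_fit(acq, lib)
  sel <- std$wavelength >= 700 & std$wavelength <= 900
  m_std <- std$mua[sel]
  m_spec <- fit$spectra$mua[fit$spectra$wavelength %in% std$wavelength[sel]]
  # dispersion of the standard fit around its own smooth trend
  trend <- stats::lowess(std$wavelength[sel], m_std, f = 0.3)$y
  disp <- sd(m_std - trend)
  expect_lt(max(abs(m_spec - m_std)), 3 * disp)
})
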