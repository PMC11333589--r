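test_that("pearson r and its t-transform p match hand values and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  p1 <- pearson_with_p(x, 2 * x + 1)
  expect_equal(p1$r, 1)
  expect_equal(p1$p, 0)

  p2 <- pearson_with_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(p2$r, 0.5)

  expect_equal(pearson_with_p(x, -x)$r, -1)

  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    ours <- pearson_with_p(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(ours$r, unname(ref$estimate))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
  expect_error(pearson_with_p(1:2, 2:1), "at least 3")
})

test_that("wilcoxon signed-rank is exact against full sign enumeration", {
  # n = 3, all positive: W+ = 6, p = 2 * (1/8)
  w <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(w$statistic, 6)
  expect_equal(w$p, 0.25)
  expect_equal(w$method, "exact")

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "All paired differences")

  # randomized instances, n <= 10, with and without ties
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    ours <- wilcoxon_signed_rank(x, y)
    oracle <- brute_wilcoxon(x, y)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p, oracle$p, tolerance = 1e-12)
  }

  # swapping the pair flips the statistic to its complement, p unchanged
  x <- c(3, 1, 4, 1, 5, 9, 2, 6); y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  ab <- wilcoxon_signed_rank(x, y)
  ba <- wilcoxon_signed_rank(y, x)
  n <- ab$n
  expect_equal(ab$statistic + ba$statistic, n * (n + 1) / 2)
  expect_equal(ab$p, ba$p)

  # large-n branch: normal approximation is close to the exact DP
  set.seed(14)
  x <- rnorm(40); y <- rnorm(40, 0.4)
  appr <- wilcoxon_signed_rank(x, y)
  exact <- wilcoxon_signed_rank(x, y, exact_max = 60)
  expect_equal(appr$method, "normal_approx")
  expect_equal(appr$p, exact$p, tolerance = 0.25)
})

test_that("bonferroni adjustment is the capped product, monotone and idempotent at the cap", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), m = 1), c(0.2, 0.9))

  p <- sort(runif(10))
  adj <- bonferroni_adjust(p, m = 10)
  expect_true(all(diff(adj) >= 0))
  expect_equal(bonferroni_adjust(adj[adj == 1], m = 10), adj[adj == 1])

  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(0.5, m = 0), ">= 1")
})

test_that("configuration correlations have the 7 x 4 report shape and detect identity data", {
  set.seed(5)
  values <- tibble::tibble(
    subject = sprintf("s%02d", 1:8),
    thb = runif(8, 10, 25), so2 = runif(8, 0.6, 0.9),
    c_lipid = runif(8, 400, 900), c_water = runif(8, 100, 500),
    c_collagen = runif(8, 20, 100), a = runif(8, 8, 16), b = runif(8, 0.4, 1.2)
  )
  tab <- toy_parameter_table(values)  # transmittance == reflectance values
  rep <- configuration_correlations(tab)
  expect_equal(nrow(rep), 28)
  expect_equal(sort(unique(paste(rep$posture, rep$distance_cm))),
               c("sitting 2", "sitting 3", "supine 2", "supine 3"))
  expect_true(all(abs(rep$r - 1) < 1e-12))
  expect_equal(attr(rep, "family_size"), 28)
  expect_equal(rep$p_adj, pmin(1, 28 * rep$p))

  # invariant to row order and to unit rescaling of a single parameter
  rep_shuf <- configuration_correlations(tab[sample(nrow(tab)), ])
  expect_equal(dplyr::arrange(as.data.frame(rep_shuf), parameter, posture, distance_cm),
               dplyr::arrange(as.data.frame(rep), parameter, posture, distance_cm))
  tab2 <- dplyr::mutate(tab, c_water = c_water * 1000)
  expect_equal(configuration_correlations(tab2)$r, rep$r)

  expect_error(configuration_correlations(dplyr::filter(tab, mode != "transmittance")),
               "transmittance")
})

test_that("paired comparison errors on identical configurations and is symmetric in p", {
  set.seed(6)
  values <- tibble::tibble(
    subject = sprintf("s%02d", 1:10),
    thb = runif(10, 10, 25), so2 = runif(10, 0.6, 0.9),
    c_lipid = runif(10, 400, 900), c_water = runif(10, 100, 500),
    c_collagen = runif(10, 20, 100), a = runif(10, 8, 16), b = runif(10, 0.4, 1.2)
  )
  tab <- toy_parameter_table(values, transform = function(v) v * 0.8)
  cfg_r <- list(posture = "supine", distance_cm = 3, mode = "reflectance")
  cfg_t <- list(mode = "transmittance")

  expect_error(paired_config_comparison(tab, cfg_r, cfg_r,
                                        parameters = "c_water"),
               "All paired differences")

  ab <- paired_config_comparison(tab, cfg_r, cfg_t, parameters = "c_water")
  ba <- paired_config_comparison(tab, cfg_t, cfg_r, parameters = "c_water")
  expect_equal(ab$p, ba$p)
  n <- ab$n
  expect_equal(ab$statistic + ba$statistic, n * (n + 1) / 2)
  # transmittance values are scaled down, so reflectance - transmittance > 0
  expect_gt(ab$mean_a, ab$mean_b)
})

test_that("density ranking is self-concordant and inverts lipid polarity", {
  # parameters engineered so every density-tracking column orders subjects
  # identically, while lipid increases with density (anti-anatomical)
  n <- 9
  values <- tibble::tibble(
    subject = sprintf("s%02d", 1:n),
    c_hbo2 = 10, c_hb = 5,
    c_water = seq(100, 500, length.out = n),
    c_lipid = seq(400, 900, length.out = n),      # increasing with density
    c_collagen = seq(20, 100, length.out = n),
    a = 12, b = seq(0.4, 1.2, length.out = n)
  )
  tab <- add_derived_indices(toy_parameter_table(values))
  dr <- density_ranking(tab)
  expect_equal(dr$subject_order, values$subject)  # ascending OI
  conc <- dr$concordance
  expect_true(all(conc$concordance[conc$parameter == "oi"] == 1))
  expect_true(all(conc$concordance[conc$parameter == "c_water"] == 1))
  # lipid is ranked on negated values: perfectly discordant here
  expect_true(all(conc$concordance[conc$parameter == "c_lipid"] == -1))

  expect_error(density_ranking(tab, reference = list(posture = "prone")),
               "no rows")
})
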