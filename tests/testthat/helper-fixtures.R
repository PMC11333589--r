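# Shared fixtures: a coarse 25.6 ns axis keeps forward evaluations cheap
# while spanning the full diffuse pulse at protocol-typical properties.

test_axis <- function(n = 1024, dt = 0.025) time_axis(0, dt, n)

test_axis_small <- function() time_axis(0, 0.05, 512)

test_library <- function() default_chromophore_library()

typical_composition <- function() {
  tissue_composition(c_hbo2 = 15, c_hb = 5, c_water = 300, c_lipid = 600,
                     c_collagen = 60, background = 0.018, a = 12, b = 0.8)
}

# Brute-force Wilcoxon signed-rank oracle: full enumeration of all 2^n sign
# assignments, midranks on tied absolute differences.
brute_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(W <= w + eps), mean(W >= w - eps)))
  list(statistic = w, p = p)
}

# A minimal parameter table: `values` is a tibble with one row per subject
# holding the parameter columns; every configuration gets a copy (optionally
# transformed), which makes cross-configuration correlations exactly 1.
toy_parameter_table <- function(values, transform = identity) {
  cfgs <- dplyr::bind_rows(
    tidyr::expand_grid(posture = "supine", position = c("O", "L", "I"),
                       distance_cm = c(2, 3), mode = "reflectance"),
    tidyr::expand_grid(posture = "sitting", position = "CC",
                       distance_cm = c(2, 3), mode = "reflectance"),
    tibble::tibble(posture = "sitting", position = "CC",
                   distance_cm = NA_real_, mode = "transmittance")
  )
  out <- tidyr::expand_grid(values, cfgs,
                            breast = c("L", "R"))
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.numeric) & !dplyr::any_of("distance_cm"),
    \(v) ifelse(out$mode == "transmittance", transform(v), v)
  ))
  out
}
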