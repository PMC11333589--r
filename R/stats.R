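#' Pearson correlation with exact t-transform p-value
#'
#' Sample Pearson r with the two-sided p-value from the exact t transform
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation undefined for constant input.")
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Signed-rank test on the nonzero paired differences, with midranks for
#' tied absolute differences. For n <= `exact_max` nonzero pairs the
#' two-sided p-value is exact over all 2^n sign assignments (computed by a
#' sign-flip convolution identical to full enumeration):
#' p = min(1, 2 min(P(W+ <= w), P(W+ >= w))). Above that, a normal
#' approximation with tie-corrected variance is used (no continuity
#' correction).
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return A list with `statistic` (W+, the positive-rank sum), `p`, `n`
#'   (nonzero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) abort("All paired differences are zero; test undefined.")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W+ over all 2^n sign assignments; double the ranks so
    # midranks (k + 0.5) stay on an integer lattice
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1)  # f[s + 1] = #assignments with 2*W+ = s
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(tot + 1 - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- round(2 * w)
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = w, p = p, n = n, method = method)
}

#' Bonferroni adjustment
#'
#' Each adjusted p-value is min(1, m p) for family size m. Raw p-values are
#' always kept alongside adjusted ones in the report functions, since a
#' Bonferroni family this size can be excessively strict for correlated
#' tests.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param m Family size (default: the number of p-values).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (m < 1) abort("Family size must be >= 1.")
  pmin(1, m * pvalues)
}

tdb_parameters <- function() c("thb", "so2", "c_lipid", "c_water",
                               "c_collagen", "a", "b")

# Average a parameter table over breasts (and over supine positions when
# collapsing to one value per posture x distance configuration).
breast_average <- function(table, parameters, collapse_positions = TRUE) {
  grp <- c("subject", "posture", "mode",
           if (!collapse_positions) "position", "distance_cm")
  dplyr::summarise(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(grp))),
    dplyr::across(dplyr::all_of(parameters), \(v) mean(v, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Transmittance-vs-reflectance configuration correlations
#'
#' The configuration-comparison table of the analysis: each tissue
#' parameter retrieved in the compressed transmittance acquisition is
#' correlated (Pearson, across subjects, breast-averaged, supine values
#' averaged over the three quadrant positions) against the four reflectance
#' configurations (sitting/supine x 2 cm/3 cm). Bonferroni family defaults
#' to all 28 cells of the report.
#'
#' @param table A parameter table: one row per subject x breast x
#'   configuration with columns `subject`, `breast`, `posture`, `position`,
#'   `distance_cm`, `mode` and the parameter columns.
#' @param parameters Parameter columns to correlate (default the seven
#'   tissue parameters: tHb, SO2, lipids, water, collagen, a, b).
#' @param family_size Bonferroni family size m (default: number of cells).
#' @return A `"tdb_correlation_report"` tibble with one row per
#'   (parameter, configuration): `r`, `p`, `p_adj`, `n`, and the family
#'   size as an attribute.
#' @export
configuration_correlations <- function(table, parameters = tdb_parameters(),
                                       family_size = NULL) {
  table <- as_tibble(table)
  if (!any(table$mode == "transmittance")) {
    abort("No transmittance configuration in the table.")
  }
  avg <- breast_average(table, parameters)
  trans <- dplyr::filter(avg, .data$mode == "transmittance")
  refl <- dplyr::filter(avg, .data$mode == "reflectance")
  cfgs <- dplyr::distinct(refl, .data$posture, .data$distance_cm)
  if (nrow(cfgs) < 1) abort("No reflectance configuration in the table.")

  cells <- tidyr::expand_grid(parameter = parameters,
                              cfgs[order(cfgs$posture, cfgs$distance_cm), ])
  m <- family_size %||% nrow(cells)
  rep <- purrr::pmap_dfr(cells, function(parameter, posture, distance_cm) {
    rr <- dplyr::filter(refl, .data$posture == !!posture,
                        .data$distance_cm == !!distance_cm)
    j <- dplyr::inner_join(
      rr[, c("subject", parameter)], trans[, c("subject", parameter)],
      by = "subject", suffix = c("_refl", "_trans")
    )
    if (nrow(j) < 3) abort("Fewer than 3 subjects shared by configurations.")
    pr <- pearson_with_p(j[[paste0(parameter, "_refl")]],
                         j[[paste0(parameter, "_trans")]])
    tibble(parameter = parameter, posture = posture,
           distance_cm = distance_cm, r = pr$r, p = pr$p, n = pr$n)
  })
  rep$p_adj <- bonferroni_adjust(rep$p, m)
  attr(rep, "family_size") <- m
  class(rep) <- c("tdb_correlation_report", class(rep))
  rep
}

# Resolve a configuration filter (named list of column = value) on a table.
filter_config <- function(table, config) {
  for (nm in names(config)) {
    if (!nm %in% names(table)) abort(paste0("Unknown config field: ", nm))
    if (is.na(config[[nm]])) {
      table <- table[is.na(table[[nm]]), ]
    } else {
      table <- table[!is.na(table[[nm]]) & table[[nm]] == config[[nm]], ]
    }
  }
  table
}

#' Paired comparison between two measurement configurations
#'
#' Wilcoxon matched-pairs signed-rank test of each parameter between two
#' configurations, on subject-level values (breast-averaged; rows matching
#' each configuration filter are averaged per subject). Unpaired subjects
#' are dropped with a warning. Adjusted within the comparison family.
#'
#' @param table A parameter table (see [configuration_correlations()]).
#' @param config_a,config_b Named lists selecting the two configurations,
#'   e.g. `list(posture = "supine", position = "O", distance_cm = 3)`.
#' @param parameters Parameter columns to test.
#' @param family_size Bonferroni family size (default: number of
#'   parameters).
#' @return Tibble with one row per parameter: `statistic` (W+ of a - b),
#'   `p`, `p_adj`, `n`, and per-configuration means `mean_a`, `mean_b`.
#' @export
paired_config_comparison <- function(table, config_a, config_b,
                                     parameters = tdb_parameters(),
                                     family_size = NULL) {
  table <- as_tibble(table)
  agg <- function(cfg) {
    sub <- filter_config(table, cfg)
    dplyr::summarise(
      dplyr::group_by(sub, .data$subject),
      dplyr::across(dplyr::all_of(parameters), \(v) mean(v, na.rm = TRUE)),
      .groups = "drop"
    )
  }
  a <- agg(config_a)
  b <- agg(config_b)
  common <- intersect(a$subject, b$subject)
  dropped <- setdiff(union(a$subject, b$subject), common)
  if (length(dropped)) {
    warn(sprintf("Dropping %d unpaired subject(s).", length(dropped)))
  }
  a <- a[match(common, a$subject), ]
  b <- b[match(common, b$subject), ]
  m <- family_size %||% length(parameters)
  out <- purrr::map_dfr(parameters, function(pm) {
    wt <- wilcoxon_signed_rank(a[[pm]], b[[pm]])
    tibble(parameter = pm, statistic = wt$statistic, p = wt$p, n = wt$n,
           mean_a = mean(a[[pm]]), mean_b = mean(b[[pm]]))
  })
  out$p_adj <- bonferroni_adjust(out$p, m)
  out
}

#' Density ranking concordance across configurations
#'
#' Orders subjects by the Optical Index in a reference configuration
#' (default: supine, right breast, outer quadrants, 3 cm) and, for every
#' (parameter, configuration) column, computes within-column ranks and the
#' Spearman rank concordance of the column against the reference ordering.
#' Lipid is ranked with inverted polarity, since it decreases with breast
#' density.
#'
#' @param table A parameter table including `oi` and `ci` columns (see
#'   [add_derived_indices()]).
#' @param reference Named list selecting the reference column.
#' @param parameters Columns to rank (default water, lipids, collagen, b,
#'   OI, CI, the density-tracking parameters).
#' @param method Concordance metric, `"spearman"` (default) or
#'   `"kendall"`.
#' @return A `"tdb_ranking_report"`: list with `subject_order` (subjects in
#'   ascending reference OI), `concordance` (tibble per parameter x
#'   configuration) and `ranks` (long tibble of within-column ranks).
#' @export
density_ranking <- function(table,
                            reference = list(posture = "supine",
                                             breast = "R", position = "O",
                                             distance_cm = 3,
                                             mode = "reflectance"),
                            parameters = c("c_water", "c_lipid",
                                           "c_collagen", "b", "oi", "ci"),
                            method = c("spearman", "kendall")) {
  method <- match.arg(method)
  table <- as_tibble(table)
  ref <- filter_config(table, reference)
  if (nrow(ref) == 0) abort("Reference configuration matches no rows.")
  if (anyDuplicated(ref$subject)) {
    abort("Reference configuration must select one row per subject.")
  }
  missing <- setdiff(unique(table$subject), ref$subject)
  if (length(missing)) {
    abort("Reference configuration missing for some subjects.")
  }
  ref <- ref[order(ref$oi), ]
  order_ranks <- stats::setNames(seq_len(nrow(ref)), ref$subject)

  cfg_cols <- c("breast", "posture", "position", "distance_cm", "mode")
  long <- tidyr::pivot_longer(
    table[, c("subject", cfg_cols, parameters)],
    dplyr::all_of(parameters), names_to = "parameter", values_to = "value"
  )
  # density polarity: lipid decreases with density
  long$polarity <- ifelse(long$parameter == "c_lipid", -1, 1)
  long$signed_value <- long$value * long$polarity
  long <- dplyr::group_by(long, dplyr::across(dplyr::all_of(
    c("parameter", cfg_cols)
  )))
  long <- dplyr::mutate(long, rank = rank(.data$signed_value))
  conc <- dplyr::summarise(
    long,
    concordance = cor(.data$signed_value, order_ranks[.data$subject],
                      method = method),
    .groups = "drop"
  )
  long <- dplyr::ungroup(long)

  structure(
    list(subject_order = ref$subject, concordance = conc,
         ranks = long[, c("subject", cfg_cols, "parameter", "rank")],
         reference = reference, method = method),
    class = "tdb_ranking_report"
  )
}

#' @export
print.tdb_ranking_report <- function(x, ...) {
  cat(sprintf("<density ranking: %d subjects, %d columns, %s concordance>\n",
              length(x$subject_order), nrow(x$concordance), x$method))
  cat(sprintf("  median concordance %.3f\n", median(x$concordance$concordance)))
  invisible(x)
}
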