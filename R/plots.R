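#' Plot a DTOF histogram
#'
#' Log-scale photon counts over time, with the 80%-to-5% fit window shaded.
#'
#' @param object A [dtof()].
#' @param ... Unused.
#' @method autoplot tdb_dtof
#' @export
autoplot.tdb_dtof <- function(object, ...) {
  t <- axis_times(object$time_axis)
  df <- tibble(time_ns = t, counts = object$counts)
  win <- tryCatch(determine_fit_window(object$counts), error = function(e) NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts",
                  title = sprintf("DTOF @ %g nm", object$wavelength))
  if (!is.null(win)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = t[win$start_index], xmax = t[win$end_index],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Plot recovered optical-property spectra of a spectral fit
#'
#' Shows the absorption and reduced-scattering spectra reconstructed from
#' the fitted tissue composition, faceted by property.
#'
#' @param object A [spectral_fit()] result.
#' @param ... Unused.
#' @method autoplot tdb_spectral_fit
#' @export
autoplot.tdb_spectral_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$spectra[, c("wavelength", "mua", "musp")],
    c("mua", "musp"), names_to = "property", values_to = "value"
  )
  df$property <- factor(df$property, c("mua", "musp"),
                        c("absorption (cm^-1)",
                          "reduced scattering (cm^-1)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = NULL)
}

#' Plot a configuration-correlation report
#'
#' Tile map of Pearson r per (parameter, reflectance configuration), with
#' significance after Bonferroni adjustment marked.
#'
#' @param object A [configuration_correlations()] report.
#' @param alpha Significance level for the marker.
#' @param ... Unused.
#' @method autoplot tdb_correlation_report
#' @export
autoplot.tdb_correlation_report <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(
    as_tibble(object),
    config = paste0(.data$posture, " ", .data$distance_cm, " cm"),
    sig = ifelse(.data$p_adj < alpha, "*", "")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$config, .data$parameter,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r, .data$sig)
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Density-ranking heat map
#'
#' Subjects (rows, in ascending reference-OI order) against measurement
#' configurations (columns), color-coded by within-column rank -- lipid
#' with inverted polarity so that red always means denser tissue.
#'
#' @param report A [density_ranking()] report.
#' @param parameter Which parameter column set to display.
#' @export
plot_ranking_heatmap <- function(report, parameter = "oi") {
  stopifnot(inherits(report, "tdb_ranking_report"))
  df <- dplyr::filter(report$ranks, .data$parameter == !!parameter)
  df$config <- paste(df$posture, df$position,
                     ifelse(is.na(df$distance_cm), "T",
                            paste0(df$distance_cm, "cm")),
                     df$breast)
  df$subject <- factor(df$subject, levels = report$subject_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$config, .data$subject,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkblue", high = "darkred") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank",
                  title = sprintf("within-column density rank (%s)", parameter)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
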