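#' Blood parameters from hemoglobin concentrations
#'
#' Total hemoglobin tHb = HbO2 + Hb (uM) and oxygen saturation
#' SO2 = HbO2 / tHb (a fraction in \[0, 1\]).
#'
#' @param c_hbo2,c_hb Oxy- / deoxy-hemoglobin concentrations (uM), >= 0.
#' @return A list with `thb` and `so2`. `so2` is undefined (error) when
#'   tHb = 0.
#' @examples
#' blood_params(15, 5)  # thb 20, so2 0.75
#' @export
blood_params <- function(c_hbo2, c_hb) {
  if (any(!is.finite(c(c_hbo2, c_hb))) || c_hbo2 < 0 || c_hb < 0) {
    abort("Hemoglobin concentrations must be finite and >= 0.")
  }
  thb <- c_hbo2 + c_hb
  if (thb == 0) abort("SO2 is undefined when total hemoglobin is 0.")
  list(thb = thb, so2 = c_hbo2 / thb)
}

#' Breast density optical indices
#'
#' The Optical Index OI = \[water\]\[collagen\] b / \[lipids\] combines every
#' constituent that tracks mammographic density (water and collagen rise,
#' lipid falls, scattering power b rises with density); the Collagen Index
#' CI = \[collagen\] b isolates the collagen-related contribution.
#' Concentrations in mg/cm^3, b dimensionless; both indices are reported
#' raw, unnormalized.
#'
#' @param comp A [tissue_composition()].
#' @return A list with `oi` and `ci`. OI is undefined (error) when lipid is
#'   0; CI is always returned by [collagen_index()].
#' @examples
#' comp <- tissue_composition(15, 5, 300, 600, 60, a = 12, b = 1)
#' density_indices(comp)  # oi 30, ci 60
#' @export
density_indices <- function(comp) {
  stopifnot(inherits(comp, "tdb_tissue_composition"))
  if (comp$c_lipid <= 0) {
    abort("OI is undefined when the lipid concentration is 0.")
  }
  list(
    oi = comp$c_water * comp$c_collagen * comp$b / comp$c_lipid,
    ci = collagen_index(comp)
  )
}

#' @rdname density_indices
#' @export
collagen_index <- function(comp) {
  stopifnot(inherits(comp, "tdb_tissue_composition"))
  comp$c_collagen * comp$b
}

#' Derive blood parameters and density indices for a parameter table
#'
#' Adds `thb`, `so2`, `oi`, `ci` columns to any tibble holding the
#' composition columns (`c_hbo2`, `c_hb`, `c_water`, `c_lipid`,
#' `c_collagen`, `b`). Rows with zero lipid get `NA` OI.
#'
#' @param data A data frame with composition columns.
#' @return The input tibble with four derived columns appended.
#' @export
add_derived_indices <- function(data) {
  data <- as_tibble(data)
  dplyr::mutate(
    data,
    thb = .data$c_hbo2 + .data$c_hb,
    so2 = dplyr::if_else(.data$thb > 0, .data$c_hbo2 / .data$thb, NA_real_),
    oi = dplyr::if_else(.data$c_lipid > 0,
                        .data$c_water * .data$c_collagen * .data$b / .data$c_lipid,
                        NA_real_),
    ci = .data$c_collagen * .data$b
  )
}
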