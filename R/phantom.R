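#' Phantom round-trip recovery experiment
#'
#' The system check of the measurement protocol: a resin phantom of known
#' optical properties (mu_a = 0.05 cm^-1, mu_s' = 10 cm^-1 at 800 nm) is
#' measured and the single-wavelength fit must recover those values. Here
#' the measurement is synthetic: the forward model at the phantom
#' properties is convolved with the IRF, scaled to the target total count,
#' Poisson noise is drawn, and [standard_fit()] is run, once per replicate.
#'
#' @param n_replicates Number of seeded noise replicates.
#' @param seed Master seed.
#' @param mua,musp Phantom ground truth (cm^-1).
#' @param rho Source-detector distance (cm).
#' @param counts Target total counts per DTOF.
#' @param axis A [time_axis()].
#' @param medium A [medium_model()].
#' @param init Fit starting point `c(mua, musp)`.
#' @return Tibble with one row per replicate: `replicate`, `mua`, `musp`,
#'   `converged`.
#' @export
phantom_recovery <- function(n_replicates = 20, seed = 1,
                             mua = 0.05, musp = 10, rho = 2, counts = 1e6,
                             axis = time_axis(), medium = medium_model(),
                             init = c(0.1, 15)) {
  geom <- geometry("reflectance", rho = rho)
  irf <- synthetic_irf(axis)
  truth <- td_forward(mua, musp, geom, medium, axis)
  curve <- pmax(convolve_with_irf(truth, irf, axis), 0)
  lam <- curve / sum(curve) * counts
  with_preserved_seed({
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    purrr::map_dfr(seq_len(n_replicates), function(i) {
      counts_i <- with_preserved_seed({
        set.seed(rep_seeds[i])
        rpois(length(lam), lam)
      })
      f <- standard_fit(dtof(800, counts_i, axis), irf, geom,
                        medium = medium, init = init)
      tibble(replicate = i, mua = f$mua, musp = f$musp,
             converged = f$converged)
    })
  })
}
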