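#' Moyer model parameters
#'
#' Constants of the classical Moyer point-loss shielding model:
#' the source-term constant `H0` (Sv m^2), the reference proton energy
#' `E0` (MeV), and the energy-scaling exponent `alpha`. The defaults are
#' the values conventionally used for high-energy accelerator shielding:
#' `H0 = 2.6e-14 Sv m^2`, `E0 = 1000 MeV` (1 GeV), `alpha = 0.8`.
#'
#' @param H0_Sv_m2 Source-term constant, Sv m^2, `> 0`.
#' @param E0_MeV Reference energy, MeV, `> 0`.
#' @param alpha Energy-scaling exponent, `> 0`.
#' @return Object of class `"moyer_parameters"`.
#' @export
moyer_parameters <- function(H0_Sv_m2 = 2.6e-14, E0_MeV = 1000,
                             alpha = 0.8) {
  check_scalar(H0_Sv_m2, "H0_Sv_m2", positive = TRUE)
  check_scalar(E0_MeV, "E0_MeV", positive = TRUE)
  check_scalar(alpha, "alpha", positive = TRUE)
  structure(list(H0_Sv_m2 = H0_Sv_m2, E0_MeV = E0_MeV, alpha = alpha),
            class = "moyer_parameters")
}

#' Moyer point-loss dose estimate
#'
#' The classical analytical bulk-shielding model for a point beam loss:
#' `H = (H0 / r^2) * (Ep / E0)^alpha * exp(-d / lambda)`,
#' combining inverse-square geometry from the loss point, a power-law
#' scaling in proton energy, and exponential attenuation through the
#' barrier. It assumes a fixed attenuation length and source-term
#' constant, which holds at high proton energies; at therapy energies it
#' serves as a quick, conservative cross-check against the
#' three-source angular model of [weekly_dose()].
#'
#' @param r_m Radial distance from the loss point, meters, `> 0`.
#' @param d_m Shield thickness along the ray, meters, `>= 0`.
#' @param lambda_m Attenuation length of the shield material, meters,
#'   `> 0`.
#' @param Ep_MeV Proton energy, MeV, `> 0` (compared internally to
#'   `E0 = 1000 MeV`).
#' @param params A [moyer_parameters()] object.
#' @return Dose equivalent per loss event scale, Sv (per the
#'   normalization carried by `H0`).
#' @examples
#' moyer_dose(r_m = 1, d_m = 0, lambda_m = 0.5, Ep_MeV = 1000)  # 2.6e-14
#' moyer_dose(r_m = 3, d_m = 1.0, lambda_m = 0.45, Ep_MeV = 250)
#' @export
moyer_dose <- function(r_m, d_m, lambda_m, Ep_MeV,
                       params = moyer_parameters()) {
  stopifnot(inherits(params, "moyer_parameters"))
  check_scalar(r_m, "r_m", positive = TRUE)
  check_scalar(d_m, "d_m", nonnegative = TRUE)
  check_scalar(lambda_m, "lambda_m", positive = TRUE)
  check_scalar(Ep_MeV, "Ep_MeV", positive = TRUE)
  params$H0_Sv_m2 / r_m^2 * (Ep_MeV / params$E0_MeV)^params$alpha *
    exp(-d_m / lambda_m)
}
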