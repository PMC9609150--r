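#' Membrane microviscosity from the rotational correlation time
#'
#' Stokes--Einstein--Debye relation for a spherical rotor:
#' `theta = 4 pi eta R^3 / (3 k_B T)`, inverted to
#' `eta = 3 k_B T theta / (4 pi R^3)`. The probe is treated as a sphere of
#' hydrodynamic radius `R` rotating in a continuum of viscosity `eta`; for
#' a lipophilic rotor embedded in a bilayer the result is the effective
#' microviscosity of its immediate lipid environment.
#'
#' @param theta_ns rotational correlation time, ns.
#' @param temperature_K absolute temperature, K.
#' @param probe_radius_nm hydrodynamic radius of the probe, nm. This is a
#'   required user input: it enters cubed, so absolute viscosities are only
#'   as good as the radius estimate.
#' @return Object of class `viscosity_estimate`: list with `eta_mPa_s`
#'   (equal to centipoise), and the inputs.
#' @examples
#' microviscosity(1, 293.15, 0.5)$eta_mPa_s  # 7.73 mPa s
#' @export
microviscosity <- function(theta_ns, temperature_K, probe_radius_nm) {
  .check_positive_scalar(theta_ns, "theta_ns")
  .check_positive_scalar(temperature_K, "temperature_K")
  .check_positive_scalar(probe_radius_nm, "probe_radius_nm")
  theta_s <- theta_ns * 1e-9
  r_m <- probe_radius_nm * 1e-9
  eta_Pa_s <- 3 * .kB * temperature_K * theta_s / (4 * pi * r_m^3)
  structure(list(eta_mPa_s = eta_Pa_s * 1e3, theta_ns = theta_ns,
                 temperature_K = temperature_K,
                 probe_radius_nm = probe_radius_nm),
            class = "viscosity_estimate")
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(sprintf(
    "Microviscosity: %.4g mPa s (theta = %.4g ns, T = %.2f K, R = %.3g nm)\n",
    x$eta_mPa_s, x$theta_ns, x$temperature_K, x$probe_radius_nm))
  invisible(x)
}

#' Rotational correlation time expected at a given microviscosity
#'
#' Algebraic inverse of [microviscosity()]:
#' `theta = 4 pi eta R^3 / (3 k_B T)`.
#'
#' @param eta_mPa_s viscosity in mPa s (centipoise).
#' @inheritParams microviscosity
#' @return Rotational correlation time in ns.
#' @examples
#' theta_from_viscosity(100, 293.15, 0.5)
#' @export
theta_from_viscosity <- function(eta_mPa_s, temperature_K, probe_radius_nm) {
  .check_positive_scalar(eta_mPa_s, "eta_mPa_s")
  .check_positive_scalar(temperature_K, "temperature_K")
  .check_positive_scalar(probe_radius_nm, "probe_radius_nm")
  r_m <- probe_radius_nm * 1e-9
  theta_s <- 4 * pi * (eta_mPa_s * 1e-3) * r_m^3 / (3 * .kB * temperature_K)
  theta_s * 1e9
}
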