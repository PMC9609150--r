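#' Photophysical constants for Forster-distance calculations
#'
#' @param kappa2 orientation factor, in `[0, 4]`; 2/3 for isotropic dynamic
#'   averaging, or an ensemble mean from [kappa2_ensemble()].
#' @param quantum_yield donor fluorescence quantum yield, in `(0, 1]`.
#' @param refractive_index refractive index of the medium, `>= 1`.
#' @param donor_conc_nM donor (probe) concentration, nM.
#' @param molar_extinction_peak acceptor peak molar extinction, M^-1 cm^-1,
#'   used to scale arbitrary-unit acceptor spectra.
#' @return Object of class `fret_inputs`.
#' @examples
#' fret_inputs(kappa2 = 0.68, quantum_yield = 0.95,
#'             refractive_index = 1.4251, molar_extinction_peak = 75300)
#' @export
fret_inputs <- function(kappa2 = 2 / 3, quantum_yield = 0.95,
                        refractive_index = 1.4251, donor_conc_nM = 1000,
                        molar_extinction_peak = 75300) {
  if (kappa2 < 0 || kappa2 > 4) {
    stop("`kappa2` must lie in [0, 4]", call. = FALSE)
  }
  if (quantum_yield <= 0 || quantum_yield > 1) {
    stop("`quantum_yield` must lie in (0, 1]", call. = FALSE)
  }
  if (refractive_index < 1) {
    stop("`refractive_index` must be >= 1", call. = FALSE)
  }
  .check_positive_scalar(donor_conc_nM, "donor_conc_nM")
  .check_positive_scalar(molar_extinction_peak, "molar_extinction_peak")
  structure(list(kappa2 = kappa2, quantum_yield = quantum_yield,
                 refractive_index = refractive_index,
                 donor_conc_nM = donor_conc_nM,
                 molar_extinction_peak = molar_extinction_peak),
            class = "fret_inputs")
}

#' Forster distance from the overlap integral
#'
#' `R0 = 0.211 * (kappa2 * n^-4 * Phi_D * J)^(1/6)` with J in
#' M^-1 cm^-1 nm^4 and R0 in Angstrom (the Lakowicz convention; the 0.211
#' prefactor absorbs all unit conversions for this choice of J units).
#'
#' @param J overlap integral, M^-1 cm^-1 nm^4 (>= 0).
#' @param inputs a [fret_inputs()] object.
#' @return Forster distance R0 in Angstrom.
#' @examples
#' forster_distance(1e15, fret_inputs())  # 48.8 A
#' @export
forster_distance <- function(J, inputs = fret_inputs()) {
  stopifnot(inherits(inputs, "fret_inputs"))
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J) || J < 0) {
    stop("`J` must be a single finite number >= 0", call. = FALSE)
  }
  0.211 * (inputs$kappa2 * inputs$refractive_index^-4 *
             inputs$quantum_yield * J)^(1 / 6)
}

#' FRET efficiency from donor lifetime quenching
#'
#' `W = 1 - tau_DA / tau_D`: the fractional reduction of the donor
#' fluorescence lifetime in the presence of the acceptor. The lifetimes
#' should be amplitude-weighted means ([amplitude_weighted_mean()]) when the
#' decays are multiexponential.
#'
#' @param tau_D_ns donor-only lifetime, ns.
#' @param tau_DA_ns donor lifetime with acceptor present, ns; must not
#'   exceed `tau_D_ns` (a longer lifetime signals mislabeled inputs).
#' @return Transfer efficiency W in `[0, 1)`.
#' @examples
#' efficiency_from_lifetimes(5.601, 4.971)  # 0.1125
#' efficiency_from_lifetimes(4.51, 1.450)   # 0.6785
#' @export
efficiency_from_lifetimes <- function(tau_D_ns, tau_DA_ns) {
  .check_positive_scalar(tau_D_ns, "tau_D_ns")
  .check_positive_scalar(tau_DA_ns, "tau_DA_ns")
  if (tau_DA_ns > tau_D_ns) {
    stop(paste("tau_DA exceeds tau_D (negative efficiency): donor and",
               "donor+acceptor lifetimes are likely swapped"), call. = FALSE)
  }
  1 - tau_DA_ns / tau_D_ns
}

#' Mean donor-acceptor distance from the transfer efficiency
#'
#' Inverts the sixth-power Forster law:
#' `R = R0 * (1/W - 1)^(1/6)`.
#'
#' @param R0_angstrom Forster distance, Angstrom (> 0).
#' @param W transfer efficiency, strictly between 0 and 1.
#' @return Donor-acceptor distance in Angstrom.
#' @examples
#' distance_from_efficiency(59, 0.310)  # ~67.4 A
#' distance_from_efficiency(44, 0.234)  # ~53.6 A
#' @export
distance_from_efficiency <- function(R0_angstrom, W) {
  .check_positive_scalar(R0_angstrom, "R0_angstrom")
  if (!is.numeric(W) || length(W) != 1L || W <= 0 || W >= 1) {
    stop("`W` must lie strictly between 0 and 1", call. = FALSE)
  }
  R0_angstrom * (1 / W - 1)^(1 / 6)
}

#' Transfer efficiency expected at a given donor-acceptor distance
#'
#' Forward Forster law `W = R0^6 / (R0^6 + R^6)`; exact inverse of
#' [distance_from_efficiency()].
#'
#' @param R0_angstrom Forster distance, Angstrom (> 0).
#' @param R_angstrom donor-acceptor distance, Angstrom (> 0).
#' @return Transfer efficiency in `(0, 1)`.
#' @examples
#' efficiency_from_distance(59, 59)  # 0.5 by definition of R0
#' @export
efficiency_from_distance <- function(R0_angstrom, R_angstrom) {
  .check_positive_scalar(R0_angstrom, "R0_angstrom")
  .check_positive_scalar(R_angstrom, "R_angstrom")
  ratio6 <- (R_angstrom / R0_angstrom)^6
  1 / (1 + ratio6)
}

#' Minimum delivered acceptor concentration from the fast-component share
#'
#' The amplitude share of the fast (quenched) decay component is the
#' fraction of donor molecules engaged in energy transfer. Assuming each
#' transferring donor is paired with `acceptors_per_donor` acceptors
#' (default 1:1), the minimum concentration of delivered acceptor is that
#' fraction times the probe concentration. It is a lower bound: acceptors
#' outside transfer range are invisible to the donor decay.
#'
#' @param fast_fraction amplitude fraction of the fast component, `[0, 1]`
#'   (see [fast_component_fraction()]).
#' @param probe_conc_nM total donor probe concentration, nM.
#' @param acceptors_per_donor acceptors per transferring donor (default 1).
#' @return Delivered acceptor concentration, nM.
#' @examples
#' delivered_concentration(0.1819, 1000)  # 181.9 nM
#' @export
delivered_concentration <- function(fast_fraction, probe_conc_nM,
                                    acceptors_per_donor = 1) {
  if (!is.numeric(fast_fraction) || fast_fraction < 0 || fast_fraction > 1) {
    stop("`fast_fraction` must lie in [0, 1]", call. = FALSE)
  }
  .check_positive_scalar(probe_conc_nM, "probe_conc_nM")
  .check_positive_scalar(acceptors_per_donor, "acceptors_per_donor")
  fast_fraction * probe_conc_nM * acceptors_per_donor
}

#' Full FRET quantification from spectra and lifetimes
#'
#' Convenience wrapper chaining [overlap_integral()], [forster_distance()],
#' [efficiency_from_lifetimes()], [distance_from_efficiency()] and
#' [delivered_concentration()].
#'
#' @param donor_emission donor emission [spectrum()].
#' @param acceptor_extinction acceptor extinction [spectrum()]; rescaled to
#'   `inputs$molar_extinction_peak` if its maximum differs.
#' @param tau_D_ns,tau_DA_ns donor lifetimes without / with acceptor, ns.
#' @param inputs a [fret_inputs()].
#' @param fast_fraction optional fast-component amplitude fraction for the
#'   delivered-concentration estimate.
#' @param acceptors_per_donor acceptors per transferring donor (default 1).
#' @return Object of class `fret_result`: `J`, `R0_angstrom`,
#'   `efficiency_W`, `R_DA_angstrom`, `delivered_conc_nM` (NA when
#'   `fast_fraction` is not given), plus the `inputs` used.
#' @export
fret_quantify <- function(donor_emission, acceptor_extinction,
                          tau_D_ns, tau_DA_ns, inputs = fret_inputs(),
                          fast_fraction = NULL, acceptors_per_donor = 1) {
  stopifnot(inherits(inputs, "fret_inputs"))
  if (abs(max(acceptor_extinction$values) -
          inputs$molar_extinction_peak) >
      1e-9 * inputs$molar_extinction_peak) {
    acceptor_extinction <- scale_to_extinction(acceptor_extinction,
                                               inputs$molar_extinction_peak)
  }
  J <- overlap_integral(donor_emission, acceptor_extinction)
  R0 <- forster_distance(J, inputs)
  W <- efficiency_from_lifetimes(tau_D_ns, tau_DA_ns)
  R_DA <- if (W > 0 && W < 1 && R0 > 0) {
    distance_from_efficiency(R0, W)
  } else {
    NA_real_
  }
  conc <- if (!is.null(fast_fraction)) {
    delivered_concentration(fast_fraction, inputs$donor_conc_nM,
                            acceptors_per_donor)
  } else {
    NA_real_
  }
  structure(list(J = J, R0_angstrom = R0, efficiency_W = W,
                 R_DA_angstrom = R_DA, delivered_conc_nM = conc,
                 inputs = inputs),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat("FRET quantification\n")
  cat(sprintf("  J   = %.4g M^-1 cm^-1 nm^4\n", x$J))
  cat(sprintf("  R0  = %.3g A (kappa2 = %.3g, Phi = %.3g, n = %.5g)\n",
              x$R0_angstrom, x$inputs$kappa2, x$inputs$quantum_yield,
              x$inputs$refractive_index))
  cat(sprintf("  W   = %.4g, R_DA = %.3g A\n", x$efficiency_W,
              x$R_DA_angstrom))
  if (!is.na(x$delivered_conc_nM)) {
    cat(sprintf("  delivered acceptor >= %.4g nM\n", x$delivered_conc_nM))
  }
  invisible(x)
}
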