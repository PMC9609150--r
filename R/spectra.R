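#' Construct a wavelength-gridded spectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param values non-negative spectral values: emission in arbitrary units
#'   or molar extinction in M^-1 cm^-1.
#' @param kind `"emission"` or `"extinction"`.
#' @return Object of class `spectrum`.
#' @examples
#' spectrum(450:650, pmax(0, 1 - abs(450:650 - 570) / 50), "emission")
#' @export
spectrum <- function(wavelength_nm, values,
                     kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (length(values) != length(wavelength_nm)) {
    stop("`values` and `wavelength_nm` must have the same length",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("spectral values must be finite and non-negative", call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 values = as.numeric(values), kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d points, %.4g-%.4g nm, peak %.4g at %.4g nm\n",
              x$kind, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), max(x$values),
              x$wavelength_nm[which.max(x$values)]))
  invisible(x)
}

#' Rescale an extinction spectrum to a known peak molar extinction
#'
#' Acceptor absorption spectra measured in arbitrary units are placed on the
#' molar-extinction scale by scaling the maximum to the literature peak
#' coefficient (e.g. 75,300 M^-1 cm^-1 for echinenone, 125,300 for
#' beta-carotene).
#'
#' @param spec a [spectrum()].
#' @param peak_extinction target peak molar extinction, M^-1 cm^-1.
#' @return A `spectrum` of kind `"extinction"` with `max(values) ==
#'   peak_extinction`.
#' @export
scale_to_extinction <- function(spec, peak_extinction) {
  stopifnot(inherits(spec, "spectrum"))
  .check_positive_scalar(peak_extinction, "peak_extinction")
  if (max(spec$values) <= 0) {
    stop("cannot rescale an identically zero spectrum", call. = FALSE)
  }
  spectrum(spec$wavelength_nm,
           spec$values * peak_extinction / max(spec$values),
           kind = "extinction")
}

# trapezoidal integral
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Spectral overlap integral for Forster transfer
#'
#' `J = integral F_D(lambda) eps_A(lambda) lambda^4 dlambda /
#'      integral F_D(lambda) dlambda`
#' evaluated by the trapezoidal rule on the union of the two wavelength
#' grids, with linear interpolation of each spectrum (zero outside its own
#' support). The donor normalization makes J invariant to rescaling of the
#' donor emission; the acceptor must be on the molar-extinction scale
#' (see [scale_to_extinction()]).
#'
#' @param donor_emission donor emission [spectrum()] (arbitrary units).
#' @param acceptor_extinction acceptor extinction [spectrum()]
#'   (M^-1 cm^-1).
#' @return Overlap integral J in M^-1 cm^-1 nm^4. Disjoint wavelength
#'   ranges yield 0 with a warning.
#' @examples
#' d <- simulate_spectrum(spectrum_spec(cbind(570, 25, 1), c(450, 720, 1)))
#' a <- simulate_spectrum(
#'   spectrum_spec(cbind(530, 35, 75300), c(380, 650, 1), "extinction"))
#' overlap_integral(d, a)
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_extinction, "spectrum"))
  fd_int <- .trapz(donor_emission$wavelength_nm, donor_emission$values)
  if (fd_int <= 0) {
    stop("donor emission spectrum has zero integral", call. = FALSE)
  }
  lo <- max(min(donor_emission$wavelength_nm),
            min(acceptor_extinction$wavelength_nm))
  hi <- min(max(donor_emission$wavelength_nm),
            max(acceptor_extinction$wavelength_nm))
  if (lo >= hi) {
    warning("donor and acceptor wavelength ranges do not overlap; J = 0",
            call. = FALSE)
    return(0)
  }
  wl <- sort(unique(c(
    donor_emission$wavelength_nm[donor_emission$wavelength_nm >= lo &
                                   donor_emission$wavelength_nm <= hi],
    acceptor_extinction$wavelength_nm[
      acceptor_extinction$wavelength_nm >= lo &
        acceptor_extinction$wavelength_nm <= hi],
    lo, hi)))
  fd <- approx(donor_emission$wavelength_nm, donor_emission$values,
               xout = wl, rule = 1)$y
  ea <- approx(acceptor_extinction$wavelength_nm,
               acceptor_extinction$values, xout = wl, rule = 1)$y
  .trapz(wl, fd * ea * wl^4) / fd_int
}
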