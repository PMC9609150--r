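#' Ground truth for the polarized TCSPC simulator
#'
#' Collects the generative parameters of a polarized decay measurement: the
#' multiexponential intensity decay, the (multi)exponential anisotropy decay
#' with initial anisotropy r0, the detector polarization sensitivity ratio
#' (true G factor), the expected photon budget, a constant background, and
#' the instrument-response width.
#'
#' @param intensity_components two-column matrix or data.frame
#'   `(fraction, tau_ns)`: amplitude fractions (summing to 1) and lifetimes
#'   in ns of the intensity decay.
#' @param anisotropy_r0 initial anisotropy r0, in `[0, 0.4]` (0.4 is the
#'   collinear-dipole photoselection limit for one-photon excitation).
#' @param anisotropy_components two-column matrix `(fraction, theta_ns)`:
#'   amplitude fractions (summing to 1) and rotational correlation times in
#'   ns; `r(t) = r0 * sum_j f_j exp(-t/theta_j)`.
#' @param g_true detector sensitivity ratio for vertically vs horizontally
#'   analyzed emission (> 0).
#' @param background_rate expected dark/background counts per channel.
#' @param total_counts expected photons in the isotropic total decay
#'   `I = VV + 2 G VH` (the polarization-independent photon budget).
#' @param irf_fwhm full width at half maximum of the Gaussian instrument
#'   response, ns; 0 means an ideal delta-function response.
#' @param seed integer seed for the Poisson noise generator.
#'
#' @return An object of class `tcspc_truth`.
#' @examples
#' ground_truth(cbind(1, 5.601), anisotropy_r0 = 0.35,
#'              anisotropy_components = cbind(1, 2),
#'              g_true = 1.1, total_counts = 5e6, seed = 42)
#' @export
ground_truth <- function(intensity_components,
                         anisotropy_r0 = 0.35,
                         anisotropy_components = cbind(1, 2),
                         g_true = 1,
                         background_rate = 0,
                         total_counts = 5e6,
                         irf_fwhm = 0.1,
                         seed = 1L) {
  ic <- .as_components(intensity_components, "intensity_components")
  ac <- .as_components(anisotropy_components, "anisotropy_components")
  num <- function(x, name) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single number", name), call. = FALSE)
    }
    v
  }
  anisotropy_r0 <- num(anisotropy_r0, "anisotropy_r0")
  g_true <- num(g_true, "g_true")
  background_rate <- num(background_rate, "background_rate")
  total_counts <- num(total_counts, "total_counts")
  irf_fwhm <- num(irf_fwhm, "irf_fwhm")
  if (!is.numeric(anisotropy_r0) || anisotropy_r0 < 0 || anisotropy_r0 > 0.4) {
    stop("`anisotropy_r0` must lie in [0, 0.4]", call. = FALSE)
  }
  .check_positive_scalar(g_true, "g_true")
  if (background_rate < 0) stop("`background_rate` must be >= 0", call. = FALSE)
  if (total_counts < 0) stop("`total_counts` must be >= 0", call. = FALSE)
  if (irf_fwhm < 0) stop("`irf_fwhm` must be >= 0", call. = FALSE)
  structure(list(intensity_components = ic,
                 anisotropy_r0 = anisotropy_r0,
                 anisotropy_components = ac,
                 g_true = g_true,
                 background_rate = background_rate,
                 total_counts = total_counts,
                 irf_fwhm = irf_fwhm,
                 seed = as.integer(seed)),
            class = "tcspc_truth")
}

# validate an (fraction, time) component table; fractions must sum to 1.
# Accepts a matrix/data.frame or a list of (fraction, time) rows (the YAML
# form).
.as_components <- function(x, name) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, unlist))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L || nrow(x) < 1L) {
    stop(sprintf("`%s` must be a two-column (fraction, time_ns) table", name),
         call. = FALSE)
  }
  colnames(x) <- c("fraction", "time_ns")
  if (any(x[, "time_ns"] <= 0)) {
    stop(sprintf("`%s`: relaxation times must be > 0", name), call. = FALSE)
  }
  if (any(x[, "fraction"] < 0)) {
    stop(sprintf("`%s`: fractions must be >= 0", name), call. = FALSE)
  }
  if (abs(sum(x[, "fraction"]) - 1) > 1e-9) {
    stop(sprintf("`%s`: fractions must sum to 1 (got %.12g)", name,
                 sum(x[, "fraction"])), call. = FALSE)
  }
  x
}

# normalized Gaussian IRF kernel on the grid, peak at 3 sigma after t = 0
.irf_kernel <- function(time_ns, fwhm_ns) {
  sigma <- fwhm_ns * .FWHM2SIGMA
  t0 <- 3 * sigma
  k <- exp(-0.5 * ((time_ns - time_ns[1] - t0) / sigma)^2)
  k / sum(k)
}

# causal discrete convolution of a decay with a normalized kernel
.convolve_irf <- function(y, kernel) {
  n <- length(y)
  out <- convolve(y, rev(kernel), type = "open")[seq_len(n)]
  pmax(out, 0)
}

#' Simulate polarized TCSPC decay histograms
#'
#' Forward model of the four-geometry polarized measurement. The noise-free
#' parallel and perpendicular emission components follow photoselection
#' theory, `I_par = I(t) (1 + 2 r(t)) / 3` and
#' `I_perp = I(t) (1 - r(t)) / 3`, where `I(t)` is the multiexponential
#' intensity decay and `r(t)` the anisotropy decay of `truth`. The detector
#' polarization bias enters as a scale `1/g_true` on the horizontally
#' analyzed channels (VH, HH), so that the horizontal-excitation pair
#' reproduces `HV/HH = g_true`. All four channels (and the IRF histogram)
#' are convolved with a Gaussian instrument response of the stated FWHM,
#' scaled so the expected isotropic total `VV + 2 g VH` carries
#' `total_counts` photons, offset by the constant background, and finally
#' Poisson-sampled channel by channel.
#'
#' @param truth a [ground_truth()] object.
#' @param time_max upper end of the time window, ns. Must cover at least five
#'   times the longest intensity lifetime and the IRF support.
#' @param n_channels number of time channels (default 4096, a standard TCSPC
#'   board depth over a 25 ns window).
#' @param noise if `TRUE` (default) draw per-channel Poisson counts with
#'   `truth$seed`; if `FALSE` return the noise-free expected counts
#'   (the infinite-photon limit, useful as a forward-model oracle).
#'
#' @return A list of class `polarized_decays` with elements `VV`, `VH`,
#'   `HV`, `HH` and `irf` ([decay_histogram] objects; `irf` is `NULL` when
#'   `irf_fwhm = 0`), plus the `truth` used.
#' @examples
#' tr <- ground_truth(cbind(1, 2), anisotropy_r0 = 0.3,
#'                    anisotropy_components = cbind(1, 0.8),
#'                    total_counts = 1e5, irf_fwhm = 0, seed = 7)
#' sim <- simulate_polarized_decays(tr, time_max = 12, n_channels = 512)
#' sim$VV
#' @export
simulate_polarized_decays <- function(truth, time_max = 25,
                                      n_channels = 4096, noise = TRUE) {
  stopifnot(inherits(truth, "tcspc_truth"))
  .check_positive_scalar(time_max, "time_max")
  if (n_channels < 8) stop("`n_channels` must be >= 8", call. = FALSE)
  tmax_life <- max(truth$intensity_components[, "time_ns"])
  if (time_max < 5 * tmax_life) {
    stop(sprintf(paste("time window (%.3g ns) must cover >= 5 x the longest",
                       "lifetime (5 x %.3g ns)"), time_max, tmax_life),
         call. = FALSE)
  }
  sigma <- truth$irf_fwhm * .FWHM2SIGMA
  if (time_max < 6 * sigma) {
    stop("time window shorter than the IRF support (6 sigma)", call. = FALSE)
  }

  t <- seq(0, time_max, length.out = n_channels)
  ic <- truth$intensity_components
  ac <- truth$anisotropy_components
  intensity <- rowSums(vapply(seq_len(nrow(ic)), function(i) {
    ic[i, "fraction"] * exp(-t / ic[i, "time_ns"])
  }, numeric(length(t))))
  r <- truth$anisotropy_r0 * rowSums(vapply(seq_len(nrow(ac)), function(j) {
    ac[j, "fraction"] * exp(-t / ac[j, "time_ns"])
  }, numeric(length(t))))

  i_par <- intensity * (1 + 2 * r) / 3
  i_perp <- intensity * (1 - r) / 3

  irf_counts <- NULL
  if (truth$irf_fwhm > 0) {
    kernel <- .irf_kernel(t, truth$irf_fwhm)
    i_par <- .convolve_irf(i_par, kernel)
    i_perp <- .convolve_irf(i_perp, kernel)
    irf_counts <- kernel
  }

  # photon budget: expected isotropic total I = VV + 2 g VH = i_par + 2 i_perp
  iso <- sum(i_par + 2 * i_perp)
  scale <- if (iso > 0) truth$total_counts / iso else 0

  exp_counts <- list(
    VV = scale * i_par,
    VH = scale * i_perp / truth$g_true,
    HV = scale * i_perp,
    HH = scale * i_perp / truth$g_true
  )
  exp_counts <- lapply(exp_counts, function(mu) mu + truth$background_rate)
  if (any(unlist(exp_counts) < 0)) {
    stop("negative expected counts", call. = FALSE)
  }

  if (noise) {
    set.seed(truth$seed)
    exp_counts <- lapply(exp_counts, function(mu) rpois(length(mu), mu))
    if (!is.null(irf_counts)) {
      irf_counts <- rpois(length(irf_counts),
                          irf_counts * truth$total_counts / 100)
    }
  } else if (!is.null(irf_counts)) {
    irf_counts <- irf_counts * truth$total_counts / 100
  }

  out <- lapply(names(exp_counts), function(g) {
    decay_histogram(t, exp_counts[[g]], geometry = g)
  })
  names(out) <- names(exp_counts)
  out$irf <- if (!is.null(irf_counts)) {
    decay_histogram(t, irf_counts, geometry = "IRF")
  }
  out$truth <- truth
  class(out) <- "polarized_decays"
  out
}

#' @export
print.polarized_decays <- function(x, ...) {
  cat("Simulated polarized TCSPC decays (VV, VH, HV, HH",
      if (!is.null(x$irf)) "+ IRF", ")\n")
  cat(sprintf("  channels: %d, window: %.3g ns, g_true = %.4g, r0 = %.3g\n",
              length(x$VV$time_ns), max(x$VV$time_ns), x$truth$g_true,
              x$truth$anisotropy_r0))
  invisible(x)
}
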