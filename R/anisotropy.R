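#' Estimate the detector G factor from horizontal-excitation decays
#'
#' With horizontal excitation both emission analyzer settings view the same
#' (perpendicular) emission, so the ratio of detected intensities isolates
#' the detector polarization sensitivity: `G = I_HV / I_HH`. The estimate
#' integrates counts over a time window (Poisson-stable, unlike a
#' channel-wise ratio) after subtracting an optional per-channel baseline.
#'
#' @param hv,hh [decay_histogram()] objects on the same grid (horizontal
#'   excitation; vertical / horizontal analyzer).
#' @param window optional `c(t_start, t_stop)` ns integration window;
#'   default is the full grid.
#' @param baseline per-channel background counts subtracted from both
#'   histograms before integration (default 0).
#' @return The scalar G estimate, with attributes `se` (propagated Poisson
#'   standard error) and `window`.
#' @examples
#' t <- seq(0, 25, length.out = 256)
#' hv <- decay_histogram(t, 1200 * exp(-t / 5), geometry = "HV")
#' hh <- decay_histogram(t, 1000 * exp(-t / 5), geometry = "HH")
#' compute_g_factor(hv, hh)  # 1.2
#' @export
compute_g_factor <- function(hv, hh, window = NULL, baseline = 0) {
  stopifnot(inherits(hv, "decay_histogram"), inherits(hh, "decay_histogram"))
  if (!.same_grid(hv, hh)) {
    stop("HV and HH histograms must share the same time grid", call. = FALSE)
  }
  idx <- if (is.null(window)) {
    seq_along(hv$time_ns)
  } else {
    which(hv$time_ns >= window[1] & hv$time_ns <= window[2])
  }
  if (!length(idx)) stop("empty integration window", call. = FALSE)
  num_counts <- sum(hv$counts[idx])
  den_counts <- sum(hh$counts[idx])
  if (num_counts < 100 || den_counts < 100) {
    warning(sprintf(paste("fewer than 100 counts in the G-factor window",
                          "(HV: %.0f, HH: %.0f); estimate is noisy"),
                    num_counts, den_counts), call. = FALSE)
  }
  num <- num_counts - baseline * length(idx)
  den <- den_counts - baseline * length(idx)
  if (den <= 0) {
    stop("HH window counts are zero or negative after baseline subtraction",
         call. = FALSE)
  }
  if (num <= 0) {
    stop("HV window counts are zero or negative after baseline subtraction",
         call. = FALSE)
  }
  g <- num / den
  se <- g * sqrt(1 / max(num_counts, 1) + 1 / max(den_counts, 1))
  structure(g, se = se, window = range(hv$time_ns[idx]))
}

#' Construct a G-corrected anisotropy decay
#'
#' Combines the vertically excited polarized decays into the time-resolved
#' anisotropy `r(t) = (VV - G VH) / (VV + 2 G VH)` and the isotropic total
#' intensity `I(t) = VV + 2 G VH`. Channels whose denominator falls below
#' `min_denominator` counts are masked (not clamped): at low counts the
#' anisotropy ratio is dominated by shot noise and unbounded. Per-channel
#' variance of `r` is propagated from Poisson count statistics by the delta
#' method and carried along for weighting downstream fits.
#'
#' @param vv,vh [decay_histogram()] objects on the same grid.
#' @param g detector sensitivity ratio, e.g. from [compute_g_factor()].
#' @param min_denominator counts threshold below which a channel is masked
#'   (default 30, keeping the per-channel anisotropy standard deviation
#'   below roughly 0.03 at r = 0).
#' @return An object of class `anisotropy_decay`: list with `time_ns`, `r`
#'   (NA on masked channels), `var_r`, `valid` (logical mask), `g_used`, and
#'   `total` (the total-intensity [decay_histogram]).
#' @examples
#' t <- seq(0, 25, length.out = 256)
#' I <- 3e4 * exp(-t / 5)
#' r <- 0.35 * exp(-t / 2)
#' vv <- decay_histogram(t, I * (1 + 2 * r) / 3, geometry = "VV")
#' vh <- decay_histogram(t, I * (1 - r) / 3, geometry = "VH")
#' a <- build_anisotropy(vv, vh, g = 1)
#' max(abs(a$r[a$valid] - 0.35 * exp(-t[a$valid] / 2)))
#' @export
build_anisotropy <- function(vv, vh, g, min_denominator = 30) {
  stopifnot(inherits(vv, "decay_histogram"), inherits(vh, "decay_histogram"))
  if (!.same_grid(vv, vh)) {
    stop("VV and VH histograms must share the same time grid", call. = FALSE)
  }
  g <- as.numeric(g)
  .check_positive_scalar(g, "g")
  num <- vv$counts - g * vh$counts
  den <- vv$counts + 2 * g * vh$counts
  valid <- den >= min_denominator
  r <- rep(NA_real_, length(den))
  r[valid] <- num[valid] / den[valid]

  # delta-method variance from Poisson counts: var(VV)=VV, var(VH)=VH
  var_r <- rep(NA_real_, length(den))
  dvv <- 3 * g * vh$counts / den^2       # dr/dVV
  dvh <- -3 * g * vv$counts / den^2      # dr/dVH
  var_r[valid] <- (dvv^2 * vv$counts + dvh^2 * vh$counts)[valid]

  total <- decay_histogram(vv$time_ns, pmax(den, 0), geometry = "magic",
                           meta = list(g_used = g))
  structure(list(time_ns = vv$time_ns, r = r, var_r = var_r, valid = valid,
                 g_used = g, total = total),
            class = "anisotropy_decay")
}

#' @export
print.anisotropy_decay <- function(x, ...) {
  cat(sprintf("Anisotropy decay r(t): %d channels (%d valid), G = %.4g\n",
              length(x$r), sum(x$valid), x$g_used))
  if (any(x$valid)) {
    cat(sprintf("  r range on valid channels: [%.4g, %.4g]\n",
                min(x$r[x$valid]), max(x$r[x$valid])))
  }
  invisible(x)
}

#' Fit the rotational correlation time from an anisotropy decay
#'
#' Fits `r(t) = sum_j A_j exp(-t/theta_j)` over the valid channels, weighted
#' by the per-channel anisotropy variance propagated from photon counts, and
#' returns the amplitude-weighted mean correlation time
#' `theta = sum(A_j theta_j) / sum(A_j)`. The hindered-rotor plateau term
#' `r_inf` is off by default (pure multiexponential model); set
#' `offset = TRUE` to free it.
#'
#' @param r an [build_anisotropy()] result.
#' @param n_components number of exponential components (1--4).
#' @param fit_range optional `c(t_start, t_stop)` ns.
#' @param offset fit a constant plateau term (default `FALSE`).
#' @return A list of class `rotational_fit`: `fit` (the [multiexp_fit]),
#'   `theta_ns` (amplitude-weighted mean, NA if the fit failed), and
#'   `r0_fitted` (sum of amplitudes, the fitted initial anisotropy).
#' @examples
#' t <- seq(0, 25, length.out = 512)
#' I <- 1e5 * exp(-t / 5)
#' rtrue <- 0.35 * exp(-t / 2)
#' vv <- decay_histogram(t, I * (1 + 2 * rtrue) / 3, geometry = "VV")
#' vh <- decay_histogram(t, I * (1 - rtrue) / 3, geometry = "VH")
#' rf <- fit_rotational_correlation(build_anisotropy(vv, vh, 1), 1)
#' rf$theta_ns  # ~2
#' @export
fit_rotational_correlation <- function(r, n_components = 1L,
                                       fit_range = NULL, offset = FALSE) {
  stopifnot(inherits(r, "anisotropy_decay"))
  valid <- r$valid & is.finite(r$r)
  if (sum(valid) < 50L) {
    stop(sprintf("only %d valid channels; need >= 50", sum(valid)),
         call. = FALSE)
  }
  t <- r$time_ns[valid]
  rv <- r$r[valid]
  sig <- sqrt(r$var_r[valid])
  if (!is.null(fit_range)) {
    keep <- t >= fit_range[1] & t <= fit_range[2]
    t <- t[keep]; rv <- rv[keep]; sig <- sig[keep]
    if (length(t) < 50L) {
      stop("fewer than 50 valid channels inside `fit_range`", call. = FALSE)
    }
  }
  if (max(abs(rv)) < 1e-12) {
    return(structure(list(
      fit = .failed_fit(n_components, t, rv, "unknown",
                        reason = "anisotropy signal is identically zero"),
      theta_ns = NA_real_, r0_fitted = NA_real_),
      class = "rotational_fit"))
  }
  if (any(!is.finite(sig)) || all(sig == 0)) sig <- rep(1, length(rv))
  sig[sig == 0] <- min(sig[sig > 0])

  fit <- .multiexp_ls(t = t, y = rv, sigma = sig,
                      n_components = n_components, baseline = offset,
                      nonneg_amplitudes = FALSE)
  theta <- if (fit$converged) {
    tryCatch(amplitude_weighted_mean(fit), error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(list(fit = fit, theta_ns = theta,
                 r0_fitted = if (fit$converged) sum(fit$components$amplitude)
                             else NA_real_),
            class = "rotational_fit")
}

#' @export
print.rotational_fit <- function(x, ...) {
  cat("Rotational correlation fit\n")
  if (is.na(x$theta_ns)) {
    cat("  ** fit failed **\n")
  } else {
    cat(sprintf("  theta (amplitude-weighted) = %.4g ns, fitted r0 = %.4g\n",
                x$theta_ns, x$r0_fitted))
  }
  invisible(x)
}
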