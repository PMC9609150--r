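#' Fit a multiexponential model to a TCSPC decay
#'
#' Weighted least-squares fit of
#' `f(t) = baseline + sum_i A_i exp(-(t - t0)/tau_i)` to a photon histogram.
#' Without an IRF the fit is a tail fit starting (by default) at the channel
#' of maximum counts; with an IRF the model decay is reconvolved with the
#' normalized instrument response on the full grid before comparison.
#' Poisson weighting uses per-channel variance `max(counts, 1)`, the
#' standard Neyman weighting for TCSPC histograms. Initial lifetimes are
#' log-spaced about the empirical 1/e time and refined through a fixed
#' multi-start schedule of bounded Levenberg--Marquardt runs, so results are
#' deterministic given the data and options.
#'
#' @param decay a [decay_histogram()].
#' @param n_components number of exponential components, 1--4.
#' @param irf optional [decay_histogram()] of the instrument response on the
#'   same grid; switches the fit from tail mode to reconvolution mode.
#' @param weighting `"poisson"` (default) or `"uniform"`; ignored when
#'   `sigma` is given.
#' @param fit_range optional `c(t_start, t_stop)` in ns restricting the
#'   fitted window; default is peak-to-end (tail) or the full grid
#'   (reconvolution).
#' @param baseline if `TRUE` (default) fit a free non-negative constant
#'   background.
#' @param nonneg_amplitudes constrain amplitudes to be `>= 0` (appropriate
#'   for intensity decays; anisotropy fits release this).
#' @param sigma optional per-channel standard deviations (same length as the
#'   histogram, or as the fit window) overriding `weighting`.
#' @param max_restarts maximum number of multi-start refinements (default 5).
#'
#' @return An object of class `multiexp_fit` with elements
#'   `components` (data.frame: `amplitude`, `amplitude_pct`, `time_ns`,
#'   `stderr_amplitude`, `stderr_time`, sorted by ascending relaxation time),
#'   `baseline`, `reduced_chi2`, `n_components`, `converged`,
#'   `identifiable` (FALSE when any relative stderr exceeds 100%),
#'   `fit_range`, `mode` (`"tail"` or `"reconvolution"`), `fitted`,
#'   `residuals` (weighted), and `data` (the fitted sub-histogram).
#' @seealso [amplitude_weighted_mean()], [fast_component_fraction()]
#' @examples
#' t <- seq(0, 30, length.out = 1024)
#' h <- decay_histogram(t, 1e4 * exp(-t / 5.601))
#' fit <- fit_multiexp(h, 1, weighting = "uniform")
#' fit$components$time_ns  # ~5.601
#' @export
fit_multiexp <- function(decay, n_components, irf = NULL,
                         weighting = c("poisson", "uniform"),
                         fit_range = NULL, baseline = TRUE,
                         nonneg_amplitudes = TRUE, sigma = NULL,
                         max_restarts = 5L) {
  stopifnot(inherits(decay, "decay_histogram"))
  weighting <- match.arg(weighting)
  if (!n_components %in% 1:4) {
    stop("`n_components` must be an integer in 1..4", call. = FALSE)
  }
  t_all <- decay$time_ns
  y_all <- decay$counts
  if (all(y_all == 0)) {
    stop("decay histogram contains no photons", call. = FALSE)
  }

  reconv <- !is.null(irf)
  kernel <- NULL
  if (reconv) {
    stopifnot(inherits(irf, "decay_histogram"))
    if (!.same_grid(decay, irf)) {
      stop("IRF and decay must share the same time grid", call. = FALSE)
    }
    if (sum(irf$counts) <= 0) stop("IRF has no counts", call. = FALSE)
    kernel <- irf$counts / sum(irf$counts)
  }

  if (is.null(fit_range)) {
    start <- if (reconv) 1L else which.max(y_all)
    idx <- start:length(t_all)
  } else {
    idx <- which(t_all >= fit_range[1] & t_all <= fit_range[2])
  }
  n_par <- n_components * 2L + as.integer(baseline)
  if (length(idx) < 10L * n_par) {
    stop(sprintf("fit window has %d channels; need >= 10 x %d parameters",
                 length(idx), n_par), call. = FALSE)
  }
  y <- y_all[idx]

  sig <- if (!is.null(sigma)) {
    if (length(sigma) == length(t_all)) sigma[idx] else sigma
  } else if (weighting == "poisson") {
    sqrt(pmax(y, 1))
  } else {
    rep(1, length(y))
  }
  if (length(sig) != length(y)) {
    stop("`sigma` must match the histogram or the fit window", call. = FALSE)
  }
  if (any(sig <= 0)) stop("weights (sigma) must be positive", call. = FALSE)

  .multiexp_ls(t = t_all[idx], y = y, sigma = sig,
               n_components = n_components, baseline = baseline,
               nonneg_amplitudes = nonneg_amplitudes, kernel = kernel,
               t_full = t_all, idx = idx, geometry = decay$geometry,
               max_restarts = max_restarts)
}

# Shared bounded Levenberg-Marquardt multiexponential engine.
# `y` may be real-valued (anisotropy); `kernel` non-NULL switches to
# reconvolution on the full grid `t_full`, sampled at `idx`.
.multiexp_ls <- function(t, y, sigma, n_components, baseline,
                         nonneg_amplitudes, kernel = NULL, t_full = NULL,
                         idx = NULL, geometry = "unknown",
                         max_restarts = 5L) {
  t0 <- t[1]
  reconv <- !is.null(kernel)

  model_fun <- function(par) {
    nA <- n_components
    A <- par[seq_len(nA)]
    tau <- par[nA + seq_len(nA)]
    base <- if (baseline) par[2L * nA + 1L] else 0
    if (reconv) {
      m_full <- rowSums(vapply(seq_len(nA), function(i) {
        A[i] * exp(-t_full / tau[i])
      }, numeric(length(t_full))))
      .convolve_irf(m_full, kernel)[idx] + base
    } else {
      rowSums(vapply(seq_len(nA), function(i) {
        A[i] * exp(-(t - t0) / tau[i])
      }, numeric(length(t)))) + base
    }
  }
  resid_fun <- function(par) (y - model_fun(par)) / sigma

  # empirical 1/e time of the decaying tail for lifetime initialization
  ay <- abs(y)
  peak_i <- which.max(ay)
  below <- which(ay <= ay[peak_i] / exp(1) & t > t[peak_i])
  te <- if (length(below)) t[below[1]] - t[peak_i] else diff(range(t)) / 3
  te <- max(te, t[2] - t[1])

  scales <- c(1, 1 / 3, 3, 1 / 10, 10)[seq_len(max(1L, min(max_restarts, 5L)))]
  lower <- c(if (nonneg_amplitudes) rep(0, n_components) else
               rep(-Inf, n_components),
             rep(1e-4 * te, n_components),
             if (baseline) 0)
  upper <- c(rep(Inf, n_components),
             rep(50 * diff(range(t)), n_components),
             if (baseline) Inf)

  best <- NULL
  for (sc in scales) {
    tau0 <- if (n_components == 1L) te * sc else
      te * sc * exp(seq(-1, 1, length.out = n_components) * log(4))
    A0 <- .init_amplitudes(t - t0, y, tau0, nonneg_amplitudes)
    par0 <- c(A0, tau0, if (baseline) max(min(y), 1e-9))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  if (is.null(best)) {
    return(.failed_fit(n_components, t, y, geometry,
                       reason = "no Levenberg-Marquardt start converged"))
  }

  par <- best$par
  A <- par[seq_len(n_components)]
  tau <- par[n_components + seq_len(n_components)]
  base <- if (baseline) par[2L * n_components + 1L] else 0

  dof <- max(length(y) - length(par), 1)
  se <- tryCatch(
    suppressWarnings(sqrt(diag(best$deviance / dof * solve(best$hessian)))),
    error = function(e) {
      # a parameter stuck at a bound makes the hessian singular; a small
      # ridge recovers finite errors for the well-determined directions
      H <- best$hessian
      ridge <- 1e-10 * max(abs(diag(H)), 1)
      tryCatch(
        suppressWarnings(sqrt(diag(best$deviance / dof *
                                     solve(H + ridge * diag(nrow(H)))))),
        error = function(e2) rep(NA_real_, length(par)))
    })
  seA <- se[seq_len(n_components)]
  seT <- se[n_components + seq_len(n_components)]

  ord <- order(tau)
  A <- A[ord]; tau <- tau[ord]; seA <- seA[ord]; seT <- seT[ord]
  tot <- sum(A)

  # a singular information matrix (NA stderr) means the model is
  # over-parameterized for the data, as does a relative stderr beyond 100%;
  # an exact (noise-free) fit carries no error information to judge by
  exact_fit <- best$deviance / dof < 1e-15 * max(abs(y / sigma))^2
  rel_se <- c(abs(seA / A), abs(seT / tau))
  identifiable <- exact_fit ||
    (all(is.finite(rel_se)) && all(rel_se <= 1))
  converged <- best$info %in% 1:4 && is.finite(best$deviance)
  if (!identifiable) {
    warning(sprintf(paste("fit with %d components is poorly identifiable",
                          "(a relative stderr exceeds 100%%)"), n_components),
            call. = FALSE)
  }

  structure(list(
    components = data.frame(
      amplitude = A,
      amplitude_pct = if (tot != 0) 100 * A / tot else
        rep(NA_real_, n_components),
      time_ns = tau,
      stderr_amplitude = seA,
      stderr_time = seT),
    baseline = base,
    reduced_chi2 = best$deviance / dof,
    n_components = n_components,
    converged = converged,
    identifiable = identifiable,
    fit_range = range(t),
    mode = if (reconv) "reconvolution" else "tail",
    fitted = model_fun(best$par),
    residuals = resid_fun(best$par),
    data = list(time_ns = t, counts = y, geometry = geometry)),
    class = "multiexp_fit")
}

# linear least-squares amplitudes for fixed lifetime guesses
.init_amplitudes <- function(tt, y, tau, nonneg) {
  X <- vapply(tau, function(tv) exp(-tt / tv), numeric(length(tt)))
  A <- tryCatch(stats::lm.fit(as.matrix(X), y)$coefficients,
                error = function(e) rep(max(abs(y)) / length(tau),
                                        length(tau)))
  A[!is.finite(A)] <- max(abs(y)) / length(tau)
  if (nonneg) A <- pmax(A, 1e-6 * max(abs(y)))
  A
}

.failed_fit <- function(n_components, t, y, geometry, reason) {
  warning("multiexponential fit failed: ", reason, call. = FALSE)
  structure(list(
    components = data.frame(amplitude = rep(NA_real_, n_components),
                            amplitude_pct = NA_real_, time_ns = NA_real_,
                            stderr_amplitude = NA_real_,
                            stderr_time = NA_real_),
    baseline = NA_real_, reduced_chi2 = NA_real_,
    n_components = n_components, converged = FALSE, identifiable = FALSE,
    fit_range = range(t), mode = "failed",
    fitted = NULL, residuals = NULL,
    data = list(time_ns = t, counts = y, geometry = geometry)),
    class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("Multiexponential fit (%d component%s, %s mode)\n",
              x$n_components, if (x$n_components > 1) "s" else "", x$mode))
  if (!x$converged) cat("  ** fit did not converge **\n")
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  A%d = %.4g (%.2f%%), time = %.4g +/- %.2g ns\n",
                i, comp$amplitude[i], comp$amplitude_pct[i],
                comp$time_ns[i], comp$stderr_time[i]))
  }
  cat(sprintf("  baseline = %.4g, reduced chi-squared = %.4g\n",
              x$baseline, x$reduced_chi2))
  invisible(x)
}

#' Amplitude-weighted mean relaxation time
#'
#' Computes `sum(A_i * tau_i) / sum(A_i)` over the components of a
#' multiexponential fit — the amplitude-weighted average lifetime
#' (`tau_av`) for intensity decays, or the mean rotational correlation time
#' when applied to an anisotropy fit.
#'
#' @param fit a [multiexp_fit] object, or a numeric vector of amplitudes.
#' @param time_ns relaxation times, required when `fit` is a plain
#'   amplitude vector.
#' @return The amplitude-weighted mean relaxation time in ns.
#' @examples
#' amplitude_weighted_mean(c(0.1819, 0.8181), c(1, 6))  # 5.0905
#' @export
amplitude_weighted_mean <- function(fit, time_ns = NULL) {
  if (inherits(fit, "multiexp_fit")) {
    A <- fit$components$amplitude
    tau <- fit$components$time_ns
  } else {
    A <- fit
    tau <- time_ns
    if (is.null(tau) || length(tau) != length(A)) {
      stop("supply matching `time_ns` for plain amplitude vectors",
           call. = FALSE)
    }
  }
  if (length(A) < 1L || any(!is.finite(A)) || any(!is.finite(tau))) {
    stop("fit has no finite components", call. = FALSE)
  }
  if (sum(A) == 0) stop("total amplitude is zero", call. = FALSE)
  sum(A * tau) / sum(A)
}

#' Amplitude fraction of the fastest decay component
#'
#' Returns the amplitude of the shortest-lifetime component divided by the
#' total amplitude. In a donor-quenching experiment this fraction is the
#' share of donor molecules engaged in energy transfer, which multiplied by
#' the probe concentration bounds the delivered acceptor concentration from
#' below (see [delivered_concentration()]).
#'
#' @param fit a [multiexp_fit] with at least two components.
#' @return Fraction in `[0, 1]` (for non-negative amplitudes).
#' @examples
#' t <- seq(0, 40, length.out = 1024)
#' y <- 1819 * exp(-t / 1) + 8181 * exp(-t / 6)
#' fit <- fit_multiexp(decay_histogram(t, y), 2, weighting = "uniform")
#' fast_component_fraction(fit)  # ~0.1819
#' @export
fast_component_fraction <- function(fit) {
  stopifnot(inherits(fit, "multiexp_fit"))
  comp <- fit$components
  if (nrow(comp) < 2L) {
    stop("fast-component fraction needs a fit with >= 2 components",
         call. = FALSE)
  }
  if (any(!is.finite(comp$amplitude))) {
    stop("fit has non-finite amplitudes", call. = FALSE)
  }
  tot <- sum(comp$amplitude)
  if (tot == 0) stop("total amplitude is zero", call. = FALSE)
  comp$amplitude[which.min(comp$time_ns)] / tot
}
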