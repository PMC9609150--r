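#' Construct a TCSPC decay histogram
#'
#' A decay histogram is the raw observable of a polarized TCSPC measurement:
#' photon counts per time channel for one excitation/emission polarizer
#' geometry. The first letter of the geometry code is the excitation
#' polarizer, the second the emission analyzer (V vertical, H horizontal);
#' `"magic"` denotes magic-angle (polarization-free) detection.
#'
#' @param time_ns numeric vector, strictly increasing uniform time grid in ns.
#' @param counts numeric vector of non-negative photon counts, same length as
#'   `time_ns`. Measured histograms hold integers; noise-free (expected-value)
#'   histograms produced by the simulator may hold non-integer values.
#' @param geometry one of `"VV"`, `"VH"`, `"HV"`, `"HH"`, `"magic"`,
#'   `"unknown"`, or `"IRF"` for an instrument-response histogram.
#' @param meta named list of free-form metadata (e.g. temperature_C,
#'   excitation_nm, emission_nm).
#'
#' @return An object of class `decay_histogram`: a list with elements
#'   `time_ns`, `counts`, `geometry`, `meta`.
#' @examples
#' t <- seq(0, 25, length.out = 512)
#' h <- decay_histogram(t, round(1e4 * exp(-t / 5)), geometry = "magic")
#' h
#' @export
decay_histogram <- function(time_ns, counts,
                            geometry = c("unknown", "VV", "VH", "HV", "HH",
                                         "magic", "IRF"),
                            meta = list()) {
  geometry <- match.arg(geometry)
  if (!is.numeric(time_ns) || length(time_ns) < 2L) {
    stop("`time_ns` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (length(counts) != length(time_ns)) {
    stop("`counts` and `time_ns` must have the same length", call. = FALSE)
  }
  dt <- diff(time_ns)
  if (any(dt <= 0)) {
    stop("`time_ns` must be strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("`time_ns` must be a uniform grid", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  structure(list(time_ns = as.numeric(time_ns),
                 counts = as.numeric(counts),
                 geometry = geometry,
                 meta = meta),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay histogram [%s]\n", x$geometry))
  cat(sprintf("  %d channels, %.4g ns/channel, range %.3g-%.3g ns\n",
              length(x$time_ns), x$time_ns[2] - x$time_ns[1],
              min(x$time_ns), max(x$time_ns)))
  cat(sprintf("  total counts: %.6g, peak: %.6g at %.3g ns\n",
              sum(x$counts), max(x$counts),
              x$time_ns[which.max(x$counts)]))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

# channel width of a histogram, ns
.dt <- function(h) h$time_ns[2] - h$time_ns[1]

.same_grid <- function(a, b) {
  length(a$time_ns) == length(b$time_ns) &&
    max(abs(a$time_ns - b$time_ns)) <= 1e-9 * (.dt(a) + 1e-300)
}
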