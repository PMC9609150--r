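#' Validated pipeline configuration
#'
#' Collects the physical constants and fit options that the end-to-end
#' pipeline needs. Unknown fields are rejected so typos cannot silently
#' fall back to defaults. Defaults follow the reference system: a BODIPY
#' membrane rotor probe at 1 uM (quantum yield 0.95) in a soy-lecithin
#' emulsion (refractive index 1.4251) with a ketocarotenoid acceptor (peak
#' molar extinction 75,300 M^-1 cm^-1).
#'
#' @param ... configuration fields overriding the defaults; see Details.
#' @details Fields: `temperature_K` (or `temperature_C`), `probe_radius_nm`,
#' `probe_conc_nM`, `kappa2`, `quantum_yield`, `refractive_index`,
#' `molar_extinction_peak`, `n_components_intensity`,
#' `n_components_anisotropy`, `weighting` ("poisson"/"uniform"),
#' `fit_range` (NULL or c(lo, hi) ns), `g_window` (NULL or c(lo, hi) ns),
#' `min_denominator`, `seed`, and an optional `truth` list forwarded to
#' [ground_truth()] together with `time_max`, `n_channels` when the
#' pipeline simulates its own input.
#' @return Object of class `run_config` (a validated named list).
#' @examples
#' run_config(temperature_C = 20, probe_radius_nm = 0.5)
#' @export
run_config <- function(...) {
  defaults <- list(
    temperature_K = 293.15,
    probe_radius_nm = 0.5,
    probe_conc_nM = 1000,
    kappa2 = 2 / 3,
    quantum_yield = 0.95,
    refractive_index = 1.4251,
    molar_extinction_peak = 75300,
    n_components_intensity = 1L,
    n_components_anisotropy = 1L,
    weighting = "poisson",
    fit_range = NULL,
    g_window = NULL,
    min_denominator = 30,
    seed = 1L,
    truth = NULL,
    time_max = 25,
    n_channels = 4096L)
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user))) {
    user <- user[[1]]
  }
  if ("temperature_C" %in% names(user)) {
    user$temperature_K <- user$temperature_C + 273.15
    user$temperature_C <- NULL
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, user, keep.null = TRUE)
  .check_positive_scalar(cfg$temperature_K, "temperature_K")
  .check_positive_scalar(cfg$probe_radius_nm, "probe_radius_nm")
  .check_positive_scalar(cfg$probe_conc_nM, "probe_conc_nM")
  if (cfg$kappa2 < 0 || cfg$kappa2 > 4) {
    stop("`kappa2` must lie in [0, 4]", call. = FALSE)
  }
  if (cfg$quantum_yield <= 0 || cfg$quantum_yield > 1) {
    stop("`quantum_yield` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$refractive_index < 1) {
    stop("`refractive_index` must be >= 1", call. = FALSE)
  }
  if (!cfg$weighting %in% c("poisson", "uniform")) {
    stop("`weighting` must be \"poisson\" or \"uniform\"", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' Run the full anisotropy / FRET pipeline
#'
#' Orchestrates the analysis chain on one four-geometry polarized
#' measurement: G factor from the horizontal-excitation pair, anisotropy
#' construction, rotational-correlation fit and microviscosity; intensity
#' (total) decay fit and amplitude-weighted lifetime; and, when a donor
#' reference lifetime and/or spectra are supplied, FRET efficiency,
#' donor-acceptor distance and delivered-acceptor concentration.
#'
#' @param config a [run_config()].
#' @param inputs either `NULL` (simulate from `config$truth`, which must
#'   then be set), a path to a [write_histogram_table()] file, or a list
#'   holding `VV`, `VH`, `HV`, `HH` ([decay_histogram]s) and optional
#'   `irf`. Optional further elements: `donor_emission` and
#'   `acceptor_extinction` ([spectrum]s) for the overlap integral, and
#'   `tau_D_ns` (donor-only reference lifetime) to turn the fitted
#'   quenched lifetime into a FRET efficiency.
#' @return Object of class `result_record`: `provenance` (package version,
#'   timestamp, config snapshot, input file digest when applicable) and
#'   `payload` with one entry per stage (`g_factor`, `anisotropy_fit`,
#'   `theta_ns`, `viscosity`, `intensity_fit`, `tau_av_ns`, and the FRET
#'   block when computable).
#' @examples
#' cfg <- run_config(truth = list(
#'   intensity_components = cbind(1, 2.5), anisotropy_r0 = 0.3,
#'   anisotropy_components = cbind(1, 1), g_true = 1.1,
#'   total_counts = 2e5, irf_fwhm = 0, seed = 11),
#'   time_max = 14, n_channels = 1024, n_components_intensity = 1)
#' res <- run_pipeline(cfg)
#' res$payload$g_factor
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  digest <- NULL
  tau_D_ns <- NULL
  donor_emission <- NULL
  acceptor_extinction <- NULL

  if (is.null(inputs)) {
    if (is.null(config$truth)) {
      stop("pipeline stage [input]: no inputs given and no `truth` in the ",
           "config to simulate from", call. = FALSE)
    }
    tr <- do.call(ground_truth, config$truth)
    decays <- simulate_polarized_decays(tr, time_max = config$time_max,
                                        n_channels = config$n_channels)
  } else if (is.character(inputs)) {
    digest <- unname(tools::md5sum(inputs))
    decays <- read_histogram_table(inputs)
  } else {
    decays <- inputs
    tau_D_ns <- inputs$tau_D_ns
    donor_emission <- inputs$donor_emission
    acceptor_extinction <- inputs$acceptor_extinction
  }
  missing <- setdiff(c("VV", "VH", "HV", "HH"), names(decays))
  if (length(missing)) {
    stop("pipeline stage [input]: missing geometries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage [%s]: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  g <- stage("g_factor", compute_g_factor(decays$HV, decays$HH,
                                          window = config$g_window))
  aniso <- stage("anisotropy",
                 build_anisotropy(decays$VV, decays$VH, as.numeric(g),
                                  min_denominator = config$min_denominator))
  rot <- stage("rotational_fit",
               fit_rotational_correlation(
                 aniso, n_components = config$n_components_anisotropy,
                 fit_range = config$fit_range))
  visc <- if (!is.na(rot$theta_ns)) {
    stage("viscosity", microviscosity(rot$theta_ns, config$temperature_K,
                                      config$probe_radius_nm))
  }

  ifit <- stage("intensity_fit",
                fit_multiexp(aniso$total,
                             n_components = config$n_components_intensity,
                             irf = decays$irf,
                             weighting = config$weighting,
                             fit_range = config$fit_range))
  tau_av <- if (ifit$converged) amplitude_weighted_mean(ifit) else NA_real_

  payload <- list(
    g_factor = as.numeric(g),
    g_factor_se = attr(g, "se"),
    anisotropy_fit = rot,
    theta_ns = rot$theta_ns,
    r0_fitted = rot$r0_fitted,
    viscosity = visc,
    intensity_fit = ifit,
    tau_av_ns = tau_av)

  fi <- fret_inputs(kappa2 = config$kappa2,
                    quantum_yield = config$quantum_yield,
                    refractive_index = config$refractive_index,
                    donor_conc_nM = config$probe_conc_nM,
                    molar_extinction_peak = config$molar_extinction_peak)
  if (!is.null(donor_emission) && !is.null(acceptor_extinction)) {
    payload$J <- stage("overlap_integral",
                       overlap_integral(
                         donor_emission,
                         scale_to_extinction(acceptor_extinction,
                                             fi$molar_extinction_peak)))
    payload$R0_angstrom <- stage("forster_distance",
                                 forster_distance(payload$J, fi))
  }
  if (!is.null(tau_D_ns) && is.finite(tau_av)) {
    payload$efficiency_W <- stage("efficiency",
                                  efficiency_from_lifetimes(tau_D_ns,
                                                            tau_av))
    if (!is.null(payload$R0_angstrom) && payload$efficiency_W > 0 &&
        payload$efficiency_W < 1) {
      payload$R_DA_angstrom <- stage("distance",
                                     distance_from_efficiency(
                                       payload$R0_angstrom,
                                       payload$efficiency_W))
    }
    if (ifit$n_components >= 2L && ifit$converged) {
      ff <- stage("fast_fraction", fast_component_fraction(ifit))
      payload$fast_fraction <- ff
      payload$delivered_conc_nM <- stage(
        "delivered_concentration",
        delivered_concentration(ff, config$probe_conc_nM))
    }
  }

  structure(list(
    provenance = list(
      package = "anisofret",
      version = as.character(utils::packageVersion("anisofret")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input_digest = digest,
      config = unclass(config)),
    payload = payload),
    class = "result_record")
}

#' @export
print.result_record <- function(x, ...) {
  cat("anisofret result record (v", x$provenance$version, ")\n", sep = "")
  p <- x$payload
  cat(sprintf("  G = %.4g, theta = %.4g ns, tau_av = %.4g ns\n",
              p$g_factor, p$theta_ns, p$tau_av_ns))
  if (!is.null(p$viscosity)) {
    cat(sprintf("  eta = %.4g mPa s\n", p$viscosity$eta_mPa_s))
  }
  if (!is.null(p$efficiency_W)) {
    cat(sprintf("  W = %.4g", p$efficiency_W))
    if (!is.null(p$R_DA_angstrom)) {
      cat(sprintf(", R_DA = %.3g A", p$R_DA_angstrom))
    }
    cat("\n")
  }
  if (!is.null(p$delivered_conc_nM)) {
    cat(sprintf("  delivered acceptor >= %.4g nM\n", p$delivered_conc_nM))
  }
  invisible(x)
}

#' Serialize a result record to JSON
#'
#' Scalar payload entries and the provenance block are written as JSON;
#' fit objects are reduced to their component tables. The numeric payload
#' round-trips losslessly (`digits = NA`).
#'
#' @param record a `result_record` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_record <- function(record, path) {
  stopifnot(inherits(record, "result_record"))
  flat <- unclass(record)
  flat$payload <- lapply(record$payload, function(el) {
    if (inherits(el, "rotational_fit")) {
      list(components = el$fit$components, theta_ns = el$theta_ns,
           converged = el$fit$converged,
           reduced_chi2 = el$fit$reduced_chi2)
    } else if (inherits(el, "multiexp_fit")) {
      list(components = el$components, baseline = el$baseline,
           converged = el$converged, reduced_chi2 = el$reduced_chi2)
    } else if (inherits(el, "viscosity_estimate")) {
      unclass(el)
    } else {
      el
    }
  })
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}
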