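# Shared synthetic fixtures. The two-component fixture emulates the
# donor-quenching situation: a dominant fast (quenched) component plus a
# minor slow (unquenched) one, 5e6 photons, detector bias 1.2, single-
# exponential anisotropy (r0 = 0.35, theta = 2 ns), ideal IRF.

two_component_truth <- function(seed, total_counts = 5e6) {
  ground_truth(
    intensity_components = cbind(c(0.82, 0.18), c(1.45, 5.601)),
    anisotropy_r0 = 0.35,
    anisotropy_components = cbind(1, 2),
    g_true = 1.2,
    total_counts = total_counts,
    irf_fwhm = 0,
    seed = seed)
}

simulate_fixture <- function(seed, n_channels = 2048, noise = TRUE,
                             total_counts = 5e6) {
  simulate_polarized_decays(two_component_truth(seed, total_counts),
                            time_max = 30, n_channels = n_channels,
                            noise = noise)
}

# single-lifetime truth used for simple recovery checks
mono_truth <- function(seed, tau = 5.601, r0 = 0.35, theta = 2,
                       g = 1.1, counts = 5e6, irf_fwhm = 0) {
  ground_truth(cbind(1, tau), anisotropy_r0 = r0,
               anisotropy_components = cbind(1, theta), g_true = g,
               total_counts = counts, irf_fwhm = irf_fwhm, seed = seed)
}
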