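# Generator: polarized decays, spectra, orientation ensembles

test_that("zero anisotropy with unit G makes VV and VH channel-wise equal", {
  tr <- ground_truth(cbind(1, 3), anisotropy_r0 = 0,
                     anisotropy_components = cbind(1, 1), g_true = 1,
                     total_counts = 1e6, irf_fwhm = 0, seed = 1)
  sim <- simulate_polarized_decays(tr, time_max = 16, n_channels = 512,
                                   noise = FALSE)
  expect_equal(sim$VV$counts, sim$VH$counts, tolerance = 1e-12)
  expect_equal(sim$HV$counts, sim$HH$counts, tolerance = 1e-12)
})

test_that("zero photon budget and zero background give all-zero histograms", {
  tr <- ground_truth(cbind(1, 3), total_counts = 0, background_rate = 0,
                     irf_fwhm = 0, seed = 1)
  sim <- simulate_polarized_decays(tr, time_max = 16, n_channels = 512)
  for (g in c("VV", "VH", "HV", "HH")) {
    expect_true(all(sim[[g]]$counts == 0))
  }
})

test_that("identical ground truth gives bit-identical histograms", {
  a <- simulate_fixture(seed = 7, n_channels = 512)
  b <- simulate_fixture(seed = 7, n_channels = 512)
  for (g in c("VV", "VH", "HV", "HH")) {
    expect_identical(a[[g]]$counts, b[[g]]$counts)
  }
  c_ <- simulate_fixture(seed = 8, n_channels = 512)
  expect_false(identical(a$VV$counts, c_$VV$counts))
})

test_that("expected counts obey photon conservation VV + 2 g VH = budget", {
  tr <- two_component_truth(seed = 3, total_counts = 2e6)
  nf <- simulate_polarized_decays(tr, time_max = 30, n_channels = 1024,
                                  noise = FALSE)
  iso <- sum(nf$VV$counts + 2 * tr$g_true * nf$VH$counts)
  expect_equal(iso, tr$total_counts, tolerance = 1e-10)

  noisy <- simulate_polarized_decays(tr, time_max = 30, n_channels = 1024)
  iso_n <- sum(noisy$VV$counts + 2 * tr$g_true * noisy$VH$counts)
  # Var(VV + 2gVH) per channel ~ VV + 4 g^2 VH; 5 sigma band on the total
  sd_tot <- sqrt(sum(noisy$VV$counts + 4 * tr$g_true^2 * noisy$VH$counts))
  expect_lt(abs(iso_n - tr$total_counts), 5 * sd_tot)
})

test_that("horizontal-analyzer channels carry the 1/g detector bias", {
  tr <- mono_truth(seed = 1, g = 1.3)
  nf <- simulate_polarized_decays(tr, time_max = 30, n_channels = 512,
                                  noise = FALSE)
  expect_equal(nf$HV$counts, 1.3 * nf$HH$counts, tolerance = 1e-12)
  expect_equal(nf$HV$counts, 1.3 * nf$VH$counts, tolerance = 1e-12)
})

test_that("time windows violating lifetime or IRF coverage are rejected", {
  tr <- mono_truth(seed = 1, tau = 5.601)
  expect_error(simulate_polarized_decays(tr, time_max = 10),
               "5 x the longest")
  tr2 <- ground_truth(cbind(1, 0.5), irf_fwhm = 20, seed = 1)
  expect_error(simulate_polarized_decays(tr2, time_max = 4,
                                         n_channels = 512),
               "IRF support")
})

test_that("ground truth validates fractions, r0 and positivity", {
  expect_error(ground_truth(cbind(c(0.5, 0.4), c(1, 2))), "sum to 1")
  expect_error(ground_truth(cbind(1, -2)), "times must be > 0")
  expect_error(ground_truth(cbind(1, 2), anisotropy_r0 = 0.5), "0, 0.4")
  expect_error(ground_truth(cbind(1, 2), g_true = -1), "g_true")
})

# --- spectra ---------------------------------------------------------------

test_that("single Gaussian band peaks at its center with its height", {
  s <- simulate_spectrum(spectrum_spec(cbind(570, 20, 1),
                                       grid = c(450, 700, 1)))
  expect_equal(s$wavelength_nm[which.max(s$values)], 570)
  expect_equal(max(s$values), 1, tolerance = 1e-12)
  # exact repeatability
  expect_identical(s$values,
                   simulate_spectrum(spectrum_spec(cbind(570, 20, 1),
                                                   grid = c(450, 700, 1)))$values)
})

test_that("integral of non-overlapping bands is the sum of band integrals", {
  spec <- spectrum_spec(rbind(c(450, 5, 2), c(650, 8, 1)),
                        grid = c(350, 750, 0.1))
  s <- simulate_spectrum(spec)
  got <- sum(diff(s$wavelength_nm) *
               (s$values[-1] + s$values[-length(s$values)]) / 2)
  analytic <- 2 * 5 * sqrt(2 * pi) + 1 * 8 * sqrt(2 * pi)
  expect_equal(got, analytic, tolerance = 1e-6)
})

test_that("zero-height bands give an identically zero spectrum", {
  s <- simulate_spectrum(spectrum_spec(cbind(500, 10, 0)))
  expect_true(all(s$values == 0))
})

test_that("empty or invalid band lists are rejected", {
  expect_error(spectrum_spec(matrix(numeric(0), ncol = 3)), "non-empty")
  expect_error(spectrum_spec(cbind(500, -1, 1)), "widths")
  expect_error(spectrum_spec(cbind(500, 1, -1)), "heights")
})

# --- orientation ensembles -------------------------------------------------

test_that("fixed mode repeats the axis; zero cone degenerates to fixed", {
  v <- simulate_orientation_ensemble(
    ensemble_spec("fixed", cone_axis = c(0, 0, 1), n_frames = 10))
  expect_equal(dim(v), c(10L, 3L))
  expect_true(all(v[, 3] == 1) && all(v[, 1:2] == 0))
  w <- simulate_orientation_ensemble(
    ensemble_spec("cone", cone_axis = c(0, 1, 0), cone_halfangle = 0,
                  n_frames = 5))
  expect_true(all(w[, 2] == 1))
})

test_that("isotropic mode matches uniform-sphere moments", {
  n <- 2e5
  v <- simulate_orientation_ensemble(
    ensemble_spec("isotropic", n_frames = n, seed = 10))
  expect_equal(sqrt(rowSums(v^2)), rep(1, n), tolerance = 1e-9)
  # component means: SE = sqrt(1/3)/sqrt(n); z^2 mean 1/3, var(z^2) = 4/45
  se1 <- sqrt(1 / 3 / n)
  for (j in 1:3) expect_lt(abs(mean(v[, j])), 3 * se1)
  se2 <- sqrt(4 / 45 / n)
  expect_lt(abs(mean(v[, 3]^2) - 1 / 3), 3 * se2)
})

test_that("cone mode stays inside the cap and is seed-reproducible", {
  ax <- c(1, 1, 1) / sqrt(3)
  sp <- ensemble_spec("cone", cone_axis = ax, cone_halfangle = 25,
                      n_frames = 5000, seed = 4)
  v <- simulate_orientation_ensemble(sp)
  ang <- acos(pmin(v %*% ax, 1)) * 180 / pi
  expect_true(all(ang <= 25 + 1e-9))
  expect_identical(v, simulate_orientation_ensemble(sp))
})

test_that("degenerate ensemble specs are rejected", {
  expect_error(ensemble_spec(cone_axis = c(0, 0, 0)), "non-zero")
  expect_error(ensemble_spec(cone_axis = c(0, 0, 2)), "unit norm")
  expect_error(ensemble_spec(cone_halfangle = 200), "0, 180")
  expect_error(ensemble_spec(n_frames = 0), "n_frames")
})
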