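# G factor, anisotropy construction, rotational correlation, microviscosity

test_that("identical HV and HH give G = 1; generator bias is recovered", {
  t <- seq(0, 25, length.out = 512)
  h <- decay_histogram(t, 500 * exp(-t / 5), geometry = "HV")
  h2 <- decay_histogram(t, 500 * exp(-t / 5), geometry = "HH")
  expect_equal(as.numeric(compute_g_factor(h, h2)), 1)

  tr <- mono_truth(seed = 21, g = 1.2, counts = 1e6)
  sim <- simulate_polarized_decays(tr, time_max = 30, n_channels = 1024)
  g <- compute_g_factor(sim$HV, sim$HH)
  expect_lt(abs(as.numeric(g) - 1.2), 3 * attr(g, "se"))
})

test_that("all-zero HH and grid mismatches are rejected", {
  t <- seq(0, 25, length.out = 512)
  hv <- decay_histogram(t, 500 * exp(-t / 5), geometry = "HV")
  hh0 <- decay_histogram(t, rep(0, 512), geometry = "HH")
  expect_error(suppressWarnings(compute_g_factor(hv, hh0)), "zero or negative")
  t2 <- seq(0, 30, length.out = 512)
  hh2 <- decay_histogram(t2, 500 * exp(-t2 / 5))
  expect_error(compute_g_factor(hv, hh2), "same time grid")
})

test_that("anisotropy limits: isotropic gives r = 0, no-VH gives r = 1", {
  t <- seq(0, 25, length.out = 256)
  I <- 3e4 * exp(-t / 5)
  vv <- decay_histogram(t, I, geometry = "VV")
  a0 <- build_anisotropy(vv, decay_histogram(t, I, geometry = "VH"), 1)
  expect_true(all(abs(a0$r[a0$valid]) < 1e-12))
  a1 <- build_anisotropy(vv, decay_histogram(t, rep(0, 256),
                                             geometry = "VH"), 1)
  expect_true(all(abs(a1$r[a1$valid] - 1) < 1e-12))
})

test_that("noise-free forward model reconstructs r(t) to 1e-8", {
  tr <- mono_truth(seed = 1, r0 = 0.35, theta = 2, g = 1.1)
  nf <- simulate_polarized_decays(tr, time_max = 30, n_channels = 2048,
                                  noise = FALSE)
  a <- build_anisotropy(nf$VV, nf$VH, 1.1, min_denominator = 1e-9)
  expected <- 0.35 * exp(-a$time_ns / 2)
  expect_lt(max(abs(a$r[a$valid] - expected[a$valid])), 1e-8)
})

test_that("rescaling horizontal-analyzer counts moves G but not r(t)", {
  tr <- two_component_truth(seed = 31)
  nf <- simulate_polarized_decays(tr, time_max = 30, n_channels = 1024,
                                  noise = FALSE)
  g1 <- as.numeric(compute_g_factor(nf$HV, nf$HH))
  c_ <- 2.5
  vh_s <- decay_histogram(nf$VH$time_ns, nf$VH$counts * c_, geometry = "VH")
  hh_s <- decay_histogram(nf$HH$time_ns, nf$HH$counts * c_, geometry = "HH")
  g2 <- as.numeric(compute_g_factor(nf$HV, hh_s))
  expect_equal(g2, g1 / c_, tolerance = 1e-10)
  r1 <- build_anisotropy(nf$VV, nf$VH, g1, min_denominator = 1e-9)
  r2 <- build_anisotropy(nf$VV, vh_s, g2, min_denominator = 1e-9)
  expect_equal(r2$r[r2$valid], r1$r[r1$valid], tolerance = 1e-10)
})

test_that("low-count channels are masked, not clamped", {
  t <- seq(0, 25, length.out = 256)
  vv <- decay_histogram(t, c(rep(1000, 100), rep(1, 156)), geometry = "VV")
  vh <- decay_histogram(t, c(rep(500, 100), rep(1, 156)), geometry = "VH")
  a <- build_anisotropy(vv, vh, 1, min_denominator = 30)
  expect_true(all(is.na(a$r[!a$valid])))
  expect_equal(sum(a$valid), 100)
})

test_that("rotational correlation time: closed-form and Eq.-6 composites", {
  t <- seq(0, 25, length.out = 1024)
  I <- 1e6 * exp(-t / 5)
  mk <- function(r) {
    vv <- decay_histogram(t, I * (1 + 2 * r) / 3, geometry = "VV")
    vh <- decay_histogram(t, I * (1 - r) / 3, geometry = "VH")
    build_anisotropy(vv, vh, 1)
  }
  f1 <- fit_rotational_correlation(mk(0.35 * exp(-t / 2)), 1)
  expect_equal(f1$theta_ns, 2, tolerance = 1e-6)
  expect_equal(f1$r0_fitted, 0.35, tolerance = 1e-6)

  r2 <- 0.2 * exp(-t / 0.5) + 0.15 * exp(-t / 5)
  f2 <- fit_rotational_correlation(mk(r2), 2)
  expect_equal(f2$theta_ns, (0.2 * 0.5 + 0.15 * 5) / 0.35,
               tolerance = 1e-4)
})

test_that("flat zero anisotropy is flagged as a failed fit", {
  t <- seq(0, 25, length.out = 512)
  I <- rep(1e4, 512)
  vv <- decay_histogram(t, I, geometry = "VV")
  vh <- decay_histogram(t, I, geometry = "VH")
  a <- build_anisotropy(vv, vh, 1)
  f <- suppressWarnings(fit_rotational_correlation(a, 1))
  expect_false(f$fit$converged)
  expect_true(is.na(f$theta_ns))
})

test_that("end-to-end simulate -> G -> r(t) -> fit recovers the truth", {
  zs <- sapply(1:3, function(s) {
    tr <- mono_truth(seed = 200 + s, r0 = 0.35, theta = 2, g = 1.1)
    sim <- simulate_polarized_decays(tr, time_max = 30, n_channels = 2048)
    g <- compute_g_factor(sim$HV, sim$HH)
    rf <- fit_rotational_correlation(build_anisotropy(sim$VV, sim$VH,
                                                      as.numeric(g)), 1)
    c(gz = abs(as.numeric(g) - 1.1) / attr(g, "se"),
      tz = abs(rf$fit$components$time_ns - 2) /
        rf$fit$components$stderr_time,
      r0 = rf$r0_fitted, r0se = rf$fit$components$stderr_amplitude)
  })
  expect_lt(median(zs["gz", ]), 3)
  expect_lt(median(zs["tz", ]), 3)
  # physical range: fitted r0 below the 0.4 photoselection limit
  expect_true(all(zs["r0", ] <= 0.4 + 3 * zs["r0se", ]))
})

test_that("Stokes-Einstein-Debye conversion matches the closed form", {
  # independent evaluation: eta = 3 kB T theta / (4 pi R^3), SI units
  kB <- 1.380649e-23
  eta_expected <- 3 * kB * 293.15 * 1e-9 / (4 * pi * (0.5e-9)^3) * 1e3
  expect_equal(microviscosity(1, 293.15, 0.5)$eta_mPa_s, eta_expected,
               tolerance = 1e-12)
  expect_equal(round(eta_expected, 2), 7.73)
})

test_that("viscosity <-> theta round-trips and scales linearly", {
  th <- theta_from_viscosity(100, 293.15, 0.5)
  expect_equal(microviscosity(th, 293.15, 0.5)$eta_mPa_s, 100,
               tolerance = 1e-12)
  # linear in theta, linear in 1/T
  e1 <- microviscosity(1, 300, 0.5)$eta_mPa_s
  expect_equal(microviscosity(3, 300, 0.5)$eta_mPa_s, 3 * e1,
               tolerance = 1e-12)
  expect_equal(microviscosity(1, 600, 0.5)$eta_mPa_s, 2 * e1,
               tolerance = 1e-12)
  expect_error(microviscosity(0, 293, 0.5), "positive")
  expect_error(theta_from_viscosity(-1, 293, 0.5), "positive")
})
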