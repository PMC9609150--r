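# kappa^2 orientation factors and membrane-frame densities

test_that("kappa2 limiting geometries: parallel, collinear, orthogonal", {
  expect_equal(kappa2_frame(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)), 1)
  expect_equal(kappa2_frame(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), 4)
  expect_equal(kappa2_frame(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 0)
  expect_error(kappa2_frame(c(0, 0, 2), c(0, 0, 1), c(1, 0, 0)),
               "unit norm")
})

test_that("kappa2 is invariant under joint rotation and sign flips", {
  set.seed(17)
  for (i in 1:20) {
    v <- matrix(rnorm(9), 3)
    v <- v / sqrt(rowSums(v^2))
    k0 <- kappa2_frame(v[1, ], v[2, ], v[3, ])
    expect_gte(k0, 0); expect_lte(k0, 4)
    # random rotation via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    expect_equal(kappa2_frame(drop(Q %*% v[1, ]), drop(Q %*% v[2, ]),
                              drop(Q %*% v[3, ])), k0, tolerance = 1e-10)
    expect_equal(kappa2_frame(-v[1, ], v[2, ], -v[3, ]), k0,
                 tolerance = 1e-12)
  }
})

test_that("ensemble kappa2: enumerated mixtures and degenerate cases", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  coll <- orientation_ensemble(rbind(z, z), rbind(z, z), rbind(z, z))
  k <- kappa2_ensemble(coll)
  expect_equal(k$mean, 4); expect_equal(k$sd, 0)
  # one frame with kappa2 = 0, one with kappa2 = 4 -> mean 2, SD 2
  mix <- orientation_ensemble(rbind(x, z), rbind(c(0, 1, 0), z),
                              rbind(z, z))
  k2 <- kappa2_ensemble(mix)
  expect_equal(k2$mean, 2)
  expect_equal(k2$sd, 2)
  one <- orientation_ensemble(rbind(z), rbind(z), rbind(z))
  expect_error(kappa2_ensemble(one), ">= 2 frames")
})

test_that("isotropic ensemble mean kappa2 converges to 2/3", {
  n <- 2e5
  mk <- function(s) simulate_orientation_ensemble(
    ensemble_spec("isotropic", n_frames = n, seed = s))
  k <- kappa2_ensemble(orientation_ensemble(mk(1), mk(2), mk(3)))
  expect_lt(abs(k$mean - 2 / 3), 3 * k$se)
})

test_that("angle density: degenerate inputs land in the expected bins", {
  z <- c(0, 0, 1)
  par_ <- matrix(z, 50, 3, byrow = TRUE)
  d <- angle_density(par_, z, bin_width = 5)
  expect_equal(d$density[1] * 5, 1)
  expect_true(all(d$density[-1] == 0))
  # headless axis: -z is the same orientation as +z
  d2 <- angle_density(-par_, z, bin_width = 5)
  expect_equal(d2$density, d$density)
  one <- angle_density(matrix(c(1, 0, 0), 1), z, bin_width = 10)
  expect_equal(max(one$density), 1 / 10)
  expect_error(angle_density(par_, c(0, 0, 0)), "non-zero")
  expect_error(angle_density(par_, z, bin_width = 45), "30")
})

test_that("all densities integrate to one", {
  v <- simulate_orientation_ensemble(
    ensemble_spec("isotropic", n_frames = 5000, seed = 2))
  d <- angle_density(v, c(0, 0, 1), bin_width = 3)
  expect_equal(sum(d$density * diff(d$bin_edges)), 1, tolerance = 1e-6)
  ds <- angle_density(v, c(0, 0, 1), bin_width = 3, sin_correction = TRUE)
  expect_equal(sum(ds$density * diff(ds$bin_edges)), 1, tolerance = 1e-6)
  set.seed(3)
  dd <- depth_density(rnorm(2000, 0, 0.5), bilayer_halfwidth = 2,
                      bin_width = 0.25)
  expect_equal(sum(dd$density * diff(dd$bin_edges)), 1, tolerance = 1e-6)
})

test_that("isotropic axes follow the analytic sine law", {
  n <- 1e5
  v <- simulate_orientation_ensemble(
    ensemble_spec("isotropic", n_frames = n, seed = 5))
  bw <- 5
  d <- angle_density(v, c(0, 0, 1), bin_width = bw)
  # expected bin probabilities: integral of sin(phi) over the bin
  lo <- d$bin_edges[-length(d$bin_edges)] * pi / 180
  hi <- d$bin_edges[-1] * pi / 180
  p <- cos(lo) - cos(hi)
  counts <- round(d$density * bw * n)
  gof <- suppressWarnings(chisq.test(counts, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("depth density recovers bimodal localization and clips outliers", {
  set.seed(11)
  z <- c(rnorm(4000, -1, 0.15), rnorm(4000, 1.2, 0.15))
  d <- depth_density(z, bilayer_halfwidth = 2, bin_width = 0.2)
  peaks <- d$mid[which(diff(sign(diff(d$density))) == -2) + 1]
  expect_true(any(abs(peaks - (-1)) <= 0.2))
  expect_true(any(abs(peaks - 1.2) <= 0.2))
  # all mass at the center lands in the midplane bin
  d0 <- depth_density(rep(0, 100), 2, 0.5)
  expect_equal(sum(d0$density > 0), 1)
  expect_warning(depth_density(c(0, 5), 2, 0.5), "clipped")
  expect_error(depth_density(numeric(0), 2, 0.5), "at least one")
  expect_error(depth_density(0, -1, 0.5), "positive")
})

test_that("state occupancy counts frames beyond the angular boundary", {
  expect_equal(state_occupancy(rep(85, 40), 60), 1)
  expect_equal(state_occupancy(c(rep(89, 10), rep(20, 10)), 89), 0)
  # 78/22 mixture emulating a bimodal in-membrane pose
  set.seed(8)
  phi <- c(rnorm(7800, 82, 3), rnorm(2200, 42, 3))
  expect_equal(state_occupancy(phi, 60), 0.78, tolerance = 0.01)
  expect_error(state_occupancy(numeric(0), 60), "at least one")
  expect_error(state_occupancy(50, 95), "between 0 and 90")
})
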