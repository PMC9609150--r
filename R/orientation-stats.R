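#' Per-frame Forster orientation factor
#'
#' `kappa = d.a - 3 (d.r)(a.r)` for unit donor dipole `d`, acceptor dipole
#' `a` and separation direction `r`; returns `kappa^2`, which lies in
#' `[0, 4]` (0 for orthogonal arrangements, 1 for parallel dipoles
#' perpendicular to the separation, 4 for the collinear head-to-tail
#' geometry).
#'
#' @param d,a,r unit 3-vectors (donor dipole, acceptor dipole, separation
#'   direction); non-unit norms beyond `tol` raise an error.
#' @param tol unit-norm tolerance (default 1e-6).
#' @return kappa^2, a scalar in `[0, 4]`.
#' @examples
#' kappa2_frame(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))  # 1
#' kappa2_frame(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))  # 4
#' @export
kappa2_frame <- function(d, a, r, tol = 1e-6) {
  .check_unit_vector(d, "d", tol)
  .check_unit_vector(a, "a", tol)
  .check_unit_vector(r, "r", tol)
  k <- sum(d * a) - 3 * sum(d * r) * sum(a * r)
  k^2
}

#' Construct an orientation ensemble from per-frame molecular axes
#'
#' @param donor,acceptor,separation `n x 3` matrices of unit row vectors:
#'   donor transition dipole, acceptor transition dipole, and donor-to-
#'   acceptor separation direction per frame.
#' @param z_nm optional per-frame center-of-mass coordinate along the
#'   membrane normal, nm.
#' @param tol unit-norm tolerance (default 1e-6).
#' @return Object of class `orientation_ensemble`.
#' @export
orientation_ensemble <- function(donor, acceptor, separation, z_nm = NULL,
                                 tol = 1e-6) {
  mats <- list(donor = as.matrix(donor), acceptor = as.matrix(acceptor),
               separation = as.matrix(separation))
  n <- nrow(mats$donor)
  if (n < 1L) stop("ensemble needs >= 1 frame", call. = FALSE)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (ncol(m) != 3L || nrow(m) != n) {
      stop(sprintf("`%s` must be an n x 3 matrix matching the other axes",
                   nm), call. = FALSE)
    }
    nrm <- sqrt(rowSums(m^2))
    if (any(abs(nrm - 1) > tol)) {
      stop(sprintf("`%s` contains non-unit vectors (max |norm-1| = %.3g)",
                   nm, max(abs(nrm - 1))), call. = FALSE)
    }
  }
  if (!is.null(z_nm) && length(z_nm) != n) {
    stop("`z_nm` must have one value per frame", call. = FALSE)
  }
  structure(c(mats, list(z_nm = z_nm, n_frames = n)),
            class = "orientation_ensemble")
}

#' Time-averaged orientation factor of an ensemble
#'
#' Arithmetic mean and standard deviation of the per-frame kappa^2 over the
#' trajectory — the dynamic-averaging regime appropriate when reorientation
#' is fast relative to the transfer time. For isotropically distributed
#' independent dipoles the mean converges to 2/3.
#'
#' @param ens an [orientation_ensemble()] with >= 2 frames (for the SD).
#' @return List with `mean`, `sd`, `se` (standard error of the mean) and
#'   `n_frames`.
#' @examples
#' v <- simulate_orientation_ensemble(
#'   ensemble_spec("isotropic", n_frames = 2000, seed = 1))
#' w <- simulate_orientation_ensemble(
#'   ensemble_spec("isotropic", n_frames = 2000, seed = 2))
#' u <- simulate_orientation_ensemble(
#'   ensemble_spec("isotropic", n_frames = 2000, seed = 3))
#' kappa2_ensemble(orientation_ensemble(v, w, u))$mean  # ~2/3
#' @export
kappa2_ensemble <- function(ens) {
  stopifnot(inherits(ens, "orientation_ensemble"))
  if (ens$n_frames < 2L) {
    stop("ensemble mean and SD need >= 2 frames", call. = FALSE)
  }
  k <- rowSums(ens$donor * ens$acceptor) -
    3 * rowSums(ens$donor * ens$separation) *
    rowSums(ens$acceptor * ens$separation)
  k2 <- k^2
  m <- mean(k2)
  # population SD: the descriptive spread of the time series itself
  s <- sqrt(mean((k2 - m)^2))
  list(mean = m, sd = s, se = s / sqrt(length(k2)),
       n_frames = ens$n_frames)
}

#' Tilt-angle probability density of a molecular axis
#'
#' The tilt angle `phi = acos(|axis . normal|)` between a headless
#' molecular axis (a transition dipole or polyene long axis, which has no
#' directionality) and the membrane normal, folded into `[0, 90]` degrees.
#' The histogram is normalized to unit integral in units of probability
#' density per degree. By default no solid-angle weighting is applied (the
#' raw density convention); `sin_correction = TRUE` divides each bin by
#' `sin(phi)` at the bin center and renormalizes, converting to a density
#' per unit solid angle.
#'
#' @param axis_series `n x 3` matrix of unit row vectors.
#' @param normal unit 3-vector, the membrane normal.
#' @param bin_width histogram bin width in degrees, in `(0, 30]`.
#' @param sin_correction apply the solid-angle correction (default `FALSE`).
#' @return Object of class `angle_density`: list with `bin_edges` (deg),
#'   `mid` (bin centers), `density` (per degree), `n_frames`.
#' @examples
#' v <- simulate_orientation_ensemble(
#'   ensemble_spec("isotropic", n_frames = 5000, seed = 1))
#' d <- angle_density(v, c(0, 0, 1), bin_width = 5)
#' sum(d$density * diff(d$bin_edges))  # 1
#' @export
angle_density <- function(axis_series, normal, bin_width = 2,
                          sin_correction = FALSE) {
  axis_series <- as.matrix(axis_series)
  if (nrow(axis_series) < 1L || ncol(axis_series) != 3L) {
    stop("`axis_series` must be an n x 3 matrix with n >= 1", call. = FALSE)
  }
  if (sqrt(sum(normal^2)) < 1e-12) {
    stop("`normal` must be a non-zero vector", call. = FALSE)
  }
  normal <- normal / sqrt(sum(normal^2))
  if (bin_width <= 0 || bin_width > 30) {
    stop("`bin_width` must lie in (0, 30] degrees", call. = FALSE)
  }
  cosphi <- abs(axis_series %*% normal)
  phi <- acos(pmin(pmax(cosphi, 0), 1)) * 180 / pi
  edges <- seq(0, 90, by = bin_width)
  if (tail(edges, 1) < 90) edges <- c(edges, 90)
  counts <- .bincount(phi, edges)
  widths <- diff(edges)
  dens <- counts / sum(counts) / widths
  if (sin_correction) {
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    w <- sin(pmax(mid, bin_width / 4) * pi / 180)
    dens <- dens / w
    dens <- dens / sum(dens * widths)
  }
  structure(list(bin_edges = edges,
                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, n_frames = nrow(axis_series),
                 sin_correction = sin_correction),
            class = "angle_density")
}

# histogram counts with right-closed final bin
.bincount <- function(x, edges) {
  x <- pmin(pmax(x, edges[1]), tail(edges, 1))
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Depth density of a molecule along the membrane normal
#'
#' Unit-integral histogram of center-of-mass positions along the bilayer
#' normal over `[-halfwidth, +halfwidth]`. Positions outside the bilayer
#' are clipped into the edge bins; their number is reported as the
#' `n_clipped` element with a warning.
#'
#' @param z_series center-of-mass coordinates along the normal, nm
#'   (bilayer midplane at 0).
#' @param bilayer_halfwidth half the bilayer thickness, nm (> 0).
#' @param bin_width histogram bin width, nm (> 0).
#' @return Object of class `depth_density`: `bin_edges` (nm), `mid`,
#'   `density` (per nm), `n_frames`, `n_clipped`.
#' @examples
#' z <- c(rnorm(500, -1, 0.2), rnorm(500, 1.2, 0.2))
#' d <- depth_density(z, bilayer_halfwidth = 2, bin_width = 0.2)
#' d$mid[which(diff(sign(diff(d$density))) == -2) + 1]  # modes near -1, 1.2
#' @export
depth_density <- function(z_series, bilayer_halfwidth, bin_width) {
  if (length(z_series) < 1L) {
    stop("`z_series` must contain at least one value", call. = FALSE)
  }
  .check_positive_scalar(bilayer_halfwidth, "bilayer_halfwidth")
  .check_positive_scalar(bin_width, "bin_width")
  n_clipped <- sum(abs(z_series) > bilayer_halfwidth)
  if (n_clipped > 0) {
    warning(sprintf("%d of %d positions lie outside the bilayer and were
clipped into the edge bins", n_clipped, length(z_series)), call. = FALSE)
  }
  z <- pmin(pmax(z_series, -bilayer_halfwidth), bilayer_halfwidth)
  edges <- seq(-bilayer_halfwidth, bilayer_halfwidth, by = bin_width)
  if (tail(edges, 1) < bilayer_halfwidth) {
    edges <- c(edges, bilayer_halfwidth)
  }
  counts <- .bincount(z, edges)
  widths <- diff(edges)
  structure(list(bin_edges = edges,
                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                 density = counts / sum(counts) / widths,
                 n_frames = length(z_series), n_clipped = n_clipped),
            class = "depth_density")
}

#' Fraction of frames beyond an angular state boundary
#'
#' Occupancy of the high-tilt orientational state: the fraction of frames
#' whose tilt angle exceeds `boundary` degrees. Used to quantify bimodal
#' in-membrane poses (e.g. a membrane-spanning vs a membrane-parallel
#' carotenoid state).
#'
#' @param angle_series tilt angles in degrees (>= 1 value).
#' @param boundary state boundary in degrees, strictly between 0 and 90.
#' @return Fraction in `[0, 1]`.
#' @examples
#' state_occupancy(c(rep(82, 78), rep(42, 22)), boundary = 60)  # 0.78
#' @export
state_occupancy <- function(angle_series, boundary) {
  if (length(angle_series) < 1L) {
    stop("`angle_series` must contain at least one value", call. = FALSE)
  }
  if (!is.numeric(boundary) || boundary <= 0 || boundary >= 90) {
    stop("`boundary` must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  mean(angle_series > boundary)
}
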