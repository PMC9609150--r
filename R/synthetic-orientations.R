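#' Specify a synthetic unit-vector orientation ensemble
#'
#' Stand-in generator for the per-frame molecular axes (transition dipoles,
#' long axes, separation directions) that a membrane molecular-dynamics
#' trajectory would supply.
#'
#' @param mode `"isotropic"` (uniform on the unit sphere), `"fixed"`
#'   (every frame equals `cone_axis`) or `"cone"` (uniform within the
#'   spherical cap of half-angle `cone_halfangle` about `cone_axis`).
#' @param cone_axis unit 3-vector; the fixed direction / cone axis.
#' @param cone_halfangle cone half-angle in degrees, in `[0, 180]`.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(mode = c("isotropic", "fixed", "cone"),
                          cone_axis = c(0, 0, 1), cone_halfangle = 30,
                          n_frames = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (sqrt(sum(cone_axis^2)) < 1e-12) {
    stop("`cone_axis` must be non-zero", call. = FALSE)
  }
  .check_unit_vector(cone_axis / sqrt(sum(cone_axis^2)), "cone_axis")
  if (abs(sqrt(sum(cone_axis^2)) - 1) > 1e-9) {
    stop("`cone_axis` must have unit norm", call. = FALSE)
  }
  if (cone_halfangle < 0 || cone_halfangle > 180) {
    stop("`cone_halfangle` must lie in [0, 180] degrees", call. = FALSE)
  }
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  structure(list(mode = mode, cone_axis = as.numeric(cone_axis),
                 cone_halfangle = cone_halfangle,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Draw a unit-vector time series from an ensemble specification
#'
#' Isotropic mode samples uniformly on the unit sphere; fixed mode repeats
#' the axis; cone mode samples uniformly (by solid angle) within the
#' spherical cap about the axis. A zero half-angle cone degenerates to
#' fixed mode. Seeded and reproducible.
#'
#' @param spec an [ensemble_spec()].
#' @return An `n_frames x 3` numeric matrix of unit row vectors.
#' @examples
#' v <- simulate_orientation_ensemble(
#'   ensemble_spec("isotropic", n_frames = 1000, seed = 3))
#' colMeans(v)  # near the origin
#' @export
simulate_orientation_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_frames
  if (spec$mode == "fixed" ||
      (spec$mode == "cone" && spec$cone_halfangle == 0)) {
    return(matrix(spec$cone_axis, nrow = n, ncol = 3, byrow = TRUE))
  }
  set.seed(spec$seed)
  if (spec$mode == "isotropic") {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
  } else {
    cos_a <- cos(spec$cone_halfangle * pi / 180)
    z <- 1 - runif(n) * (1 - cos_a)  # uniform in solid angle within the cap
    phi <- runif(n, 0, 2 * pi)
  }
  s <- sqrt(pmax(1 - z^2, 0))
  v <- cbind(s * cos(phi), s * sin(phi), z)
  if (spec$mode == "cone") {
    v <- v %*% t(.rotation_to(spec$cone_axis))
  }
  v
}

# rotation matrix taking (0,0,1) onto `axis` (Rodrigues formula)
.rotation_to <- function(axis) {
  z <- c(0, 0, 1)
  c_ <- sum(z * axis)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  u <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(u^2))
  u <- u / s
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * K %*% K
}
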