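#' Specify a synthetic Gaussian-band spectrum
#'
#' @param bands three-column matrix or data.frame `(center_nm, width_nm,
#'   height)`: Gaussian band centers, widths (the Gaussian sigma, nm) and
#'   peak heights (emission arbitrary units, or molar extinction in
#'   M^-1 cm^-1 for `kind = "extinction"`).
#' @param grid numeric `c(start_nm, stop_nm, step_nm)` wavelength grid.
#' @param kind `"emission"` or `"extinction"`.
#' @return An object of class `spectrum_spec`.
#' @examples
#' spectrum_spec(cbind(570, 20, 1), grid = c(450, 700, 1))
#' @export
spectrum_spec <- function(bands, grid = c(350, 750, 1),
                          kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  bands <- as.matrix(bands)
  if (nrow(bands) < 1L || ncol(bands) != 3L) {
    stop("`bands` must be a non-empty (center, width, height) table",
         call. = FALSE)
  }
  colnames(bands) <- c("center_nm", "width_nm", "height")
  if (any(bands[, "width_nm"] <= 0)) {
    stop("band widths must be > 0", call. = FALSE)
  }
  if (any(bands[, "height"] < 0)) {
    stop("band heights must be >= 0", call. = FALSE)
  }
  if (length(grid) != 3L || grid[3] <= 0 || grid[2] <= grid[1]) {
    stop("`grid` must be c(start, stop, step) with stop > start, step > 0",
         call. = FALSE)
  }
  structure(list(bands = bands, grid = as.numeric(grid), kind = kind),
            class = "spectrum_spec")
}

#' Evaluate a synthetic band spectrum on its wavelength grid
#'
#' Sums the Gaussian bands of a [spectrum_spec()] on the grid. Fully
#' deterministic (no noise model): repeat calls are bit-identical.
#'
#' @param spec a [spectrum_spec()].
#' @return A [spectrum()] object.
#' @examples
#' s <- simulate_spectrum(spectrum_spec(cbind(570, 20, 1)))
#' s$wavelength_nm[which.max(s$values)]
#' @export
simulate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  wl <- seq(spec$grid[1], spec$grid[2], by = spec$grid[3])
  vals <- rowSums(vapply(seq_len(nrow(spec$bands)), function(i) {
    b <- spec$bands[i, ]
    b["height"] * exp(-0.5 * ((wl - b["center_nm"]) / b["width_nm"])^2)
  }, numeric(length(wl))))
  spectrum(wl, vals, kind = spec$kind)
}
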