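#' Write polarized decay histograms to a delimited-text table
#'
#' Tab-separated columns `time_ns, counts_VV, counts_VH, counts_HV,
#' counts_HH` (and `irf` when present), preceded by `#`-prefixed header
#' lines carrying metadata as `key=value` pairs. When the object carries a
#' simulation ground truth, its parameters are written into the header so
#' the file is self-describing.
#'
#' @param decays a `polarized_decays` object from
#'   [simulate_polarized_decays()], or a named list of [decay_histogram()]
#'   objects (names among VV, VH, HV, HH, irf) on a common grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram_table <- function(decays, path) {
  geoms <- intersect(c("VV", "VH", "HV", "HH"), names(decays))
  if (!length(geoms)) {
    stop("`decays` must contain at least one of VV, VH, HV, HH",
         call. = FALSE)
  }
  ref <- decays[[geoms[1]]]
  df <- data.frame(time_ns = ref$time_ns)
  for (g in geoms) {
    if (!.same_grid(decays[[g]], ref)) {
      stop("all histograms must share one time grid", call. = FALSE)
    }
    df[[paste0("counts_", g)]] <- decays[[g]]$counts
  }
  if (!is.null(decays$irf)) df$irf <- decays$irf$counts

  hdr <- c(sprintf("# anisofret polarized TCSPC histogram v1"),
           sprintf("# n_channels=%d", nrow(df)))
  if (!is.null(decays$truth)) {
    tr <- decays$truth
    hdr <- c(hdr,
             sprintf("# intensity_fractions=%s",
                     paste(tr$intensity_components[, "fraction"],
                           collapse = ",")),
             sprintf("# intensity_lifetimes_ns=%s",
                     paste(tr$intensity_components[, "time_ns"],
                           collapse = ",")),
             sprintf("# anisotropy_r0=%.12g", tr$anisotropy_r0),
             sprintf("# anisotropy_fractions=%s",
                     paste(tr$anisotropy_components[, "fraction"],
                           collapse = ",")),
             sprintf("# anisotropy_theta_ns=%s",
                     paste(tr$anisotropy_components[, "time_ns"],
                           collapse = ",")),
             sprintf("# g_true=%.12g", tr$g_true),
             sprintf("# background_rate=%.12g", tr$background_rate),
             sprintf("# total_counts=%.12g", tr$total_counts),
             sprintf("# irf_fwhm=%.12g", tr$irf_fwhm),
             sprintf("# seed=%d", tr$seed))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read polarized decay histograms from a delimited-text table
#'
#' Counterpart of [write_histogram_table()]. `#` header lines are parsed
#' into a metadata list; rows out of time order are re-sorted with a
#' warning; a negative count raises an error naming the offending row.
#'
#' @param path input file path.
#' @return A list with one [decay_histogram()] per geometry column found
#'   (`VV`, `VH`, `HV`, `HH`), `irf` (or `NULL`), and `meta` (named list of
#'   header key=value pairs, numeric where possible).
#' @export
read_histogram_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- .parse_header_meta(hdr)

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   check.names = FALSE)
  if (!"time_ns" %in% names(df)) {
    stop("missing required column `time_ns`", call. = FALSE)
  }
  count_cols <- grep("^counts_", names(df), value = TRUE)
  if (!length(count_cols)) {
    stop("no `counts_*` columns found", call. = FALSE)
  }
  for (cc in c(count_cols, intersect("irf", names(df)))) {
    bad <- which(df[[cc]] < 0)
    if (length(bad)) {
      stop(sprintf("negative count in column `%s`, data row %d", cc,
                   bad[1]), call. = FALSE)
    }
  }
  if (is.unsorted(df$time_ns, strictly = TRUE)) {
    warning("time grid not sorted; rows re-sorted by time_ns",
            call. = FALSE)
    df <- df[order(df$time_ns), , drop = FALSE]
  }
  out <- list()
  for (cc in count_cols) {
    g <- sub("^counts_", "", cc)
    out[[g]] <- decay_histogram(df$time_ns, df[[cc]],
                                geometry = if (g %in% c("VV", "VH", "HV",
                                                        "HH", "magic"))
                                  g else "unknown")
  }
  out$irf <- if ("irf" %in% names(df)) {
    decay_histogram(df$time_ns, df$irf, geometry = "IRF")
  }
  out$meta <- meta
  out
}

.parse_header_meta <- function(hdr) {
  kv <- grep("=", hdr, value = TRUE)
  meta <- list()
  for (line in kv) {
    s <- sub("^#\\s*", "", line)
    key <- trimws(sub("=.*$", "", s))
    val <- trimws(sub("^[^=]*=", "", s))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[key]] <- if (all(is.finite(num))) num else val
  }
  meta
}

#' Write / read a two-column spectrum table
#'
#' Tab-separated `wavelength_nm, value` with `#` comment headers.
#'
#' @param spec a [spectrum()].
#' @param path file path.
#' @return `write_spectrum_table`: `path` invisibly;
#'   `read_spectrum_table`: a [spectrum()].
#' @export
write_spectrum_table <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# anisofret spectrum v1"),
               sprintf("# kind=%s", spec$kind),
               "wavelength_nm\tvalue"), con)
  write.table(data.frame(format(spec$wavelength_nm, digits = 15,
                                trim = TRUE),
                         format(spec$values, digits = 15, trim = TRUE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @param kind spectrum kind override when the header carries none.
#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- .parse_header_meta(grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- read.table(text = body, header = TRUE, sep = "\t")
  if (is.null(kind)) {
    kind <- if (identical(meta$kind, "extinction")) "extinction"
            else "emission"
  }
  spectrum(df[[1]], df[[2]], kind = kind)
}

#' Read an orientation trajectory from a delimited-text table
#'
#' Expected tab- or whitespace-separated columns: `frame`, `dx dy dz`
#' (donor dipole), `ax ay az` (acceptor dipole), `rx ry rz` (separation
#' direction), optional `z_nm` (center-of-mass depth). Vectors are
#' normalized to unit length on read (MD exports carry rounding error).
#'
#' @param path file path.
#' @return An [orientation_ensemble()].
#' @export
read_trajectory_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, comment.char = "#")
  need <- c("dx", "dy", "dz", "ax", "ay", "az", "rx", "ry", "rz")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing trajectory columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unit <- function(m) m / sqrt(rowSums(m^2))
  orientation_ensemble(
    donor = unit(as.matrix(df[, c("dx", "dy", "dz")])),
    acceptor = unit(as.matrix(df[, c("ax", "ay", "az")])),
    separation = unit(as.matrix(df[, c("rx", "ry", "rz")])),
    z_nm = if ("z_nm" %in% names(df)) df$z_nm)
}
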