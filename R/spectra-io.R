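# Core spectral containers and delimited-text readers/writers.
#
# Unit conventions used throughout the package: difference absorbance in mOD,
# pump-probe delay in ps, wavenumber in cm^-1, molar absorptivity in
# M^-1 cm^-1, energies in eV. Conversions are always explicit.

#' Wavenumber axis
#'
#' A strictly increasing vector of probe wavenumbers in cm^-1. The ascending
#' order is a storage convention; the IR custom of plotting wavenumbers
#' descending is a display concern only.
#'
#' @param values numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   all positive.
#' @return an object of class `wavenumber_axis`.
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("wavenumber axis must be non-empty and finite", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("wavenumber axis values must be positive", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  structure(values, class = "wavenumber_axis")
}

#' Pump-probe delay axis
#'
#' Strictly increasing delays in ps. Small negative pre-time-zero delays are
#' allowed (they serve as a baseline check downstream).
#'
#' @param values numeric vector of delays (ps), strictly increasing.
#' @return an object of class `delay_axis`.
#' @export
delay_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(!is.finite(values))) {
    stop("delay axis must be non-empty and finite", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("delay axis must be strictly increasing", call. = FALSE)
  }
  structure(values, class = "delay_axis")
}

#' Single spectrum with a unit tag
#'
#' @param axis `wavenumber_axis` (or numeric convertible to one); for UV-Vis
#'   molar absorptivity spectra the "wavenumber" slot carries wavelength in
#'   nm — the container only requires a strictly increasing positive axis.
#' @param intensity numeric vector, same length as `axis`.
#' @param unit one of `"OD"`, `"mOD"`, `"eps"`.
#' @return an object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(axis, intensity, unit = c("OD", "mOD", "eps")) {
  unit <- match.arg(unit)
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(axis)) {
    stop("intensity and axis lengths differ", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensity must be finite", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity, unit = unit),
            class = "spectrum_1d")
}

#' @export
print.spectrum_1d <- function(x, ...) {
  cat(sprintf("<spectrum_1d> %d points, %.1f-%.1f, unit %s\n",
              length(x$axis), min(x$axis), max(x$axis), x$unit))
  invisible(x)
}

#' Transient vibrational absorption map
#'
#' Difference-absorbance matrix over (delay, wavenumber) with metadata.
#' Rows are delays, columns wavenumbers; entries are in mOD.
#'
#' @param nu `wavenumber_axis` of probe wavenumbers (cm^-1).
#' @param t `delay_axis` of pump-probe delays (ps).
#' @param dA numeric matrix, `length(t)` rows by `length(nu)` columns, mOD.
#' @param meta optional named list (e.g. pump wavelength nm, solvent).
#' @return an object of class `tva_map`.
#' @export
tva_map <- function(nu, t, dA, meta = list()) {
  if (!inherits(nu, "wavenumber_axis")) nu <- wavenumber_axis(nu)
  if (!inherits(t, "delay_axis")) t <- delay_axis(t)
  dA <- as.matrix(dA)
  storage.mode(dA) <- "double"
  if (!all(dim(dA) == c(length(t), length(nu)))) {
    stop(sprintf("dA must be %d x %d (delays x wavenumbers), got %d x %d",
                 length(t), length(nu), nrow(dA), ncol(dA)), call. = FALSE)
  }
  if (anyNA(dA) || any(!is.finite(dA))) {
    stop("dA entries must be finite", call. = FALSE)
  }
  structure(list(nu = nu, t = t, dA = dA, meta = meta), class = "tva_map")
}

#' @export
print.tva_map <- function(x, ...) {
  cat(sprintf("<tva_map> %d delays x %d wavenumbers, nu %.0f-%.0f cm^-1, t %.2g-%.3g ps\n",
              length(x$t), length(x$nu), min(x$nu), max(x$nu),
              min(x$t), max(x$t)))
  invisible(x)
}

# Auto-detect comma vs whitespace delimiting from the first non-comment line.
.detect_sep <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("file is empty: ", path, call. = FALSE)
  if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
}

.read_delim_rows <- function(path) {
  sep <- .detect_sep(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, function(l) {
    fields <- if (sep == ",") strsplit(l, ",", fixed = TRUE)[[1]]
              else strsplit(trimws(l), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("non-numeric field in ", path, call. = FALSE)
    vals
  })
}

#' Read a TVA map from delimited text
#'
#' Expected layout: first row holds the wavenumber axis (its first cell is a
#' corner placeholder and is ignored), first column of each following row is
#' the delay, remaining cells are dA in mOD. Comma or whitespace delimiting
#' is auto-detected; `#` lines are comments.
#'
#' @param path file path.
#' @return a [tva_map()].
#' @export
read_tva <- function(path) {
  rows <- .read_delim_rows(path)
  if (length(rows) < 2) stop("TVA file needs a header row and data rows", call. = FALSE)
  header <- rows[[1]]
  nu <- header[-1]
  body <- rows[-1]
  ncols <- lengths(body)
  if (any(ncols != length(nu) + 1L)) {
    stop("ragged rows in TVA file: expected ", length(nu) + 1L,
         " fields, got ", paste(unique(ncols), collapse = "/"), call. = FALSE)
  }
  t <- vapply(body, `[[`, numeric(1), 1L)
  dA <- do.call(rbind, lapply(body, function(r) r[-1]))
  tva_map(wavenumber_axis(nu), delay_axis(t), dA)
}

#' Write a TVA map as delimited text
#'
#' Inverse of [read_tva()]; emits comma-separated values at full double
#' precision (17 significant digits) so read/write round-trips are exact to
#' better than 1e-12.
#'
#' @param map a [tva_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tva <- function(map, path) {
  stopifnot(inherits(map, "tva_map"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- character(length(map$t) + 1L)
  lines[1] <- paste(c("0", fmt(as.numeric(map$nu))), collapse = ",")
  for (i in seq_along(map$t)) {
    lines[i + 1L] <- paste(c(fmt(map$t[i]), fmt(map$dA[i, ])), collapse = ",")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column (x, y) spectrum
#'
#' @param path file path; two delimited numeric columns, `#` comments allowed.
#' @param unit unit tag to attach (`"OD"`, `"mOD"` or `"eps"`).
#' @return a [spectrum_1d()].
#' @export
read_xy <- function(path, unit = "OD") {
  rows <- .read_delim_rows(path)
  if (any(lengths(rows) < 2)) {
    stop("XY file must have at least two columns", call. = FALSE)
  }
  x <- vapply(rows, `[[`, numeric(1), 1L)
  y <- vapply(rows, `[[`, numeric(1), 2L)
  spectrum_1d(wavenumber_axis(x), y, unit = unit)
}

#' Write a two-column spectrum
#'
#' @param spec a [spectrum_1d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_1d"))
  writeLines(sprintf("%.17g,%.17g", as.numeric(spec$axis), spec$intensity), path)
  invisible(path)
}
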