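# Harmonic line-list scaling, peak finding, band assignment, difference
# spectra and two-component isomer unmixing of steady-state FTIR spectra.

#' Harmonic line list
#'
#' @param frequency harmonic frequencies, cm^-1 (> 0).
#' @param intensity IR intensities, km mol^-1 (>= 0).
#' @param label optional mode labels.
#' @return data.frame of class `line_list`.
#' @export
line_list <- function(frequency, intensity, label = NULL) {
  frequency <- as.numeric(frequency)
  intensity <- as.numeric(intensity)
  if (length(frequency) != length(intensity)) {
    stop("frequency and intensity lengths differ", call. = FALSE)
  }
  if (any(frequency <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (is.null(label)) label <- rep("", length(frequency))
  structure(data.frame(frequency = frequency, intensity = intensity,
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("line_list", "data.frame"))
}

#' Scale a harmonic line list
#'
#' Multiplies every frequency by a scalar scaling factor (the usual remedy
#' for systematic harmonic overestimation, e.g. 0.9879 or 0.9908 at
#' B3LYP/6-311++G**); intensities are untouched. Not idempotent: applying a
#' factor twice scales twice.
#'
#' @param lines a [line_list()].
#' @param factor scaling factor in (0, 1.2].
#' @return a scaled [line_list()].
#' @export
scale_linelist <- function(lines, factor) {
  stopifnot(inherits(lines, "line_list"))
  if (!is.finite(factor) || factor <= 0 || factor > 1.2) {
    stop("scaling factor must lie in (0, 1.2]", call. = FALSE)
  }
  line_list(lines$frequency * factor, lines$intensity, lines$label)
}

#' Find peaks in a spectrum
#'
#' Local maxima whose prominence over the higher of the two flanking minima
#' exceeds `min_prominence`, with 3-point parabolic sub-grid refinement of
#' each peak position.
#'
#' @param spec a [spectrum_1d()].
#' @param min_prominence minimum peak prominence (same unit as intensity).
#' @return data.frame with columns `position` (cm^-1, refined), `height`.
#' @export
find_peaks <- function(spec, min_prominence = 0) {
  x <- as.numeric(spec$axis)
  y <- spec$intensity
  n <- length(y)
  if (n < 3) stop("spectrum must have at least 3 points", call. = FALSE)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  pos <- numeric(0); hgt <- numeric(0)
  for (i in idx) {
    # prominence: drop to the higher of the minima separating this peak
    # from the nearest higher ground on each side (spectrum edge counts)
    left <- y[1:(i - 1)]
    right <- y[(i + 1):n]
    higher_l <- which(left >= y[i])
    base_l <- if (length(higher_l)) min(y[(max(higher_l)):(i - 1)]) else min(left)
    higher_r <- which(right >= y[i])
    base_r <- if (length(higher_r)) min(y[i + 1:(min(higher_r))]) else min(right)
    prom <- y[i] - max(base_l, base_r)
    if (prom < min_prominence) next
    # parabolic refinement through (i-1, i, i+1)
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (abs(denom) > 1e-300) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    step <- if (i < n) x[i + 1] - x[i] else x[i] - x[i - 1]
    pos <- c(pos, x[i] + delta * step)
    hgt <- c(hgt, y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
  }
  data.frame(position = pos, height = hgt)
}

#' Match observed peaks to scaled calculated lines
#'
#' Greedy nearest-neighbour assignment: pairs are formed in order of
#' increasing |observed - calculated| distance, each line and each peak used
#' at most once, pairs beyond `tol` discarded. Ties (two peaks equidistant
#' from one line) resolve toward the lower-wavenumber peak.
#'
#' @param peaks numeric observed peak positions (cm^-1), or the data.frame
#'   from [find_peaks()].
#' @param scaled a scaled [line_list()].
#' @param tol maximum assignment distance, cm^-1 (default 15, a typical
#'   scaled-harmonic residual).
#' @return list with `pairs` (data.frame: observed, calculated, label,
#'   delta) and `unmatched_peaks`.
#' @export
match_bands <- function(peaks, scaled, tol = 15) {
  if (is.data.frame(peaks)) peaks <- peaks$position
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) == 0 || nrow(scaled) == 0) {
    return(list(pairs = data.frame(observed = numeric(0),
                                   calculated = numeric(0),
                                   label = character(0), delta = numeric(0)),
                unmatched_peaks = peaks))
  }
  d <- abs(outer(peaks, scaled$frequency, `-`))
  used_p <- rep(FALSE, length(peaks))
  used_l <- rep(FALSE, nrow(scaled))
  obs <- calc <- dl <- numeric(0); lab <- character(0)
  repeat {
    d_open <- d
    d_open[used_p, ] <- Inf
    d_open[, used_l] <- Inf
    m <- min(d_open)
    if (!is.finite(m) || m > tol) break
    # which() scans column-major so among equal distances the lowest peak
    # index (lowest wavenumber, peaks sorted) wins: documented tie-break
    hit <- which(d_open == m, arr.ind = TRUE)[1, ]
    i <- hit[1]; j <- hit[2]
    used_p[i] <- TRUE; used_l[j] <- TRUE
    obs <- c(obs, peaks[i]); calc <- c(calc, scaled$frequency[j])
    lab <- c(lab, scaled$label[j]); dl <- c(dl, m)
  }
  list(pairs = data.frame(observed = obs, calculated = calc, label = lab,
                          delta = dl),
       unmatched_peaks = peaks[!used_p])
}

#' Difference spectrum (post minus pre)
#'
#' @param pre,post [spectrum_1d()]s on identical axes and units.
#' @return a [spectrum_1d()] of the pointwise difference.
#' @export
difference_spectrum <- function(pre, post) {
  if (!isTRUE(all.equal(as.numeric(pre$axis), as.numeric(post$axis))) ||
      pre$unit != post$unit) {
    stop("spectra must share axis and unit", call. = FALSE)
  }
  spectrum_1d(pre$axis, post$intensity - pre$intensity, unit = pre$unit)
}

#' Isomer fraction from two-component spectral unmixing
#'
#' Non-negative linear unmixing of a mixture spectrum onto the two pure
#' isomer spectra; returns the Z fraction of the fitted coefficients. Exact
#' on noiseless mixtures.
#'
#' @param mixture,pure_E,pure_Z [spectrum_1d()]s on a shared axis.
#' @return list with `fraction_Z`, coefficients `a_E`, `a_Z`, and
#'   `rms_residual`.
#' @export
composition_from_spectrum <- function(mixture, pure_E, pure_Z) {
  ax <- as.numeric(mixture$axis)
  if (!isTRUE(all.equal(ax, as.numeric(pure_E$axis))) ||
      !isTRUE(all.equal(ax, as.numeric(pure_Z$axis)))) {
    stop("spectra must share the same axis", call. = FALSE)
  }
  X <- cbind(pure_E$intensity, pure_Z$intensity)
  if (abs(stats::cor(X[, 1], X[, 2])) > 1 - 1e-12) {
    stop("pure spectra are collinear; composition is unidentifiable",
         call. = FALSE)
  }
  sol <- .nnls_enum(X, mixture$intensity)
  a <- sol$coef
  if (sum(a) <= 0) stop("mixture has no overlap with the pure spectra",
                        call. = FALSE)
  list(fraction_Z = a[2] / sum(a), a_E = a[1], a_Z = a[2],
       rms_residual = sqrt(sol$rss / length(ax)))
}
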