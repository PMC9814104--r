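# Seeded generators for synthetic pump-probe IR maps, UV-Vis irradiation
# series and FTIR spectra. These emulate the structure the downstream
# analysis assumes: a three-component transient map (negative ground-state
# bleach, broad decaying hot-band ESA, growing photoisomer ESA) with
# mono-exponential kinetics, a two-state E<->Z photokinetic irradiation
# series approaching a photostationary state, and broadened harmonic line
# lists.

# Run code with a temporary RNG state so generators are seed-deterministic
# without clobbering the caller's random stream.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Spectral band shape
#'
#' Unit-peak band profile (peak = 1 before amplitude scaling). The `sign`
#' field records the physical direction of the component's amplitude —
#' -1 for a bleach (coefficient <= 0), +1 for an ESA (coefficient >= 0) —
#' and is used as a fit constraint; the profile itself is non-negative, the
#' sign always being carried by the amplitude.
#'
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param sign +1 (absorption) or -1 (bleach).
#' @param family `"gaussian"` or `"lorentzian"`.
#' @return an object of class `band_shape`.
#' @export
band_shape <- function(center, fwhm, sign = 1, family = c("gaussian", "lorentzian")) {
  family <- match.arg(family)
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, sign = sign, family = family),
            class = "band_shape")
}

#' Evaluate a band shape on a wavenumber grid
#'
#' @param band a [band_shape()].
#' @param nu numeric wavenumber grid, cm^-1.
#' @return non-negative unit-peak profile, same length as `nu` (the
#'   component's sign rides on its amplitude, not the profile).
#' @export
eval_band <- function(band, nu) {
  nu <- as.numeric(nu)
  z <- (nu - band$center) / band$fwhm
  switch(band$family,
    gaussian   = exp(-4 * log(2) * z^2),
    lorentzian = 1 / (1 + 4 * z^2)
  )
}

#' Mono-exponential component kinetics
#'
#' @param kind `"gsb_recovery"` (bleach recovering to a residual plateau),
#'   `"decay"` (ESA decaying to zero) or `"rise"` (photoproduct growth).
#' @param tau time constant, ps (> 0).
#' @param amplitude reference amplitude in mOD (peak |c| at the relevant
#'   endpoint: t = 0 for gsb/decay, t -> Inf for rise).
#' @param residual_fraction for `gsb_recovery` only: fraction R of the bleach
#'   that recovers, so c(0) = -amplitude and c(Inf) = -amplitude * (1 - R).
#' @return an object of class `component_kinetics`.
#' @export
component_kinetics <- function(kind = c("gsb_recovery", "decay", "rise"),
                               tau, amplitude, residual_fraction = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (kind == "gsb_recovery") {
    if (is.null(residual_fraction) || residual_fraction < 0 || residual_fraction > 1) {
      stop("gsb_recovery needs residual_fraction in [0, 1]", call. = FALSE)
    }
  } else if (!is.null(residual_fraction)) {
    stop("residual_fraction is defined only for gsb_recovery", call. = FALSE)
  }
  structure(list(kind = kind, tau = tau, amplitude = amplitude,
                 residual_fraction = residual_fraction),
            class = "component_kinetics")
}

# Gaussian-IRF-convolved primitives. sigma = 0 gives the sharp-onset limit.
# step(t): 1(t >= 0); expdecay(t): exp(-t/tau) * 1(t >= 0).
.irf_step <- function(t, sigma) {
  if (sigma <= 0) return(as.numeric(t >= 0))
  stats::pnorm(t / sigma)
}

.irf_expdecay <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  # exponentially modified gaussian, erfc written via pnorm
  arg <- sigma / (sqrt(2) * tau) - t / (sqrt(2) * sigma)
  0.5 * exp(sigma^2 / (2 * tau^2) - t / tau) * 2 * stats::pnorm(-arg * sqrt(2))
}

#' Evaluate a kinetic component trace
#'
#' All traces are zero before time zero; an optional Gaussian instrument
#' response of the given FWHM smooths the onset.
#'
#' @param kin a [component_kinetics()].
#' @param t delays, ps.
#' @param irf_fwhm Gaussian IRF FWHM in ps (0 disables convolution).
#' @return numeric trace c(t) in mOD.
#' @export
eval_kinetics <- function(kin, t, irf_fwhm = 0) {
  t <- as.numeric(t)
  sigma <- irf_fwhm / (2 * sqrt(2 * log(2)))
  A <- kin$amplitude
  switch(kin$kind,
    gsb_recovery = {
      R <- kin$residual_fraction
      -A * ((1 - R) * .irf_step(t, sigma) + R * .irf_expdecay(t, kin$tau, sigma))
    },
    decay = A * .irf_expdecay(t, kin$tau, sigma),
    rise  = A * (.irf_step(t, sigma) - .irf_expdecay(t, kin$tau, sigma))
  )
}

#' Synthetic TVA fixture
#'
#' Bundles three band shapes (one bleach, one hot-band ESA, one photoisomer
#' ESA), their kinetics, grids and noise level.
#'
#' @param bands named list of three [band_shape()]s: `gsb`, `vib_relax`,
#'   `photoisomer`.
#' @param kinetics named list of three [component_kinetics()]s with kinds
#'   `gsb_recovery`, `decay`, `rise` (same names as `bands`).
#' @param nu wavenumber grid (cm^-1).
#' @param t delay grid (ps).
#' @param noise_sd additive Gaussian noise SD, mOD.
#' @param irf_fwhm Gaussian IRF FWHM, ps (default 0 = off).
#' @return an object of class `tva_fixture`.
#' @export
tva_fixture <- function(bands, kinetics, nu, t, noise_sd = 0, irf_fwhm = 0) {
  need <- c("gsb", "vib_relax", "photoisomer")
  if (!identical(sort(names(bands)), sort(need)) ||
      !identical(sort(names(kinetics)), sort(need))) {
    stop("bands and kinetics must be named gsb, vib_relax, photoisomer", call. = FALSE)
  }
  kinds <- vapply(kinetics[need], `[[`, character(1), "kind")
  if (!identical(unname(kinds), c("gsb_recovery", "decay", "rise"))) {
    stop("need exactly one gsb_recovery, one decay, one rise component", call. = FALSE)
  }
  if (!inherits(nu, "wavenumber_axis")) nu <- wavenumber_axis(nu)
  if (!inherits(t, "delay_axis")) t <- delay_axis(t)
  structure(list(bands = bands[need], kinetics = kinetics[need],
                 nu = nu, t = t, noise_sd = noise_sd, irf_fwhm = irf_fwhm),
            class = "tva_fixture")
}

# Default grids: 1620-1780 cm^-1 step 1; one pre-time-zero delay then 60
# log-spaced delays from 0.2 to 600 ps.
.default_nu <- function() wavenumber_axis(seq(1620, 1780, by = 1))
.default_t <- function() delay_axis(c(-0.5, exp(seq(log(0.2), log(600), length.out = 60))))

#' Packaged TVA fixtures for the E and Z starting isomers
#'
#' Band centers, time constants and bleach recovery fractions follow the
#' values measured for ethyl sinapate in acetonitrile: for the E isomer,
#' bands at 1707 (bleach), 1680 (hot ESA) and 1718 (photoisomer) cm^-1 with
#' tau 9.05 / 16.42 / 18.90 ps and 49% bleach recovery; for the Z isomer,
#' 1713 / 1690 / 1708 cm^-1 with tau 7.33 / 13.30 / 18.72 ps and 94%
#' recovery. The bleach peaks at 1 mOD; ESA amplitudes (0.5 hot band; 0.45 E
#' / 0.10 Z photoisomer) and 0.01 mOD pixel noise keep band overlap mild.
#'
#' @param isomer `"E"` or `"Z"` starting isomer.
#' @param noise_sd override the 0.01 mOD default noise.
#' @param irf_fwhm Gaussian IRF FWHM, ps (default 0 = off).
#' @return a [tva_fixture()].
#' @export
default_fixture <- function(isomer = c("E", "Z"), noise_sd = 0.01, irf_fwhm = 0) {
  isomer <- match.arg(isomer)
  p <- if (isomer == "E") {
    list(centers = c(1707, 1680, 1718), tau = c(9.05, 16.42, 18.90),
         R = 0.49, A = c(1, 0.5, 0.45))
  } else {
    list(centers = c(1713, 1690, 1708), tau = c(7.33, 13.30, 18.72),
         R = 0.94, A = c(1, 0.5, 0.10))
  }
  bands <- list(
    gsb         = band_shape(p$centers[1], 10, sign = -1),
    vib_relax   = band_shape(p$centers[2], 40, sign = +1),
    photoisomer = band_shape(p$centers[3], 10, sign = +1)
  )
  kinetics <- list(
    gsb         = component_kinetics("gsb_recovery", p$tau[1], p$A[1],
                                     residual_fraction = p$R),
    vib_relax   = component_kinetics("decay", p$tau[2], p$A[2]),
    photoisomer = component_kinetics("rise", p$tau[3], p$A[3])
  )
  tva_fixture(bands, kinetics, .default_nu(), .default_t(),
              noise_sd = noise_sd, irf_fwhm = irf_fwhm)
}

#' True component amplitude traces of a fixture
#'
#' The noiseless coefficients c_k(t) used to build a synthetic map; the
#' oracle against which decomposition is checked.
#'
#' @param fixture a [tva_fixture()].
#' @param t delays, ps (default: the fixture grid).
#' @return matrix `length(t)` x 3, columns gsb / vib_relax / photoisomer, mOD.
#' @export
component_traces <- function(fixture, t = fixture$t) {
  out <- vapply(fixture$kinetics,
                function(k) eval_kinetics(k, t, fixture$irf_fwhm),
                numeric(length(t)))
  out <- matrix(out, nrow = length(t),
                dimnames = list(NULL, names(fixture$kinetics)))
  out
}

#' Generate a synthetic TVA map
#'
#' dA(t, nu) = sum_k c_k(t) S_k(nu) + eps with eps iid N(0, noise_sd).
#' The bleach trace is -amplitude * (1 - R (1 - exp(-t/tau))), the hot ESA
#' decays and the photoisomer rises mono-exponentially; all components are
#' zero before time zero (unless an IRF is enabled on the fixture).
#'
#' @param fixture a [tva_fixture()].
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @return a [tva_map()].
#' @export
generate_tva_map <- function(fixture, seed = NULL) {
  stopifnot(inherits(fixture, "tva_fixture"))
  traces <- component_traces(fixture)
  shapes <- vapply(fixture$bands, eval_band, numeric(length(fixture$nu)),
                   nu = as.numeric(fixture$nu))
  dA <- traces %*% t(shapes)
  if (fixture$noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0", call. = FALSE)
    dA <- dA + .with_seed(seed, matrix(
      stats::rnorm(length(dA), sd = fixture$noise_sd), nrow = nrow(dA)))
  }
  tva_map(fixture$nu, fixture$t, dA,
          meta = list(generator = "synthetic", noise_sd = fixture$noise_sd))
}

#' Generate a synthetic UV-Vis irradiation series
#'
#' Integrates the two-state photokinetic system on the requested time grid,
#' converts concentrations to absorbance A(lambda, t) = l (eps_E [E] +
#' eps_Z [Z]), and applies multiplicative noise (1 + eta), eta ~ N(0,
#' noise_rel).
#'
#' @param system a [photokinetic_system()].
#' @param times irradiation times, s, increasing, starting at or after 0.
#' @param seed integer seed; required whenever `noise_rel > 0`.
#' @param noise_rel relative noise SD (default 0.01).
#' @return list with `times`, `spectra` (list of [spectrum_1d()], unit OD)
#'   and the noiseless `conc` trajectory matrix (columns E, Z).
#' @export
generate_irradiation_series <- function(system, times, seed = NULL,
                                        noise_rel = 0.01) {
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and increasing", call. = FALSE)
  }
  conc <- integrate_photokinetics(system, times)
  lam <- as.numeric(system$eps_E$axis)
  pure <- cbind(system$eps_E$intensity, system$eps_Z$intensity)
  A <- system$path_l * (conc %*% t(pure))  # times x lambda
  if (noise_rel > 0) {
    if (is.null(seed)) stop("seed is required when noise_rel > 0", call. = FALSE)
    A <- A * .with_seed(seed, matrix(
      1 + stats::rnorm(length(A), sd = noise_rel), nrow = nrow(A)))
  }
  spectra <- lapply(seq_along(times), function(i) {
    spectrum_1d(wavenumber_axis(lam), A[i, ], unit = "OD")
  })
  list(times = times, spectra = spectra, conc = conc)
}

#' Synthesize an FTIR spectrum from a harmonic line list
#'
#' Sum of unit-area Lorentzians at scaled line positions, weighted by the
#' line intensities, plus optional additive noise. The integral of the
#' noiseless spectrum equals the summed intensities (up to truncation of the
#' Lorentzian wings by the grid).
#'
#' @param lines a [line_list()].
#' @param scale harmonic frequency scaling factor (see [scale_linelist()]).
#' @param fwhm Lorentzian FWHM, cm^-1.
#' @param grid `wavenumber_axis` to evaluate on.
#' @param noise_sd additive noise SD (same unit as intensities per cm^-1).
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @return a [spectrum_1d()] (unit OD).
#' @export
generate_ftir <- function(lines, scale = 1, fwhm = 8, grid = NULL,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(lines, "line_list"))
  if (nrow(lines) == 0) stop("line list is empty", call. = FALSE)
  scaled <- scale_linelist(lines, scale)
  if (is.null(grid)) {
    grid <- wavenumber_axis(seq(max(1, min(scaled$frequency) - 20 * fwhm),
                                max(scaled$frequency) + 20 * fwhm, by = fwhm / 10))
  }
  if (!inherits(grid, "wavenumber_axis")) grid <- wavenumber_axis(grid)
  nu <- as.numeric(grid)
  gamma <- fwhm / 2
  y <- rep(0, length(nu))
  for (i in seq_len(nrow(scaled))) {
    y <- y + scaled$intensity[i] * (gamma / pi) /
      ((nu - scaled$frequency[i])^2 + gamma^2)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0", call. = FALSE)
    y <- y + .with_seed(seed, stats::rnorm(length(y), sd = noise_sd))
  }
  spectrum_1d(grid, y, unit = "OD")
}
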