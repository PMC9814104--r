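# Fixed-shape spectral decomposition of a TVA map: at every pump-probe delay
# the difference spectrum is fit as a sign-constrained linear combination of
# three band shapes (bleach <= 0, ESA components >= 0).

#' Build a three-component spectral basis
#'
#' Default band parameters are the packaged fixture values for the requested
#' starting isomer: bleach / hot-ESA / photoisomer centers at 1707 / 1680 /
#' 1718 cm^-1 (E) or 1713 / 1690 / 1708 cm^-1 (Z), FWHM 10 / 40 / 10 cm^-1,
#' all Gaussian. Any band parameter can be overridden.
#'
#' @param isomer `"E"` or `"Z"`.
#' @param overrides named list of per-component overrides, e.g.
#'   `list(gsb = list(center = 1700), vib_relax = list(family = "lorentzian"))`.
#'   Recognised fields: `center`, `fwhm`, `family`.
#' @return an object of class `basis_set`: named list of [band_shape()]s
#'   (`gsb`, `vib_relax`, `photoisomer`) with sign constraints gsb -, others +.
#' @export
build_basis <- function(isomer = c("E", "Z"), overrides = NULL) {
  isomer <- match.arg(isomer)
  bands <- default_fixture(isomer)$bands
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(bands)) {
        stop("unknown component in overrides: ", nm, call. = FALSE)
      }
      ov <- overrides[[nm]]
      b <- bands[[nm]]
      bands[[nm]] <- band_shape(
        center = if (!is.null(ov$center)) ov$center else b$center,
        fwhm   = if (!is.null(ov$fwhm)) ov$fwhm else b$fwhm,
        sign   = b$sign,
        family = if (!is.null(ov$family)) ov$family else b$family
      )
    }
  }
  structure(bands, class = "basis_set")
}

#' Basis design matrix on a wavenumber grid
#'
#' Columns are the unit-peak band profiles; each component's sign constraint
#' (bleach coefficient <= 0, ESA >= 0) is carried by the band's `sign` field
#' and absorbed into the solver, so the constrained solve is a plain
#' non-negativity problem.
#'
#' @param basis a `basis_set` (or plain named list of [band_shape()]s).
#' @param nu numeric wavenumber grid.
#' @return matrix `length(nu)` x n_components of non-negative profiles.
#' @export
basis_matrix <- function(basis, nu) {
  m <- vapply(basis, eval_band, numeric(length(nu)), nu = as.numeric(nu))
  matrix(m, nrow = length(nu), dimnames = list(NULL, names(basis)))
}

# Exact small-scale sign-constrained least squares: minimise ||y - X c|| with
# c_j >= 0 after sign absorption. Enumerates all active sets (2^p feasible
# for p <= ~6) and returns the feasible solution with minimal RSS; exact for
# the three-component basis used here.
.nnls_enum <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    c_full <- rep(0, p)
    if (length(free) > 0) {
      Xf <- X[, free, drop = FALSE]
      cf <- tryCatch(qr.solve(Xf, y), error = function(e) NULL)
      if (is.null(cf) || any(cf < 0)) next
      c_full[free] <- cf
    }
    r <- y - X %*% c_full
    rss <- sum(r^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c_full
    }
  }
  list(coef = best, rss = best_rss)
}

#' Decompose a TVA map onto a fixed spectral basis
#'
#' For each delay, solves the sign-constrained linear least-squares problem
#' dA(., t) ~ sum_k c_k S_k(.) with the bleach coefficient constrained <= 0
#' and ESA coefficients >= 0. Standard errors come from the unconstrained
#' normal-equation covariance sigma^2 (S'S)^-1 with sigma^2 the per-delay
#' residual variance. Delays before time zero are fit like any other and
#' flagged in the `pre_t0` column; they act as a zero-baseline check.
#'
#' @param map a [tva_map()].
#' @param basis a `basis_set` from [build_basis()].
#' @return an object of class `amplitude_traces`: a data.frame with columns
#'   `t`, one coefficient column per component (mOD, signed), matching
#'   `se_*` columns, `rms_residual` and `pre_t0`.
#' @export
decompose <- function(map, basis) {
  stopifnot(inherits(map, "tva_map"))
  nu <- as.numeric(map$nu)
  centers <- vapply(basis, `[[`, numeric(1), "center")
  if (any(centers < min(nu) | centers > max(nu))) {
    stop("basis band centers must lie inside the map wavenumber range",
         call. = FALSE)
  }
  S <- basis_matrix(basis, nu)
  # conditioning check: near-identical band pairs make the fit meaningless
  cn <- stats::cor(S)
  for (i in seq_len(ncol(S) - 1)) {
    for (j in (i + 1):ncol(S)) {
      if (abs(cn[i, j]) > 1 - 1e-10) {
        stop(sprintf("basis components '%s' and '%s' are (anti)collinear",
                     colnames(S)[i], colnames(S)[j]), call. = FALSE)
      }
    }
  }
  signs <- vapply(basis, `[[`, numeric(1), "sign")
  Xpos <- sweep(S, 2, signs, `*`)  # columns now all carry the + constraint
  n <- length(nu)
  p <- ncol(S)
  XtX_inv <- solve(crossprod(S))
  k <- length(map$t)
  coefs <- matrix(0, k, p, dimnames = list(NULL, colnames(S)))
  ses <- matrix(0, k, p)
  rms <- numeric(k)
  for (i in seq_len(k)) {
    y <- map$dA[i, ]
    sol <- .nnls_enum(Xpos, y)
    coefs[i, ] <- signs * sol$coef
    sigma2 <- sol$rss / max(1, n - p)
    ses[i, ] <- sqrt(sigma2 * diag(XtX_inv))
    rms[i] <- sqrt(sol$rss / n)
  }
  out <- data.frame(t = as.numeric(map$t), coefs, check.names = FALSE)
  colnames(ses) <- paste0("se_", colnames(S))
  out <- cbind(out, ses, rms_residual = rms, pre_t0 = as.numeric(map$t) < 0)
  class(out) <- c("amplitude_traces", "data.frame")
  out
}

#' Extract a single component trace
#'
#' @param traces an `amplitude_traces` data.frame from [decompose()].
#' @param component component name, e.g. `"photoisomer"`.
#' @return data.frame with columns `t`, `c`, `se`.
#' @export
component_trace <- function(traces, component) {
  if (!component %in% colnames(traces)) {
    stop("no such component: ", component, call. = FALSE)
  }
  data.frame(t = traces$t, c = traces[[component]],
             se = traces[[paste0("se_", component)]])
}
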