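# Mono-exponential kinetic fitting of component amplitude traces, bootstrap
# uncertainties, and ground-state-bleach percentage recovery.

.kin_models <- c("decay_to_offset", "rise_to_plateau", "gsb_recovery")

.model_fn <- function(model) {
  switch(model,
    decay_to_offset = function(p, t) p[["A"]] * exp(-t / p[["tau"]]) + p[["C"]],
    rise_to_plateau = function(p, t) p[["A"]] * (1 - exp(-t / p[["tau"]])),
    gsb_recovery    = function(p, t)
      -(1 - p[["R"]] * (1 - exp(-t / p[["tau"]]))) * p[["A0"]]
  )
}

# Deterministic starting values: tau0 from the 1/e crossing of the range,
# amplitudes from the trace endpoints. No random initialisation, so fits are
# reproducible given (trace, model, t_start).
.init_params <- function(model, t, y) {
  y1 <- y[1]
  yn <- y[length(y)]
  rng <- y1 - yn
  target <- yn + rng / exp(1)
  crossed <- if (rng >= 0) which(y <= target) else which(y >= target)
  tau0 <- if (length(crossed) > 0) max(t[min(crossed)], 1e-2) else stats::median(t)
  switch(model,
    decay_to_offset = c(A = rng, tau = tau0, C = yn),
    rise_to_plateau = c(A = yn, tau = tau0),
    gsb_recovery    = {
      A0 <- max(abs(y1), 1e-12)
      R0 <- min(max(1 - abs(yn) / A0, 1e-3), 0.999)
      c(A0 = A0, R = R0, tau = tau0)
    }
  )
}

.param_bounds <- function(model) {
  switch(model,
    decay_to_offset = list(lower = c(A = -Inf, tau = 1e-3, C = -Inf),
                           upper = c(A = Inf, tau = 1e5, C = Inf)),
    rise_to_plateau = list(lower = c(A = -Inf, tau = 1e-3),
                           upper = c(A = Inf, tau = 1e5)),
    gsb_recovery    = list(lower = c(A0 = 0, R = 0, tau = 1e-3),
                           upper = c(A0 = Inf, R = 1, tau = 1e5))
  )
}

#' Fit a mono-exponential model to a component trace
#'
#' Models: `decay_to_offset` A exp(-t/tau) + C (hot-band ESA),
#' `rise_to_plateau` A (1 - exp(-t/tau)) (photoisomer growth), and
#' `gsb_recovery` -(1 - R (1 - exp(-t/tau))) |A0| (bleach recovering a
#' fraction R). Weighted (optional) nonlinear least squares by
#' Levenberg-Marquardt with deterministic initialisation; `tau_se` from the
#' parameter covariance.
#'
#' @param trace data.frame with columns `t` (ps) and `c` (mOD), e.g. from
#'   [component_trace()]; an optional `se` column supplies weights when
#'   `weighted = TRUE`.
#' @param model one of `"decay_to_offset"`, `"rise_to_plateau"`,
#'   `"gsb_recovery"`.
#' @param t_start fit window start, ps (default 0.3, past the time-zero /
#'   IRF region).
#' @param weighted use 1/se weights if an `se` column is present.
#' @return an object of class `kinetic_fit`: list with `model`, `tau`,
#'   `tau_se`, `params`, `se`, `redchi2`, `fitted`, `residuals`, `t`, `y`,
#'   `t_start`, `at_bounds`.
#' @export
fit_monoexp <- function(trace, model = c("decay_to_offset", "rise_to_plateau",
                                         "gsb_recovery"),
                        t_start = 0.3, weighted = FALSE) {
  model <- match.arg(model)
  keep <- trace$t >= t_start
  t <- trace$t[keep]
  y <- trace$c[keep]
  if (length(t) < 6) stop("need at least 6 points with t >= t_start", call. = FALSE)
  if (diff(range(y)) < 1e-12 * max(1, max(abs(y)))) {
    stop("trace is constant over the fit window; no kinetics to fit", call. = FALSE)
  }
  w <- rep(1, length(t))
  if (weighted && !is.null(trace$se)) {
    se <- trace$se[keep]
    if (any(se <= 0)) stop("non-positive se; cannot weight", call. = FALSE)
    w <- 1 / se
  }
  fn <- .model_fn(model)
  bounds <- .param_bounds(model)
  resid_fn <- function(p) w * (y - fn(p, t))
  start <- .init_params(model, t, y)
  fit <- NULL
  # deterministic restart ladder on tau if the first attempt fails
  for (fac in c(1, 0.3, 3, 0.1, 10)) {
    st <- start
    st[["tau"]] <- start[["tau"]] * fac
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = bounds$lower, upper = bounds$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4) { fit <- cand; break }
  }
  if (is.null(fit)) {
    stop("mono-exponential fit failed to converge after restarts (model ",
         model, ")", call. = FALSE)
  }
  p <- fit$par
  n <- length(t)
  np <- length(p)
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / max(1, n - np)
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, np, np, dimnames = list(names(p), names(p)))
  })
  se_p <- sqrt(pmax(diag(covm), 0))
  names(se_p) <- names(p)
  at_bounds <- names(p)[p <= bounds$lower + 1e-10 | p >= bounds$upper - 1e-10]
  at_bounds <- setdiff(at_bounds, c("A0"))  # A0 lower bound 0 only matters if hit
  structure(list(
    model = model,
    tau = unname(p[["tau"]]), tau_se = unname(se_p[["tau"]]),
    params = unlist(p), se = se_p,
    redchi2 = sigma2,  # reduced chi-square (residual variance for unit weights)
    fitted = fn(p, t), residuals = y - fn(p, t),
    t = t, y = y, t_start = t_start,
    at_bounds = at_bounds
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: tau = %.3f +/- %.3f ps\n",
              x$model, x$tau, x$tau_se))
  invisible(x)
}

#' Bootstrap standard error of a fitted time constant
#'
#' Residual-resampling bootstrap: residuals of the point fit are resampled
#' with replacement, added to the fitted curve, and the model refit; the SD
#' of the refit time constants is returned. Errors if more than 20% of the
#' bootstrap refits fail.
#'
#' @param trace,model,t_start as in [fit_monoexp()].
#' @param n_boot number of bootstrap replicates (default 200).
#' @param seed integer seed (required; resampling is the only randomness).
#' @return list with `tau_se` (bootstrap SD), `tau_boot` (replicates), and
#'   the point `fit`.
#' @export
bootstrap_tau <- function(trace, model, n_boot = 200, seed, t_start = 0.3) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fit <- fit_monoexp(trace, model, t_start = t_start)
  taus <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ystar <- fit$fitted + sample(fit$residuals, replace = TRUE)
      tr <- data.frame(t = fit$t, c = ystar)
      f <- tryCatch(fit_monoexp(tr, model, t_start = t_start),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$tau
    }, numeric(1))
  })
  fail <- mean(is.na(taus))
  if (fail > 0.2) {
    stop(sprintf("%.0f%% of bootstrap refits failed", 100 * fail), call. = FALSE)
  }
  list(tau_se = stats::sd(taus, na.rm = TRUE), tau_boot = taus, fit = fit)
}

#' Ground-state-bleach percentage recovery
#'
#' 100 (|c_early| - |c_late|) / |c_early| with window means, where the early
#' window captures the full bleach just after time zero and the late window
#' sits after all kinetics have completed. Scale-invariant in the trace.
#'
#' @param gsb_trace data.frame with columns `t` (ps) and `c` (mOD; bleach,
#'   so typically negative).
#' @param early_window,late_window numeric length-2 windows in ps; defaults
#'   c(0.2, 1) and c(300, 600). Must not overlap.
#' @return recovery percentage (0 = static bleach, 100 = full recovery).
#' @export
gsb_recovery_percent <- function(gsb_trace, early_window = c(0.2, 1),
                                 late_window = c(300, 600)) {
  if (early_window[2] >= late_window[1]) {
    stop("early and late windows must not overlap", call. = FALSE)
  }
  win_mean <- function(w) {
    sel <- gsb_trace$t >= w[1] & gsb_trace$t <= w[2]
    if (!any(sel)) stop("no trace points in window [", w[1], ", ", w[2], "] ps",
                        call. = FALSE)
    mean(gsb_trace$c[sel])
  }
  early <- abs(win_mean(early_window))
  late <- abs(win_mean(late_window))
  if (early < 1e-12) stop("early-window bleach is ~0; recovery undefined",
                          call. = FALSE)
  100 * (early - late) / early
}
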