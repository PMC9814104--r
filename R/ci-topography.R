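# First-order branching-plane model of a conical intersection. From the
# gradient-difference vector g, the interstate-coupling vector h and the
# mean gradient s, build an orthogonal branching-plane frame, evaluate the
# first-order double-cone energies, and classify the intersection as
# peaked/sloped and single-path/bifurcating by sampling the cone on a circle.

#' Conical-intersection first-order model
#'
#' @param g gradient-difference vector (half the energy-difference gradient),
#'   eV per unit displacement.
#' @param h interstate coupling gradient vector, same units and dimension.
#' @param s mean-gradient vector, same units and dimension.
#' @param label optional text label (e.g. "CI_Z").
#' @return an object of class `ci_model`.
#' @export
ci_model <- function(g, h, s = rep(0, length(g)), label = "") {
  g <- as.numeric(g); h <- as.numeric(h); s <- as.numeric(s)
  if (length(g) != length(h) || length(g) != length(s)) {
    stop("g, h, s must have the same dimension", call. = FALSE)
  }
  if (sqrt(sum(g^2)) == 0 && sqrt(sum(h^2)) == 0) {
    stop("g and h cannot both be zero", call. = FALSE)
  }
  structure(list(g = g, h = h, s = s, label = label), class = "ci_model")
}

#' Orthogonalised branching-plane frame
#'
#' Rotates (g, h) by the mixing angle beta with tan(2 beta) =
#' 2 (g.h) / (|g|^2 - |h|^2) so the rotated vectors are orthogonal, then
#' orients the frame with x1 along the larger rotated vector. The returned
#' magnitudes g_t >= h_t define the cone semi-axes.
#'
#' @param g,h numeric vectors (not both zero).
#' @return list with orthonormal `x1`, `x2`, magnitudes `g_t`, `h_t`
#'   (g_t >= h_t), and the mixing angle `beta`.
#' @export
branching_plane <- function(g, h) {
  g <- as.numeric(g); h <- as.numeric(h)
  ng2 <- sum(g^2); nh2 <- sum(h^2)
  if (ng2 + nh2 == 0) stop("zero branching plane", call. = FALSE)
  beta <- 0.5 * atan2(2 * sum(g * h), ng2 - nh2)
  gr <- cos(beta) * g + sin(beta) * h
  hr <- -sin(beta) * g + cos(beta) * h
  g_t <- sqrt(sum(gr^2)); h_t <- sqrt(sum(hr^2))
  if (g_t >= h_t) {
    v1 <- gr; v2 <- hr
  } else {
    v1 <- hr; v2 <- gr
    tmp <- g_t; g_t <- h_t; h_t <- tmp
  }
  x1 <- v1 / sqrt(sum(v1^2))
  x2 <- if (h_t > 1e-300) v2 / sqrt(sum(v2^2)) else rep(0, length(v1))
  list(x1 = x1, x2 = x2, g_t = g_t, h_t = h_t, beta = beta)
}

#' First-order double-cone energies in the branching plane
#'
#' E+-(r) = s_bp . r +- sqrt((g_t r1)^2 + (h_t r2)^2) with the intersection
#' energy as zero; r is expressed in the orthonormal (x1, x2) frame and
#' s_bp is the projection of the mean gradient onto that frame.
#'
#' @param model a [ci_model()].
#' @param r length-2 point (or n x 2 matrix of points) in the branching
#'   plane, frame coordinates.
#' @return matrix with columns `lower`, `upper` (eV).
#' @export
cone_energies <- function(model, r) {
  fr <- branching_plane(model$g, model$h)
  r <- matrix(as.numeric(r), ncol = 2)
  s_bp <- c(sum(model$s * fr$x1), sum(model$s * fr$x2))
  tilt <- r %*% s_bp
  cone <- sqrt((fr$g_t * r[, 1])^2 + (fr$h_t * r[, 2])^2)
  cbind(lower = as.numeric(tilt - cone), upper = as.numeric(tilt + cone))
}

#' Classify a conical intersection from its sampled first-order cone
#'
#' Samples both sheets on a circle of the given radius around the
#' intersection. The CI is *sloped* if the upper sheet dips below the
#' intersection energy in some direction (both surfaces tilt downhill),
#' otherwise *peaked*. Valleys are the strict local minima of the lower
#' sheet over the circle; exactly one valley means *single-path*, two or
#' more *bifurcating*. The classification is invariant to a common positive
#' scaling of (g, h, s) and to rigid rotations of the ambient coordinates.
#'
#' @param model a [ci_model()].
#' @param n_theta number of circle samples (default 3600).
#' @param radius sampling radius in the branching plane (default 1; the
#'   first-order classification is radius-independent).
#' @return list with `peaking` ("peaked"/"sloped"), `pathing`
#'   ("single_path"/"bifurcating"), `theta_minima` (radians) and the
#'   sampled `theta`, `lower`, `upper`.
#' @export
classify_ci <- function(model, n_theta = 3600, radius = 1) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r <- radius * cbind(cos(theta), sin(theta))
  E <- cone_energies(model, r)
  lo <- E[, "lower"]; up <- E[, "upper"]
  if (diff(range(lo)) < 1e-12 * max(1, max(abs(lo)))) {
    stop("lower sheet is flat on the sampling circle; classification degenerate",
         call. = FALSE)
  }
  peaking <- if (any(up < 0)) "sloped" else "peaked"
  # strict local minima on the periodic grid
  prv <- c(lo[n_theta], lo[-n_theta])
  nxt <- c(lo[-1], lo[1])
  is_min <- lo < prv & lo < nxt
  th_min <- theta[is_min]
  # merge minima that are adjacent-and-degenerate (flat valley bottoms)
  if (length(th_min) > 1) {
    Emin <- lo[is_min]
    keep <- rep(TRUE, length(th_min))
    for (i in seq_along(th_min)[-1]) {
      dth <- min(abs(th_min[i] - th_min[i - 1]),
                 2 * pi - abs(th_min[i] - th_min[i - 1]))
      if (dth < 3 * 2 * pi / n_theta && abs(Emin[i] - Emin[i - 1]) < 1e-9) {
        keep[i] <- FALSE
      }
    }
    th_min <- th_min[keep]
  }
  pathing <- if (length(th_min) <= 1) "single_path" else "bifurcating"
  list(peaking = peaking, pathing = pathing, theta_minima = th_min,
       theta = theta, lower = lo, upper = up, label = model$label)
}
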