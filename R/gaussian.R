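# Baseline bivariate-Gaussian player influence, the classical alternative to
# the data-driven movement model and the reference for comparisons: the
# player's influence is a normal density centered ahead of the player, whose
# shape stretches with speed and whose size grows with distance to the ball.

#' Influence radius as a function of distance to the ball
#'
#' Sigmoidal map from ball distance to influence radius, rescaled so that
#' r(0) = 4 m exactly and r -> 10 m for large d (the radius range used by the
#' baseline model). The default inflection at 15 m with scale 3 m reproduces
#' the usual S-shape; both are configurable.
#'
#' @param d distance(s) to the ball in meters (nonnegative).
#' @param r_min,r_max radius range in meters.
#' @param midpoint,scale logistic inflection point and scale in meters.
#' @return Radius in meters, monotone nondecreasing in `d`.
#' @export
radius_from_ball <- function(d, r_min = 4, r_max = 10, midpoint = 15, scale = 3) {
  if (any(d < 0)) stop("argument error: distance to ball must be nonnegative")
  f0 <- stats::plogis(-midpoint / scale)
  f <- (stats::plogis((d - midpoint) / scale) - f0) / (1 - f0)
  clamp(r_min + (r_max - r_min) * f, r_min, r_max)
}

#' Parameters of the Gaussian influence ellipse
#'
#' The density is centered at `mu = p_t + 0.5 * v` (half the velocity vector
#' ahead of the player, reading v in m/s over a 0.5 s projection). The
#' covariance is `Sigma = R V V R^-1` with R the rotation by the movement
#' heading and V diagonal with entries `(r + r s) / 2` and `(r - r s) / 2`,
#' where `s = (|v| / v_max)^2` and r is the ball-distance radius: fast
#' movement stretches the ellipse along the heading and shrinks it across.
#' At `|v| = v_max` the second entry vanishes; entries are floored at
#' `eps` before squaring so Sigma stays positive definite.
#'
#' @param state a `player_state`.
#' @param ball length-2 ball position.
#' @param v_max maximum player speed in m/s (speeds above it are clipped,
#'   with a warning).
#' @param eps positive floor for the scaling entries, in meters.
#' @return A `gaussian_params` list: `mu`, `Sigma`, `R`, `V`, `theta`, `r`,
#'   `v_max`.
#' @export
gaussian_params <- function(state, ball, v_max = 13, eps = 1e-6) {
  if (v_max <= 0) stop("config error: v_max must be positive")
  v <- state$v
  spd <- sqrt(sum(v^2))
  if (spd > v_max) {
    warning(sprintf("speed %.2f m/s above v_max=%.2f; clipping", spd, v_max))
    v <- v * (v_max / spd)
    spd <- v_max
  }
  r <- radius_from_ball(euclid(state$p_t, ball))
  s <- (spd / v_max)^2
  vdiag <- pmax(c((r + r * s) / 2, (r - r * s) / 2), eps)
  th <- state$heading
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  V <- diag(vdiag)
  Sigma <- R %*% (V %*% V) %*% solve(R)
  structure(list(mu = state$p_t + 0.5 * v, Sigma = Sigma, R = R, V = V,
                 theta = th, r = r, v_max = v_max),
            class = "gaussian_params")
}

#' Normalized Gaussian influence
#'
#' The bivariate normal density at the query divided by its value at the
#' mode `mu`, i.e. `exp(-0.5 * (p - mu)' Sigma^-1 (p - mu))`, in (0, 1] with
#' 1 exactly at `mu`.
#'
#' @param params a `gaussian_params`.
#' @param points n x 2 matrix (or length-2 vector) of positions.
#' @return Numeric vector of influence values.
#' @export
gaussian_influence <- function(params, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  Sinv <- solve(params$Sigma)
  dx <- points[, 1] - params$mu[1]
  dy <- points[, 2] - params$mu[2]
  q <- Sinv[1, 1] * dx^2 + 2 * Sinv[1, 2] * dx * dy + Sinv[2, 2] * dy^2
  exp(-0.5 * q)
}

#' Gaussian influence density (unnormalized by mode)
#'
#' The plain bivariate normal density, provided for cross-checking the
#' normalized influence against direct evaluation.
#'
#' @param params a `gaussian_params`.
#' @param points n x 2 matrix (or length-2 vector).
#' @return Density values.
#' @export
gaussian_density <- function(params, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  detS <- det(params$Sigma)
  gaussian_influence(params, points) / (2 * pi * sqrt(detS))
}
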