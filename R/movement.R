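#' Movement time horizons
#'
#' The discrete set of look-ahead horizons used by the movement models,
#' T = 0.2, 0.4, ..., 5.0 s. The upper end reflects that passes are
#' completed within 5 s.
#'
#' @return Numeric vector of 25 horizons in seconds.
#' @export
movement_horizons <- function() (1:25) * 0.2

#' Snap a continuous time to the horizon set
#'
#' Nearest element of [movement_horizons()]; equidistant ties are broken
#' upward; values outside the set are clipped to its range.
#'
#' @param x time(s) in seconds.
#' @return Element(s) of the horizon set.
#' @export
snap_horizon <- function(x) {
  horizons <- movement_horizons()
  vapply(x, function(xi) {
    dd <- abs(horizons - xi)
    horizons[max(which(dd <= min(dd) + 1e-9))]
  }, numeric(1))
}

#' Velocity bin of a speed
#'
#' Speeds in km/h are grouped into standing \[0, 1), walking \[1, 7),
#' jogging \[7, 14), running \[14, 20), sprinting \[20, Inf); the bins
#' partition the nonnegative axis.
#'
#' @param speed_kmh speed(s) in km/h.
#' @return Factor with levels standing, walking, jogging, running, sprinting.
#' @export
velocity_bin <- function(speed_kmh) {
  cut(speed_kmh, breaks = c(0, 1, 7, 14, 20, Inf), right = FALSE,
      labels = c("standing", "walking", "jogging", "running", "sprinting"))
}

#' Extract trajectory triplets for one player
#'
#' A triplet (p_{t-delta}, p_t, p_{t+Delta}) encodes initial velocity (from
#' the first leg) and the realized displacement after Delta seconds. One
#' triplet is produced per (t, Delta) with both ends inside the sequence;
#' base times advance by `stride` frames, so consecutive triplets overlap.
#'
#' @param tracking a `tracking_sequence` (or a list of them, pooled).
#' @param player_id agent id.
#' @param delta velocity window in seconds (default 0.2).
#' @param horizons look-ahead horizons (default [movement_horizons()]).
#' @param stride step between base frames (default 1).
#' @return data.frame with columns `t, delta, Delta, x0, y0, x1, y1, x2, y2,
#'   speed_kmh, bin` where (x0,y0) = p_{t-delta}, (x1,y1) = p_t,
#'   (x2,y2) = p_{t+Delta}.
#' @export
extract_triplets <- function(tracking, player_id, delta = 0.2,
                             horizons = movement_horizons(), stride = 1L) {
  if (inherits(tracking, "tracking_sequence")) tracking <- list(tracking)
  out <- lapply(tracking, function(seq1) {
    fps <- attr(seq1, "fps") %||% 25
    rows <- seq1[seq1$agent_id == player_id & seq1$team != "ball", ]
    rows <- rows[order(rows$t), ]
    n <- nrow(rows)
    kd <- as.integer(round(delta * fps))
    if (n < kd + as.integer(round(min(horizons) * fps)) + 1L) {
      warning("sequence shorter than delta + min horizon: no triplets")
      return(NULL)
    }
    base <- seq.int(kd + 1L, n, by = stride)
    res <- lapply(horizons, function(Dl) {
      kD <- as.integer(round(Dl * fps))
      b <- base[base + kD <= n]
      if (!length(b)) return(NULL)
      data.frame(
        t = rows$t[b], delta = delta, Delta = Dl,
        x0 = rows$x[b - kd], y0 = rows$y[b - kd],
        x1 = rows$x[b], y1 = rows$y[b],
        x2 = rows$x[b + kD], y2 = rows$y[b + kD]
      )
    })
    do.call(rbind, res)
  })
  tri <- do.call(rbind, out)
  if (is.null(tri)) {
    tri <- data.frame(t = numeric(0), delta = numeric(0), Delta = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  }
  tri$speed_kmh <- 3.6 * sqrt((tri$x1 - tri$x0)^2 + (tri$y1 - tri$y0)^2) / delta
  tri$bin <- velocity_bin(tri$speed_kmh)
  rownames(tri) <- NULL
  tri
}

#' Transform triplets into the player-local frame
#'
#' Each triplet is translated so p_t sits at the origin and rotated so the
#' initial movement p_{t-delta} -> p_t points along +x. The endpoint is then
#' (d cos(theta), d sin(theta)) with d the length of the second leg and theta
#' the signed angle from the initial to the realized movement direction
#' (difference of the two atan2 headings). A left turn therefore lands at
#' positive y. Standing triplets (zero first leg) use heading 0, i.e. pure
#' translation. The transform is invariant under rigid motions of the raw
#' trajectory.
#'
#' @param triplets data.frame from [extract_triplets()].
#' @return The input with added columns `xe, ye` (local endpoint, meters),
#'   `d` (meters) and `theta` (radians).
#' @export
transform_triplets <- function(triplets) {
  dx1 <- triplets$x1 - triplets$x0
  dy1 <- triplets$y1 - triplets$y0
  dx2 <- triplets$x2 - triplets$x1
  dy2 <- triplets$y2 - triplets$y1
  head1 <- ifelse(dx1 == 0 & dy1 == 0, 0, atan2(dy1, dx1))
  d <- sqrt(dx2^2 + dy2^2)
  theta <- ifelse(d == 0, 0, atan2(dy2, dx2) - head1)
  triplets$xe <- d * cos(theta)
  triplets$ye <- d * sin(theta)
  triplets$d <- d
  triplets$theta <- theta
  triplets
}

# Diagonal Scott bandwidth for a 2-D sample, floored so degenerate clouds
# (e.g. constant-velocity endpoints) still give a proper density.
scott_bandwidth <- function(xy, floor = 0.05) {
  n <- nrow(xy)
  h <- apply(xy, 2, stats::sd) * n^(-1 / 6)
  pmax(h, floor)
}

# Gaussian-kernel mean shift with diagonal bandwidth; returns the mode the
# iteration converges to from `start`.
mean_shift_mode <- function(xy, h, start = colMeans(xy), tol = 1e-4,
                            max_iter = 500L) {
  x <- start
  for (i in seq_len(max_iter)) {
    w <- exp(-0.5 * (((xy[, 1] - x[1]) / h[1])^2 +
                     ((xy[, 2] - x[2]) / h[2])^2))
    sw <- sum(w)
    if (sw == 0) break # started too far out; stay put
    xn <- c(sum(w * xy[, 1]), sum(w * xy[, 2])) / sw
    if (sqrt(sum((xn - x)^2)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  x
}

kde_eval <- function(xy, h, q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 2)
  kde_gauss_eval(q, xy, h[1], h[2])
}

# Cross-validated scaling of the Scott bandwidth (k-fold held-out mean
# log-likelihood over a multiplicative grid).
cv_bandwidth <- function(xy, folds = 5L, grid = c(0.5, 0.75, 1, 1.5, 2),
                         floor = 0.05) {
  n <- nrow(xy)
  fold <- rep_len(seq_len(folds), n)
  base <- scott_bandwidth(xy, floor)
  ll <- vapply(grid, function(s) {
    h <- pmax(base * s, floor)
    mean(vapply(seq_len(folds), function(k) {
      tr <- xy[fold != k, , drop = FALSE]
      te <- xy[fold == k, , drop = FALSE]
      mean(log(pmax(kde_eval(tr, h, te), 1e-300)))
    }, numeric(1)))
  }, numeric(1))
  pmax(base * grid[which.max(ll)], floor)
}

#' Fit a data-driven movement model for one player
#'
#' Transformed triplet endpoints are grouped by (velocity bin, horizon) and
#' each populated cell is summarized by a Gaussian-kernel density estimate.
#' The default bandwidth is the (diagonal) Scott rule; `bandwidth = "cv"`
#' selects a multiplicative rescaling by k-fold cross-validated held-out
#' log-likelihood. The main mode of each cell is located by mean shift
#' (bandwidth equal to the KDE bandwidth, initialized at the endpoint mean,
#' tolerance 1e-4 m, at most 500 iterations) and its density is stored so
#' influence queries can be normalized. Cells with fewer than `min_count`
#' endpoints are marked unavailable.
#'
#' @param triplets data.frame from [extract_triplets()] (transformed
#'   internally if needed).
#' @param player_id id stored in the model.
#' @param min_count minimum endpoints per cell (default 50).
#' @param bandwidth `"scott"` (default) or `"cv"`.
#' @param horizons horizon set of the model.
#' @return A `movement_model`: list with `player_id`, `horizons`, `cells`
#'   (per "bin|Delta" key: `endpoints`, `h`, `n`, `mode`, `peak`).
#' @export
fit_movement_model <- function(triplets, player_id = "player",
                               min_count = 50L, bandwidth = c("scott", "cv"),
                               horizons = movement_horizons()) {
  bandwidth <- match.arg(bandwidth)
  if (!all(c("xe", "ye") %in% names(triplets))) {
    triplets <- transform_triplets(triplets)
  }
  cells <- list()
  for (bn in levels(triplets$bin)) {
    for (Dl in horizons) {
      sub <- triplets[triplets$bin == bn & abs(triplets$Delta - Dl) < 1e-9, ]
      if (nrow(sub) < min_count) next
      xy <- cbind(sub$xe, sub$ye)
      h <- if (bandwidth == "cv") cv_bandwidth(xy) else scott_bandwidth(xy)
      mode <- mean_shift_mode(xy, h)
      peak <- kde_eval(xy, h, mode)
      cells[[cell_key(bn, Dl)]] <- list(
        bin = bn, Delta = Dl, endpoints = xy, h = h, n = nrow(xy),
        mode = mode, peak = peak
      )
    }
  }
  structure(list(player_id = player_id, horizons = horizons,
                 min_count = min_count, bandwidth = bandwidth, cells = cells),
            class = "movement_model")
}

cell_key <- function(bin, Delta) sprintf("%s|%.1f", bin, Delta)

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model '%s': %d populated (bin, horizon) cells>\n",
              x$player_id, length(x$cells)))
  invisible(x)
}

# Locate the cell for (bin, Delta), falling back to the nearest available
# horizon within the same bin.
model_cell <- function(model, bin, Delta) {
  key <- cell_key(bin, snap_horizon(Delta))
  cell <- model$cells[[key]]
  if (!is.null(cell)) return(cell)
  avail <- Filter(function(c) c$bin == bin, model$cells)
  if (!length(avail)) {
    stop(sprintf("movement model '%s' has no cell for bin '%s'",
                 model$player_id, bin))
  }
  dd <- vapply(avail, function(c) abs(c$Delta - Delta), numeric(1))
  cell <- avail[[which.min(dd)]]
  message(sprintf("cell (%s, %.1f s) unavailable; using nearest horizon %.1f s",
                  bin, Delta, cell$Delta))
  cell
}

#' Normalized player influence from a movement model
#'
#' Query points are translated by -p_t and rotated by -heading into the
#' player-local frame, the cell density for (velocity bin, snapped horizon)
#' is evaluated there, and the result is divided by the density at the cell's
#' main mode, so influence lies in \[0, 1\] and equals 1 exactly at the mode.
#'
#' @param model a `movement_model`.
#' @param state a `player_state`.
#' @param Delta time horizon in seconds (snapped to the horizon set).
#' @param points n x 2 matrix (or length-2 vector) of pitch positions.
#' @return Numeric vector of influence values in \[0, 1\].
#' @export
player_influence <- function(model, state, Delta, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  cell <- model_cell(model, as.character(velocity_bin(state$speed_kmh)), Delta)
  th <- state$heading
  dx <- points[, 1] - state$p_t[1]
  dy <- points[, 2] - state$p_t[2]
  local <- cbind(cos(th) * dx + sin(th) * dy,
                 -sin(th) * dx + cos(th) * dy)
  as.numeric(kde_eval(cell$endpoints, cell$h, local) / cell$peak)
}

#' Global-frame position of a cell's main mode
#'
#' @param model a `movement_model`.
#' @param state a `player_state`.
#' @param Delta time horizon in seconds.
#' @return Length-2 pitch position where the player's influence is 1.
#' @export
influence_mode <- function(model, state, Delta) {
  cell <- model_cell(model, as.character(velocity_bin(state$speed_kmh)), Delta)
  th <- state$heading
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.numeric(state$p_t + rot %*% cell$mode)
}

#' Influence field of one player on a grid
#'
#' @param model a `movement_model`.
#' @param state a `player_state`.
#' @param Delta time horizon in seconds.
#' @param grid a `pitch_grid`.
#' @return A `pitch_field` with values in \[0, 1\].
#' @export
influence_field <- function(model, state, Delta, grid) {
  pitch_field(grid, player_influence(model, state, Delta, grid_matrix(grid)),
              what = "PI", meta = list(player_id = state$player_id,
                                       Delta = Delta))
}

#' Serialize a movement model to JSON
#'
#' @param model a `movement_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movement_model <- function(model, path) {
  obj <- list(
    schema = "spacekit-movement-1",
    player_id = model$player_id,
    horizons = model$horizons,
    min_count = model$min_count,
    bandwidth = model$bandwidth,
    cells = lapply(model$cells, function(c) {
      list(bin = c$bin, Delta = c$Delta, h = c$h, n = c$n,
           mode = c$mode, peak = c$peak,
           endpoints = unname(c$endpoints))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized movement model
#'
#' @param path JSON path written by [write_movement_model()].
#' @return A `movement_model`.
#' @export
read_movement_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$schema, "spacekit-movement-1"))
  cells <- lapply(obj$cells, function(c) {
    list(bin = c$bin, Delta = c$Delta, endpoints = c$endpoints,
         h = c$h, n = c$n, mode = c$mode, peak = c$peak)
  })
  structure(list(player_id = obj$player_id, horizons = obj$horizons,
                 min_count = obj$min_count, bandwidth = obj$bandwidth,
                 cells = cells),
            class = "movement_model")
}

#' Convex hull of a cell's endpoints
#'
#' Utility for inspecting reachable sets (the hull of the local-frame
#' endpoint cloud for one (bin, horizon) cell).
#'
#' @param model a `movement_model`.
#' @param bin velocity bin name.
#' @param Delta horizon in seconds.
#' @return m x 2 matrix of hull vertices in local coordinates.
#' @export
reachable_hull <- function(model, bin, Delta) {
  cell <- model$cells[[cell_key(bin, snap_horizon(Delta))]]
  if (is.null(cell)) stop("cell unavailable")
  cell$endpoints[grDevices::chull(cell$endpoints), , drop = FALSE]
}
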