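# Pitch control, observed defensive influence, the learned defensive
# influence surface, and pitch value.

# Per-player movement horizon for a frame: each player's time budget is the
# predicted pass duration for her current distance to the ball; the ball
# carrier (nearest player to the ball unless given) gets the smallest
# horizon.
frame_horizons <- function(frame, pass_time_model, carrier_id = NULL,
                           Delta_default = 1) {
  pl <- frame$players
  if (nrow(pl) == 0) return(numeric(0))
  d <- sqrt((pl$x - frame$ball[1])^2 + (pl$y - frame$ball[2])^2)
  if (is.null(pass_time_model)) {
    Dl <- rep(snap_horizon(Delta_default), nrow(pl))
  } else {
    Dl <- predict_horizon(pass_time_model, d)
  }
  if (is.null(carrier_id)) carrier_id <- pl$player_id[which.min(d)]
  Dl[pl$player_id == carrier_id] <- min(movement_horizons())
  Dl
}

# n_nodes x n_players matrix of normalized influences for one frame.
frame_influence_matrix <- function(frame, backend, points, pass_time_model,
                                   carrier_id = NULL, exclude_gk = FALSE) {
  pl <- frame$players
  keep <- if (exclude_gk) which(pl$role != "GK") else seq_len(nrow(pl))
  Dl <- frame_horizons(frame, pass_time_model, carrier_id)
  out <- matrix(0, nrow(points), length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    out[, j] <- influence_at(backend, frame_state(frame, i), points,
                             Delta = Dl[i], ball = frame$ball)
  }
  colnames(out) <- pl$player_id[keep]
  out
}

#' Pitch control field
#'
#' The tanh-squashed difference of summed team influences,
#' `PC(p) = tanh(sum_A PI_a(p) - sum_B PI_b(p))`, in \[-1, 1\] with +1 full
#' control by team A (the attacking/possessing team by convention). Each
#' player's influence horizon is the pass-time prediction for her distance to
#' the ball; the ball carrier gets the smallest horizon.
#'
#' @param frame a `game_frame`.
#' @param backend an `influence_backend`.
#' @param pass_time_model a `pass_time_model`, or NULL to use a fixed
#'   1 s horizon.
#' @param grid a `pitch_grid` (or n x 2 matrix of query points).
#' @param carrier_id ball carrier id (default: player nearest the ball).
#' @return A `pitch_field` when `grid` is a grid, else a numeric vector.
#' @export
pitch_control <- function(frame, backend, pass_time_model, grid,
                          carrier_id = NULL) {
  as_field <- inherits(grid, "pitch_grid")
  points <- if (as_field) grid_matrix(grid) else
    if (is.null(dim(grid))) matrix(grid, ncol = 2) else grid
  if (nrow(frame$players) == 0) {
    pc <- rep(tanh(0), nrow(points))
  } else {
    pi_mat <- frame_influence_matrix(frame, backend, points, pass_time_model,
                                     carrier_id)
    sgn <- ifelse(frame$players$team == "A", 1, -1)
    pc <- tanh(as.numeric(pi_mat %*% sgn))
  }
  if (!as_field) return(pc)
  pitch_field(grid, pc, what = "PC", t = frame$t,
              meta = list(ball = frame$ball, backend = backend$kind))
}

#' Pitch control at final passes of successful possessions
#'
#' For every successful possession with at least three passes, evaluates the
#' attacking team's pitch control at the destination of the final pass, at
#' the time that pass was made. The share of positive values summarizes how
#' often the attack had created control at the shot-preparing pass.
#'
#' @param possessions list from [group_possessions()].
#' @param tracking a `tracking_sequence`.
#' @param backend an `influence_backend`.
#' @param pass_time_model a `pass_time_model` (or NULL).
#' @param delta velocity window for frame reconstruction.
#' @return data.frame with `possession_id`, `t`, `pc`; attribute
#'   `share_positive`.
#' @export
final_pass_pc <- function(possessions, tracking, backend, pass_time_model,
                          delta = 0.2) {
  keep <- Filter(function(p) p$success && p$n_p >= 3, possessions)
  p <- attr(tracking, "pitch") %||% pitch()
  rows <- lapply(keep, function(po) {
    ev <- po$passes[po$n_p, ]
    if (!in_pitch(ev$x_dest, ev$y_dest, p)) {
      message(sprintf("possession %d skipped: destination outside pitch",
                      po$possession_id))
      return(NULL)
    }
    ft <- align_events(tracking, ev)$frame_t
    fr <- frame_at(tracking, ft, delta)
    # sign convention: possessing team is A
    pc1 <- pitch_control(fr, backend, pass_time_model,
                         matrix(c(ev$x_dest, ev$y_dest), 1, 2),
                         carrier_id = ev$player_id)
    data.frame(possession_id = po$possession_id, t = ev$t,
               pc = if (po$team == "A") pc1 else -pc1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(possession_id = integer(0),
                                      t = numeric(0), pc = numeric(0))
  attr(out, "share_positive") <- mean(out$pc > 0)
  out
}

#' Observed defensive influence
#'
#' The summed normalized influence of the defending team's outfield players,
#' capped at one: `DI(p) = min(sum_defenders PI(p), 1)`. Goalkeepers are
#' excluded.
#'
#' @param frame a `game_frame`.
#' @param defending_team team label of the defenders (default "B").
#' @param grid a `pitch_grid` or n x 2 point matrix.
#' @param backend an `influence_backend`.
#' @param pass_time_model a `pass_time_model` (or NULL for a fixed horizon).
#' @return A `pitch_field` (or numeric vector) of DI values in \[0, 1\].
#' @export
observed_di <- function(frame, defending_team = "B", grid, backend,
                        pass_time_model = NULL) {
  as_field <- inherits(grid, "pitch_grid")
  points <- if (as_field) grid_matrix(grid) else
    if (is.null(dim(grid))) matrix(grid, ncol = 2) else grid
  def <- frame$players[frame$players$team == defending_team &
                         frame$players$role != "GK", , drop = FALSE]
  sub <- frame
  sub$players <- def
  if (nrow(def) == 0) {
    di <- rep(0, nrow(points))
  } else {
    pi_mat <- frame_influence_matrix(sub, backend, points, pass_time_model)
    di <- pmin(rowSums(pi_mat), 1)
  }
  if (!as_field) return(di)
  pitch_field(grid, di, what = "DI", t = frame$t,
              meta = list(ball = frame$ball, defending_team = defending_team))
}

#' Learn the defensive-influence surface
#'
#' Trains a feed-forward network `fn(ball, p)` that predicts observed
#' defensive influence at a grid node from four features: the node
#' coordinates and the ball coordinates. Training rows are all (frame, node)
#' pairs on the coarse grid; the shipped architecture is two hidden layers of
#' 64 ReLU units with dropout, optimized by Adam on mean squared error.
#' Features are standardized with constants stored in the model; at inference
#' the output is clipped to \[0, 1\], the range of the training target.
#'
#' @param frames list of `game_frame`s.
#' @param grid coarse training grid (default the 21 x 16 lattice).
#' @param backend an `influence_backend` for the observed-DI targets.
#' @param pass_time_model optional `pass_time_model` for the targets.
#' @param defending_team defenders' team label.
#' @param hidden hidden layer sizes.
#' @param dropout dropout rate on hidden layers.
#' @param epochs,batch,lr Adam training parameters.
#' @param val_frac held-out fraction for the reported diagnostics.
#' @param seed RNG seed (initialization, batching, split).
#' @return A `di_model`: network, feature scaling, diagnostics (`mse_val`,
#'   `r2_val`, `mse_train`, `mse_mean_baseline`).
#' @export
fit_di_model <- function(frames, grid = pitch_grid_dims(21, 16), backend,
                         pass_time_model = NULL, defending_team = "B",
                         hidden = c(64, 64), dropout = 0.1, epochs = 50,
                         batch = 256, lr = 1e-3, val_frac = 0.2, seed = 1) {
  points <- grid_matrix(grid)
  feats <- lapply(frames, function(fr) {
    di <- observed_di(fr, defending_team, points, backend, pass_time_model)
    cbind(points[, 1], points[, 2], fr$ball[1], fr$ball[2], di)
  })
  M <- do.call(rbind, feats)
  X <- M[, 1:4, drop = FALSE]
  y <- M[, 5]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  n <- nrow(Xs)
  idx <- with_seed(seed, sample.int(n))
  nva <- floor(val_frac * n)
  va <- idx[seq_len(nva)]
  tr <- idx[(nva + 1):n]
  net <- mlp_new(c(4, hidden, 1), seed = seed)
  net <- mlp_train(net, Xs[tr, , drop = FALSE], y[tr], epochs = epochs,
                   batch = batch, lr = lr, dropout = dropout, seed = seed + 1)
  pred_va <- clamp(mlp_forward(net, Xs[va, , drop = FALSE]), 0, 1)
  pred_tr <- clamp(mlp_forward(net, Xs[tr, , drop = FALSE]), 0, 1)
  mse_val <- mean((pred_va - y[va])^2)
  structure(list(
    net = net, center = center, scale = scale_,
    hidden = hidden, dropout = dropout, epochs = epochs,
    defending_team = defending_team,
    mse_train = mean((pred_tr - y[tr])^2),
    mse_val = mse_val,
    r2_val = 1 - mse_val / stats::var(y[va]),
    mse_mean_baseline = mean((mean(y[tr]) - y[va])^2),
    n = n
  ), class = "di_model")
}

#' @export
print.di_model <- function(x, ...) {
  cat(sprintf("<di_model: %s hidden units, held-out MSE %.5f (R2 %.3f) on %d rows>\n",
              paste(x$hidden, collapse = "x"), x$mse_val, x$r2_val, x$n))
  invisible(x)
}

#' Predict defensive influence from the learned surface
#'
#' @param model a `di_model`.
#' @param ball length-2 ball position.
#' @param points n x 2 matrix of positions.
#' @return Predicted DI in \[0, 1\].
#' @export
predict_di <- function(model, ball, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  X <- cbind(points[, 1], points[, 2], ball[1], ball[2])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  clamp(mlp_forward(model$net, Xs), 0, 1)
}

#' Serialize a learned DI surface to JSON
#'
#' @param model a `di_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_di_model <- function(model, path) {
  obj <- list(
    schema = "spacekit-di-1",
    hidden = model$hidden, dropout = model$dropout,
    defending_team = model$defending_team,
    center = model$center, scale = model$scale,
    sizes = model$net$sizes,
    W = lapply(model$net$W, unname), b = model$net$b,
    diagnostics = list(mse_train = model$mse_train, mse_val = model$mse_val,
                       r2_val = model$r2_val, n = model$n)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized DI surface
#'
#' @param path JSON path written by [write_di_model()].
#' @return A `di_model`.
#' @export
read_di_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$schema, "spacekit-di-1"))
  structure(list(
    net = list(sizes = obj$sizes, W = lapply(obj$W, as.matrix), b = obj$b),
    center = obj$center, scale = obj$scale, hidden = obj$hidden,
    dropout = obj$dropout, defending_team = obj$defending_team,
    mse_train = obj$diagnostics$mse_train, mse_val = obj$diagnostics$mse_val,
    r2_val = obj$diagnostics$r2_val, n = obj$diagnostics$n
  ), class = "di_model")
}

#' Goal-distance scaling factor of the pitch value
#'
#' `1 - |p - p_goal| / |p_corner - p_goal|`, where the corner diagonally
#' opposite the attacked goal realizes the longest possible distance, so the
#' factor is 1 at the goal center and 0 at that corner.
#'
#' @param points n x 2 matrix of positions.
#' @param attack_direction +1 if the team under analysis attacks toward +x.
#' @param p a [pitch()].
#' @return Scaling factors in \[0, 1\] for points inside the pitch.
#' @export
goal_distance_scale <- function(points, attack_direction = 1, p = pitch()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pg <- c(attack_direction * p$xlim[2], 0)
  pc_ <- c(-attack_direction * p$xlim[2], p$ylim[2])
  1 - dist_to_point(points, pg) / euclid(pc_, pg)
}

#' Pitch value field
#'
#' The learned defensive influence at each node, scaled by proximity to the
#' attacked goal: `PV(p) = (1 - |p - pg| / |pc - pg|) * fn(ball, p)`, clipped
#' to \[0, 1\]. High values mark ground that defenders typically protect and
#' that is close to the goal.
#'
#' @param di_model a `di_model`.
#' @param ball length-2 ball position.
#' @param grid a `pitch_grid` or point matrix.
#' @param attack_direction +1 (attacking the +x goal) or -1.
#' @return A `pitch_field` (or numeric vector) of PV values.
#' @export
pitch_value <- function(di_model, ball, grid, attack_direction = 1) {
  as_field <- inherits(grid, "pitch_grid")
  points <- if (as_field) grid_matrix(grid) else
    if (is.null(dim(grid))) matrix(grid, ncol = 2) else grid
  pv <- clamp(goal_distance_scale(points, attack_direction) *
                predict_di(di_model, ball, points), 0, 1)
  if (!as_field) return(pv)
  pitch_field(grid, pv, what = "PV",
              meta = list(ball = ball, attack_direction = attack_direction))
}
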