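# Space quality, possession outcome features and classifier, space
# generation, and per-player aggregation / pass-network reports.

#' Space quality field
#'
#' Node-wise product of pitch control and pitch value: high where the team in
#' possession controls ground that defenders usually protect near the goal.
#'
#' @param control a `pitch_field` of PC values.
#' @param value a `pitch_field` of PV values on the identical grid.
#' @return A `pitch_field` of SQ values in \[-1, 1\].
#' @export
space_quality <- function(control, value) {
  if (!same_grid(control$grid, value$grid)) {
    stop("grid mismatch between control and value fields")
  }
  pitch_field(control$grid, control$values * value$values, what = "SQ",
              t = control$t, meta = control$meta)
}

#' Exponentially weighted possession features
#'
#' For a possession with pass timestamps T_k, the origin feature is the sum
#' over grid nodes of space quality weighted by exponential decay in the
#' distance to the pass origin, averaged over the passes:
#' `x_o = (1/n_p) sum_t sum_j SQ_t(p_j) exp(-lambda_o |p_j - p_o|)`,
#' and analogously `x_d` with the pass destination as anchor. Large lambda
#' focuses the feature on the anchor node; lambda = 0 gives the plain field
#' sum.
#'
#' @param possession a `possession`.
#' @param fields named list of SQ `pitch_field`s keyed by
#'   `sprintf("%.3f", t)` for each pass timestamp.
#' @param lambda_o,lambda_d decay rates in 1/m.
#' @return List with `possession_id`, `x_o`, `x_d`, `n_p`.
#' @export
possession_features <- function(possession, fields, lambda_o = 0.2,
                                lambda_d = 0.2) {
  stopifnot(possession$n_p > 0)
  xo <- 0
  xd <- 0
  for (i in seq_len(possession$n_p)) {
    ev <- possession$passes[i, ]
    f <- fields[[sprintf("%.3f", ev$t)]]
    if (is.null(f)) stop(sprintf("missing SQ field for pass timestamp t=%.3f", ev$t))
    nodes <- grid_matrix(f$grid)
    xo <- xo + sum(f$values * exp(-lambda_o * dist_to_point(nodes, c(ev$x, ev$y))))
    xd <- xd + sum(f$values * exp(-lambda_d * dist_to_point(nodes, c(ev$x_dest, ev$y_dest))))
  }
  list(possession_id = possession$possession_id,
       x_o = xo / possession$n_p, x_d = xd / possession$n_p,
       n_p = possession$n_p)
}

#' Default decay-rate grid for feature model selection
#'
#' @return Candidate lambda values in 1/m.
#' @export
lambda_grid <- function() c(0.05, 0.1, 0.2, 0.5, 1, 2)

#' Possession-outcome classification experiment
#'
#' Repeatedly fits a linear support vector machine on standardized possession
#' features to predict whether the possession ends with a shot, evaluating
#' each repeat by AUC on a random 20% held-out split. Splits that leave a
#' single class in train or test are redrawn (and counted).
#'
#' @param features data.frame or matrix of numeric features (e.g. `x_o`,
#'   `x_d`).
#' @param labels binary outcome vector (1 = possession ends with a shot).
#' @param n_repeats number of random splits (default 100).
#' @param seed RNG seed for the split sequence.
#' @param train_frac training fraction.
#' @return List with `auc` (vector of per-repeat AUCs), `mean`, `sd`,
#'   `redraws`.
#' @export
outcome_experiment <- function(features, labels, n_repeats = 100, seed = 1,
                               train_frac = 0.8) {
  X <- scale(as.matrix(features))
  X[, attr(X, "scaled:scale") == 0] <- 0
  y <- factor(as.integer(labels), levels = c(0, 1))
  n <- nrow(X)
  aucs <- numeric(n_repeats)
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      repeat {
        idx <- sample.int(n, floor(train_frac * n))
        if (length(unique(y[idx])) == 2 && length(unique(y[-idx])) == 2) break
        redraws <- redraws + 1L
      }
      fit <- e1071::svm(X[idx, , drop = FALSE], y[idx], kernel = "linear",
                        scale = FALSE)
      pr <- stats::predict(fit, X[-idx, , drop = FALSE], decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the decision value toward the positive class
      score <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
      aucs[r] <- as.numeric(pROC::auc(response = y[-idx], predictor = score,
                                      levels = c("0", "1"), direction = "<",
                                      quiet = TRUE))
    }
  })
  list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs), redraws = redraws)
}

#' Space generation of one player at one moment
#'
#' Per-player space quality is the player's own normalized influence weighted
#' by pitch value, `SQ_i(p) = PI_i(p) * PV(p)`. Space generation of player i
#' is the surplus of her space quality over every other player on the pitch,
#' summed over the grid:
#' `SG_i = sum_p sum_{j != i} max(SQ_i(p) - SQ_j(p), 0)`,
#' which is nonnegative and zero for a player whose space is everywhere
#' matched.
#'
#' @param frame a `game_frame` (typically at a pass initiation time).
#' @param player_id the player credited (usually the intended receiver).
#' @param backend an `influence_backend`.
#' @param value either a `di_model` or a precomputed PV `pitch_field` on
#'   `grid`.
#' @param grid a `pitch_grid`.
#' @param pass_time_model optional `pass_time_model` for per-player horizons.
#' @param attack_direction +1 or -1 (used when `value` is a `di_model`).
#' @return Nonnegative SG value.
#' @export
space_generation <- function(frame, player_id, backend, value, grid,
                             pass_time_model = NULL, attack_direction = 1) {
  points <- grid_matrix(grid)
  pv <- if (inherits(value, "pitch_field")) {
    stopifnot(same_grid(value$grid, grid))
    value$values
  } else {
    pitch_value(value, frame$ball, points, attack_direction)
  }
  pl <- frame$players
  i <- which(pl$player_id == player_id)
  if (length(i) != 1) stop("player not in frame: ", player_id)
  if (nrow(pl) == 1) return(0)
  pi_mat <- frame_influence_matrix(frame, backend, points, pass_time_model)
  sq <- pi_mat * pv
  sum(rowSums(pmax(sq[, i] - sq[, -i, drop = FALSE], 0)))
}

#' Space generation at every completed pass of a match
#'
#' Evaluates the receiver's space generation at each pass initiation time
#' (the moments when a player controls the ball and attempts a pass), for the
#' passes of one attacking team.
#'
#' @param tracking a `tracking_sequence`.
#' @param events an `event_log`.
#' @param team attacking team whose passes are scored (default "A").
#' @param backend an `influence_backend`.
#' @param value a `di_model` or precomputed PV field logic (see
#'   [space_generation()]).
#' @param grid a `pitch_grid`.
#' @param pass_time_model optional `pass_time_model`.
#' @param delta velocity window for frame reconstruction.
#' @return data.frame with `t`, `passer_id`, `receiver_id`, `sg`,
#'   `x_dest`, `y_dest`, `x`, `y`.
#' @export
space_generation_at_passes <- function(tracking, events, team = "A", backend,
                                       value, grid, pass_time_model = NULL,
                                       delta = 0.2) {
  passes <- events[events$type == "pass" & events$outcome == "complete" &
                     events$team == team, ]
  passes <- align_events(tracking, passes)
  passes <- passes[passes$frame_t - delta >= min(tracking$t) - 1e-9, ]
  rows <- lapply(seq_len(nrow(passes)), function(k) {
    ev <- passes[k, ]
    fr <- frame_at(tracking, ev$frame_t, delta)
    sg <- space_generation(fr, ev$receiver_id, backend, value, grid,
                           pass_time_model, attack_direction = 1)
    data.frame(t = ev$t, passer_id = ev$player_id,
               receiver_id = ev$receiver_id, sg = sg,
               x = ev$x, y = ev$y, x_dest = ev$x_dest, y_dest = ev$y_dest,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(t = numeric(0), passer_id = character(0),
                      receiver_id = character(0), sg = numeric(0),
                      x = numeric(0), y = numeric(0),
                      x_dest = numeric(0), y_dest = numeric(0))
  }
  out
}

#' Aggregate space generation per player
#'
#' `sg_rec` is the mean receiver space generation over the passes a player
#' received; `sg_pas` credits the same per-pass value to the passer;
#' `sg_total` is their sum. Per-90 columns rescale the per-player event sums
#' to 90 minutes of presence. Players with fewer than `min_involvements`
#' passes (as passer or receiver) are kept but flagged; players with zero
#' involvements are excluded.
#'
#' @param pass_sg data.frame from [space_generation_at_passes()].
#' @param minutes named vector of minutes played per player (default: the
#'   span of observed pass timestamps for everyone).
#' @param min_involvements robustness threshold (default 30).
#' @return data.frame, one row per player, sorted by `sg_total` descending,
#'   with a `flagged` column for players below the threshold.
#' @export
aggregate_sg <- function(pass_sg, minutes = NULL, min_involvements = 30) {
  players <- sort(unique(c(pass_sg$passer_id, pass_sg$receiver_id)))
  if (is.null(minutes)) {
    span <- (max(pass_sg$t) - min(pass_sg$t)) / 60
    minutes <- stats::setNames(rep(max(span, 1e-9), length(players)), players)
  }
  rows <- lapply(players, function(id) {
    rec <- pass_sg$sg[pass_sg$receiver_id == id]
    pas <- pass_sg$sg[pass_sg$passer_id == id]
    inv <- length(rec) + length(pas)
    if (inv == 0) return(NULL)
    m <- unname(minutes[id])
    data.frame(
      player_id = id,
      n_received = length(rec), n_passed = length(pas), involvements = inv,
      sg_rec = if (length(rec)) mean(rec) else 0,
      sg_pas = if (length(pas)) mean(pas) else 0,
      sg_rec_p90 = sum(rec) / m * 90,
      sg_pas_p90 = sum(pas) / m * 90,
      flagged = inv < min_involvements,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$sg_total <- out$sg_rec + out$sg_pas
  out$sg_total_p90 <- out$sg_rec_p90 + out$sg_pas_p90
  out[order(-out$sg_total), ]
}

#' Pass network toward a focus player
#'
#' Summarizes who passes to the focus player and how much space those passes
#' found: one row per passer with pass count and mean receiver space
#' generation, plus the per-pass records for rendering.
#'
#' @param pass_sg data.frame from [space_generation_at_passes()].
#' @param focus_player receiver of interest.
#' @return List with `edges` (data.frame `passer_id`, `n`, `mean_sg`) and
#'   `passes` (per-pass rows with origins/destinations and SG).
#' @export
pass_network <- function(pass_sg, focus_player) {
  sub <- pass_sg[pass_sg$receiver_id == focus_player, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no passes to focus player ", focus_player)
    return(list(edges = data.frame(passer_id = character(0), n = integer(0),
                                   mean_sg = numeric(0)),
                passes = sub))
  }
  agg <- stats::aggregate(sg ~ passer_id, data = sub,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  edges <- data.frame(passer_id = agg$passer_id,
                      n = as.integer(agg$sg[, "n"]),
                      mean_sg = agg$sg[, "mean"],
                      stringsAsFactors = FALSE)
  list(edges = edges[order(-edges$n), ], passes = sub)
}
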