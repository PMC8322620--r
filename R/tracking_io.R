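#' Read a tracking CSV
#'
#' Expected columns: `frame,t,agent_id,team,role,x,y` with one row per agent
#' per frame, `team` in `{A,B,ball}`, positions in meters in the centered
#' pitch frame. An optional first line `# fps: <n>` overrides the default
#' frame rate of 25 Hz. Frames must be complete and equally spaced: gaps are
#' an error, never interpolated, because silent interpolation corrupts
#' velocity estimates downstream.
#'
#' @param path file path.
#' @param fps frame rate in Hz used when the file has no `# fps:` header.
#' @param p a [pitch()] for bounds checks.
#' @return A `tracking_sequence`: a data.frame of the columns above, sorted
#'   by frame, with attributes `fps` and `pitch`.
#' @export
read_tracking <- function(path, fps = 25, p = pitch()) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fps:\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) fps <- as.numeric(m[2])
    skip <- 1L
  }
  d <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  need <- c("frame", "t", "agent_id", "team", "role", "x", "y")
  if (!all(need %in% names(d))) {
    stop("tracking format error: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  as_tracking(d[need], fps = fps, p = p)
}

#' Assemble a tracking sequence from a data.frame
#'
#' Validates the invariants of the tracking format (see [read_tracking()]).
#'
#' @param d data.frame with tracking columns.
#' @param fps frame rate in Hz.
#' @param p a [pitch()].
#' @return A `tracking_sequence`.
#' @export
as_tracking <- function(d, fps = 25, p = pitch()) {
  if (!all(is.finite(d$x)) || !all(is.finite(d$y))) {
    stop("tracking data error: non-finite positions")
  }
  bad <- which(!in_pitch(d$x, d$y, p))
  if (length(bad)) {
    stop(sprintf("tracking data error: position out of pitch bounds at row %d (x=%g, y=%g)",
                 bad[1], d$x[bad[1]], d$y[bad[1]]))
  }
  if (!all(d$team %in% c("A", "B", "ball"))) {
    stop("tracking format error: team must be one of A, B, ball")
  }
  d <- d[order(d$frame, match(d$team, c("A", "B", "ball")), d$agent_id), ,
         drop = FALSE]
  rownames(d) <- NULL
  ft <- unique(d$t[order(d$frame)])
  if (is.unsorted(ft, strictly = TRUE)) {
    stop("tracking data error: non-monotone timestamps")
  }
  if (length(ft) > 1) {
    dt <- diff(ft)
    if (any(abs(dt - 1 / fps) > 1e-4)) {
      stop(sprintf("tracking data error: frame gap near t=%.3f (expected step %.4f s); gaps are not interpolated",
                   ft[which(abs(dt - 1 / fps) > 1e-4)[1]], 1 / fps))
    }
  }
  per_frame <- table(d$frame)
  if (any(per_frame != per_frame[1])) {
    stop("tracking data error: frames differ in agent count")
  }
  if (!all(tapply(d$team == "ball", d$frame, sum) == 1)) {
    stop("tracking format error: each frame needs exactly one ball row")
  }
  structure(d, fps = fps, pitch = p,
            class = c("tracking_sequence", "data.frame"))
}

#' Write a tracking sequence in canonical form
#'
#' Canonical form: `# fps:` header line, rows sorted by frame then team
#' (A, B, ball) then agent id, positions with 4 decimals, times with 6.
#' `write_tracking(read_tracking(f))` is byte-identical to a canonical `f`.
#'
#' @param tracking a `tracking_sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracking, path) {
  fps <- attr(tracking, "fps") %||% 25
  lines <- c(
    sprintf("# fps: %g", fps),
    "frame,t,agent_id,team,role,x,y",
    sprintf("%d,%.6f,%s,%s,%s,%.4f,%.4f",
            tracking$frame, tracking$t, tracking$agent_id, tracking$team,
            tracking$role, tracking$x, tracking$y)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an event CSV (passes and shots)
#'
#' Expected columns:
#' `event_id,type,t,team,player_id,receiver_id,t_receive,x,y,x_dest,y_dest,outcome`
#' with `type` in `{pass,shot}`. For completed passes `outcome` is
#' `"complete"` and reception time/position must be present.
#'
#' @param path file path.
#' @param p a [pitch()] for bounds checks.
#' @return A data.frame of events sorted by time, class `event_log`.
#' @export
read_events <- function(path, p = pitch()) {
  stopifnot(file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "type", "t", "team", "player_id", "receiver_id",
            "t_receive", "x", "y", "x_dest", "y_dest", "outcome")
  if (!all(need %in% names(d))) {
    stop("event format error: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  as_events(d[need], p = p)
}

#' Validate an event data.frame
#'
#' @param d data.frame with event columns (see [read_events()]).
#' @param p a [pitch()].
#' @return An `event_log` data.frame sorted by time.
#' @export
as_events <- function(d, p = pitch()) {
  if (!all(d$type %in% c("pass", "shot"))) {
    stop("event format error: type must be 'pass' or 'shot'")
  }
  is_pass <- d$type == "pass"
  completed <- is_pass & d$outcome == "complete"
  if (any(completed & (is.na(d$receiver_id) | d$receiver_id == ""))) {
    stop("event data error: completed pass without receiver (event_id ",
         d$event_id[which(completed & (is.na(d$receiver_id) | d$receiver_id == ""))[1]], ")")
  }
  if (any(completed & !(d$t_receive > d$t))) {
    stop("event data error: pass reception not after initiation")
  }
  ok <- in_pitch(d$x, d$y, p) &
    (!completed | in_pitch(d$x_dest, d$y_dest, p))
  if (!all(ok)) {
    stop("event data error: position out of pitch bounds (event_id ",
         d$event_id[which(!ok)[1]], ")")
  }
  d <- d[order(d$t), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, pitch = p, class = c("event_log", "data.frame"))
}

#' Write events in canonical CSV form
#'
#' @param events an `event_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Segment an event log into ball possessions
#'
#' A possession is an uninterrupted sequence of passes by one team. It is
#' closed when the passing team changes or when a shot occurs; it is
#' successful iff its final event is a shot by the possessing team.
#' Possessions with fewer than three passes are flagged `short` (kept, not
#' deleted) because downstream analyses discard them.
#'
#' @param events an `event_log` (time-sorted).
#' @return A list of `possession` objects with fields `possession_id`,
#'   `team`, `passes` (data.frame of pass events), `n_p`, `success`,
#'   `short`, `pass_timestamps`.
#' @export
group_possessions <- function(events) {
  events <- events[order(events$t), , drop = FALSE]
  poss <- list()
  cur <- NULL
  new_poss <- function(team) list(team = team, rows = integer(0), success = FALSE)
  close_cur <- function() {
    if (!is.null(cur)) poss[[length(poss) + 1]] <<- cur
    cur <<- NULL
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$type == "pass") {
      if (is.null(cur) || cur$team != ev$team) {
        close_cur()
        cur <- new_poss(ev$team)
      }
      cur$rows <- c(cur$rows, i)
    } else { # shot
      if (is.null(cur) || cur$team != ev$team) {
        close_cur()
        cur <- new_poss(ev$team)
      }
      cur$success <- TRUE
      close_cur()
    }
  }
  close_cur()
  lapply(seq_along(poss), function(k) {
    pk <- poss[[k]]
    passes <- events[pk$rows, , drop = FALSE]
    structure(list(
      possession_id = k,
      team = pk$team,
      passes = passes,
      n_p = nrow(passes),
      success = pk$success,
      short = nrow(passes) < 3,
      pass_timestamps = passes$t
    ), class = "possession")
  })
}

#' @export
print.possession <- function(x, ...) {
  cat(sprintf("<possession %d: team %s, %d passes, %s%s>\n",
              x$possession_id, x$team, x$n_p,
              if (x$success) "successful" else "unsuccessful",
              if (x$short) ", short" else ""))
  invisible(x)
}

#' Align events to tracking frames
#'
#' Each event time is mapped to the nearest frame time; an equidistant tie is
#' broken toward the later frame so the mapping is deterministic. Events
#' outside the tracking span, or farther than `max_gap` from every frame, are
#' an alignment error.
#'
#' @param tracking a `tracking_sequence`.
#' @param events an `event_log`.
#' @param max_gap maximum tolerated |event time - frame time| in seconds.
#' @return `events` with added columns `frame_t` (aligned frame time) and
#'   `frame` (frame number).
#' @export
align_events <- function(tracking, events, max_gap = 0.1) {
  ft <- sort(unique(tracking$t))
  fidx <- sort(unique(tracking$frame))
  snap <- function(t, id) {
    if (t < ft[1] - max_gap || t > ft[length(ft)] + max_gap) {
      stop(sprintf("alignment error: event %s at t=%.3f outside tracking span [%.3f, %.3f]",
                   id, t, ft[1], ft[length(ft)]))
    }
    i <- findInterval(t, ft)
    cand <- unique(as.integer(pmin(pmax(c(i, i + 1L), 1L), length(ft))))
    dd <- abs(ft[cand] - t)
    # tie (equidistant frames) resolved toward the later frame
    j <- cand[max(which(dd <= min(dd) + 1e-9))]
    if (abs(ft[j] - t) > max_gap) {
      stop(sprintf("alignment error: event %s at t=%.3f is %.3f s from nearest frame (max_gap=%.3f)",
                   id, t, abs(ft[j] - t), max_gap))
    }
    j
  }
  j <- vapply(seq_len(nrow(events)),
              function(i) snap(events$t[i], events$event_id[i]), integer(1))
  events$frame_t <- ft[j]
  events$frame <- fidx[j]
  events
}

#' Kinematic state of a player at a time point
#'
#' The velocity is the backward finite difference over `delta` seconds,
#' `v = (p_t - p_{t-delta}) / delta`; speed is reported in km/h and the
#' heading is `atan2` of the displacement. A stationary player gets heading 0
#' by convention (the standing velocity bin is direction-free).
#'
#' @param tracking a `tracking_sequence`.
#' @param player_id agent id.
#' @param t time in seconds (must be a frame time).
#' @param delta velocity estimation window in seconds (default 0.2).
#' @return A `player_state` list: `player_id`, `team`, `role`, `p_t`,
#'   `p_tdelta`, `v` (m/s), `speed_kmh`, `heading` (radians).
#' @export
velocity_state <- function(tracking, player_id, t, delta = 0.2) {
  ft <- sort(unique(tracking$t))
  if (t - delta < ft[1] - 1e-9) {
    stop(sprintf("boundary error: t - delta = %.3f before first frame %.3f",
                 t - delta, ft[1]))
  }
  row_at <- function(tt) {
    r <- tracking[abs(tracking$t - tt) < 1e-6 & tracking$agent_id == player_id, ]
    if (nrow(r) != 1) {
      stop(sprintf("data error: no frame for player %s at t=%.3f", player_id, tt))
    }
    r
  }
  r1 <- row_at(t - delta)
  r2 <- row_at(t)
  player_state(player_id,
               team = r2$team, role = r2$role,
               p_t = c(r2$x, r2$y), p_tdelta = c(r1$x, r1$y), delta = delta)
}

#' Construct a player state from two positions
#'
#' @param player_id agent id.
#' @param team team label.
#' @param role role label ("GK" or "FIELD").
#' @param p_t position at time t (meters).
#' @param p_tdelta position delta seconds earlier.
#' @param delta time difference in seconds.
#' @return A `player_state`.
#' @export
player_state <- function(player_id, team, role = "FIELD", p_t, p_tdelta,
                         delta = 0.2) {
  v <- (p_t - p_tdelta) / delta
  disp <- p_t - p_tdelta
  heading <- if (all(disp == 0)) 0 else atan2(disp[2], disp[1])
  structure(list(player_id = player_id, team = team, role = role,
                 p_t = as.numeric(p_t), p_tdelta = as.numeric(p_tdelta),
                 delta = delta, v = as.numeric(v),
                 speed_kmh = 3.6 * sqrt(sum(v^2)), heading = heading),
            class = "player_state")
}

#' Snapshot of all players and the ball at one frame
#'
#' @param tracking a `tracking_sequence`.
#' @param t frame time in seconds; `t - delta` must also be a frame.
#' @param delta velocity estimation window in seconds.
#' @return A `game_frame`: list with `t`, `players` (data.frame with
#'   `player_id, team, role, x, y, vx, vy, speed_kmh, heading`), `ball`
#'   (length-2 position).
#' @export
frame_at <- function(tracking, t, delta = 0.2) {
  rows <- tracking[abs(tracking$t - t) < 1e-6, ]
  if (nrow(rows) == 0) stop(sprintf("data error: no frame at t=%.3f", t))
  prev <- tracking[abs(tracking$t - (t - delta)) < 1e-6, ]
  if (nrow(prev) == 0) {
    stop(sprintf("boundary error: no frame at t - delta = %.3f", t - delta))
  }
  ball <- rows[rows$team == "ball", ]
  pl <- rows[rows$team != "ball", ]
  m <- match(pl$agent_id, prev$agent_id)
  if (anyNA(m)) stop("data error: player missing in velocity frame")
  game_frame(
    players = data.frame(
      player_id = pl$agent_id, team = pl$team, role = pl$role,
      x = pl$x, y = pl$y,
      vx = (pl$x - prev$x[m]) / delta,
      vy = (pl$y - prev$y[m]) / delta,
      stringsAsFactors = FALSE
    ),
    ball = c(ball$x, ball$y), t = t
  )
}

#' Construct a game frame directly
#'
#' @param players data.frame with columns `player_id, team, role, x, y, vx,
#'   vy` (velocities in m/s).
#' @param ball length-2 ball position.
#' @param t frame time.
#' @return A `game_frame`.
#' @export
game_frame <- function(players, ball, t = 0) {
  need <- c("player_id", "team", "role", "x", "y", "vx", "vy")
  stopifnot(all(need %in% names(players)), length(ball) == 2,
            all(is.finite(ball)))
  players$speed_kmh <- 3.6 * sqrt(players$vx^2 + players$vy^2)
  players$heading <- ifelse(players$vx == 0 & players$vy == 0, 0,
                            atan2(players$vy, players$vx))
  structure(list(t = t, players = players, ball = as.numeric(ball)),
            class = "game_frame")
}

#' @export
print.game_frame <- function(x, ...) {
  cat(sprintf("<game_frame t=%.2f s: %d players (A: %d, B: %d), ball at (%.1f, %.1f)>\n",
              x$t, nrow(x$players), sum(x$players$team == "A"),
              sum(x$players$team == "B"), x$ball[1], x$ball[2]))
  invisible(x)
}

frame_state <- function(frame, i) {
  p <- frame$players[i, ]
  player_state(p$player_id, p$team, p$role,
               p_t = c(p$x, p$y),
               p_tdelta = c(p$x, p$y) - 0.2 * c(p$vx, p$vy),
               delta = 0.2)
}

#' Random game frame
#'
#' Uniform player positions, random velocities, random ball position; used
#' for property checks on pitch control surfaces.
#'
#' @param n_a,n_b number of players per team.
#' @param max_speed maximum drawn speed in m/s.
#' @param p a [pitch()].
#' @return A `game_frame`.
#' @export
random_frame <- function(n_a = 11, n_b = 11, max_speed = 8, p = pitch()) {
  n <- n_a + n_b
  ang <- stats::runif(n, -pi, pi)
  spd <- stats::runif(n, 0, max_speed)
  game_frame(
    players = data.frame(
      player_id = paste0(rep(c("A", "B"), c(n_a, n_b)), seq_len(n)),
      team = rep(c("A", "B"), c(n_a, n_b)),
      role = "FIELD",
      x = stats::runif(n, p$xlim[1], p$xlim[2]),
      y = stats::runif(n, p$ylim[1], p$ylim[2]),
      vx = spd * cos(ang), vy = spd * sin(ang),
      stringsAsFactors = FALSE
    ),
    ball = c(stats::runif(1, p$xlim[1], p$xlim[2]),
             stats::runif(1, p$ylim[1], p$ylim[2]))
  )
}
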