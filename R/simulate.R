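# Synthetic tracking + event generator with known ground truth. Team A
# attacks +x and strings passes together; team B defends with each player
# chasing a fixed affine function of the ball position (so the defensive
# influence surface is learnable); every agent obeys hard kinematic caps at
# every frame. Pass durations follow a plantable distance law and possession
# outcomes follow a plantable logistic law of receiver separation, so the
# downstream fitting stages can be validated against known truth.

#' Kinematic limits of a simulated player
#'
#' @param max_speed maximum speed in m/s.
#' @param max_accel maximum acceleration in m/s^2.
#' @param turn_rate_cap maximum heading change in rad/s.
#' @return A `kinematic_profile`.
#' @export
kinematic_profile <- function(max_speed = 8, max_accel = 4,
                              turn_rate_cap = 2 * pi) {
  stopifnot(max_speed > 0, max_accel > 0, turn_rate_cap > 0)
  structure(list(max_speed = max_speed, max_accel = max_accel,
                 turn_rate_cap = turn_rate_cap),
            class = "kinematic_profile")
}

#' Scenario configuration for the synthetic match
#'
#' @param seed RNG seed; the same seed yields byte-identical outputs.
#' @param n_players outfield players per team (one goalkeeper is added to
#'   each team on top).
#' @param duration match duration in seconds.
#' @param fps frame rate in Hz.
#' @param pass_law coefficients of the planted distance-to-duration law
#'   `Delta = alpha + beta * d^gamma + N(0, sd^2)`.
#' @param outcome_law coefficients (a, b) of the planted success law
#'   `P(success) = logistic(a + b * z)` with z the final-pass receiver's
#'   separation (meters to the nearest defender at the destination).
#' @param skill per-player space-creation multipliers for team A's outfield
#'   players (length `n_players`); a receiver's intended separation from the
#'   nearest defender scales with her skill.
#' @param kinematics a [kinematic_profile()] applied to every player.
#' @param defender_gain diagonal gain of the affine defender rule
#'   `target_b = anchor_b + gain * ball`.
#' @param defender_noise_sd isotropic noise (meters) on defender targets.
#' @param sep_base baseline receiver separation in meters (scaled by skill).
#' @param pass_interval range (s) between consecutive passes of a possession.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1, n_players = 10, duration = 120,
                            fps = 25,
                            pass_law = list(alpha = 0.5, beta = 0.045,
                                            gamma = 1, sd = 0.05),
                            outcome_law = list(a = -1, b = 0.3),
                            skill = rep(1, n_players),
                            kinematics = kinematic_profile(),
                            defender_gain = c(0.3, 0.4),
                            defender_noise_sd = 0.5,
                            sep_base = 3,
                            pass_interval = c(2, 4)) {
  stopifnot(length(skill) == n_players, all(skill > 0), duration > 0,
            fps > 0, n_players >= 2)
  structure(list(seed = seed, n_players = n_players, duration = duration,
                 fps = fps, pass_law = pass_law, outcome_law = outcome_law,
                 skill = skill, kinematics = kinematics,
                 defender_gain = defender_gain,
                 defender_noise_sd = defender_noise_sd,
                 sep_base = sep_base, pass_interval = pass_interval),
            class = "scenario_config")
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# One kinematic step for all agents: seek waypoints under speed, acceleration
# and turn-rate caps. pos, vel: n x 2; wp: n x 2. Returns updated pos, vel.
kin_step <- function(pos, vel, wp, prof, dt, p = NULL) {
  dvec <- wp - pos
  dist <- sqrt(rowSums(dvec^2))
  des_speed <- pmin(prof$max_speed, dist / 0.5)
  ang_des <- ifelse(dist < 1e-9, 0, atan2(dvec[, 2], dvec[, 1]))
  spd <- sqrt(rowSums(vel^2))
  ang_cur <- ifelse(spd < 1e-9, ang_des, atan2(vel[, 2], vel[, 1]))
  turn <- wrap_angle(ang_des - ang_cur)
  maxturn <- prof$turn_rate_cap * dt
  can_turn <- spd < 0.5 # near-stationary players reorient freely
  mis <- abs(turn)
  turn <- ifelse(can_turn, turn, clamp(turn, -maxturn, maxturn))
  ang_new <- ang_cur + turn
  # brake when badly aligned with the target direction, otherwise the
  # acceleration cap turns fast players into orbits around their waypoints
  des_speed <- des_speed * ifelse(can_turn, 1, pmax(0, cos(mis)))
  vdes <- cbind(des_speed * cos(ang_new), des_speed * sin(ang_new))
  dv <- vdes - vel
  dvn <- sqrt(rowSums(dv^2))
  amax <- prof$max_accel * dt
  f <- ifelse(dvn > amax, amax / dvn, 1)
  vel <- vel + dv * f
  spd <- sqrt(rowSums(vel^2))
  f <- ifelse(spd > prof$max_speed, prof$max_speed / spd, 1)
  vel <- vel * f
  newpos <- pos + vel * dt
  if (!is.null(p)) {
    cl <- cbind(clamp(newpos[, 1], p$xlim[1] + 0.2, p$xlim[2] - 0.2),
                clamp(newpos[, 2], p$ylim[1] + 0.2, p$ylim[2] - 0.2))
    vel[cl[, 1] != newpos[, 1], 1] <- 0
    vel[cl[, 2] != newpos[, 2], 2] <- 0
    newpos <- cl
  }
  # simulator bug assertion: the caps must hold frame by frame
  stopifnot(all(sqrt(rowSums((newpos - pos)^2)) <=
                  prof$max_speed * dt + 1e-9))
  list(pos = newpos, vel = vel)
}

#' Simulate a synthetic match
#'
#' @param config a [scenario_config()].
#' @return List with `tracking` (a `tracking_sequence`), `events` (an
#'   `event_log`) and `truth` (planted laws, skills, defender anchors, and
#'   the per-pass receiver separations).
#' @export
simulate_match <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, simulate_match_impl(config))
}

simulate_match_impl <- function(cfg) {
  p <- pitch()
  dt <- 1 / cfg$fps
  nf <- as.integer(round(cfg$duration * cfg$fps))
  npl <- cfg$n_players
  prof <- cfg$kinematics

  ids <- c(paste0("A", seq_len(npl)), "A_GK",
           paste0("B", seq_len(npl)), "B_GK")
  team <- rep(c("A", "B"), each = npl + 1)
  role <- rep(c(rep("FIELD", npl), "GK"), 2)
  na <- npl + 1 # agents per team
  n <- 2 * na
  iA <- seq_len(npl)               # A outfield
  iAgk <- npl + 1
  iB <- npl + 1 + seq_len(npl)     # B outfield
  iBgk <- n

  # initial layout: A spread in own half, B anchors in their defending half
  pos <- matrix(0, n, 2)
  pos[iA, 1] <- stats::runif(npl, -40, 0)
  pos[iA, 2] <- stats::runif(npl, -28, 28)
  pos[iAgk, ] <- c(p$xlim[1] + 2, 0)
  anchors <- cbind(stats::runif(npl, 8, 40), seq(-26, 26, length.out = npl))
  pos[iB, ] <- anchors
  pos[iBgk, ] <- c(p$xlim[2] - 2, 0)
  vel <- matrix(0, n, 2)
  wp <- pos

  holder <- sample(iA, 1)
  ball <- pos[holder, ]
  in_flight <- FALSE
  flight <- NULL
  passes_left <- sample(3:7, 1)
  next_pass_t <- stats::runif(1, cfg$pass_interval[1], cfg$pass_interval[2])
  wp_reset_t <- rep(0, n)

  pos_x <- matrix(NA_real_, nf, n + 1)
  pos_y <- matrix(NA_real_, nf, n + 1)
  ev <- list()
  seps <- numeric(0)
  eid <- 0L

  # Attackers operate around the defensive block, each in a zone whose
  # advancement toward the attacked goal grows with her skill: skilled
  # players occupy (and so create) space in more valuable areas, the way
  # strikers operate higher up the pitch than holding midfielders. Within
  # the zone every player seeks openness: among candidate spots around the
  # defenders closest to her preference point, she takes the one farthest
  # from the nearest defender.
  # operating zones: skilled players play higher up the pitch and more
  # central (both advance the zone toward the attacked goal); width is
  # covered by alternating the wing by skill rank
  rk <- rank(cfg$skill, ties.method = "first")
  pref <- cbind(clamp(-5 + 18 * cfg$skill, -20, 44),
                ifelse(rk %% 2 == 0, 1, -1) *
                  (26 - 22 * (rk - 1) / max(npl - 1, 1)))
  roam_spot <- function(i, near = pref[i, ], radius = 3 * cfg$sep_base) {
    rad <- stats::runif(8, 0, radius)
    angs <- stats::runif(8, -pi, pi)
    cand <- cbind(near[1] + rad * cos(angs), near[2] + rad * sin(angs))
    cand[, 1] <- clamp(cand[, 1], p$xlim[1] + 1, p$xlim[2] - 1)
    cand[, 2] <- clamp(cand[, 2], p$ylim[1] + 1, p$ylim[2] - 1)
    mind <- apply(cand, 1, function(q) min(dist_to_point(pos[iB, , drop = FALSE], q)))
    cand[which.max(mind), ]
  }

  # reception spot: a short lead near the receiver's current position (the
  # pass is played roughly to feet), into the openest nearby spot
  pick_destination <- function(r) {
    roam_spot(r, near = pos[r, ], radius = cfg$sep_base)
  }

  add_event <- function(type, t, tm, pid, rid = NA, t_rec = NA,
                        o = c(NA, NA), dst = c(NA, NA), outcome = "") {
    eid <<- eid + 1L
    ev[[eid]] <<- data.frame(
      event_id = sprintf("e%04d", eid), type = type, t = t, team = tm,
      player_id = pid, receiver_id = as.character(rid), t_receive = t_rec,
      x = o[1], y = o[2], x_dest = dst[1], y_dest = dst[2], outcome = outcome,
      stringsAsFactors = FALSE
    )
  }

  pass_duration <- function(d) {
    pl <- cfg$pass_law
    max(2 * dt, pl$alpha + pl$beta * d^pl$gamma + stats::rnorm(1, 0, pl$sd))
  }

  start_possession <- function(t) {
    holder <<- sample(iA, 1)
    ball <<- pos[holder, ]
    passes_left <<- sample(3:7, 1)
    next_pass_t <<- t + stats::runif(1, cfg$pass_interval[1], cfg$pass_interval[2])
  }

  for (k in seq_len(nf)) {
    t <- (k - 1) * dt

    # waypoints: A outfield roam forward, holder holds position loosely
    due <- which(t >= wp_reset_t)
    for (i in intersect(due, iA)) {
      wp[i, ] <- roam_spot(i)
      wp_reset_t[i] <- t + stats::runif(1, 1, 2)
    }
    if (holder %in% iA) {
      wp[holder, ] <- pos[holder, ] + stats::rnorm(2, 0, 0.5)
    }
    wp[iAgk, ] <- c(p$xlim[1] + 2, clamp(0.1 * ball[2], -3, 3))
    # defenders: fixed affine function of the ball, projected into their
    # defending half, plus isotropic noise
    tgt <- anchors + matrix(c(cfg$defender_gain[1] * ball[1],
                              cfg$defender_gain[2] * ball[2]),
                            npl, 2, byrow = TRUE)
    tgt <- tgt + matrix(stats::rnorm(2 * npl, 0, cfg$defender_noise_sd), npl, 2)
    tgt[, 1] <- clamp(tgt[, 1], 1, p$xlim[2] - 1)
    tgt[, 2] <- clamp(tgt[, 2], p$ylim[1] + 1, p$ylim[2] - 1)
    wp[iB, ] <- tgt
    wp[iBgk, ] <- c(p$xlim[2] - 2, clamp(0.1 * ball[2], -3, 3))
    if (in_flight) wp[flight$receiver, ] <- flight$dest

    st <- kin_step(pos, vel, wp, prof, dt, p)
    pos <- st$pos
    vel <- st$vel

    # ball and pass state machine
    if (in_flight) {
      if (t >= flight$t_r - 1e-9) {
        ball <- flight$dest
        holder <- flight$receiver
        in_flight <- FALSE
        if (flight$final) {
          if (flight$team == "A") {
            z <- flight$sep
            succ <- stats::runif(1) < stats::plogis(cfg$outcome_law$a +
                                                      cfg$outcome_law$b * z)
            if (succ) {
              add_event("shot", t + 2 * dt, "A", ids[holder],
                        o = pos[holder, ], outcome = "shot")
            } else {
              # turnover: one clearance pass by the defending team
              b1 <- iB[which.min(dist_to_point(pos[iB, , drop = FALSE], ball))]
              b2 <- sample(setdiff(iB, b1), 1)
              d <- euclid(pos[b1, ], pos[b2, ])
              Dl <- pass_duration(d)
              add_event("pass", t + 2 * dt, "B", ids[b1], ids[b2],
                        t_rec = t + 2 * dt + Dl,
                        o = pos[b1, ], dst = pos[b2, ], outcome = "complete")
            }
            start_possession(t + 0.8)
          }
          flight <- NULL
        } else {
          next_pass_t <- t + stats::runif(1, cfg$pass_interval[1],
                                          cfg$pass_interval[2])
          flight <- NULL
        }
      } else {
        frac <- (t - flight$t_p) / (flight$t_r - flight$t_p)
        ball <- flight$origin + frac * (flight$dest - flight$origin)
      }
    } else {
      ball <- pos[holder, ]
      if (t >= next_pass_t) {
        r <- sample(setdiff(iA, holder), 1)
        dest <- pick_destination(r)
        d <- euclid(pos[holder, ], pos[r, ]) # passer-receiver distance at t_p
        Dl <- pass_duration(d)
        sep <- min(dist_to_point(pos[iB, , drop = FALSE], dest))
        passes_left <- passes_left - 1
        add_event("pass", t, "A", ids[holder], ids[r], t_rec = t + Dl,
                  o = ball, dst = dest, outcome = "complete")
        seps <- c(seps, sep)
        flight <- list(team = "A", t_p = t, t_r = t + Dl,
                       origin = ball, dest = dest, receiver = r,
                       sep = sep, final = passes_left == 0)
        in_flight <- TRUE
      }
    }

    pos_x[k, ] <- c(pos[, 1], ball[1])
    pos_y[k, ] <- c(pos[, 2], ball[2])
  }

  frames <- rep(seq_len(nf), each = n + 1)
  tracking <- data.frame(
    frame = frames,
    t = (frames - 1) * dt,
    agent_id = rep(c(ids, "ball"), nf),
    team = rep(c(team, "ball"), nf),
    role = rep(c(role, "ball"), nf),
    x = as.numeric(t(pos_x)),
    y = as.numeric(t(pos_y)),
    stringsAsFactors = FALSE
  )
  events <- do.call(rbind, ev)
  # drop trailing events that extend past the tracked span
  events <- events[events$t <= (nf - 1) * dt &
                     (is.na(events$t_receive) | events$t_receive <= (nf - 1) * dt), ]
  list(
    tracking = as_tracking(tracking, fps = cfg$fps),
    events = as_events(events),
    truth = list(pass_law = cfg$pass_law, outcome_law = cfg$outcome_law,
                 skill = cfg$skill, anchors = anchors,
                 defender_gain = cfg$defender_gain,
                 defender_noise_sd = cfg$defender_noise_sd,
                 kinematics = cfg$kinematics, separations = seps,
                 player_ids = ids)
  )
}

#' Simulate a triplet corpus for one player
#'
#' Generates `n` short trajectory segments under a kinematic profile, with
#' initial speeds stratified evenly across the five velocity bins (bins above
#' the profile's maximum speed are skipped with a warning). Each segment
#' holds its initial velocity for the velocity-estimation window and then
#' seeks random waypoints under the caps, yielding one triplet per horizon.
#'
#' @param profile a [kinematic_profile()].
#' @param n number of segments (>= 1000 recommended for stable KDEs).
#' @param seed RNG seed.
#' @param horizons horizon set.
#' @param delta velocity window in seconds.
#' @param fps frame rate in Hz.
#' @return List with `triplets` (transformed, see [transform_triplets()]),
#'   `bin_counts` (segments per bin) and `profile`.
#' @export
simulate_triplet_corpus <- function(profile, n, seed = 1,
                                    horizons = movement_horizons(),
                                    delta = 0.2, fps = 25) {
  stopifnot(n >= 1)
  bins <- data.frame(
    name = c("standing", "walking", "jogging", "running", "sprinting"),
    lo = c(0, 1, 7, 14, 20),
    hi = c(1, 7, 14, 20, Inf),
    stringsAsFactors = FALSE
  )
  vmax_kmh <- 3.6 * profile$max_speed
  bins$hi <- pmin(bins$hi, vmax_kmh)
  avail <- bins$lo < vmax_kmh
  if (!all(avail)) {
    warning(sprintf("max speed %.1f km/h leaves bin(s) empty: %s",
                    vmax_kmh, paste(bins$name[!avail], collapse = ", ")))
    bins <- bins[avail, ]
  }
  nb <- nrow(bins)
  per <- rep(n %/% nb, nb)
  if (n %% nb) per[seq_len(n %% nb)] <- per[seq_len(n %% nb)] + 1
  dt <- 1 / fps
  kd <- as.integer(round(delta * fps))
  kmax <- as.integer(round(max(horizons) * fps))
  kh <- as.integer(round(horizons * fps))
  with_seed(seed, {
    # all segments advance in parallel: kinematics are vectorized over rows
    spd0 <- unlist(lapply(seq_len(nb), function(b) {
      stats::runif(per[b], bins$lo[b], min(bins$hi[b], vmax_kmh)) / 3.6
    }))
    head0 <- stats::runif(n, -pi, pi)
    vel <- cbind(spd0 * cos(head0), spd0 * sin(head0))
    pos <- matrix(0, n, 2)
    p0 <- pos
    # phase 1: hold the initial velocity over the estimation window
    pos <- pos + vel * (kd * dt)
    p1 <- pos
    maxdist <- profile$max_speed * max(horizons)
    ang <- head0 + stats::rnorm(n, 0, 0.6)
    wp <- pos + stats::runif(n, 5, maxdist) * cbind(cos(ang), sin(ang))
    wp_next <- rep(2, n)
    ends <- vector("list", length(horizons))
    for (k in seq_len(kmax)) {
      tseg <- k * dt
      due <- which(tseg >= wp_next)
      if (length(due)) {
        ang <- atan2(vel[due, 2], vel[due, 1]) +
          stats::rnorm(length(due), 0, 0.8)
        wp[due, ] <- pos[due, ] + stats::runif(length(due), 5, maxdist) *
          cbind(cos(ang), sin(ang))
        wp_next[due] <- tseg + 2
      }
      st <- kin_step(pos, vel, wp, profile, dt)
      pos <- st$pos
      vel <- st$vel
      hit <- which(kh == k)
      if (length(hit)) ends[[hit]] <- pos
    }
    tri <- do.call(rbind, lapply(seq_along(horizons), function(j) {
      data.frame(t = delta, delta = delta, Delta = horizons[j],
                 x0 = p0[, 1], y0 = p0[, 2], x1 = p1[, 1], y1 = p1[, 2],
                 x2 = ends[[j]][, 1], y2 = ends[[j]][, 2])
    }))
    tri$speed_kmh <- 3.6 * sqrt((tri$x1 - tri$x0)^2 + (tri$y1 - tri$y0)^2) / delta
    tri$bin <- velocity_bin(tri$speed_kmh)
    tri <- transform_triplets(tri)
    counts <- table(tri$bin[abs(tri$Delta - horizons[1]) < 1e-9])
    list(triplets = tri, bin_counts = counts, profile = profile)
  })
}
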