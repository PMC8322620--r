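test_that("pitch geometry and grids respect the coordinate conventions", {
  p <- pitch()
  expect_equal(p$xlim, c(-52.5, 52.5))
  expect_equal(p$ylim, c(-34, 34))
  expect_equal(unname(p$goal_center_home), c(52.5, 0))

  g <- pitch_grid(0.5)
  expect_equal(nrow(g), 210 * 136)
  expect_true(all(g$x > -52.5 & g$x < 52.5 & g$y > -34 & g$y < 34))
  # row-major, x fastest, deterministic
  expect_equal(g$x[1:3], c(-52.25, -51.75, -51.25))
  expect_identical(pitch_grid(0.5), g)

  gc <- pitch_grid_dims(21, 16)
  expect_equal(nrow(gc), 21 * 16)
  expect_equal(range(gc$x), c(-52.5, 52.5))
})

test_that("tracking files round-trip byte-identically through canonical form", {
  sim <- fx_match()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_tracking(sim$tracking, f1)
  tr <- read_tracking(f1)
  expect_s3_class(tr, "tracking_sequence")
  expect_equal(attr(tr, "fps"), 25)
  write_tracking(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tracking reader rejects out-of-bounds and broken files", {
  d <- data.frame(frame = 1L, t = 0, agent_id = c("p1", "ball"),
                  team = c("A", "ball"), role = c("FIELD", "ball"),
                  x = c(0, 0), y = c(40, 0))
  expect_error(as_tracking(d), "row 1.*y=40|out of pitch")
  d$y <- c(0, 0)
  expect_s3_class(as_tracking(d), "tracking_sequence")
  # frame gap is a hard error
  d3 <- data.frame(frame = c(1L, 1L, 3L, 3L), t = c(0, 0, 0.08, 0.08),
                   agent_id = c("p1", "ball", "p1", "ball"),
                   team = c("A", "ball", "A", "ball"),
                   role = c("FIELD", "ball", "FIELD", "ball"),
                   x = 0, y = 0)
  expect_error(as_tracking(d3), "gap")
})

test_that("a tiny hand-written tracking file round-trips", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "# fps: 25",
    "frame,t,agent_id,team,role,x,y",
    sprintf("%d,%.6f,%s,%s,%s,%.4f,%.4f",
            rep(1:3, each = 5), rep((0:2) / 25, each = 5),
            rep(c("p1", "p2", "q1", "q2", "ball"), 3),
            rep(c("A", "A", "B", "B", "ball"), 3),
            rep(c("FIELD", "FIELD", "FIELD", "FIELD", "ball"), 3),
            rep(c(0, 5, -5, 10, 1), 3) + rep((0:2) * 0.1, each = 5),
            rep(c(0, 1, 2, -1, 0), 3))
  ), f)
  tr <- read_tracking(f)
  expect_equal(length(unique(tr$frame)), 3)
  expect_equal(sum(tr$team != "ball") / 3, 4)
  f2 <- tempfile()
  write_tracking(tr, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("possession segmentation follows the team-change and shot rules", {
  mk <- function(type, t, team, pid = "x", rid = NA) {
    data.frame(event_id = paste0("e", t), type = type, t = t, team = team,
               player_id = pid, receiver_id = rid,
               t_receive = ifelse(type == "pass", t + 1, NA),
               x = 0, y = 0,
               x_dest = ifelse(type == "pass", 1, NA),
               y_dest = ifelse(type == "pass", 1, NA),
               outcome = ifelse(type == "pass", "complete", "shot"),
               stringsAsFactors = FALSE)
  }
  # three passes by A then a shot by A: one successful possession
  ev <- as_events(do.call(rbind, list(
    mk("pass", 1, "A", rid = "y"), mk("pass", 3, "A", rid = "y"),
    mk("pass", 5, "A", rid = "y"), mk("shot", 7, "A")
  )))
  poss <- group_possessions(ev)
  expect_length(poss, 1)
  expect_equal(poss[[1]]$n_p, 3)
  expect_true(poss[[1]]$success)
  expect_false(poss[[1]]$short)

  # two passes by A then a pass by B: A possession closed short, B opened
  ev2 <- as_events(do.call(rbind, list(
    mk("pass", 1, "A", rid = "y"), mk("pass", 3, "A", rid = "y"),
    mk("pass", 5, "B", rid = "z")
  )))
  poss2 <- group_possessions(ev2)
  expect_length(poss2, 2)
  expect_equal(poss2[[1]]$team, "A")
  expect_equal(poss2[[1]]$n_p, 2)
  expect_true(poss2[[1]]$short)
  expect_false(poss2[[1]]$success)
  expect_equal(poss2[[2]]$team, "B")

  # a shot with no preceding pass: degenerate possession, flagged
  poss3 <- group_possessions(as_events(mk("shot", 2, "A")))
  expect_length(poss3, 1)
  expect_equal(poss3[[1]]$n_p, 0)
  expect_true(poss3[[1]]$success)
  expect_true(poss3[[1]]$short)

  # permuting non-event columns never changes the segmentation
  ev4 <- ev[, c(2, 1, 3:12)]
  ev4 <- as_events(ev4[names(ev)])
  expect_equal(length(group_possessions(ev4)), length(poss))
})

test_that("event alignment snaps to the nearest frame, later on ties", {
  sim <- fx_match()
  tr <- sim$tracking
  mk_ev <- function(t) {
    data.frame(event_id = "e1", type = "pass", t = t, team = "A",
               player_id = "A1", receiver_id = "A2", t_receive = t + 1,
               x = 0, y = 0, x_dest = 1, y_dest = 1, outcome = "complete",
               stringsAsFactors = FALSE)
  }
  a <- align_events(tr, mk_ev(10.03))
  expect_equal(a$frame_t, 10.04)
  # equidistant between 10.00 and 10.04: later frame wins
  a2 <- align_events(tr, mk_ev(10.02))
  expect_equal(a2$frame_t, 10.04)
  # beyond the tracked span
  expect_error(align_events(tr, mk_ev(max(tr$t) + 5)), "alignment error")
  # every aligned event within half a frame interval
  al <- align_events(tr, sim$events)
  expect_true(all(abs(al$t - al$frame_t) <= 0.02 + 1e-9))
})

test_that("velocity states follow the finite-difference definition", {
  d <- data.frame(frame = rep(1:6, each = 2), t = rep((0:5) * 0.04, each = 2),
                  agent_id = rep(c("p1", "ball"), 6),
                  team = rep(c("A", "ball"), 6),
                  role = rep(c("FIELD", "ball"), 6),
                  x = c(rbind((0:5) * 0.2, 0)), y = 0)
  tr <- as_tracking(d)
  st <- velocity_state(tr, "p1", 0.2, delta = 0.2)
  expect_equal(st$v, c(5, 0))
  expect_equal(st$speed_kmh, 18)
  expect_equal(st$heading, 0)
  expect_error(velocity_state(tr, "p1", 0.1, delta = 0.2), "boundary")

  # movement along +y gives heading pi/2 (independent atan2 check)
  st2 <- player_state("p", "A", "FIELD", p_t = c(0, 1), p_tdelta = c(0, 0))
  expect_equal(st2$heading, atan2(1, 0))
  expect_equal(st2$heading, pi / 2)

  # stationary: zero velocity, heading 0 by convention
  st3 <- player_state("p", "A", "FIELD", p_t = c(3, 3), p_tdelta = c(3, 3))
  expect_equal(st3$v, c(0, 0))
  expect_equal(st3$heading, 0)
})
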