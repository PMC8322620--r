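test_that("space quality is the node-wise product with matching grids", {
  g <- pitch_grid(4)
  pc <- pitch_field(g, rep(0.57, nrow(g)), "PC")
  pv <- pitch_field(g, rep(0.5, nrow(g)), "PV")
  sq <- space_quality(pc, pv)
  expect_true(all(sq$values == 0.285))
  # absorbing zero
  expect_true(all(space_quality(pitch_field(g, rep(0, nrow(g))), pv)$values == 0))
  # bound by both factors
  set.seed(2)
  pcr <- pitch_field(g, runif(nrow(g), -1, 1))
  pvr <- pitch_field(g, runif(nrow(g), 0, 1))
  sqr <- space_quality(pcr, pvr)
  expect_true(all(abs(sqr$values) <= pmin(abs(pcr$values), pvr$values) + 1e-12))
  expect_error(space_quality(pitch_field(pitch_grid(2), rep(0, nrow(pitch_grid(2)))), pv),
               "mismatch")
})

test_that("possession features follow the exponential-decay definition", {
  g <- pitch_grid(2)
  mk_pass <- function(t, o, d) {
    data.frame(event_id = paste0("e", t), type = "pass", t = t, team = "A",
               player_id = "p1", receiver_id = "p2", t_receive = t + 1,
               x = o[1], y = o[2], x_dest = d[1], y_dest = d[2],
               outcome = "complete", stringsAsFactors = FALSE)
  }
  ev <- as_events(rbind(mk_pass(1, c(0, 0), c(10, 0)),
                        mk_pass(3, c(10, 0), c(20, 5))))
  poss <- group_possessions(ev)[[1]]
  # constant field, lambda = 0: feature is c * |F|
  cf <- pitch_field(g, rep(0.2, nrow(g)), "SQ")
  fields <- list("1.000" = cf, "3.000" = cf)
  f0 <- possession_features(poss, fields, lambda_o = 0, lambda_d = 0)
  expect_equal(f0$x_o, 0.2 * nrow(g))
  expect_equal(f0$x_d, 0.2 * nrow(g))
  # spike field, large lambda: feature concentrates at the anchor node
  nodes <- grid_matrix(g)
  spike <- rep(0, nrow(g))
  near <- which.min((nodes[, 1] - 10)^2 + (nodes[, 2] - 0)^2)
  spike[near] <- 1
  sf <- pitch_field(g, spike, "SQ")
  fd <- possession_features(poss, list("1.000" = sf, "3.000" = sf),
                            lambda_o = 10, lambda_d = 10)
  # pass 1 destination and pass 2 origin sit on the spike
  dist1 <- sqrt(sum((nodes[near, ] - c(10, 0))^2))
  expect_equal(fd$x_d, 0.5 * (exp(-10 * dist1) +
                                exp(-10 * sqrt(sum((nodes[near, ] - c(20, 5))^2)))),
               tolerance = 1e-9)
  # naive double-loop oracle
  lam <- 0.3
  set.seed(5)
  vals <- runif(nrow(g))
  vf <- pitch_field(g, vals, "SQ")
  got <- possession_features(poss, list("1.000" = vf, "3.000" = vf),
                             lambda_o = lam, lambda_d = lam)
  want_o <- 0
  for (i in 1:2) {
    o <- c(poss$passes$x[i], poss$passes$y[i])
    for (j in seq_len(nrow(g))) {
      want_o <- want_o + vals[j] * exp(-lam * sqrt(sum((nodes[j, ] - o)^2)))
    }
  }
  expect_equal(got$x_o, want_o / 2, tolerance = 1e-9)
  # features shrink monotonically in lambda for nonnegative fields
  lams <- c(0, 0.1, 0.5, 1, 2)
  xs <- vapply(lams, function(l) {
    possession_features(poss, list("1.000" = vf, "3.000" = vf), l, l)$x_o
  }, numeric(1))
  expect_true(all(diff(xs) < 0))
  # missing field is an error naming the timestamp
  expect_error(possession_features(poss, list("1.000" = vf), 1, 1), "3.000")
})

test_that("the outcome classifier is calibrated on null labels and detects a planted signal", {
  n <- 800
  X <- with_test_seed(7, data.frame(x_o = stats::rnorm(n), x_d = stats::rnorm(n)))
  y0 <- with_test_seed(8, stats::rbinom(n, 1, 0.2))
  oe0 <- outcome_experiment(X, y0, n_repeats = 60, seed = 1)
  expect_gte(oe0$mean, 0.45)
  expect_lte(oe0$mean, 0.55)
  y1 <- with_test_seed(9, stats::rbinom(n, 1, stats::plogis(-2 + 3 * X$x_d)))
  oe1 <- outcome_experiment(X, y1, n_repeats = 60, seed = 1)
  expect_gte(oe1$mean, 0.65)
  # same seed, identical AUC sequence
  oe2 <- outcome_experiment(X, y1, n_repeats = 60, seed = 1)
  expect_identical(oe1$auc, oe2$auc)
})

test_that("space generation matches a naive triple loop and its degeneracies", {
  bk <- gaussian_backend()
  g <- pitch_grid(4)
  fr <- toy_frame()
  ptm <- fx_ptm()
  pv <- pitch_field(g, goal_distance_scale(grid_matrix(g)) * 0.8, "PV")
  sg <- space_generation(fr, "a2", bk, pv, g, ptm)
  expect_gte(sg, 0)
  # naive triple loop over nodes and other players
  nodes <- grid_matrix(g)
  Dl <- spacekit:::frame_horizons(fr, ptm)
  sq <- sapply(seq_len(nrow(fr$players)), function(i) {
    influence_at(bk, spacekit:::frame_state(fr, i), nodes, Dl[i], fr$ball) *
      pv$values
  })
  want <- 0
  i <- which(fr$players$player_id == "a2")
  for (p in seq_len(nrow(nodes))) {
    for (j in seq_len(ncol(sq))[-i]) {
      want <- want + max(sq[p, i] - sq[p, j], 0)
    }
  }
  expect_equal(sg, want, tolerance = 1e-12)

  # a player alone on the pitch generates nothing
  solo <- game_frame(fr$players[2, ], ball = fr$ball)
  expect_equal(space_generation(solo, "a2", bk, pv, g, ptm), 0)
  # two identical players cancel exactly
  twin <- fr$players[c(2, 2), ]
  twin$player_id <- c("a2", "a2b")
  twins <- game_frame(twin, ball = fr$ball)
  expect_equal(space_generation(twins, "a2", bk, pv, g, ptm), 0)
  # relabeling uninvolved players changes nothing
  fr2 <- fr
  fr2$players$player_id[fr2$players$player_id == "b1"] <- "zz"
  expect_equal(space_generation(fr2, "a2", bk, pv, g, ptm), sg)
})

test_that("per-player aggregation means, flags and per-90 scaling", {
  pass_sg <- data.frame(
    t = c(60, 120, 180, 240, 300),
    passer_id = c("p9", "p9", "p9", "p7", "p7"),
    receiver_id = c("p7", "p7", "p7", "p9", "p5"),
    sg = c(1, 2, 3, 4, 6)
  )
  rep <- aggregate_sg(pass_sg, minutes = c(p9 = 90, p7 = 90, p5 = 45),
                      min_involvements = 30)
  p7 <- rep[rep$player_id == "p7", ]
  expect_equal(p7$sg_rec, 2)       # mean of 1, 2, 3
  expect_equal(p7$sg_pas, 5)       # mean of 4, 6 (receiver SG credited)
  expect_equal(p7$sg_total, 7)
  expect_equal(p7$sg_rec_p90, 6)   # sum 6 over 90 minutes
  expect_true(all(rep$flagged))    # everyone below 30 involvements
  p5 <- rep[rep$player_id == "p5", ]
  expect_equal(p5$sg_rec_p90, 6 / 45 * 90)
  # threshold boundary: 29 involvements flagged, 30 not
  many <- data.frame(t = 1:30, passer_id = "q1", receiver_id = "q2", sg = 1)
  r29 <- aggregate_sg(many[1:29, ], minutes = c(q1 = 90, q2 = 90))
  expect_true(all(r29$flagged))
  r30 <- aggregate_sg(many, minutes = c(q1 = 90, q2 = 90))
  expect_false(any(r30$flagged))
})

test_that("pass networks count edges and recompute their means", {
  pass_sg <- data.frame(
    t = seq_len(12),
    passer_id = c(rep("13", 10), "4", "4"),
    receiver_id = c(rep("6", 10), "6", "9"),
    sg = c(1:10, 5, 2)
  )
  net <- pass_network(pass_sg, "6")
  e13 <- net$edges[net$edges$passer_id == "13", ]
  expect_equal(e13$n, 10L)
  expect_equal(e13$mean_sg, mean(1:10))
  # edge means equal recomputation from the per-pass list
  for (k in seq_len(nrow(net$edges))) {
    sub <- net$passes[net$passes$passer_id == net$edges$passer_id[k], ]
    expect_equal(net$edges$mean_sg[k], mean(sub$sg))
    expect_equal(net$edges$n[k], nrow(sub))
  }
  expect_warning(empty <- pass_network(pass_sg, "99"), "no passes")
  expect_equal(nrow(empty$edges), 0)
})
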