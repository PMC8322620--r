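test_that("triplet extraction matches a brute-force enumeration", {
  # constant-velocity walk along x at 1.5 m/s, 10 s at 25 Hz
  n <- 251
  d <- data.frame(frame = rep(seq_len(n), each = 2),
                  t = rep((seq_len(n) - 1) / 25, each = 2),
                  agent_id = rep(c("p1", "ball"), n),
                  team = rep(c("A", "ball"), n),
                  role = rep(c("FIELD", "ball"), n),
                  x = c(rbind((seq_len(n) - 1) * 1.5 / 25, 0)), y = 0)
  tr <- as_tracking(d)
  tri <- extract_triplets(tr, "p1")
  # boundary arithmetic: for Delta = 5 the base times span [0.2, 5.0]
  t5 <- tri$t[abs(tri$Delta - 5) < 1e-9]
  expect_equal(range(t5), c(0.2, 5.0))
  # count oracle: enumerate valid (t, Delta) pairs by brute force
  expected <- sum(vapply(movement_horizons(), function(Dl) {
    sum((0:(n - 1)) / 25 >= 0.2 & (0:(n - 1)) / 25 + Dl <= (n - 1) / 25)
  }, numeric(1)))
  expect_equal(nrow(tri), expected)
  # all endpoints on the straight line at (1.5 * Delta, 0) in the local frame
  tt <- transform_triplets(tri)
  expect_equal(tt$xe, 1.5 * tt$Delta, tolerance = 1e-9)
  expect_equal(tt$ye, rep(0, nrow(tt)), tolerance = 1e-9)
  expect_true(all(tt$bin == "walking"))
})

test_that("the local-frame transform matches the explicit angle computation", {
  tri <- data.frame(t = 0, delta = 0.2, Delta = 1,
                    x0 = c(0, 0), y0 = c(0, 0),
                    x1 = c(1, 0), y1 = c(0, 1),
                    x2 = c(3, -1), y2 = c(0, 1))
  tt <- transform_triplets(tri)
  # collinear: endpoint at (2, 0)
  expect_equal(c(tt$xe[1], tt$ye[1]), c(2, 0), tolerance = 1e-12)
  # initial +y, endpoint one to the left: d = 1, theta = pi/2 -> (0, 1)
  expect_equal(tt$d[2], 1)
  expect_equal(tt$xe[2], 0, tolerance = 1e-12)
  expect_equal(tt$ye[2], 1, tolerance = 1e-12)

  # global rotation of all three points leaves the transform unchanged
  for (ang in c(0.3, 1.2, -2.5)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    pts <- rbind(c(0, 0), c(0, 1), c(-1, 1)) %*% t(R)
    tr2 <- transform_triplets(data.frame(
      t = 0, delta = 0.2, Delta = 1,
      x0 = pts[1, 1], y0 = pts[1, 2], x1 = pts[2, 1], y1 = pts[2, 2],
      x2 = pts[3, 1], y2 = pts[3, 2]))
    expect_equal(c(tr2$xe, tr2$ye), c(0, 1), tolerance = 1e-9)
  }
})

test_that("fitted densities are proper and deterministic", {
  # planted isotropic Gaussian endpoint cloud
  ep <- with_test_seed(4, matrix(stats::rnorm(2 * 5000, 0, 1), ncol = 2))
  tri <- data.frame(t = 0, delta = 0.2, Delta = 1,
                    x0 = 0, y0 = 0, x1 = 0.1, y1 = 0,
                    x2 = ep[, 1], y2 = ep[, 2])
  tri$speed_kmh <- 3.6 * 0.1 / 0.2
  tri$bin <- velocity_bin(tri$speed_kmh)
  tri <- transform_triplets(tri)
  m1 <- fit_movement_model(tri, "p")
  cell <- m1$cells[["walking|1.0"]]
  expect_false(is.null(cell))
  # quadrature oracle over [-10, 10]^2
  sp <- 0.05
  q <- as.matrix(expand.grid(seq(-10, 10, sp), seq(-10, 10, sp)))
  integral <- sum(spacekit:::kde_eval(cell$endpoints, cell$h, q)) * sp^2
  expect_gte(integral, 0.98)
  expect_lte(integral, 1.02)
  # mode near the planted center, peak is the density maximum
  expect_lt(sqrt(sum(cell$mode^2)), 0.3)
  expect_gte(cell$peak, max(spacekit:::kde_eval(cell$endpoints, cell$h,
                                                cell$endpoints[1:200, ])))
  m2 <- fit_movement_model(tri, "p")
  expect_identical(m1$cells[["walking|1.0"]]$h, m2$cells[["walking|1.0"]]$h)
  expect_identical(m1$cells[["walking|1.0"]]$mode, m2$cells[["walking|1.0"]]$mode)
})

test_that("mean shift finds the heavier mode of a bimodal cloud", {
  ep <- with_test_seed(8, rbind(
    matrix(stats::rnorm(2 * 3000, 0, 0.8), ncol = 2) +
      matrix(c(3, 0), 3000, 2, byrow = TRUE),
    matrix(stats::rnorm(2 * 1500, 0, 0.8), ncol = 2) +
      matrix(c(-3, 0), 1500, 2, byrow = TRUE)))
  h <- spacekit:::scott_bandwidth(ep)
  mode <- spacekit:::mean_shift_mode(ep, h)
  # brute-force density argmax on a 1 cm grid around the components
  q <- as.matrix(expand.grid(seq(-5, 5, 0.01), seq(-1, 1, 0.05)))
  dens <- spacekit:::kde_eval(ep, h, q)
  argmax <- q[which.max(dens), ]
  expect_lt(sqrt(sum((mode - argmax)^2)), 0.3)
  expect_lt(sqrt(sum((mode - c(3, 0))^2)), 0.3)
})

test_that("player influence is a normalized density ratio in [0, 1]", {
  mm <- fx_model()
  st <- player_state("fx", "A", "FIELD", p_t = c(10, 5), p_tdelta = c(9.5, 5))
  mode_pos <- influence_mode(mm, st, 1.0)
  expect_equal(player_influence(mm, st, 1.0, mode_pos), 1.0, tolerance = 1e-12)
  # far beyond reach
  expect_lt(player_influence(mm, st, 0.2, c(10 + 60, 5)), 1e-6)
  # everywhere within [0, 1]
  g <- pitch_grid(4)
  vals <- player_influence(mm, st, 2.0, grid_matrix(g))
  expect_true(all(vals >= 0 & vals <= 1 + 1e-12))

  # duplicate-path oracle: independent transform + naive KDE ratio
  cell <- mm$cells[["jogging|1.0"]]
  st2 <- player_state("fx", "A", "FIELD", p_t = c(3, -2),
                      p_tdelta = c(3, -2) - 0.2 * c(2, 1.2)) # jogging speed
  expect_equal(as.character(velocity_bin(st2$speed_kmh)), "jogging")
  pts <- with_test_seed(12, cbind(stats::runif(100, -20, 20),
                                  stats::runif(100, -20, 20)))
  got <- player_influence(mm, st2, 1.0, pts)
  th <- st2$heading
  loc <- cbind(cos(th) * (pts[, 1] - 3) + sin(th) * (pts[, 2] + 2),
               -sin(th) * (pts[, 1] - 3) + cos(th) * (pts[, 2] + 2))
  want <- naive_kde(cell$endpoints, cell$h, loc) /
    naive_kde(cell$endpoints, cell$h, matrix(cell$mode, 1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("movement models respect reachability and monotone spread", {
  corp <- fx_corpus()
  tri <- corp$triplets
  smax <- corp$profile$max_speed
  q99 <- stats::aggregate(d ~ bin + Delta, tri, stats::quantile, 0.99)
  expect_true(all(q99$d <= 1.05 * smax * q99$Delta))
  for (b in levels(tri$bin)) {
    m <- stats::aggregate(d ~ Delta, tri[tri$bin == b, ], mean)
    m <- m[order(m$Delta), ]
    expect_true(all(diff(m$d) >= -0.05 * utils::head(m$d, -1)))
  }
})

test_that("rigid motions of the raw trajectories leave the model unchanged", {
  sim <- fx_match()
  tri1 <- extract_triplets(sim$tracking, "A3", stride = 5L)
  ang <- 0.7
  tr2 <- sim$tracking
  x <- tr2$x; y <- tr2$y
  tr2$x <- cos(ang) * x - sin(ang) * y + 2
  tr2$y <- sin(ang) * x + cos(ang) * y - 1
  # bypass bounds (rotation leaves the pitch); build triplets directly
  tri2 <- extract_triplets(structure(as.data.frame(tr2), fps = 25,
                                     class = c("tracking_sequence", "data.frame")),
                           "A3", stride = 5L)
  t1 <- transform_triplets(tri1)
  t2 <- transform_triplets(tri2)
  expect_equal(t2$xe, t1$xe, tolerance = 1e-9)
  expect_equal(t2$ye, t1$ye, tolerance = 1e-9)
  expect_equal(t2$speed_kmh, t1$speed_kmh, tolerance = 1e-9)
})

test_that("horizon snapping is nearest with ties upward", {
  expect_equal(snap_horizon(0.33), 0.4)
  expect_equal(snap_horizon(0.30), 0.4) # tie broken upward
  expect_equal(snap_horizon(7), 5.0)    # clipped
  expect_equal(snap_horizon(0.05), 0.2)
  expect_true(all(snap_horizon(runif(50, 0, 6)) %in% movement_horizons()))
})

test_that("movement models serialize and reload faithfully", {
  mm <- fx_model()
  f <- tempfile(fileext = ".json")
  write_movement_model(mm, f)
  m2 <- read_movement_model(f)
  st <- player_state("fx", "A", "FIELD", p_t = c(0, 0), p_tdelta = c(-0.4, 0))
  pts <- cbind(seq(-5, 20, 2), seq(-5, 20, 2))
  expect_equal(player_influence(m2, st, 1.4, pts),
               player_influence(mm, st, 1.4, pts), tolerance = 1e-12)
})

test_that("unavailable cells fall back to the nearest horizon in the bin", {
  corp <- fx_corpus()
  tri <- corp$triplets
  sub <- tri[abs(tri$Delta - 1.0) < 1e-9 | abs(tri$Delta - 0.2) < 1e-9, ]
  mm <- fit_movement_model(sub, "p", horizons = movement_horizons())
  st <- player_state("p", "A", "FIELD", p_t = c(0, 0), p_tdelta = c(-0.4, 0))
  expect_message(v <- player_influence(mm, st, 3.0, c(1, 1)), "nearest")
  expect_equal(v, player_influence(mm, st, 1.0, matrix(c(1, 1), 1)))
})
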