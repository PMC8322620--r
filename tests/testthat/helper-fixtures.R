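# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# small triplet corpus + movement model shared across tests
fx_corpus <- function() {
  fx_cache("corpus", simulate_triplet_corpus(kinematic_profile(), n = 600, seed = 11))
}

fx_model <- function() {
  fx_cache("model", fit_movement_model(fx_corpus()$triplets, "fx", min_count = 50))
}

# short synthetic match
fx_match <- function() {
  fx_cache("match", simulate_match(scenario_config(seed = 5, duration = 120)))
}

# pass-time model on planted pairs
fx_ptm <- function() {
  fx_cache("ptm", {
    d <- with_test_seed(99, stats::runif(600, 1, 60))
    pairs <- data.frame(d = d,
                        Delta = 0.5 + 0.045 * d +
                          with_test_seed(100, stats::rnorm(600, 0, 0.05)))
    fit_pass_time(pairs, split_seed = 1)
  })
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# independent 2-D Gaussian KDE, used as the duplicate-path oracle
naive_kde <- function(xy, h, q) {
  vapply(seq_len(nrow(q)), function(i) {
    mean(stats::dnorm(q[i, 1], xy[, 1], h[1]) *
           stats::dnorm(q[i, 2], xy[, 2], h[2]))
  }, numeric(1))
}

# quadrature of a fitted KDE cell over its endpoint bounding box
cell_integral <- function(cell, pad = 6, min_spacing = 0.02) {
  h <- cell$h
  e <- cell$endpoints
  sp <- max(min(h) / 2, min_spacing)
  xs <- seq(min(e[, 1]) - pad * h[1], max(e[, 1]) + pad * h[1], by = sp)
  ys <- seq(min(e[, 2]) - pad * h[2], max(e[, 2]) + pad * h[2], by = sp)
  q <- as.matrix(expand.grid(xs, ys))
  sum(spacekit:::kde_eval(e, h, q)) * sp^2
}

# hand-built five-player toy frame for loop oracles
toy_frame <- function() {
  game_frame(
    players = data.frame(
      player_id = c("a1", "a2", "a3", "b1", "b2"),
      team = c("A", "A", "A", "B", "B"),
      role = "FIELD",
      x = c(10, 20, 30, 25, 15),
      y = c(5, -8, 0, 6, -2),
      vx = c(2, 0, -1, 3, 0),
      vy = c(0, 1, 2, 0, -2),
      stringsAsFactors = FALSE
    ),
    ball = c(18, 0), t = 10
  )
}
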