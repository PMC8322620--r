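# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Row-wise distances from an n x 2 matrix to a single point.
dist_to_point <- function(xy, p) sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
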