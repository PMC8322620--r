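# Distance -> available-time regression: how long a player at distance d
# from the passer has to move before the ball can reach her, learned from
# completed passes (duration = reception time - initiation time).

#' Yeo-Johnson power transform
#'
#' @param x numeric vector.
#' @param lambda transform parameter.
#' @return Transformed values; lambda = 1 is (essentially) the identity shift.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  l2 <- 2 - lambda
  if (abs(l2) > 1e-12) {
    out[!pos] <- -((-x[!pos] + 1)^l2 - 1) / l2
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

#' Build the (distance, duration) pass dataset
#'
#' For every completed pass: d is the passer-receiver distance at the
#' initiation time (both read from tracking at the aligned frame) and the
#' response is the pass duration `t_receive - t`. Pairs longer than the
#' largest movement horizon are dropped (passes complete within 5 s); the
#' number dropped is recorded in the `dropped` attribute. Passes whose
#' receiver is untracked at initiation are skipped with a warning.
#'
#' @param events an `event_log` (aligned or alignable to `tracking`).
#' @param tracking a `tracking_sequence`.
#' @param max_Delta duration cap in seconds (default `max(movement_horizons())`).
#' @return data.frame with columns `d`, `Delta` and attribute `dropped`.
#' @export
build_pass_dataset <- function(events, tracking,
                               max_Delta = max(movement_horizons())) {
  if (!"frame_t" %in% names(events)) {
    events <- align_events(tracking, events)
  }
  passes <- events[events$type == "pass" & events$outcome == "complete", ]
  rows <- lapply(seq_len(nrow(passes)), function(i) {
    ev <- passes[i, ]
    fr <- tracking[abs(tracking$t - ev$frame_t) < 1e-6, ]
    pr <- fr[fr$agent_id == ev$player_id, ]
    rr <- fr[fr$agent_id == ev$receiver_id, ]
    if (nrow(pr) != 1 || nrow(rr) != 1) {
      warning(sprintf("pass %s skipped: passer or receiver untracked at t=%.2f",
                      ev$event_id, ev$t))
      return(NULL)
    }
    data.frame(d = euclid(c(pr$x, pr$y), c(rr$x, rr$y)),
               Delta = ev$t_receive - ev$t)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(d = numeric(0), Delta = numeric(0))
  keep <- d$Delta <= max_Delta
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Fit the pass-time regression
#'
#' A Yeo-Johnson power transform of the distance followed by a least-squares
#' line. The transform parameter lambda is chosen over a grid by mean squared
#' error on a held-out validation split (80% train / 20% validation, drawn
#' with `split_seed`). Only the predictor is transformed; the response stays
#' in seconds.
#'
#' @param pairs data.frame from [build_pass_dataset()] (columns `d`, `Delta`).
#' @param split_seed RNG seed for the train/validation split.
#' @param lambda_grid candidate Yeo-Johnson parameters.
#' @return A `pass_time_model`: `lambda`, `coef` (intercept, slope),
#'   `train_mse`, `val_mse`, `n`.
#' @export
fit_pass_time <- function(pairs, split_seed = 1,
                          lambda_grid = seq(-1, 2, by = 0.25)) {
  n <- nrow(pairs)
  if (n < 100) stop("fit error: need at least 100 pass pairs")
  if (stats::sd(pairs$d) < 1e-8) stop("fit error: degenerate distance variance")
  idx <- with_seed(split_seed, sample.int(n))
  ntr <- floor(0.8 * n)
  tr <- pairs[idx[seq_len(ntr)], ]
  va <- pairs[idx[(ntr + 1):n], ]
  best <- NULL
  for (lam in lambda_grid) {
    fit <- stats::lm(Delta ~ z, data = data.frame(z = yeo_johnson(tr$d, lam),
                                                  Delta = tr$Delta))
    pred <- stats::predict(fit, data.frame(z = yeo_johnson(va$d, lam)))
    mse <- mean((pred - va$Delta)^2)
    if (is.null(best) || mse < best$val_mse) {
      best <- list(lambda = lam, coef = unname(stats::coef(fit)),
                   train_mse = mean(stats::resid(fit)^2), val_mse = mse)
    }
  }
  if (best$coef[2] < 0) {
    warning("fitted pass-time slope is negative; predictions will not be monotone increasing")
  }
  structure(c(best, list(n = n)), class = "pass_time_model")
}

#' @export
print.pass_time_model <- function(x, ...) {
  cat(sprintf("<pass_time_model: lambda=%.2f, Delta = %.3f + %.4f * yj(d); val MSE %.4f (n=%d)>\n",
              x$lambda, x$coef[1], x$coef[2], x$val_mse, x$n))
  invisible(x)
}

#' Predict pass duration from distance
#'
#' @param model a `pass_time_model`.
#' @param d distance(s) in meters.
#' @param clip clip the raw prediction to the horizon range (default TRUE).
#' @return Predicted duration in seconds (continuous).
#' @export
predict_pass_time <- function(model, d, clip = TRUE) {
  out <- model$coef[1] + model$coef[2] * yeo_johnson(d, model$lambda)
  horizons <- movement_horizons()
  if (clip) out <- clamp(out, min(horizons), max(horizons))
  out
}

#' Predict the movement horizon for a distance
#'
#' The continuous prediction snapped to the horizon set (nearest element,
#' ties upward) and clipped to its range, so it can index a movement-model
#' cell directly.
#'
#' @param model a `pass_time_model`.
#' @param d distance(s) in meters.
#' @return Horizon(s) in the set returned by [movement_horizons()].
#' @export
predict_horizon <- function(model, d) {
  snap_horizon(predict_pass_time(model, d, clip = TRUE))
}
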