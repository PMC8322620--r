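# One interface for the two player-influence models so pitch control,
# defensive influence and space generation can swap between them.

#' Gaussian influence backend
#'
#' @param v_max maximum player speed in m/s used by the covariance scaling.
#' @return An `influence_backend`.
#' @export
gaussian_backend <- function(v_max = 13) {
  structure(list(kind = "gaussian", v_max = v_max),
            class = "influence_backend")
}

#' Data-driven influence backend
#'
#' @param models either a single `movement_model` (shared by all players) or
#'   a named list of movement models keyed by player id.
#' @param fallback backend used for players without a model (default the
#'   Gaussian backend); a message is emitted when it is used.
#' @return An `influence_backend`.
#' @export
datadriven_backend <- function(models, fallback = gaussian_backend()) {
  if (inherits(models, "movement_model")) models <- list(default = models)
  structure(list(kind = "datadriven", models = models, fallback = fallback),
            class = "influence_backend")
}

#' @export
print.influence_backend <- function(x, ...) {
  cat(sprintf("<influence_backend: %s>\n", x$kind))
  invisible(x)
}

#' Evaluate normalized player influence under a backend
#'
#' @param backend an `influence_backend`.
#' @param state a `player_state`.
#' @param points n x 2 matrix of pitch positions.
#' @param Delta time horizon in seconds (used by the data-driven backend).
#' @param ball length-2 ball position (used by the Gaussian backend's radius).
#' @return Influence values in \[0, 1\].
#' @export
influence_at <- function(backend, state, points, Delta, ball) {
  if (backend$kind == "gaussian") {
    return(gaussian_influence(gaussian_params(state, ball, backend$v_max),
                              points))
  }
  model <- backend$models[[as.character(state$player_id)]] %||%
    backend$models[["default"]]
  if (is.null(model)) {
    message(sprintf("no movement model for player %s; using fallback backend",
                    state$player_id))
    return(influence_at(backend$fallback, state, points, Delta, ball))
  }
  player_influence(model, state, Delta, points)
}
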