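#' Pitch geometry
#'
#' Standard pitch of 105 x 68 m centered at the origin, so x spans
#' \[-52.5, 52.5\] and y spans \[-34, 34\]. Goal centers sit on the x-axis at
#' x = +-52.5. All coordinates in this package are meters in this frame; by
#' convention the team under analysis attacks toward +x.
#'
#' @param length pitch length in meters along x.
#' @param width pitch width in meters along y.
#' @return An object of class `pitch` with fields `length`, `width`,
#'   `xlim`, `ylim`, `goal_center_home` (+x goal), `goal_center_away`
#'   (-x goal) and the four `corners`.
#' @export
#' @examples
#' p <- pitch()
#' p$xlim
pitch <- function(length = 105, width = 68) {
  stopifnot(length > 0, width > 0)
  hx <- length / 2
  hy <- width / 2
  structure(list(
    length = length, width = width,
    xlim = c(-hx, hx), ylim = c(-hy, hy),
    goal_center_home = c(x = hx, y = 0),
    goal_center_away = c(x = -hx, y = 0),
    corners = rbind(
      c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy)
    )
  ), class = "pitch")
}

#' @export
print.pitch <- function(x, ...) {
  cat(sprintf("<pitch %g x %g m, origin at center>\n", x$length, x$width))
  invisible(x)
}

in_pitch <- function(x, y, p = pitch(), tol = 1e-9) {
  x >= p$xlim[1] - tol & x <= p$xlim[2] + tol &
    y >= p$ylim[1] - tol & y <= p$ylim[2] + tol
}

#' Regular evaluation grid over the pitch
#'
#' Nodes are placed at cell centers of a regular lattice with the given
#' spacing, so every node lies strictly inside the pitch. Node order is
#' row-major and deterministic: y increases slowest, x fastest, starting at
#' the lower-left corner (most negative x and y).
#'
#' @param spacing node spacing in meters (default 0.5, the grid used for the
#'   possession features and space generation).
#' @param p a [pitch()].
#' @return An object of class `pitch_grid`: a data.frame with columns `x`,
#'   `y`, plus attributes `spacing`, `nx`, `ny`, `pitch`.
#' @export
#' @examples
#' g <- pitch_grid(1)
#' nrow(g)  # 105 * 68 nodes
pitch_grid <- function(spacing = 0.5, p = pitch()) {
  stopifnot(spacing > 0)
  xs <- seq(p$xlim[1] + spacing / 2, p$xlim[2] - spacing / 2, by = spacing)
  ys <- seq(p$ylim[1] + spacing / 2, p$ylim[2] - spacing / 2, by = spacing)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(g,
    spacing = spacing, nx = length(xs), ny = length(ys), pitch = p,
    class = c("pitch_grid", "data.frame")
  )
}

#' Evenly spaced n_x-by-n_y grid over the pitch (bounds inclusive)
#'
#' The coarse lattice used as feature locations when training the defensive
#' influence network; the default 21 x 16 keeps that regression tractable.
#'
#' @param nx,ny node counts along x and y.
#' @param p a [pitch()].
#' @return A `pitch_grid` (spacing attribute holds the x step).
#' @export
pitch_grid_dims <- function(nx = 21, ny = 16, p = pitch()) {
  stopifnot(nx >= 2, ny >= 2)
  xs <- seq(p$xlim[1], p$xlim[2], length.out = nx)
  ys <- seq(p$ylim[1], p$ylim[2], length.out = ny)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(g,
    spacing = diff(xs[1:2]), nx = nx, ny = ny, pitch = p,
    class = c("pitch_grid", "data.frame")
  )
}

grid_matrix <- function(grid) cbind(grid$x, grid$y)

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

#' Scalar field on a pitch grid
#'
#' Container for the gridded surfaces (player influence, pitch control,
#' defensive influence, pitch value, space quality). Values are stored in
#' grid node order.
#'
#' @param grid a `pitch_grid`.
#' @param values numeric vector, one value per grid node.
#' @param what short label ("PI", "PC", "DI", "PV", "SQ", ...).
#' @param t frame time in seconds (optional).
#' @param meta named list of extra metadata (ball position, backend, ...).
#' @return An object of class `pitch_field`.
#' @export
pitch_field <- function(grid, values, what = "field", t = NA_real_, meta = list()) {
  stopifnot(inherits(grid, "pitch_grid"), length(values) == nrow(grid))
  structure(list(grid = grid, values = as.numeric(values), what = what,
                 t = t, meta = meta),
            class = "pitch_field")
}

#' @export
print.pitch_field <- function(x, ...) {
  cat(sprintf("<pitch_field '%s': %d x %d nodes, range [%.4g, %.4g]>\n",
              x$what, attr(x$grid, "nx"), attr(x$grid, "ny"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.pitch_field <- function(x, ...) {
  matrix(x$values, nrow = attr(x$grid, "nx"), ncol = attr(x$grid, "ny"))
}

#' Heatmap of a pitch field
#'
#' @param x a `pitch_field`.
#' @param ... passed to [graphics::image()].
#' @export
plot.pitch_field <- function(x, ...) {
  nx <- attr(x$grid, "nx"); ny <- attr(x$grid, "ny")
  xs <- sort(unique(x$grid$x)); ys <- sort(unique(x$grid$y))
  graphics::image(xs, ys, matrix(x$values, nx, ny),
                  xlab = "x [m]", ylab = "y [m]", main = x$what,
                  asp = 1, ...)
  invisible(x)
}
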