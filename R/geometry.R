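#' Rectangular arena
#'
#' Construct the rectangular enclosure in which agents roam. The coordinate
#' origin sits at the centre of the rectangle, with x along the long (width)
#' side and y along the short (height) side. Walls are identified by compass
#' labels: "E" at x = width/2, "N" at y = height/2, "W" at x = -width/2 and
#' "S" at y = -height/2.
#'
#' @param width Extent along x in metres (default 11.4).
#' @param height Extent along y in metres (default 6.7).
#' @return An object of class `ped_arena` with fields `width`, `height`,
#'   `walls` (the fixed wall order used for tie-breaking) and `area`.
#' @examples
#' a <- arena()
#' a$area  # 76.38 m^2
#' @export
arena <- function(width = 11.4, height = 6.7) {
  stopifnot(is.numeric(width), is.numeric(height),
            length(width) == 1L, length(height) == 1L)
  if (!(width > 0) || !(height > 0)) {
    stop("arena dimensions must be strictly positive")
  }
  structure(
    list(width = width, height = height,
         walls = c("E", "N", "W", "S"),
         area = width * height),
    class = "ped_arena"
  )
}

#' @export
print.ped_arena <- function(x, ...) {
  cat(sprintf("<ped_arena> %.2f m x %.2f m (area %.2f m^2), walls %s\n",
              x$width, x$height, x$area, paste(x$walls, collapse = " ")))
  invisible(x)
}

# Inward unit normals, one row per wall in the order E, N, W, S.
wall_normals <- function() {
  matrix(c(-1, 0,
            0, -1,
            1, 0,
            0, 1),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("E", "N", "W", "S"), c("x", "y")))
}

# Tangents of counterclockwise boundary traversal: the inward normal rotated
# by -90 degrees, (nx, ny) -> (ny, -nx).
wall_tangents <- function() {
  n <- wall_normals()
  cbind(x = n[, "y"], y = -n[, "x"])
}

# Perpendicular distance from (x, y) to each of the four walls (E, N, W, S).
wall_distances <- function(x, y, arena) {
  c(E = arena$width / 2 - x,
    N = arena$height / 2 - y,
    W = x + arena$width / 2,
    S = y + arena$height / 2)
}

#' Wall frames at a position
#'
#' For a point strictly inside the arena, return one frame per wall carrying
#' the perpendicular distance `r_iw`, the unit inward normal `n_hat` and the
#' unit tangents `t_plus` / `t_minus`. `t_plus` is the inward normal rotated
#' by -90 degrees; following it along any wall traverses the boundary
#' counterclockwise, so it is the tangent a CCW-preferring agent is pushed
#' along. Frames are sorted by distance, ties broken by the fixed wall order
#' E, N, W, S.
#'
#' @param position Numeric length-2 position in metres.
#' @param arena A [arena()] object.
#' @return A list of four frames, each a list with `wall_id`, `r_iw`,
#'   `n_hat`, `t_plus`, `t_minus`, sorted by `r_iw` ascending.
#' @examples
#' f <- wall_frames(c(5, 0), arena())
#' f[[1]]$wall_id  # "E"
#' f[[1]]$r_iw     # 0.7
#' @export
wall_frames <- function(position, arena) {
  stopifnot(is.numeric(position), length(position) == 2L,
            inherits(arena, "ped_arena"))
  d <- wall_distances(position[1], position[2], arena)
  if (any(d <= 0)) {
    stop(sprintf(
      "position (%.4g, %.4g) is outside or on the arena boundary (escaped agent?)",
      position[1], position[2]))
  }
  n <- wall_normals()
  tp <- wall_tangents()
  # stable order: ties keep the E, N, W, S listing
  ord <- order(d)
  lapply(ord, function(k) {
    list(wall_id = names(d)[k],
         r_iw = unname(d[k]),
         n_hat = unname(n[k, ]),
         t_plus = unname(tp[k, ]),
         t_minus = -unname(tp[k, ]))
  })
}

#' Reflect a state about the x-axis
#'
#' Mirror utility for symmetry tests: negates all y coordinates and y
#' velocity components and flips every chirality label (+1 becomes -1).
#' Applying it twice is the identity. A purely counterclockwise-rotating
#' configuration maps to the clockwise mirror image with the angular momentum
#' negated.
#'
#' @param positions N x 2 matrix of positions.
#' @param velocities N x 2 matrix of velocities.
#' @param chiralities Integer vector of +1 / -1 labels, or `NULL` / `NA`s for
#'   runs without turning preference.
#' @return A list with the reflected `positions`, `velocities`, `chiralities`.
#' @export
mirror_state <- function(positions, velocities, chiralities = NULL) {
  positions <- as_xy_matrix(positions)
  velocities <- as_xy_matrix(velocities)
  p <- positions; p[, 2] <- -p[, 2]
  v <- velocities; v[, 2] <- -v[, 2]
  ch <- chiralities
  if (!is.null(ch)) ch <- -ch
  list(positions = p, velocities = v, chiralities = ch)
}

# Coerce a length-2 vector or an N x 2 matrix-like to an N x 2 matrix.
as_xy_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) %% 2L == 0L)
    x <- matrix(x, ncol = 2, byrow = TRUE)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L)
  storage.mode(x) <- "double"
  x
}

# TRUE for rows strictly inside the arena.
inside_arena <- function(positions, arena) {
  p <- as_xy_matrix(positions)
  abs(p[, 1]) < arena$width / 2 & abs(p[, 2]) < arena$height / 2
}
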