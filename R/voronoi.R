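#' Voronoi areas clipped to the arena
#'
#' Area of each agent's Voronoi cell, intersected with the arena rectangle.
#' Each cell is built directly as an intersection of half-planes: starting
#' from the rectangle, the polygon is clipped against the perpendicular
#' bisector of every other agent (keeping the side nearer to the focal
#' agent). This is exact for a rectangular domain and needs no unbounded-cell
#' handling. The areas always partition the arena: they sum to
#' `width * height` up to clipping round-off.
#'
#' The distribution of these areas quantifies how homogeneously a crowd
#' occupies space; it is the statistic used to calibrate the social
#' repulsion amplitude and decay length.
#'
#' @param positions N x 2 agent positions, strictly inside the arena.
#' @param arena An [arena()].
#' @return Numeric vector of N cell areas, m^2.
#' @examples
#' voronoi_areas(rbind(c(-1, 0), c(1, 0)), arena())  # 38.19 each
#' @export
voronoi_areas <- function(positions, arena = pedvortex::arena()) {
  p <- as_xy_matrix(positions)
  n <- nrow(p)
  stopifnot(n >= 1L)
  if (!all(inside_arena(p, arena))) stop("all positions must lie inside the arena")
  if (n > 1L && any(stats::dist(p) == 0)) {
    stop("duplicate positions: Voronoi cells undefined")
  }
  hw <- arena$width / 2
  hh <- arena$height / 2
  rect <- list(x = c(-hw, hw, hw, -hw), y = c(-hh, -hh, hh, hh))
  vapply(seq_len(n), function(i) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i) next
      # half-plane of points nearer to i than j:  a . q <= b
      a <- p[j, ] - p[i, ]
      b <- sum(a * (p[i, ] + p[j, ]) / 2)
      poly <- clip_halfplane(poly, a, b)
      if (length(poly$x) == 0L) break
    }
    polygon_area(poly)
  }, numeric(1))
}

# Sutherland-Hodgman clip of polygon `poly` against {q : a . q <= b}.
clip_halfplane <- function(poly, a, b) {
  nx <- poly$x; ny <- poly$y
  m <- length(nx)
  if (m == 0L) return(poly)
  ox <- numeric(0); oy <- numeric(0)
  s <- a[1] * nx + a[2] * ny - b   # signed violation at each vertex
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    in1 <- s[k] <= 0; in2 <- s[k2] <= 0
    if (in1) { ox <- c(ox, nx[k]); oy <- c(oy, ny[k]) }
    if (xor(in1, in2)) {
      tt <- s[k] / (s[k] - s[k2])
      ox <- c(ox, nx[k] + tt * (nx[k2] - nx[k]))
      oy <- c(oy, ny[k] + tt * (ny[k2] - ny[k]))
    }
  }
  list(x = ox, y = oy)
}

# Shoelace area of a simple polygon (vertices in order).
polygon_area <- function(poly) {
  m <- length(poly$x)
  if (m < 3L) return(0)
  x <- poly$x; y <- poly$y
  j <- c(m, seq_len(m - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
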