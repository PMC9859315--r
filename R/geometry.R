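# Planar geometry helpers for simple (non-self-intersecting) polygons given as
# n x 2 coordinate matrices (metres, open rings: first vertex not repeated).
# All layers are required to be in a projected CRS, so plain Euclidean
# formulas apply throughout.

#' Area of a simple planar polygon
#'
#' Shoelace formula; returns the absolute area regardless of ring
#' orientation.
#'
#' @param ring numeric matrix with two columns (x, y), one row per vertex,
#'   open ring (last vertex differs from the first).
#' @return Area in square units of the coordinates (m^2 for metre input).
#' @keywords internal
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Centroid of a simple planar polygon
#'
#' Area-weighted centroid (centre of mass of the lamina), not the vertex
#' mean. Degenerate (zero-area) rings fall back to the vertex mean.
#'
#' @inheritParams polygon_area
#' @return Length-2 numeric vector (x, y).
#' @keywords internal
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) {
    return(c(mean(x), mean(y)))
  }
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  c(cx, cy)
}

#' Point-in-polygon test (ray casting)
#'
#' Boundary points count as inside (within a small tolerance of an edge).
#'
#' @param pt length-2 numeric (x, y).
#' @inheritParams polygon_area
#' @keywords internal
point_in_polygon <- function(pt, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  px <- pt[1]; py <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # boundary check on segment (j, i)
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x[j]) * dx + (py - y[j]) * dy) / len2
      t <- min(1, max(0, t))
      qx <- x[j] + t * dx; qy <- y[j] + t * dy
      if ((px - qx)^2 + (py - qy)^2 < 1e-12) return(TRUE)
    }
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[j] + (py - y[j]) * (x[i] - x[j]) / (y[i] - y[j])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Orientation of the ordered triple (p, q, r): >0 counter-clockwise,
# <0 clockwise, 0 collinear.
.orient <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

# Proper or improper intersection of closed segments [a1,a2] and [b1,b2].
.segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- .orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- .orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- .orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- .orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) { # r collinear with [p,q]: does r lie on it?
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  (d1 == 0 && on_seg(b1, b2, a1)) || (d2 == 0 && on_seg(b1, b2, a2)) ||
    (d3 == 0 && on_seg(a1, a2, b1)) || (d4 == 0 && on_seg(a1, a2, b2))
}

#' Detect self-intersection of a polygon ring
#'
#' Tests every pair of non-adjacent edges; O(n^2), fine for the small rings
#' this pipeline handles.
#'
#' @inheritParams polygon_area
#' @return TRUE when any two non-adjacent edges cross or touch.
#' @keywords internal
polygon_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE) # a triangle cannot self-intersect
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (k in seq.int(i + 2L, n)) {
      # skip adjacent edges (sharing a vertex), incl. the wrap-around pair
      if (k == i || nxt[k] == i || nxt[i] == k) next
      if (.segments_intersect(ring[i, ], ring[nxt[i], ],
                              ring[k, ], ring[nxt[k], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Representative interior point of a polygon
#'
#' The centroid when it falls inside the ring (always the case for the
#' convex rectangles the generator emits); otherwise the midpoint of the
#' widest interior run of a horizontal scanline through the ring's
#' vertical midpoint.
#'
#' @inheritParams polygon_area
#' @keywords internal
representative_point <- function(ring) {
  ctr <- polygon_centroid(ring)
  if (point_in_polygon(ctr, ring)) return(ctr)
  ymid <- (min(ring[, 2]) + max(ring[, 2])) / 2
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  xs <- numeric(0)
  for (i in seq_len(n)) {
    y1 <- y[j[i]]; y2 <- y[i]
    if ((y1 > ymid) != (y2 > ymid)) {
      xs <- c(xs, x[j[i]] + (ymid - y1) * (x[i] - x[j[i]]) / (y2 - y1))
    }
  }
  xs <- sort(xs)
  if (length(xs) < 2) return(ctr)
  runs <- matrix(xs[seq_len(length(xs) - length(xs) %% 2)], ncol = 2, byrow = TRUE)
  widths <- runs[, 2] - runs[, 1]
  k <- which.max(widths)
  c(mean(runs[k, ]), ymid)
}

# axis-aligned rectangle ring from bounds
.rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
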