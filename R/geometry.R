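#' Planar geometry helpers
#'
#' Small planar-geometry primitives used throughout the package. All
#' coordinates are projected meters; no geographic (lon/lat) support.
#'
#' @name geometry
#' @keywords internal
NULL

#' Signed polygon area (shoelace formula)
#'
#' @param x,y numeric vectors of ring vertices (the ring need not repeat its
#'   first vertex).
#' @return Signed area in squared input units; positive for counter-clockwise
#'   rings.
#' @keywords internal
ring_area_signed <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Even-odd point-in-rings test, boundary inclusive
#'
#' Classifies points against a set of rings using the even-odd (crossing
#' parity) rule, so holes nested inside outer rings are handled without
#' orientation bookkeeping. Points lying exactly on a ring edge count as
#' inside.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param rings list of two-column matrices (x, y), one per ring.
#' @return logical vector, one element per point.
#' @keywords internal
points_in_rings <- function(px, py, rings) {
  np <- length(px)
  inside <- logical(np)
  on_edge <- logical(np)
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    # drop duplicated closing vertex if present
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]; n <- n - 1L
    }
    if (n < 3) next
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      x1 <- x[j[k]]; y1 <- y[j[k]]; x2 <- x[k]; y2 <- y[k]
      # boundary test: point on segment (within numerical tolerance)
      dx <- x2 - x1; dy <- y2 - y1
      seg2 <- dx * dx + dy * dy
      if (seg2 > 0) {
        t <- ((px - x1) * dx + (py - y1) * dy) / seg2
        t <- pmin(1, pmax(0, t))
        qx <- x1 + t * dx; qy <- y1 + t * dy
        d2 <- (px - qx)^2 + (py - qy)^2
        on_edge <- on_edge | d2 <= (1e-9 * (1 + seg2))
      }
      # ray casting: horizontal ray to +x
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
    }
  }
  inside | on_edge
}

#' Total area of a ring set under the even-odd rule
#'
#' Rings nested inside an odd number of other rings are holes and their area
#' is subtracted.
#'
#' @param rings list of two-column matrices.
#' @return Non-negative area in squared input units.
#' @keywords internal
rings_area <- function(rings) {
  nr <- length(rings)
  if (nr == 0) return(0)
  areas <- vapply(rings, function(r) abs(ring_area_signed(r[, 1], r[, 2])),
                  numeric(1))
  depth <- integer(nr)
  if (nr > 1) {
    for (i in seq_len(nr)) {
      p <- rings[[i]][1, ]
      for (j in seq_len(nr)) {
        if (i == j) next
        if (points_in_rings(p[1], p[2], rings[j])) depth[i] <- depth[i] + 1L
      }
    }
  }
  sum(areas * ifelse(depth %% 2 == 0, 1, -1))
}

#' Convex hull area of a point set
#'
#' @param x,y coordinates.
#' @return list with `area` (squared input units) and `degenerate` flag
#'   (fewer than 3 distinct non-collinear points).
#' @keywords internal
convex_hull_area <- function(x, y) {
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(list(area = 0, degenerate = TRUE))
  h <- grDevices::chull(x, y)
  a <- abs(ring_area_signed(x[h], y[h]))
  list(area = a, degenerate = a <= 0)
}
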