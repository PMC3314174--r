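#' Closed sub-pixel contour
#'
#' An ordered, closed polygon of sub-pixel vertices tracing one nucleus
#' boundary. Vertices are stored as an n x 2 matrix of (x, y) coordinates
#' (column, row; 0-based pixel centers). Orientation is normalized to
#' counter-clockwise, i.e. positive shoelace area.
#'
#' @param vertices Numeric n x 2 matrix (or data frame) of (x, y) vertices,
#'   n >= 3, without a repeated closing vertex.
#' @param ccw Enforce counter-clockwise orientation (default TRUE).
#' @return An object of class `contour`: the vertex matrix with attributes.
#' @export
contour <- function(vertices, ccw = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must have two columns (x, y)")
  if (nrow(v) < 3L) stop("a contour needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertices must be finite")
  colnames(v) <- c("x", "y")
  if (ccw && polygon_signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  structure(v, class = c("contour", "matrix"))
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, area %.1f px^2, perimeter %.1f px\n",
              nrow(x), polygon_area(x), polygon_perimeter(x)))
  invisible(x)
}

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#' @param v An n x 2 vertex matrix or [contour].
#' @return Absolute enclosed area in square pixels.
#' @export
polygon_area <- function(v) abs(polygon_signed_area(as.matrix(v)))

#' Polygon perimeter (closed arc length)
#' @param v An n x 2 vertex matrix or [contour].
#' @return Perimeter in pixels.
#' @export
polygon_perimeter <- function(v) {
  v <- as.matrix(v)
  d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
  sum(d)
}

# Area centroid of a simple polygon (shoelace centroid); falls back to the
# vertex mean for (near-)degenerate polygons.
polygon_centroid <- function(v) {
  v <- as.matrix(v)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Exact second-order central moments of the region enclosed by a simple
# polygon (Green's theorem). Returns list(area, mu20, mu02, mu11) with the
# moments normalized by area (i.e. the covariance of the uniform measure on
# the region).
polygon_moments <- function(v) {
  v <- as.matrix(v)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(list(area = 0, mu20 = NA_real_, mu02 = NA_real_, mu11 = NA_real_))
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw second moments about the origin
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12      # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12      # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  s <- sign(a)
  list(area = abs(a),
       mu20 = s * iyy / a - cx^2,   # var of x
       mu02 = s * ixx / a - cy^2,   # var of y
       mu11 = s * ixy / a - cx * cy)
}

# Convex hull of a vertex set as a CCW polygon.
convex_hull_polygon <- function(v) {
  v <- as.matrix(v)
  idx <- grDevices::chull(v[, 1], v[, 2])
  contour(v[idx, , drop = FALSE])
}

# Vectorized point-in-polygon (boundary counts as inside).
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
}

# Project points onto the boundary of a polygon: for each point, the nearest
# point over all edges. Returns an n x 2 matrix.
project_onto_polygon <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best <- pts
  m <- nrow(poly)
  for (e in seq_len(m)) {
    a <- poly[e, ]; b <- poly[if (e == m) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
    sel <- d2 < best_d2
    best_d2[sel] <- d2[sel]
    best[sel, 1] <- qx[sel]; best[sel, 2] <- qy[sel]
  }
  best
}

#' Test a polygon for self-intersection
#'
#' Brute-force segment pair test; intended for validation, not for hot paths.
#'
#' @param v An n x 2 vertex matrix or [contour].
#' @return TRUE if no two non-adjacent edges intersect.
#' @export
is_simple_polygon <- function(v) {
  v <- as.matrix(v)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  a1 <- v; a2 <- v[nxt, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (shared vertex)
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (length(js) == 0L) next
    if (any(segments_intersect(a1[i, ], a2[i, ], a1[js, , drop = FALSE], a2[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(p2 - p1, t(t(q1) - p1))
  d2 <- cross2(p2 - p1, t(t(q2) - p1))
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

cross2 <- function(ab, pts) ab[1] * pts[, 2] - ab[2] * pts[, 1]

# Cumulative arc length from vertex 1 (0 at the first vertex), including the
# closing segment as the final entry; length n + 1.
cumulative_arc <- function(v) {
  v <- as.matrix(v)
  d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
  c(0, cumsum(d))
}
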