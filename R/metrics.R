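#' Signed boundary curvature by circle fitting
#'
#' For each vertex i, fits the circle through vertices `i - offset`, `i`, and
#' `i + offset` (cyclic indexing) and takes curvature as the reciprocal of its
#' radius. Convex (left-turning, for a counter-clockwise contour) points are
#' positive; concave points negative; collinear triples give curvature 0.
#'
#' @param c A [contour] with more than `2 * offset` vertices, normally at the
#'   final uniform spacing of 0.5 px.
#' @param offset Index offset of the flanking points (default 25).
#' @return A `curvature_profile`: numeric vector of signed curvatures
#'   (1/pixel), one per vertex, with attribute `offset`.
#' @export
signed_curvature <- function(c, offset = 25L) {
  v <- as.matrix(c)
  n <- nrow(v)
  offset <- as.integer(offset)
  if (n <= 2L * offset)
    stop(sprintf("contour has %d vertices; curvature with offset %d needs at least %d",
                 n, offset, 2L * offset + 1L))
  idx <- seq_len(n)
  im <- ((idx - 1L - offset) %% n) + 1L
  ip <- ((idx - 1L + offset) %% n) + 1L
  ax <- v[idx, 1] - v[im, 1]; ay <- v[idx, 2] - v[im, 2]
  bx <- v[ip, 1] - v[idx, 1]; by <- v[ip, 2] - v[idx, 2]
  cx <- v[ip, 1] - v[im, 1]; cy <- v[ip, 2] - v[im, 2]
  cross <- ax * by - ay * bx
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2); lc <- sqrt(cx^2 + cy^2)
  # circumradius R = |a||b||c| / (4 * triangle area) = |a||b||c| / (2 |cross|)
  denom <- la * lb * lc
  kappa <- ifelse(denom > 0, 2 * cross / denom, 0)
  structure(kappa, offset = offset, class = "curvature_profile")
}

#' Rotate contour and curvature profile to the canonical start
#'
#' Cyclically rotates both so that index 0 (the first element) is the vertex
#' farthest from the polygon centroid; ties broken by the lowest original
#' index. Used to align curvature profiles before heat-map assembly.
#'
#' @param c A [contour].
#' @param prof The matching curvature profile (optional).
#' @return `list(contour, profile)` rotated consistently.
#' @export
rotate_to_start <- function(c, prof = NULL) {
  v <- as.matrix(c)
  if (!is.null(prof) && length(prof) != nrow(v))
    stop("profile length must match contour vertex count")
  ctr <- polygon_centroid(v)
  d2 <- (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2
  i0 <- which.max(d2)  # first maximum = lowest-index tie-break
  ord <- c(i0:nrow(v), seq_len(i0 - 1L))
  out_c <- contour(v[ord, , drop = FALSE], ccw = FALSE)
  out_p <- if (is.null(prof)) NULL else {
    structure(as.numeric(prof)[ord], offset = attr(prof, "offset"),
              class = "curvature_profile")
  }
  list(contour = out_c, profile = out_p)
}

#' Mean negative curvature (MNC)
#'
#' The blebbing statistic: the absolute value of the mean of all negative
#' (concave) curvatures on the boundary, positive curvatures excluded
#' entirely. A fully convex boundary has MNC 0.
#'
#' @param prof A curvature profile from [signed_curvature()].
#' @return MNC in 1/pixel (non-negative scalar).
#' @export
mean_negative_curvature <- function(prof) {
  k <- as.numeric(prof)
  neg <- k[k < 0]
  if (length(neg) == 0) return(0)
  abs(mean(neg))
}

#' Count boundary invaginations
#'
#' The number of maximal cyclic runs of strictly negative curvature,
#' uninterrupted by positive (or zero) curvature. A run wrapping the profile
#' end counts once.
#'
#' @param prof A curvature profile.
#' @return Non-negative integer run count.
#' @export
count_invaginations <- function(prof) {
  neg <- as.numeric(prof) < 0
  n <- length(neg)
  if (n == 0 || !any(neg)) return(0L)
  if (all(neg)) return(1L)
  starts <- neg & !neg[c(n, seq_len(n - 1))]
  sum(starts)
}

#' Moment-equivalent ellipse eccentricity
#'
#' Eccentricity of the ellipse sharing the second-order central moments of
#' the enclosed region, computed by exact polygon moment integrals:
#' `sqrt(1 - (minor/major)^2)`. A circle scores 0 and a line segment 1. For a
#' degenerate (zero-area) contour the moments of the vertex point set are
#' used instead, which yields exactly 1 for collinear points.
#'
#' @param c A [contour] or n x 2 vertex matrix.
#' @return Eccentricity in `[0, 1]`.
#' @export
eccentricity <- function(c) {
  v <- as.matrix(c)
  mom <- polygon_moments(v)
  if (mom$area < 1e-9) {
    warning("degenerate contour; using point-set moments for eccentricity")
    cv <- stats::cov.wt(v, method = "ML")$cov
    mom <- list(mu20 = cv[1, 1], mu02 = cv[2, 2], mu11 = cv[1, 2])
  }
  eig <- moment_ellipse_axes(mom$mu20, mom$mu02, mom$mu11)
  if (eig$major <= 0) return(1)
  sqrt(max(0, 1 - eig$minor / eig$major))
}

# Eigenvalues of the 2x2 second-moment matrix: squared semi-axis scales of
# the moment-equivalent ellipse (up to a common factor).
moment_ellipse_axes <- function(mu20, mu02, mu11) {
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  list(major = tr / 2 + disc, minor = max(0, tr / 2 - disc))
}

#' Per-nucleus shape and intensity metrics
#'
#' Assembles the full measurement panel for one nucleus: MNC and negative
#' curvature spread, invagination count, area (shoelace), perimeter,
#' equivalent diameter, convex-hull area and perimeter, solidity
#' (area / hull area), tortuosity (perimeter / hull perimeter), eccentricity,
#' curvature extremes, and lamin fluorescence intensity statistics over the
#' enclosed pixels.
#'
#' @param c A [contour].
#' @param prof Matching curvature profile (computed if NULL).
#' @param img Optional [gray_image] for intensity statistics; if NULL or if
#'   the contour leaves the image, intensity fields are NA.
#' @param offset Curvature offset used when `prof` is NULL.
#' @param pixel_size Physical pixel size; lengths scale by it, areas by its
#'   square, curvatures by its inverse (default 1 = pixel units).
#' @return One-row data frame of class `nucleus_metrics`.
#' @export
metric_table <- function(c, prof = NULL, img = NULL, offset = 25L, pixel_size = 1) {
  v <- as.matrix(c)
  if (is.null(prof)) prof <- signed_curvature(c, offset)
  k <- as.numeric(prof)
  neg <- k[k < 0]; pos <- k[k > 0]
  area <- polygon_area(v)
  perim <- polygon_perimeter(v)
  hull <- convex_hull_polygon(v)
  hull_area <- polygon_area(hull)
  hull_perim <- polygon_perimeter(hull)

  int_mean <- NA_real_; int_sd <- NA_real_
  if (!is.null(img)) {
    img <- as_gray_image(img)
    if (min(v[, 1]) < -0.5 || min(v[, 2]) < -0.5 ||
        max(v[, 1]) > img$width - 0.5 || max(v[, 2]) > img$height - 0.5) {
      warning("contour outside image bounds; intensity statistics set to NA")
    } else {
      vals <- pixels_inside(img, v)
      if (length(vals) > 0) { int_mean <- mean(vals); int_sd <- sd_or_zero(vals) }
    }
  }

  ps <- pixel_size
  out <- data.frame(
    mnc = mean_negative_curvature(prof) / ps,
    neg_curv_std = if (length(neg) >= 2) stats::sd(neg) / ps else 0,
    max_neg_curv = if (length(neg) > 0) max(abs(neg)) / ps else 0,
    mean_pos_curv = if (length(pos) > 0) mean(pos) / ps else 0,
    invaginations = count_invaginations(prof),
    area = area * ps^2,
    perimeter = perim * ps,
    equiv_diameter = 2 * sqrt(area / pi) * ps,
    hull_area = hull_area * ps^2,
    hull_perimeter = hull_perim * ps,
    solidity = area / hull_area,
    tortuosity = perim / hull_perim,
    eccentricity = eccentricity(c),
    intensity_mean = int_mean,
    intensity_std = int_sd)
  class(out) <- c("nucleus_metrics", "data.frame")
  out
}

sd_or_zero <- function(x) if (length(x) >= 2) stats::sd(x) else 0

# Intensities of the pixels whose centers fall inside the polygon.
pixels_inside <- function(img, v) {
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(img$width - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(img$height - 1L, ceiling(max(v[, 2])))
  if (x1 < x0 || y1 < y0) return(numeric(0))
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- points_in_polygon(gx, gy, v)
  sub <- img$pixels[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  as.numeric(sub)[inside]
}

#' Metric names of the standard 15-measure panel
#' @return Character vector of the metric columns produced by [metric_table()].
#' @export
metric_panel <- function() {
  c("mnc", "neg_curv_std", "max_neg_curv", "mean_pos_curv", "invaginations",
    "area", "perimeter", "equiv_diameter", "hull_area", "hull_perimeter",
    "solidity", "tortuosity", "eccentricity", "intensity_mean", "intensity_std")
}
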