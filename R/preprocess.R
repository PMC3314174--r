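#' Contrast-limited adaptive histogram equalization (Rayleigh target)
#'
#' Per-tile histogram equalization with a clipped histogram and a Rayleigh
#' target distribution, blended bilinearly between neighboring tile mappings.
#' This is the first step of boundary extraction: it evens out staining and
#' illumination variability between and within frames before thresholding.
#'
#' @param img A [gray_image] (or plain matrix, assumed 16-bit).
#' @param tile_grid Integer pair: number of tile columns and rows (default
#'   `c(8, 8)`).
#' @param clip_limit Histogram clip limit as a fraction of tile pixel count
#'   (default 0.02); the clipped excess is redistributed uniformly.
#' @param rayleigh_alpha Shape parameter of the Rayleigh target (default 0.4).
#' @param n_bins Number of histogram bins (default 256).
#' @return A [gray_image] spanning the full representable range.
#' @export
equalize_adaptive <- function(img, tile_grid = c(8L, 8L), clip_limit = 0.02,
                              rayleigh_alpha = 0.4, n_bins = 256L) {
  img <- as_gray_image(img)
  gx <- as.integer(tile_grid[1]); gy <- as.integer(tile_grid[2])
  if (img$width < gx || img$height < gy)
    stop(sprintf("image (%d x %d) smaller than the tile grid; needs at least %d x %d pixels",
                 img$width, img$height, gx, gy))
  mx <- max_intensity(img)
  px <- img$pixels
  if (max(px) == min(px)) return(img)  # no contrast to redistribute

  # tile boundaries (last tile absorbs the remainder)
  xb <- floor(seq(0, img$width, length.out = gx + 1))
  yb <- floor(seq(0, img$height, length.out = gy + 1))
  bin_of <- pmin(floor(px / (mx + 1) * n_bins) + 1L, n_bins)

  # per-tile lookup tables: clipped histogram -> CDF -> Rayleigh inverse CDF
  luts <- array(0, dim = c(n_bins, gy, gx))
  centers_x <- numeric(gx); centers_y <- numeric(gy)
  for (tx in seq_len(gx)) {
    for (ty in seq_len(gy)) {
      rows <- (yb[ty] + 1):yb[ty + 1]
      cols <- (xb[tx] + 1):xb[tx + 1]
      h <- tabulate(bin_of[rows, cols], nbins = n_bins)
      luts[, ty, tx] <- rayleigh_mapping(h, clip_limit, rayleigh_alpha) * mx
      centers_x[tx] <- (xb[tx] + xb[tx + 1] - 1) / 2
      centers_y[ty] <- (yb[ty] + 1 - 1 + yb[ty + 1] - 1) / 2
    }
  }

  # bilinear blending between the four surrounding tile mappings
  out <- blend_tile_luts(bin_of, luts, centers_x, centers_y)
  gray_image(out, img$bit_depth)
}

# Clip a histogram at clip_limit * n, redistribute the excess uniformly, and
# map the resulting CDF through the inverse Rayleigh CDF. The CDF is scaled
# by vmax = F(1) = 1 - exp(-1/(2 alpha^2)) so that the mapping reaches
# exactly 1 at the top of the histogram (the standard convention for a
# Rayleigh-target CLAHE).
rayleigh_mapping <- function(h, clip_limit, alpha) {
  n <- sum(h)
  limit <- max(clip_limit * n, 1)
  excess <- sum(pmax(h - limit, 0))
  h <- pmin(h, limit) + excess / length(h)
  cdf <- cumsum(h) / sum(h)
  vmax <- 1 - exp(-1 / (2 * alpha^2))
  sqrt(-2 * alpha^2 * log(1 - cdf * vmax))
}

blend_tile_luts <- function(bin_of, luts, centers_x, centers_y) {
  nr <- nrow(bin_of); nc <- ncol(bin_of)
  gx <- length(centers_x); gy <- length(centers_y)
  # for each pixel, the two bracketing tiles and weights per axis
  wx <- axis_weights((seq_len(nc) - 1), centers_x)
  wy <- axis_weights((seq_len(nr) - 1), centers_y)
  out <- matrix(0, nr, nc)
  # accumulate the four corner contributions tile-pair by tile-pair
  for (tx in seq_len(gx)) {
    colsel <- which(wx$lo == tx | wx$hi == tx)
    if (length(colsel) == 0) next
    w_col <- ifelse(wx$lo[colsel] == tx, 1 - wx$w[colsel], 0) +
             ifelse(wx$hi[colsel] == tx, wx$w[colsel], 0)
    for (ty in seq_len(gy)) {
      rowsel <- which(wy$lo == ty | wy$hi == ty)
      if (length(rowsel) == 0) next
      w_row <- ifelse(wy$lo[rowsel] == ty, 1 - wy$w[rowsel], 0) +
               ifelse(wy$hi[rowsel] == ty, wy$w[rowsel], 0)
      lut <- luts[, ty, tx]
      vals <- matrix(lut[bin_of[rowsel, colsel]], length(rowsel), length(colsel))
      out[rowsel, colsel] <- out[rowsel, colsel] + vals * (w_row %o% w_col)
    }
  }
  out
}

# For positions p along one axis, the indices of the two bracketing tile
# centers and the interpolation weight toward the upper one (clamped at the
# image border so edge pixels use the nearest tile mapping alone).
axis_weights <- function(p, centers) {
  k <- length(centers)
  hi <- findInterval(p, centers) + 1L
  lo <- hi - 1L
  lo <- pmin(pmax(lo, 1L), k)
  hi <- pmin(pmax(hi, 1L), k)
  w <- ifelse(hi == lo, 0, (p - centers[lo]) / (centers[hi] - centers[lo]))
  w <- pmin(pmax(w, 0), 1)
  list(lo = lo, hi = hi, w = w)
}

#' Otsu binarization
#'
#' Thresholds an image at the intensity maximizing between-class variance and
#' returns the foreground mask (pixels strictly above the threshold).
#'
#' @param img A [gray_image] or matrix.
#' @param return_threshold If TRUE, return the threshold instead of the mask.
#' @return A binary integer matrix (1 = foreground), with the threshold in
#'   attribute `"threshold"`; or the threshold itself.
#' @export
binarize_otsu <- function(img, return_threshold = FALSE) {
  img <- as_gray_image(img)
  if (max(img$pixels) == min(img$pixels))
    stop("Otsu threshold undefined: image is constant")
  thr <- otsu_threshold(img$pixels, max_intensity(img))
  if (return_threshold) return(thr)
  mask <- (img$pixels > thr) * 1L
  attr(mask, "threshold") <- thr
  mask
}

# Otsu threshold over a 256-bin histogram of the full representable range
# (the binning convention of the original method's thresholding function).
otsu_threshold <- function(px, mx, levels = 256L) {
  ebi <- EBImage::Image(t(pmin(pmax(px / mx, 0), 1)))
  as.numeric(EBImage::otsu(ebi, range = c(0, 1), levels = levels)) * mx
}

#' Label, fill and filter foreground regions
#'
#' Labels the foreground 8-connectedly, fills holes within each region
#' (4-connected background), then removes regions touching the image border
#' and regions smaller than `min_area`. Survivors are relabeled 1..n.
#'
#' @param mask Binary or labeled integer matrix (0 = background).
#' @param min_area Minimum region area in square pixels (default 800).
#' @return Labeled integer matrix with attribute `"region_count"`.
#' @export
clean_regions <- function(mask, min_area = 800) {
  mask <- as.matrix(mask)
  lbl <- label_regions(mask > 0)
  if (max(lbl) > 0) lbl <- EBImage::fillHull(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  keep <- seq_len(max(lbl))
  if (length(keep)) {
    border <- unique(c(lbl[1, ], lbl[nr, ], lbl[, 1], lbl[, nc]))
    areas <- tabulate(lbl[lbl > 0], nbins = max(lbl))
    keep <- keep[!(keep %in% border) & areas[keep] >= min_area]
  }
  relabel <- integer(max(lbl, 1))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nr, nc)
  out[lbl > 0] <- relabel[lbl[lbl > 0]]
  attr(out, "region_count") <- length(keep)
  out
}

# 8-connected labeling built on EBImage's 4-connected bwlabel by union-find
# merging of labels that touch diagonally.
label_regions <- function(bin) {
  lbl <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  m <- max(lbl)
  if (m <= 1) return(structure(matrix(as.integer(lbl), nrow(lbl)), region_count = m))
  nr <- nrow(lbl); nc <- ncol(lbl)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]      # down-right diagonal
  a2 <- lbl[-nr, -1];  b2 <- lbl[-1, -nc]     # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(m), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  out[lbl > 0] <- dense[lbl[lbl > 0]]
  structure(out, region_count = max(dense))
}

# Rasterized Euclidean disk structuring element: pixel included iff its
# center is within `radius` of the disk center.
disc_kernel <- function(radius) {
  r <- as.integer(radius)
  g <- seq(-r, r)
  d <- outer(g, g, function(i, j) sqrt(i^2 + j^2))
  (d <= radius + 1e-9) * 1
}

#' Per-region convex hull pairs
#'
#' For each labeled region, smooths and enlarges it by erosion (radius
#' `outer_erode_r`) followed by dilation (radius `outer_dilate_r`) and takes
#' the convex hull as the outer search limit of the boundary. The inner hull,
#' used to initialize the active contour, is the convex hull of the same
#' smoothed region after a further erosion of radius `inner_erode_r`.
#'
#' @param mask Labeled matrix from [clean_regions()].
#' @param outer_erode_r,outer_dilate_r,inner_erode_r Disk radii in pixels
#'   (defaults 3, 6, 2).
#' @return A list of hull pairs: each `list(outer, inner, region_label)` with
#'   `outer`/`inner` CCW [contour] polygons, inner contained in outer.
#'   Regions erased by erosion are dropped with a warning.
#' @export
build_hulls <- function(mask, outer_erode_r = 3, outer_dilate_r = 6, inner_erode_r = 2) {
  mask <- as.matrix(mask)
  n <- max(mask)
  hulls <- list()
  for (k in seq_len(n)) {
    bin <- (mask == k) * 1
    sm <- EBImage::dilate(EBImage::erode(bin, disc_kernel(outer_erode_r)),
                          disc_kernel(outer_dilate_r))
    if (!any(sm > 0)) {
      warning("region ", k, " vanished under erosion; dropped")
      next
    }
    inner_mask <- EBImage::erode(sm, disc_kernel(inner_erode_r))
    if (!any(inner_mask > 0)) {
      warning("region ", k, " too small to seed an inner hull; dropped")
      next
    }
    hulls[[length(hulls) + 1L]] <- list(
      outer = mask_hull(sm), inner = mask_hull(inner_mask), region_label = k)
  }
  hulls
}

mask_hull <- function(bin) {
  idx <- which(bin > 0, arr.ind = TRUE)
  convex_hull_polygon(cbind(x = idx[, 2] - 1, y = idx[, 1] - 1))
}

#' Saturating linear contrast stretch
#'
#' Maps the lowest `saturate_frac` intensity quantile to 0 and the highest to
#' the maximum representable intensity, with the interior rescaled linearly.
#'
#' @param img A [gray_image] or matrix.
#' @param saturate_frac Fraction saturated at each end (default 0.01); must be
#'   in `[0, 0.5)`.
#' @return A [gray_image]; constant images are returned unchanged.
#' @export
stretch_contrast <- function(img, saturate_frac = 0.01) {
  img <- as_gray_image(img)
  if (saturate_frac < 0 || saturate_frac >= 0.5)
    stop("saturate_frac must be in [0, 0.5)")
  q <- quantile(img$pixels, c(saturate_frac, 1 - saturate_frac), names = FALSE)
  if (q[2] <= q[1]) return(img)
  mx <- max_intensity(img)
  out <- (img$pixels - q[1]) / (q[2] - q[1]) * mx
  gray_image(pmin(pmax(out, 0), mx), img$bit_depth)
}

#' Near-binarization of one nucleus for the external force field
#'
#' Prepares the image a snake's gradient-vector-flow field is computed from.
#' Following the extraction pipeline: contrast-stretch the frame, zero all
#' pixels outside the nucleus' outer hull, stretch again, compute (but do not
#' apply) the Otsu threshold T, then set pixels below `low_frac * T` to the
#' minimum and above `high_frac * T` to the maximum intensity, stretch the
#' mid-range linearly, and fill gray-scale holes (intensity basins enclosed by
#' brighter pixels) by morphological reconstruction.
#'
#' Operates on a crop around the outer hull (bounding box plus `margin`).
#'
#' @param img Raw frame as a [gray_image].
#' @param hull A hull pair from [build_hulls()].
#' @param low_frac,high_frac Threshold fractions (defaults 0.7 and 1.3).
#' @param saturate_frac Saturation fraction for the contrast stretches.
#' @param margin Crop margin around the outer hull in pixels.
#' @param prestretched Set TRUE if `img` has already been contrast-stretched
#'   at the frame level (skips the first stretch).
#' @return A [gray_image] crop with attribute `"offset"` = (x0, y0) giving
#'   the crop origin in frame coordinates, or NULL (with a warning) if the
#'   hull interior has no contrast.
#' @export
near_binarize <- function(img, hull, low_frac = 0.7, high_frac = 1.3,
                          saturate_frac = 0.01, margin = 5L, prestretched = FALSE) {
  img <- as_gray_image(img)
  if (!prestretched) img <- stretch_contrast(img, saturate_frac)
  mx <- max_intensity(img)
  outer <- as.matrix(hull$outer)
  x0 <- max(0L, floor(min(outer[, 1])) - margin)
  x1 <- min(img$width - 1L, ceiling(max(outer[, 1])) + margin)
  y0 <- max(0L, floor(min(outer[, 2])) - margin)
  y1 <- min(img$height - 1L, ceiling(max(outer[, 2])) + margin)
  crop <- img$pixels[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]

  gx <- rep(x0:x1, each = nrow(crop))
  gy <- rep(y0:y1, times = ncol(crop))
  inside <- matrix(points_in_polygon(gx, gy, outer), nrow(crop), ncol(crop))
  crop[!inside] <- 0
  if (max(crop) == min(crop)) {
    warning("nucleus region ", hull$region_label, " has no contrast; skipped")
    return(NULL)
  }
  crop <- stretch_contrast(gray_image(crop, img$bit_depth), saturate_frac)$pixels
  thr <- otsu_threshold(crop, mx)

  out <- (crop - low_frac * thr) / ((high_frac - low_frac) * thr) * mx
  out <- pmin(pmax(out, 0), mx)
  out <- fill_holes_gray(out, mx)
  structure(gray_image(out, img$bit_depth), offset = c(x0, y0))
}

# Gray-scale hole filling: morphological reconstruction by erosion from a
# marker that is maximal everywhere except on the border, where it equals the
# image. Raises enclosed intensity basins to their enclosing rim level.
fill_holes_gray <- function(px, mx) {
  marker <- matrix(mx, nrow(px), ncol(px))
  marker[1, ] <- px[1, ]; marker[nrow(px), ] <- px[nrow(px), ]
  marker[, 1] <- px[, 1]; marker[, ncol(px)] <- px[, ncol(px)]
  .reconstruct_erode(marker, px)
}
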