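#' Parametric nucleus shape
#'
#' Describes a star-convex nucleus outline in polar form around its center:
#' an ellipse of eccentricity set by `axis_ratio`, modulated by `bleb_count`
#' smooth inward invaginations (wrapped-Gaussian dents of relative depth
#' `bleb_depth` and angular scale `bleb_width`), equally spaced with a
#' `rotation` offset:
#' `r(theta) = R e(theta) (1 - sum_j depth * exp(-0.5 ((theta - theta_j)/width)^2))`.
#'
#' @param base_radius Minor semi-axis R in pixels.
#' @param axis_ratio Major/minor axis ratio, >= 1 (1 = circle).
#' @param bleb_count Number of invaginations (integer >= 0).
#' @param bleb_depth Dent depth as a fraction of local radius, in `[0, 0.5)`.
#' @param bleb_width Angular scale of a dent in radians.
#' @param rotation Angular offset of the dent positions (radians).
#' @param center (x, y) center in pixel coordinates.
#' @return A list of class `shape_spec`.
#' @export
shape_spec <- function(base_radius, axis_ratio = 1, bleb_count = 0L,
                       bleb_depth = 0, bleb_width = 0.15, rotation = 0,
                       center = c(0, 0)) {
  if (base_radius <= 0) stop("base_radius must be positive")
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  if (bleb_depth < 0 || bleb_depth >= 0.5) stop("bleb_depth must be in [0, 0.5)")
  if (bleb_count < 0) stop("bleb_count must be >= 0")
  if (bleb_count >= 2 && 2 * pi / bleb_count < 4 * bleb_width)
    stop("invaginations overlap: need 2*pi/bleb_count >= 4*bleb_width")
  structure(list(base_radius = base_radius, axis_ratio = axis_ratio,
                 bleb_count = as.integer(bleb_count), bleb_depth = bleb_depth,
                 bleb_width = bleb_width, rotation = rotation,
                 center = as.numeric(center)),
            class = "shape_spec")
}

# Radial profile r(theta) of a shape spec (vectorized over theta).
shape_radius <- function(spec, theta) {
  q <- spec$axis_ratio
  e <- q / sqrt(cos(theta - spec$rotation)^2 * 1 + q^2 * sin(theta - spec$rotation)^2)
  dent <- 0
  if (spec$bleb_count > 0 && spec$bleb_depth > 0) {
    centers <- spec$rotation + 2 * pi * (seq_len(spec$bleb_count) - 1) / spec$bleb_count
    for (tc in centers) {
      d <- (theta - tc + pi) %% (2 * pi) - pi  # wrapped angular distance
      dent <- dent + exp(-0.5 * (d / spec$bleb_width)^2)
    }
  }
  spec$base_radius * e * (1 - spec$bleb_depth * dent)
}

#' Sample an analytic nucleus contour
#'
#' Evaluates the polar shape at `n_vertices` equally spaced angles and returns
#' the ground-truth boundary polygon.
#'
#' @param spec A [shape_spec()].
#' @param n_vertices Number of boundary vertices (default 720).
#' @return A CCW [contour].
#' @export
sample_shape <- function(spec, n_vertices = 720L) {
  theta <- 2 * pi * (0:(n_vertices - 1)) / n_vertices
  r <- shape_radius(spec, theta)
  if (any(r <= 0)) stop("shape spec yields non-positive radius")
  contour(cbind(spec$center[1] + r * cos(theta), spec$center[2] + r * sin(theta)))
}

#' Rendering parameters for synthetic fluorescence frames
#'
#' Emulates an anti-lamin rim stain: a bright rim of width `rim_width`
#' extending inward from the boundary, a dimmer nucleoplasmic interior, a dark
#' background, and additive Gaussian noise. 16-bit output.
#'
#' @param rim_intensity Rim level in intensity units (16-bit scale).
#' @param rim_width Rim thickness in pixels.
#' @param interior_intensity Interior level as a fraction of the rim level.
#' @param background_level Background intensity.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Optional RNG seed for the noise.
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(rim_intensity = 40000, rim_width = 3,
                        interior_intensity = 0.35, background_level = 2000,
                        noise_sd = 1500, seed = NULL) {
  if (rim_intensity <= background_level)
    stop("rim_intensity must exceed background_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(rim_intensity = rim_intensity, rim_width = rim_width,
                 interior_intensity = interior_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed),
            class = "render_spec")
}

#' Render nucleus contours into a synthetic fluorescence frame
#'
#' Paints each (star-convex) contour as a lamin-like rim image: using the
#' radial distance of each pixel to the contour around its centroid, pixels
#' within `rim_width` inside the boundary take the rim intensity, deeper
#' pixels the interior intensity, outside pixels the background, with 1-px
#' linear ramps across the transitions so the intensity gradient peaks on the
#' true boundary. Seeded Gaussian noise is added and the image clipped to the
#' 16-bit range.
#'
#' @param contours A [contour] or list of contours; each must fit in the
#'   frame with a margin of at least `rim_width`.
#' @param rspec A [render_spec()].
#' @param frame_size (width, height) in pixels.
#' @return A 16-bit [gray_image].
#' @export
render <- function(contours, rspec = render_spec(), frame_size = c(160, 160)) {
  if (inherits(contours, "contour")) contours <- list(contours)
  w <- frame_size[1]; h <- frame_size[2]
  for (cnt in contours) {
    v <- as.matrix(cnt)
    if (min(v[, 1]) < rspec$rim_width || min(v[, 2]) < rspec$rim_width ||
        max(v[, 1]) > w - 1 - rspec$rim_width || max(v[, 2]) > h - 1 - rspec$rim_width)
      stop("contour does not fit in the frame with a rim_width margin")
  }
  img <- matrix(rspec$background_level, nrow = h, ncol = w)
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  for (cnt in contours) {
    v <- as.matrix(cnt)
    ctr <- polygon_centroid(v)
    theta_v <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
    r_v <- sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2)
    ord <- order(theta_v)
    tv <- theta_v[ord]; rv <- r_v[ord]
    # periodic radial lookup
    tv <- c(tv[length(tv)] - 2 * pi, tv, tv[1] + 2 * pi)
    rv <- c(rv[length(rv)], rv, rv[1])
    th <- atan2(py - ctr[2], px - ctr[1])
    rho <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
    rb <- stats::approx(tv, rv, xout = th)$y
    s <- rb - rho  # radial signed distance: positive inside
    ramp_in <- pmin(pmax(s + 0.5, 0), 1)                       # bg -> rim at s = 0
    ramp_deep <- pmin(pmax(s - rspec$rim_width + 0.5, 0), 1)   # rim -> interior
    lv <- rspec$background_level +
      (rspec$rim_intensity - rspec$background_level) * ramp_in -
      (rspec$rim_intensity * (1 - rspec$interior_intensity)) * ramp_deep
    val <- matrix(lv, nrow = h)
    img <- pmax(img, val)
  }
  noise <- if (rspec$noise_sd > 0) {
    with_local_seed(rspec$seed, matrix(rnorm(w * h, 0, rspec$noise_sd), nrow = h))
  } else 0
  gray_image(pmin(pmax(round(img + noise), 0), 65535), 16L)
}

# Evaluate `expr` under a temporary RNG state when seed is non-NULL.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic nucleus population with ground truth
#'
#' Draws `n` nuclei with shape parameters from the stated distributions,
#' places them on jittered grids with `nuclei_per_frame` nuclei per frame,
#' renders the frames, and tabulates per-nucleus ground truth (the analytic
#' contour and the metrics computed from it). Each nucleus uses an RNG
#' substream derived from `seed` and its index, so extending `n` does not
#' reshuffle earlier nuclei.
#'
#' @param n Number of nuclei.
#' @param seed Integer master seed.
#' @param shape_dist List of parameter ranges: `radius` (min, max),
#'   `axis_ratio` (min, max), `bleb_count` (min, max integers),
#'   `depth` (min, max), `width` (fixed angular scale).
#' @param rspec A [render_spec()] (its `seed` field is ignored; noise seeds
#'   derive from `seed`).
#' @param nuclei_per_frame Nuclei per rendered frame (default 1).
#' @param frame_size Frame (width, height); default scales with density.
#' @return `list(frames, truth, contours)`: frames is a list of
#'   [gray_image]s, truth a data frame with one row per nucleus (frame index,
#'   center, shape parameters, and true metrics), contours the analytic
#'   ground-truth contours.
#' @export
generate_population <- function(n, seed,
                                shape_dist = list(radius = c(22, 30),
                                                  axis_ratio = c(1, 1.4),
                                                  bleb_count = c(2L, 5L),
                                                  depth = c(0, 0.3),
                                                  width = 0.15),
                                rspec = render_spec(),
                                nuclei_per_frame = 1L,
                                frame_size = NULL) {
  stopifnot(n >= 1)
  g <- ceiling(sqrt(nuclei_per_frame))
  max_r <- shape_dist$radius[2] * max(shape_dist$axis_ratio)
  cell <- 2 * (max_r + rspec$rim_width + 6)
  if (is.null(frame_size)) frame_size <- rep(ceiling(g * cell), 2)
  if (min(frame_size) < g * cell)
    stop("frame_size too small for the requested density")

  n_frames <- ceiling(n / nuclei_per_frame)
  frames <- vector("list", n_frames)
  contours <- vector("list", n)
  truth <- vector("list", n)
  idx <- 1L
  for (f in seq_len(n_frames)) {
    in_frame <- min(nuclei_per_frame, n - (f - 1L) * nuclei_per_frame)
    frame_contours <- vector("list", in_frame)
    for (j in seq_len(in_frame)) {
      sub_seed <- (as.integer(seed) + 1013904223 + 69069 * (idx - 1L)) %% 2147483647L
      spec <- with_local_seed(sub_seed, {
        gx <- (j - 1L) %% g; gy <- (j - 1L) %/% g
        jit <- runif(2, -cell * 0.06, cell * 0.06)
        ctr <- c((gx + 0.5) * frame_size[1] / g, (gy + 0.5) * frame_size[2] / g) + jit
        shape_spec(
          base_radius = runif(1, shape_dist$radius[1], shape_dist$radius[2]),
          axis_ratio = runif(1, shape_dist$axis_ratio[1], shape_dist$axis_ratio[2]),
          bleb_count = sample(shape_dist$bleb_count[1]:shape_dist$bleb_count[2], 1),
          bleb_depth = runif(1, shape_dist$depth[1], shape_dist$depth[2]),
          bleb_width = shape_dist$width,
          rotation = runif(1, 0, 2 * pi),
          center = ctr)
      })
      cnt <- sample_shape(spec)
      prof <- signed_curvature(cnt, guess_offset(cnt))
      tm <- metric_table(cnt, prof)
      truth[[idx]] <- cbind(
        data.frame(frame = f, nucleus = idx,
                   center_x = spec$center[1], center_y = spec$center[2],
                   base_radius = spec$base_radius, axis_ratio = spec$axis_ratio,
                   bleb_count = spec$bleb_count, bleb_depth = spec$bleb_depth),
        stats::setNames(tm[, c("mnc", "area", "perimeter", "eccentricity",
                               "invaginations", "solidity")],
                        paste0("true_", c("mnc", "area", "perimeter",
                                          "eccentricity", "invaginations", "solidity"))))
      contours[[idx]] <- cnt
      frame_contours[[j]] <- cnt
      idx <- idx + 1L
    }
    noise_seed <- (as.integer(seed) + 777 + f) %% 2147483647L
    rs <- rspec; rs$seed <- noise_seed
    frames[[f]] <- render(frame_contours, rs, frame_size)
  }
  list(frames = frames, truth = do.call(rbind, truth), contours = contours)
}

# Curvature offset matched to the analytic 720-vertex sampling so that the
# fitted arc spans the same boundary length as offset 25 does at the 0.5-px
# output spacing of the extraction pipeline.
guess_offset <- function(cnt, target_arc = 12.5) {
  spacing <- polygon_perimeter(cnt) / nrow(cnt)
  max(2L, round(target_arc / spacing))
}

#' Match extracted contours to ground-truth nuclei
#'
#' Pairs each extracted contour with the nearest ground-truth center (within
#' `max_dist` pixels of its centroid).
#'
#' @param contours List of extracted [contour]s (with `centroid` attributes).
#' @param truth Ground-truth table from [generate_population()] (one frame).
#' @param max_dist Maximum centroid-to-center distance for a match.
#' @return Integer vector: for each contour, the matched `truth$nucleus` id
#'   or NA.
#' @export
match_truth <- function(contours, truth, max_dist = 20) {
  vapply(contours, function(cnt) {
    ctr <- attr(cnt, "centroid")
    if (is.null(ctr)) ctr <- polygon_centroid(as.matrix(cnt))
    d <- sqrt((truth$center_x - ctr[1])^2 + (truth$center_y - ctr[2])^2)
    i <- which.min(d)
    if (length(i) == 0 || d[i] > max_dist) NA_integer_ else as.integer(truth$nucleus[i])
  }, integer(1))
}
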