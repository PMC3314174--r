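#' Snake parameter set
#'
#' Bundles the deformable-model parameters used during boundary extraction.
#' Defaults are the published operating point of the method: 80 GVF
#' iterations, vertex spacing kept in `[d_min, d_max] = [0.5, 2]` pixels
#' during evolution, tension `alpha = 0.02`, rigidity `beta = 0.05`, step size
#' `gamma = 1`, external force weight `kappa = 0.6`, convergence checked every
#' `batch_size = 75` deformations against an area tolerance of 10 square
#' pixels, and a hard cap of 50,025 total deformations.
#'
#' @param gvf_iterations,gvf_mu GVF diffusion iterations and regularization.
#' @param d_min,d_max Vertex spacing bounds (pixels); the final contour is
#'   resampled to constant side length `d_min`.
#' @param alpha,beta,gamma,kappa Snake tension, rigidity, step size and
#'   external force weights.
#' @param batch_size Deformations per convergence check.
#' @param area_tol Convergence tolerance on the area change between batches
#'   (square pixels).
#' @param max_deformations Upper bound on total deformations.
#' @return A list of class `snake_params`.
#' @export
snake_params <- function(gvf_iterations = 80L, gvf_mu = 0.2, d_min = 0.5,
                         d_max = 2, alpha = 0.02, beta = 0.05, gamma = 1,
                         kappa = 0.6, batch_size = 75L, area_tol = 10,
                         max_deformations = 50025L) {
  stopifnot(d_min < d_max, alpha > 0, beta > 0, gamma > 0, kappa > 0,
            gvf_mu > 0, max_deformations >= batch_size)
  structure(list(gvf_iterations = as.integer(gvf_iterations), gvf_mu = gvf_mu,
                 d_min = d_min, d_max = d_max, alpha = alpha, beta = beta,
                 gamma = gamma, kappa = kappa, batch_size = as.integer(batch_size),
                 area_tol = area_tol, max_deformations = as.integer(max_deformations)),
            class = "snake_params")
}

#' Gradient vector flow field
#'
#' Computes the GVF field of an image: the edge map is the gradient magnitude
#' of the (near-binarized) image, normalized to `[0, 1]`, and its gradient is
#' diffused for `iterations` steps under the regularization weight `mu`. Far
#' from edges the field extends smoothly, pointing toward the nearest edge.
#'
#' @param img A [gray_image] or matrix (typically from [near_binarize()]).
#' @param iterations Diffusion iterations (default 80).
#' @param mu Regularization weight (default 0.2; must be below 0.25 for the
#'   explicit update to be stable).
#' @return List with matrices `u`, `v` (force components along x and y).
#' @export
compute_gvf <- function(img, iterations = 80L, mu = 0.2) {
  img <- as_gray_image(img)
  f <- img$pixels / max(max_intensity(img), 1)
  g <- gradient_xy(f)
  edge <- sqrt(g$x^2 + g$y^2)
  if (max(edge) > 0) edge <- edge / max(edge)
  ge <- gradient_xy(edge)
  .gvf_diffuse(ge$x, ge$y, mu, as.integer(iterations))
}

# Central-difference gradient with replicated borders; x along columns,
# y along rows.
gradient_xy <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  list(x = gx, y = gy)
}

#' Resample a closed contour
#'
#' In evolution mode (`uniform = FALSE`) vertices closer than `d_min` to
#' their predecessor are merged and sides longer than `d_max` are subdivided,
#' so every side length ends in `[d_min, d_max]`. With `uniform = TRUE` the
#' contour is resampled by arc length to sides of constant length `d_min`
#' (within 10%), as used for the final output polygon.
#'
#' @param c A [contour].
#' @param d_min,d_max Spacing bounds in pixels.
#' @param uniform Final constant-spacing mode.
#' @return A resampled [contour].
#' @export
resample_contour <- function(c, d_min = 0.5, d_max = 2, uniform = FALSE) {
  v <- as.matrix(c)
  per <- polygon_perimeter(v)
  if (per < 3 * d_min)
    stop(sprintf("degenerate contour: perimeter %.3f px < 3 * d_min", per))
  if (uniform) {
    # arc-length resampling gives chords shorter than the arc step at sharp
    # corners; iterate (each pass cuts corners at the d_min scale) until all
    # side lengths are within 10% of d_min
    for (pass in 1:8) {
      per <- polygon_perimeter(v)
      n_out <- max(3L, round(per / d_min))
      s <- cumulative_arc(v)
      t_out <- per * (0:(n_out - 1)) / n_out
      v <- cbind(interp_cyclic(s, c(v[, 1], v[1, 1]), t_out),
                 interp_cyclic(s, c(v[, 2], v[1, 2]), t_out))
      d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
      if (all(abs(d - d_min) <= 0.1 * d_min)) break
    }
    return(contour(v, ccw = FALSE))
  }
  # merge sides shorter than d_min, then split sides longer than d_max;
  # a merge can create a side > d_max and a split never creates one < d_min
  # (subdivided sides have length in (d_max/2, d_max]), so a few passes settle
  for (pass in 1:20) {
    # merge pass: drop vertices too close to their predecessor, never two
    # adjacent drops at once and never below a triangle
    repeat {
      if (nrow(v) <= 3) break
      d <- sqrt(rowSums((v - v[c(nrow(v), 1:(nrow(v) - 1)), ])^2))
      drop <- which(d < d_min)
      if (length(drop) == 0) break
      drop <- drop[c(TRUE, diff(drop) > 1)]
      drop <- head(drop, nrow(v) - 3L)
      if (length(drop) == 0) break
      v <- v[-drop, , drop = FALSE]
    }
    # split pass
    d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
    long <- which(d > d_max)
    if (length(long) > 0) {
      pieces <- vector("list", nrow(v))
      for (i in seq_len(nrow(v))) {
        pieces[[i]] <- v[i, , drop = FALSE]
        if (i %in% long) {
          nxt <- v[if (i == nrow(v)) 1L else i + 1L, ]
          k <- ceiling(d[i] / d_max)
          t <- seq_len(k - 1) / k
          pieces[[i]] <- rbind(pieces[[i]],
                               cbind(v[i, 1] + t * (nxt[1] - v[i, 1]),
                                     v[i, 2] + t * (nxt[2] - v[i, 2])))
        }
      }
      v <- do.call(rbind, pieces)
    }
    d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
    if (nrow(v) <= 3 || all(d >= d_min & d <= d_max)) break
  }
  contour(v, ccw = FALSE)
}

interp_cyclic <- function(s, vals, t_out) {
  stats::approx(s, vals, xout = t_out, rule = 2)$y
}

# Inverse of the semi-implicit internal-energy system (K + gamma I), K the
# cyclic pentadiagonal tension/rigidity stiffness matrix.
snake_system_inverse <- function(n, alpha, beta, gamma) {
  row <- numeric(n)
  row[1] <- 2 * alpha + 6 * beta + gamma
  row[2] <- -(alpha + 4 * beta); row[n] <- row[2]
  if (n >= 3) { row[3] <- beta; row[n - 1] <- beta }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) K[i, ] <- row[((seq_len(n) - i) %% n) + 1]
  solve(K)
}

#' Evolve a GVF snake to a nucleus boundary
#'
#' Deforms an initial contour (the inner convex hull of the nucleus region)
#' under internal tension/rigidity forces and the normalized GVF external
#' force, in batches of `batch_size` deformations with re-interpolation
#' between batches. Terminates when the enclosed area changes by at most
#' `area_tol` square pixels between consecutive batches, or when the total
#' deformation count reaches `max_deformations`. Vertices escaping
#' `outer_limit` are projected back onto it after every batch.
#'
#' @param init Initial [contour] (in the coordinate frame of `field`).
#' @param field GVF field from [compute_gvf()].
#' @param params A [snake_params()] list.
#' @param outer_limit Convex polygon the contour may not leave (same frame),
#'   or NULL for unconstrained evolution.
#' @return The converged [contour], uniformly resampled at spacing `d_min`,
#'   with attribute `"deformations"`; NULL (with a warning) if the contour
#'   collapses.
#' @export
evolve_snake <- function(init, field, params = snake_params(), outer_limit = NULL) {
  mag <- sqrt(field$u^2 + field$v^2)
  u <- field$u / (mag + 1e-10)
  v <- field$v / (mag + 1e-10)
  cur <- resample_contour(init, params$d_min, params$d_max)
  prev_area <- polygon_area(cur)
  n_def <- 0L
  Minv <- NULL; n_cached <- -1L
  while (n_def < params$max_deformations) {
    n <- nrow(cur)
    if (n != n_cached) {
      Minv <- snake_system_inverse(n, params$alpha, params$beta, params$gamma)
      n_cached <- n
    }
    res <- .snake_deform(cur[, 1], cur[, 2], u, v, Minv,
                         params$gamma, params$kappa, params$batch_size)
    n_def <- n_def + params$batch_size
    pts <- cbind(res$x, res$y)
    if (!is.null(outer_limit)) {
      outside <- !points_in_polygon(pts[, 1], pts[, 2], outer_limit)
      if (any(outside))
        pts[outside, ] <- project_onto_polygon(pts[outside, , drop = FALSE], outer_limit)
    }
    if (polygon_perimeter(pts) < 3 * params$d_min) {
      warning("snake collapsed; nucleus rejected")
      return(NULL)
    }
    cur <- resample_contour(contour(pts, ccw = FALSE), params$d_min, params$d_max)
    area <- polygon_area(cur)
    if (abs(area - prev_area) <= params$area_tol) break
    prev_area <- area
  }
  out <- resample_contour(cur, params$d_min, params$d_max, uniform = TRUE)
  out <- contour(out)  # enforce CCW orientation
  attr(out, "deformations") <- n_def
  out
}

#' Extract all nucleus boundaries from a frame
#'
#' Runs the full boundary-extraction pipeline on one fluorescence frame:
#' adaptive histogram equalization, Otsu binarization, hole filling and
#' region filtering, per-region convex hull construction, near-binarization,
#' GVF computation, and snake evolution from the inner hull limited by the
#' outer hull. Deterministic given the image and configuration.
#'
#' @param img A [gray_image] (lamin channel).
#' @param config A [pipeline_config()] list (defaults used if NULL).
#' @return A list of [contour] objects in frame coordinates, each carrying
#'   attributes `region_label` and `centroid`; empty list if no nucleus
#'   passes the filters.
#' @export
extract_nuclei <- function(img, config = NULL) {
  cfg <- if (is.null(config)) pipeline_config() else config
  pp <- cfg$preprocess
  img <- as_gray_image(img)
  eq <- equalize_adaptive(img, pp$tile_grid, pp$clip_limit, pp$rayleigh_alpha)
  if (max(eq$pixels) == min(eq$pixels)) return(list())
  mask <- tryCatch(binarize_otsu(eq), error = function(e) NULL)
  if (is.null(mask)) return(list())
  lbl <- clean_regions(mask, pp$min_area)
  if (attr(lbl, "region_count") == 0L) return(list())
  hulls <- build_hulls(lbl, pp$outer_erode_r, pp$outer_dilate_r, pp$inner_erode_r)
  if (length(hulls) == 0L) return(list())

  stretched <- stretch_contrast(img, pp$saturate_frac)
  sp <- do.call(snake_params, cfg$snake)
  out <- list()
  for (h in hulls) {
    nb <- near_binarize(stretched, h, pp$low_frac, pp$high_frac,
                        pp$saturate_frac, pp$crop_margin, prestretched = TRUE)
    if (is.null(nb)) next
    off <- attr(nb, "offset")
    fld <- compute_gvf(nb, sp$gvf_iterations, sp$gvf_mu)
    shift <- function(poly) {
      p <- as.matrix(poly); p[, 1] <- p[, 1] - off[1]; p[, 2] <- p[, 2] - off[2]
      contour(p, ccw = FALSE)
    }
    snk <- tryCatch(
      evolve_snake(shift(h$inner), fld, sp, outer_limit = shift(h$outer)),
      error = function(e) { warning("region ", h$region_label, ": ", conditionMessage(e)); NULL })
    if (is.null(snk)) next
    p <- as.matrix(snk)
    p[, 1] <- p[, 1] + off[1]; p[, 2] <- p[, 2] + off[2]
    res <- contour(p, ccw = FALSE)
    attr(res, "region_label") <- h$region_label
    attr(res, "centroid") <- polygon_centroid(p)
    attr(res, "deformations") <- attr(snk, "deformations")
    out[[length(out) + 1L]] <- res
  }
  out
}

#' Remove contours by exclusion points
#'
#' File-driven replacement for interactive curation: every contour whose
#' polygon contains one of the exclusion points is removed. A point inside
#' several overlapping contours removes all of them.
#'
#' @param contours List of [contour] objects.
#' @param exclusions Numeric matrix or data frame of (x, y) points.
#' @return The retained contours.
#' @export
curate <- function(contours, exclusions) {
  if (is.null(exclusions) || NROW(exclusions) == 0) return(contours)
  ex <- as.matrix(exclusions)[, 1:2, drop = FALSE]
  hit_any <- rep(FALSE, nrow(ex))
  keep <- vapply(contours, function(cnt) {
    hits <- points_in_polygon(ex[, 1], ex[, 2], cnt)
    hit_any <<- hit_any | hits
    !any(hits)
  }, logical(1))
  if (any(!hit_any))
    warning(sum(!hit_any), " exclusion point(s) hit no contour; ignored")
  contours[keep]
}
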