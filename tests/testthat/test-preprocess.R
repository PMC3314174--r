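test_that("adaptive equalization maps a constant image to a constant image", {
  img <- gray_image(matrix(1234, 64, 64), 16L)
  out <- equalize_adaptive(img)
  expect_equal(length(unique(as.vector(out$pixels))), 1L)
})

test_that("adaptive equalization pulls tile histograms toward the Rayleigh CDF", {
  # horizontal intensity ramp; per-tile KS distance to the Rayleigh target
  # must decrease after equalization
  alpha <- 0.4
  # intensity ramps along x; each 16 x 16 tile sees a narrow uniform slice
  ramp <- matrix(rep(seq(0, 65535, length.out = 128), each = 128), 128, 128)
  img <- gray_image(ramp, 16L)
  out <- equalize_adaptive(img, tile_grid = c(8, 8), clip_limit = 0.02,
                           rayleigh_alpha = alpha)
  rayleigh_cdf <- function(x) 1 - exp(-x^2 / (2 * alpha^2))
  vmax <- rayleigh_cdf(1)
  ks_to_rayleigh <- function(v) {
    # direct CDF evaluation: empirical CDF vs the Rayleigh target truncated
    # at the top of the intensity range (the mapping's convention)
    u <- sort(v) / 65535
    target <- rayleigh_cdf(u) / vmax
    emp <- seq_along(u) / length(u)
    max(abs(emp - target))
  }
  before <- after <- matrix(0, 8, 8)
  for (tx in 0:7) for (ty in 0:7) {
    rows <- (ty * 16 + 1):((ty + 1) * 16)
    cols <- (tx * 16 + 1):((tx + 1) * 16)
    before[ty + 1, tx + 1] <- ks_to_rayleigh(as.vector(ramp[rows, cols]))
    after[ty + 1, tx + 1] <- ks_to_rayleigh(as.vector(out$pixels[rows, cols]))
  }
  # bilinear blending between neighboring tile mappings can leave the tiles
  # whose input slice already sits at the Rayleigh bulk marginally worse on a
  # pure ramp, so the distance must drop in the large majority of tiles and
  # on average
  expect_gte(mean(after < before), 0.75)
  expect_lt(mean(after), mean(before))
})

test_that("adaptive equalization preserves rank order within tiles", {
  set.seed(4)
  vals <- matrix(sample(c(10, 200), 64 * 64, replace = TRUE), 64, 64)
  out <- equalize_adaptive(gray_image(vals, 8L), tile_grid = c(8, 8))
  # two-tone input stays two-tone per tile with the same ordering
  for (tx in 0:7) for (ty in 0:7) {
    tile_in <- vals[(ty * 8 + 1):((ty + 1) * 8), (tx * 8 + 1):((tx + 1) * 8)]
    tile_out <- out$pixels[(ty * 8 + 1):((ty + 1) * 8), (tx * 8 + 1):((tx + 1) * 8)]
    lo <- tile_out[tile_in == 10]; hi <- tile_out[tile_in == 200]
    if (length(lo) && length(hi)) expect_lt(max(lo), min(hi))
  }
})

test_that("adaptive equalization rejects images smaller than the tile grid", {
  expect_error(equalize_adaptive(gray_image(matrix(1:12, 3, 4), 8L), c(8, 8)),
               "at least 8 x 8")
})

test_that("Otsu threshold separates a bimodal image at the stated fraction", {
  set.seed(1)
  v <- sample(c(rep(10, 60), rep(200, 40)))
  img <- gray_image(matrix(v, 10, 10), 8L)
  thr <- binarize_otsu(img, return_threshold = TRUE)
  expect_gt(thr, 10); expect_lt(thr, 200)
  mask <- binarize_otsu(img)
  expect_equal(sum(mask), 40)
})

test_that("Otsu classification matches the brute-force between-class-variance argmax", {
  set.seed(7)
  for (rep in 1:3) {
    levels <- sample(0:255, sample(3:8, 1))
    v <- sample(levels, 900, replace = TRUE)
    img <- gray_image(matrix(v, 30, 30), 8L)
    thr <- binarize_otsu(img, return_threshold = TRUE)
    best <- -1; bt <- NA
    for (t in 0:254) {
      w0 <- mean(v <= t)
      if (w0 == 0 || w0 == 1) next
      m0 <- mean(v[v <= t]); m1 <- mean(v[v > t])
      s <- w0 * (1 - w0) * (m0 - m1)^2
      if (s > best) { best <- s; bt <- t }
    }
    expect_identical((v > thr), (v > bt))
  }
})

test_that("Otsu on a bright disk recovers the disk exactly and rejects constants", {
  img <- disk_image(15, frame = 50)
  mask <- binarize_otsu(img)
  expect_identical(mask > 0, img$pixels > 0)
  expect_error(binarize_otsu(gray_image(matrix(7, 5, 5), 8L)), "constant")
})

test_that("region cleaning enforces the area and border rules", {
  m <- matrix(0L, 120, 120)
  # region A: 900 px^2 (30 x 30), interior
  m[10:39, 10:39] <- 1L
  # region B: 799 px^2, interior
  m[60:( 60 + 16), 60:106] <- 1L   # 17 x 47 = 799
  expect_equal(sum(m[60:76, 60:106]), 17 * 47)
  lbl <- clean_regions(m, min_area = 800)
  expect_equal(attr(lbl, "region_count"), 1L)
  expect_equal(sum(lbl > 0), 900)

  # a large region overlapping the image edge is removed
  m2 <- matrix(0L, 120, 120)
  m2[1:60, 20:100] <- 1L
  lbl2 <- clean_regions(m2, min_area = 800)
  expect_equal(attr(lbl2, "region_count"), 0L)
})

test_that("region cleaning fills interior holes", {
  m <- matrix(0L, 80, 80)
  m[20:59, 20:59] <- 1L
  m[35:39, 35:44] <- 0L  # 50 px^2 hole
  lbl <- clean_regions(m, min_area = 800)
  expect_equal(sum(lbl > 0), 40 * 40)
})

test_that("region cleaning is idempotent", {
  set.seed(11)
  m <- matrix(0L, 150, 150)
  m[15:60, 15:60] <- 1L
  m[80:140, 70:130] <- 1L
  m[sample(150 * 150, 200)] <- 1L  # speckle
  once <- clean_regions(m, 800)
  twice <- clean_regions(once, 800)
  expect_identical(unclass(once), unclass(twice))
})

test_that("hull construction nets the stated size changes on a disk", {
  img <- disk_image(40, frame = 120)
  lbl <- clean_regions(binarize_otsu(img), 800)
  hulls <- build_hulls(lbl)
  expect_length(hulls, 1)
  # erode 3 then dilate 6 nets +3; inner erodes 2 more
  outer_area <- polygon_area(hulls[[1]]$outer)
  inner_area <- polygon_area(hulls[[1]]$inner)
  expect_lt(abs(outer_area / (pi * 43^2) - 1), 0.03)
  expect_lt(abs(inner_area / (pi * 41^2) - 1), 0.03)
  expect_lte(inner_area, outer_area)
  # inner hull vertices inside (or on) the outer hull
  iv <- as.matrix(hulls[[1]]$inner)
  expect_true(all(nucmorph:::points_in_polygon(iv[, 1], iv[, 2], hulls[[1]]$outer)))
})

test_that("hulls are convex (left turns only) and tiny regions are dropped", {
  img <- disk_image(40, frame = 120)
  lbl <- clean_regions(binarize_otsu(img), 800)
  h <- build_hulls(lbl)[[1]]
  for (poly in list(h$outer, h$inner)) {
    v <- as.matrix(poly)
    n <- nrow(v)
    a <- v[c(2:n, 1), ] - v
    b <- a[c(2:n, 1), ]
    cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    expect_true(all(cross >= -1e-9))
  }
  tiny <- matrix(0L, 30, 30); tiny[14:16, 14:16] <- 1L
  expect_warning(res <- build_hulls(tiny, 3, 6, 2), "dropped")
  expect_length(res, 0)
})

test_that("contrast stretch saturates the stated quantiles and keeps ranks", {
  v <- matrix(0:99, 10, 10)
  out <- stretch_contrast(gray_image(v, 8L), 0.01)
  expect_equal(min(out$pixels), 0)
  expect_equal(max(out$pixels), 255)
  # interior strictly increasing (rank preservation)
  mid <- out$pixels[order(v)][2:99]
  expect_true(all(diff(mid) > 0))
  # full-range uniform image unchanged up to rounding
  set.seed(2)
  u <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  u[1] <- 0; u[2] <- 255
  out2 <- stretch_contrast(gray_image(u, 8L), 0)
  expect_equal(out2$pixels, u, tolerance = 1e-12)
  # constant image unchanged
  k <- gray_image(matrix(42, 5, 5), 8L)
  expect_equal(stretch_contrast(k, 0.01)$pixels, k$pixels)
})

test_that("contrast stretch suppresses a single hot pixel", {
  set.seed(3)
  v <- matrix(sample(0:100, 2500, replace = TRUE), 50, 50)
  v[25, 25] <- 65535
  out <- stretch_contrast(gray_image(v, 16L), 0.01)
  expect_gt(max(out$pixels[-which.max(v)]), 0.95 * 65535)
})

test_that("near-binarization is a fixed point on binary images", {
  img <- disk_image(20, frame = 70)
  lbl <- clean_regions(binarize_otsu(img), 800)
  h <- build_hulls(lbl)[[1]]
  nb <- near_binarize(img, h)
  off <- attr(nb, "offset")
  sub <- img$pixels[(off[2] + 1):(off[2] + nb$height), (off[1] + 1):(off[1] + nb$width)]
  expect_equal(nb$pixels, sub)
})

test_that("near-binarization applies the 70%/130% threshold arithmetic", {
  set.seed(5)
  # full-height stripes (no enclosed basins, so hole filling is inert):
  # dark mode ~N(40, 5), a mid stripe at exactly 100, bright mode ~N(160, 5);
  # Otsu lands near 100, so dark < 0.7 T, bright > 1.3 T, mid in between
  v <- matrix(0, 60, 60)
  v[, 1:28] <- pmin(pmax(round(rnorm(60 * 28, 40, 5)), 20), 60)
  v[, 29:32] <- 100
  v[, 33:60] <- pmin(pmax(round(rnorm(60 * 28, 160, 5)), 140), 180)
  v[1, 1] <- 0; v[60, 60] <- 255  # pin the range so the stretch is identity
  img <- gray_image(v, 8L)
  hull <- list(outer = contour(cbind(c(0, 59, 59, 0), c(0, 0, 59, 59)), ccw = FALSE),
               region_label = 1L)
  nb <- near_binarize(img, hull, saturate_frac = 0)
  out <- nb$pixels
  expect_equal(dim(out), dim(v))
  # expected mapping from the module's own threshold: pixels below 0.7 T to
  # the minimum, above 1.3 T to the maximum, mid-range stretched linearly,
  # then gray-scale holes filled (checked against the independent oracle)
  T <- binarize_otsu(img, return_threshold = TRUE)
  want <- pmin(pmax((v - 0.7 * T) / (0.6 * T) * 255, 0), 255)
  expect_true(all(want[v < 0.7 * T] == 0))
  expect_true(all(want[v > 1.3 * T] == 255))
  mid_sel <- v > 0.7 * T & v < 1.3 * T
  expect_gt(sum(mid_sel), 0)
  expect_true(all(want[mid_sel] > 0 & want[mid_sel] < 255))
  expect_equal(out, fill_oracle(want), tolerance = 1e-9)
})

test_that("gray-scale hole filling matches an iterative reconstruction oracle", {
  set.seed(6)
  # rim image with a dark interior basin on a 20 x 20 grid
  px <- matrix(10, 20, 20)
  px[5:16, 5:16] <- 200
  px[8:13, 8:13] <- 30
  px <- px + matrix(sample(0:5, 400, TRUE), 20, 20)
  filled <- nucmorph:::fill_holes_gray(px, 255)
  expect_equal(filled, fill_oracle(px))
  # the interior basin was raised to its surrounding rim level
  expect_true(all(filled[9:12, 9:12] >= 200))
})

test_that("full preprocess finds exactly k hulls for k separated nuclei", {
  pop <- generate_population(4, seed = 21, nuclei_per_frame = 4L,
                             shape_dist = study_shape_dist(c(0.05, 0.2)))
  img <- pop$frames[[1]]
  eq <- equalize_adaptive(img)
  lbl <- clean_regions(binarize_otsu(eq), 800)
  hulls <- build_hulls(lbl)
  expect_length(hulls, 4)
})
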