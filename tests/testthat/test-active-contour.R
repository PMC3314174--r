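# Reference implementation of the GVF diffusion recurrence in plain R,
# used as an oracle for the compiled kernel.
gvf_oracle <- function(fx, fy, mu, iters) {
  u <- fx; v <- fy
  b <- fx^2 + fy^2
  nr <- nrow(fx); nc <- ncol(fx)
  up <- function(m) m[c(1, 1:(nr - 1)), ]
  dn <- function(m) m[c(2:nr, nr), ]
  lf <- function(m) m[, c(1, 1:(nc - 1))]
  rt <- function(m) m[, c(2:nc, nc)]
  for (i in seq_len(iters)) {
    lapu <- up(u) + dn(u) + lf(u) + rt(u) - 4 * u
    lapv <- up(v) + dn(v) + lf(v) + rt(v) - 4 * v
    u <- u + mu * lapu - b * (u - fx)
    v <- v + mu * lapv - b * (v - fy)
  }
  list(u = u, v = v)
}

test_that("GVF of a constant image is zero everywhere", {
  fld <- compute_gvf(gray_image(matrix(500, 32, 32), 16L), 80, 0.2)
  expect_true(all(fld$u == 0))
  expect_true(all(fld$v == 0))
})

test_that("compiled GVF diffusion matches the R recurrence oracle", {
  set.seed(9)
  fx <- matrix(rnorm(16 * 16), 16, 16)
  fy <- matrix(rnorm(16 * 16), 16, 16)
  fx <- fx / (2 * max(abs(fx))); fy <- fy / (2 * max(abs(fy)))
  got <- nucmorph:::.gvf_diffuse(fx, fy, 0.15, 12L)
  want <- gvf_oracle(fx, fy, 0.15, 12L)
  expect_equal(got$u, want$u, tolerance = 1e-12)
  expect_equal(got$v, want$v, tolerance = 1e-12)
})

test_that("GVF of a vertical step edge points toward the edge from both sides", {
  px <- matrix(0, 16, 16); px[, 9:16] <- 255
  fld <- compute_gvf(gray_image(px, 8L), 40, 0.2)
  # edge sits between columns 8 and 9 (0-based x ~ 7.5..8.5)
  expect_true(all(fld$u[, 2:6] > 0))     # left of edge: force points right
  expect_true(all(fld$u[, 11:15] < 0))   # right of edge: force points left
  expect_lt(max(abs(fld$v)), 1e-8)
})

test_that("one GVF step approaches uniform smoothing in the large-mu limit", {
  set.seed(10)
  fx <- matrix(rnorm(12 * 12, sd = 1e-3), 12, 12)  # negligible b = |grad f|^2
  fy <- matrix(rnorm(12 * 12, sd = 1e-3), 12, 12)
  got <- nucmorph:::.gvf_diffuse(fx, fy, 0.24, 1L)
  # with b ~ 0, a single step is u + mu * laplacian(u): pure smoothing
  want <- gvf_oracle(fx, fy, 0.24, 1L)
  expect_equal(got$u, want$u, tolerance = 1e-12)
  lap <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    m[c(1, 1:(nr - 1)), ] + m[c(2:nr, nr), ] + m[, c(1, 1:(nc - 1))] +
      m[, c(2:nc, nc)] - 4 * m
  }
  expect_equal(got$u, fx + 0.24 * lap(fx) - (fx^2 + fy^2) * 0, tolerance = 1e-5)
})

test_that("uniform resampling yields constant sides of length d_min", {
  sq <- square_contour(10, spacing = 2.5)
  out <- resample_contour(sq, d_min = 0.5, uniform = TRUE)
  expect_equal(nrow(out), 80)
  v <- as.matrix(out)
  d <- sqrt(rowSums((v[c(2:80, 1), ] - v)^2))
  expect_true(all(d > 0.45 & d < 0.55))
  expect_equal(polygon_perimeter(out), 40, tolerance = 0.01)
})

test_that("resampling is a fixed point on uniformly spaced contours", {
  circ <- circle_contour(20, n = round(2 * pi * 20 / 0.5))
  out <- resample_contour(circ, 0.5, 2, uniform = TRUE)
  expect_equal(as.matrix(out), as.matrix(circ), tolerance = 1e-6)
  out2 <- resample_contour(circ, 0.5, 2)
  expect_equal(nrow(out2), nrow(circ))
})

test_that("resampling keeps evolution spacing within [d_min, d_max]", {
  set.seed(12)
  th <- sort(runif(40, 0, 2 * pi))
  v <- cbind(30 * cos(th), 30 * sin(th)) + matrix(rnorm(80, 0, 0.3), ncol = 2)
  out <- resample_contour(contour(v), d_min = 0.5, d_max = 2)
  w <- as.matrix(out)
  d <- sqrt(rowSums((w[c(2:nrow(w), 1), ] - w)^2))
  expect_true(all(d >= 0.5 - 1e-9 & d <= 2 + 1e-9))
})

test_that("resampling rejects degenerate contours", {
  tiny <- contour(matrix(c(0, 0, 1e-4, 0, 0, 1e-4), ncol = 2, byrow = TRUE),
                  ccw = FALSE)
  expect_error(resample_contour(tiny, 0.5, 2), "degenerate")
})

# A near-binarized disk image and its GVF field, shared by the snake tests.
disk_field <- function(R = 30, frame = 90) {
  px <- rep(0:(frame - 1), each = frame)
  py <- rep(0:(frame - 1), times = frame)
  d <- sqrt((px - frame / 2)^2 + (py - frame / 2)^2)
  ramp <- pmin(pmax(R - d + 0.5, 0), 1)
  img <- gray_image(matrix(65535 * ramp, nrow = frame), 16L)
  list(img = img, field = compute_gvf(img))
}

test_that("snake converges onto a disk boundary with sub-pixel accuracy", {
  df <- disk_field(30, 90)
  init <- circle_contour(33, n = 100, center = c(45, 45))
  out <- evolve_snake(init, df$field)
  expect_lt(abs(polygon_area(out) / (pi * 900) - 1), 0.02)
  v <- as.matrix(out)
  r <- sqrt((v[, 1] - 45)^2 + (v[, 2] - 45)^2)
  expect_lt(mean(abs(r - 30)), 0.5)
})

test_that("with zero external force the contour area shrinks monotonically", {
  zero <- list(u = matrix(0, 90, 90), v = matrix(0, 90, 90))
  init <- circle_contour(30, n = 100, center = c(45, 45))
  areas <- vapply(1:3, function(k) {
    p <- snake_params(area_tol = 0, max_deformations = 75L * k)
    polygon_area(evolve_snake(init, zero, p))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("a huge area tolerance stops evolution after one batch", {
  df <- disk_field(30, 90)
  init <- circle_contour(33, n = 100, center = c(45, 45))
  out <- evolve_snake(init, df$field, snake_params(area_tol = 1e6))
  expect_equal(attr(out, "deformations"), 75L)
})

test_that("total deformations never exceed the cap", {
  zero <- list(u = matrix(0, 90, 90), v = matrix(0, 90, 90))
  init <- circle_contour(25, n = 80, center = c(45, 45))
  p <- snake_params(area_tol = 0, max_deformations = 1500L)
  out <- evolve_snake(init, zero, p)
  expect_lte(attr(out, "deformations"), 1500L)
})

test_that("the outer hull constrains the snake", {
  # inflating force field (points outward everywhere)
  frame <- 90
  px <- rep(0:(frame - 1), each = frame); py <- rep(0:(frame - 1), times = frame)
  dx <- px - 45; dy <- py - 45
  nm <- sqrt(dx^2 + dy^2) + 1e-9
  fld <- list(u = matrix(dx / nm, nrow = frame), v = matrix(dy / nm, nrow = frame))
  limit <- circle_contour(20, n = 60, center = c(45, 45))
  init <- circle_contour(15, n = 60, center = c(45, 45))
  out <- evolve_snake(init, fld, snake_params(area_tol = 0, max_deformations = 750L),
                      outer_limit = limit)
  v <- as.matrix(out)
  r <- sqrt((v[, 1] - 45)^2 + (v[, 2] - 45)^2)
  expect_true(all(r <= 20 + 0.05))
})

test_that("extraction recovers disk radii within 2% across sizes", {
  for (R in c(20, 40, 60)) {
    fs <- ceiling(2 * (R + 10))
    cnt <- sample_shape(shape_spec(R, center = c(fs / 2, fs / 2)))
    img <- render(cnt, render_spec(noise_sd = 0), frame_size = c(fs, fs))
    cc <- extract_nuclei(img)
    expect_length(cc, 1)
    r_est <- sqrt(polygon_area(cc[[1]]) / pi)
    expect_lt(abs(r_est / R - 1), 0.02)
  }
})

test_that("extracted contours are simple, CCW, and uniformly spaced", {
  pop <- generate_population(2, seed = 31, shape_dist = study_shape_dist(c(0.15, 0.3)))
  for (f in 1:2) {
    cc <- extract_nuclei(pop$frames[[f]])
    expect_length(cc, 1)
    v <- as.matrix(cc[[1]])
    expect_gt(nucmorph:::polygon_signed_area(v), 0)
    expect_true(is_simple_polygon(v))
    d <- sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2))
    expect_true(all(abs(d - 0.5) <= 0.05))
  }
})

test_that("extraction handles blank frames and border-touching nuclei", {
  blank <- gray_image(matrix(100, 100, 100), 16L)
  expect_length(extract_nuclei(blank), 0)
  # nucleus overlapping the frame edge is filtered out
  cnt <- sample_shape(shape_spec(25, center = c(50, 50)))
  img <- render(cnt, render_spec(noise_sd = 0), frame_size = c(110, 110))
  cropped <- gray_image(img$pixels[31:110, , drop = FALSE], 16L)
  expect_length(extract_nuclei(cropped), 0)
})

test_that("extraction is deterministic", {
  pop <- generate_population(1, seed = 55, shape_dist = study_shape_dist(c(0.2, 0.2)))
  a <- extract_nuclei(pop$frames[[1]])
  b <- extract_nuclei(pop$frames[[1]])
  expect_identical(as.matrix(a[[1]]), as.matrix(b[[1]]))
})

test_that("curation removes contours containing exclusion points", {
  c1 <- circle_contour(10, 60, center = c(20, 20))
  c2 <- circle_contour(10, 60, center = c(60, 20))
  c3 <- circle_contour(10, 60, center = c(100, 20))
  kept <- curate(list(c1, c2, c3), cbind(60, 20))
  expect_length(kept, 2)
  expect_identical(kept, list(c1, c3))
  # empty exclusion list is the identity
  expect_identical(curate(list(c1, c2), NULL), list(c1, c2))
  expect_identical(curate(list(c1, c2), matrix(numeric(0), ncol = 2)), list(c1, c2))
  # a point inside two overlapping contours removes both
  o1 <- circle_contour(10, 60, center = c(20, 20))
  o2 <- circle_contour(10, 60, center = c(26, 20))
  expect_length(curate(list(o1, o2), cbind(23, 20)), 0)
  # a pointless exclusion warns and is ignored
  expect_warning(kept2 <- curate(list(c1), cbind(500, 500)), "no contour")
  expect_length(kept2, 1)
})
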