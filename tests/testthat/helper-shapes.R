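# Analytic fixtures used across tests: all built in code, no stored data.

circle_contour <- function(R, n = 720, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1)) / n
  contour(cbind(center[1] + R * cos(th), center[2] + R * sin(th)))
}

# k-lobed flower r(theta) = R (1 + a cos(k theta)); valleys are strictly
# concave iff a k^2 > 1 - a.
flower_contour <- function(R, k, a = 0.25, n = 720, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1)) / n
  r <- R * (1 + a * cos(k * th))
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

square_contour <- function(side = 10, spacing = 0.5, origin = c(0, 0)) {
  m <- round(side / spacing)
  s <- seq(0, side, length.out = m + 1)[-(m + 1)]
  v <- rbind(cbind(s, 0), cbind(side, s), cbind(side - s, side), cbind(0, side - s))
  contour(cbind(origin[1] + v[, 1], origin[2] + v[, 2]), ccw = FALSE)
}

# Binary disk mask as a gray_image (value `hi` inside radius R).
disk_image <- function(R, frame = ceiling(2 * (R + 10)), hi = 255, bit_depth = 8L,
                       center = c(frame / 2, frame / 2)) {
  px <- rep(0:(frame - 1), each = frame)
  py <- rep(0:(frame - 1), times = frame)
  d <- sqrt((px - center[1])^2 + (py - center[2])^2)
  gray_image(matrix(ifelse(d <= R, hi, 0), nrow = frame), bit_depth)
}

# Extract MNC values for a generated population, matched to ground truth.
extract_population_mnc <- function(pop, offset = 25L) {
  out <- NULL
  for (f in seq_along(pop$frames)) {
    cc <- suppressWarnings(extract_nuclei(pop$frames[[f]]))
    if (!length(cc)) next
    ids <- match_truth(cc, pop$truth[pop$truth$frame == f, ])
    mnc <- vapply(cc, function(ct) mean_negative_curvature(signed_curvature(ct, offset)),
                  numeric(1))
    out <- rbind(out, data.frame(nucleus = ids, mnc = mnc))
  }
  out
}

# Independent oracle for gray-scale hole filling: iterate
# marker = max(4-neighbour erosion of marker, image) to convergence, from a
# marker that is maximal everywhere except the border.
fill_oracle <- function(px, top = 255) {
  nr <- nrow(px); nc <- ncol(px)
  marker <- matrix(top, nr, nc)
  marker[1, ] <- px[1, ]; marker[nr, ] <- px[nr, ]
  marker[, 1] <- px[, 1]; marker[, nc] <- px[, nc]
  erode4 <- function(m) {
    up <- rbind(m[1, ], m[-nr, ]); dn <- rbind(m[-1, ], m[nr, ])
    lf <- cbind(m[, 1], m[, -nc]); rt <- cbind(m[, -1], m[, nc])
    pmin(m, up, dn, lf, rt)
  }
  repeat {
    nxt <- pmax(erode4(marker), px)
    if (identical(nxt, marker)) return(marker)
    marker <- nxt
  }
}

# The shared shape distribution of the synthetic experiments, with the bleb
# depth range as the condition under study.
study_shape_dist <- function(depth) {
  list(radius = c(22, 30), axis_ratio = c(1, 1.4), bleb_count = c(2L, 5L),
       depth = depth, width = 0.15)
}
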