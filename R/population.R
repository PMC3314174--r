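#' Assemble a population table
#'
#' Bundles per-nucleus metrics rows, their curvature profiles with matching
#' contours, and a group label (cell line / treatment / density) per nucleus.
#'
#' @param metrics Data frame with one [metric_table()] row per nucleus.
#' @param profiles List of curvature profiles, one per row.
#' @param contours List of matching [contour] objects (needed for arc-length
#'   positions in heat maps); may be NULL if no heat map will be built.
#' @param group Character vector of group labels (recycled if length 1).
#' @return An object of class `population`.
#' @export
population_table <- function(metrics, profiles = NULL, contours = NULL,
                             group = "all") {
  n <- nrow(metrics)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) stop("one group label per metrics row required")
  if (!is.null(profiles) && length(profiles) != n)
    stop("profile count must match metrics row count")
  metrics$group <- group
  structure(list(metrics = metrics, profiles = profiles, contours = contours),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d nuclei, %d group(s): %s\n", nrow(x$metrics),
              length(unique(x$metrics$group)),
              paste(unique(x$metrics$group), collapse = ", ")))
  invisible(x)
}

#' MNC-sorted curvature heat map
#'
#' Builds the population curvature matrix: each column is one nucleus'
#' signed-curvature profile, cut at the boundary point farthest from the
#' centroid (position 0), stretched to `n_rows` values by normalized arc
#' length, clipped at `±cutoff`, and columns ordered left to right by
#' increasing MNC.
#'
#' @param pop A [population_table()] with profiles and contours.
#' @param n_rows Number of resampled boundary positions (default 200).
#' @param cutoff Display clip for curvature magnitudes, 1/pixel
#'   (default 0.15).
#' @return A `heatmap_matrix`: `n_rows` x n_nuclei matrix with attributes
#'   `column_order` (original nucleus indices) and `cutoff`.
#' @export
heatmap_matrix <- function(pop, n_rows = 200L, cutoff = 0.15) {
  if (!inherits(pop, "population")) stop("`pop` must be a population")
  n <- nrow(pop$metrics)
  if (n == 0) stop("empty population: no nuclei to map")
  if (is.null(pop$profiles) || is.null(pop$contours))
    stop("heat map needs profiles and contours in the population")
  cols <- matrix(NA_real_, n_rows, n)
  for (i in seq_len(n)) {
    rot <- rotate_to_start(pop$contours[[i]], pop$profiles[[i]])
    v <- as.matrix(rot$contour)
    k <- as.numeric(rot$profile)
    s <- cumulative_arc(v)
    per <- s[length(s)]
    t_out <- per * (0:(n_rows - 1)) / n_rows
    cols[, i] <- interp_cyclic(s, c(k, k[1]), t_out)
  }
  cols <- pmin(pmax(cols, -cutoff), cutoff)
  mnc <- vapply(pop$profiles, mean_negative_curvature, numeric(1))
  ord <- order(mnc)
  structure(cols[, ord, drop = FALSE], column_order = ord, mnc = mnc[ord],
            cutoff = cutoff, class = c("heatmap_matrix", "matrix"))
}

#' Render a curvature heat map to PNG
#'
#' @param hm A [heatmap_matrix()].
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @export
plot_heatmap <- function(hm, path, width = 900, height = 500) {
  cutoff <- attr(hm, "cutoff")
  pal <- colorRampPalette(c("darkred", "red", "yellow", "green", "cyan", "blue"))(255)
  grDevices::png(path, width = width, height = height)
  op <- graphics::par(mar = c(4, 4, 2, 6))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(x = seq_len(ncol(hm)), y = seq_len(nrow(hm)),
                  z = t(unclass(hm)[rev(seq_len(nrow(hm))), , drop = FALSE]),
                  zlim = c(-cutoff, cutoff), col = pal,
                  xlab = "nucleus (increasing MNC)", ylab = "boundary position",
                  main = "Boundary curvature")
  invisible(path)
}

#' One-tailed Welch t-test
#'
#' Unequal-variance (Welch) two-sample t-test with Welch-Satterthwaite
#' degrees of freedom and a one-tailed p-value in the stated direction.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param direction `"less"` tests mean(a) < mean(b); `"greater"` the
#'   opposite.
#' @return `list(t, df, p)`.
#' @export
welch_t_one_tailed <- function(a, b, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples have zero variance; t statistic undefined")
  ht <- stats::t.test(a, b, alternative = direction, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Correlation structure and hierarchical clustering of shape measures
#'
#' Computes the pairwise correlation matrix over metric columns and clusters
#' the measures agglomeratively with distance `1 - |r|` and average linkage.
#' Constant columns are excluded with a warning.
#'
#' @param pop A [population_table()] or a plain metrics data frame.
#' @param metrics Metric columns to use (default: the intersection of
#'   [metric_panel()] with available, non-NA columns).
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return `list(correlation, hclust, dendrogram)` with the dendrogram as a
#'   serializable nested list.
#' @export
metric_clustering <- function(pop, metrics = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- if (inherits(pop, "population")) pop$metrics else as.data.frame(pop)
  if (is.null(metrics))
    metrics <- intersect(metric_panel(), names(df))
  mat <- as.matrix(df[, metrics, drop = FALSE])
  mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  if (nrow(mat) < 10) stop("metric clustering needs at least 10 nuclei")
  keep <- apply(mat, 2, function(x) stats::sd(x) > 0)
  if (any(!keep))
    warning("constant metric column(s) excluded: ",
            paste(colnames(mat)[!keep], collapse = ", "))
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 3) stop("metric clustering needs at least 3 varying metrics")
  r <- stats::cor(mat, method = method)
  hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = "average")
  list(correlation = r, hclust = hc, dendrogram = dendrogram_list(hc))
}

# hclust merge tree as a nested list (JSON-serializable).
dendrogram_list <- function(hc) {
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         left = build(hc$merge[i, 1]),
         right = build(hc$merge[i, 2]))
  }
  build(nrow(hc$merge))
}

# Labels of the two leaf clusters obtained by cutting the tree into k groups.
cut_clusters <- function(hc, k) {
  grp <- stats::cutree(hc, k = k)
  split(names(grp), grp)
}

#' Per-group distribution summaries
#'
#' Box-plot statistics per group and metric: n, mean, median, quartiles
#' (linear-interpolation convention, R type 7) and whiskers by the 1.5 * IQR
#' rule (most extreme observations within the fences).
#'
#' @param pop A [population_table()] or metrics data frame with a `group`
#'   column.
#' @param metrics Metric columns to summarize (default [metric_panel()]
#'   columns present).
#' @return Data frame with one row per group x metric.
#' @export
group_summary <- function(pop, metrics = NULL) {
  df <- if (inherits(pop, "population")) pop$metrics else as.data.frame(pop)
  if (is.null(df$group)) df$group <- "all"
  if (is.null(metrics)) metrics <- intersect(metric_panel(), names(df))
  rows <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, , drop = FALSE]
    for (m in metrics) {
      x <- sub[[m]]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = length(x), mean = mean(x),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
        whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
    }
  }
  do.call(rbind, rows)
}
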