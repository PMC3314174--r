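#' Write contours to JSON
#'
#' Stable interchange format: a JSON object with a format version and one
#' record per nucleus (`image`, `nucleus_id`, `vertices` as an n x 2 array).
#'
#' @param contours Named list: one element per image, each a list of
#'   [contour]s.
#' @param path Output path.
#' @export
write_contours <- function(contours, path) {
  recs <- list()
  for (img_name in names(contours)) {
    for (i in seq_along(contours[[img_name]])) {
      cnt <- contours[[img_name]][[i]]
      recs[[length(recs) + 1L]] <- list(
        image = img_name, nucleus_id = i,
        vertices = unname(as.matrix(cnt)))
    }
  }
  jsonlite::write_json(list(format = "nucmorph-contours", version = "1",
                            contours = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read contours from JSON
#' @param path File written by [write_contours()].
#' @return Named list of contour lists, one element per image.
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(obj$format, "nucmorph-contours"))
    stop("not a nucmorph contour file: ", path)
  out <- list()
  recs <- obj$contours
  for (k in seq_len(length(recs$image))) {
    img <- recs$image[k]
    cnt <- contour(recs$vertices[[k]], ccw = FALSE)
    if (is.null(out[[img]])) out[[img]] <- list()
    out[[img]][[recs$nucleus_id[k]]] <- cnt
  }
  out
}

#' Compute metrics for extracted contours of one image
#'
#' @param contours List of [contour]s from [extract_nuclei()].
#' @param img The source [gray_image] (for intensity statistics).
#' @param config A [pipeline_config()].
#' @param image_id Identifier recorded in the output rows.
#' @return `list(metrics, profiles)`: a data frame with one row per nucleus
#'   and the matching curvature profiles.
#' @export
image_metrics <- function(contours, img = NULL, config = NULL, image_id = "image") {
  cfg <- if (is.null(config)) pipeline_config() else config
  off <- cfg$metrics$curvature_offset
  ps <- cfg$metrics$pixel_size
  rows <- list(); profs <- list()
  for (i in seq_along(contours)) {
    cnt <- contours[[i]]
    prof <- signed_curvature(cnt, off)
    m <- metric_table(cnt, prof, img, pixel_size = ps)
    m <- cbind(data.frame(image = image_id, nucleus_id = i), m)
    rows[[i]] <- m
    profs[[i]] <- prof
  }
  list(metrics = if (length(rows)) do.call(rbind, rows) else NULL,
       profiles = profs)
}

#' Run the end-to-end analysis pipeline
#'
#' Reads every TIFF/PNG frame under `image_dir` (group labels taken from
#' first-level subdirectory names when present), extracts nucleus boundaries,
#' applies file-driven curation, computes the metric panel, and writes the
#' artifact bundle to `out_dir`: `contours.json`, `metrics.csv`,
#' `heatmap.csv` (+ `heatmap.png`), `summary.csv`, `stats.json` (pairwise
#' one-tailed Welch tests on MNC when there are >= 2 groups), and `run.log`.
#'
#' @param image_dir Directory of input frames.
#' @param out_dir Output directory (created if missing).
#' @param config A `pipeline_config` (defaults if NULL).
#' @param exclusions Optional data frame with columns `image`, `x`, `y` of
#'   curation points.
#' @param channel Channel index for multi-channel inputs.
#' @return Invisibly, the assembled [population_table()].
#' @export
run_pipeline <- function(image_dir, out_dir, config = NULL, exclusions = NULL,
                         channel = NULL) {
  cfg <- validate_config(if (is.null(config)) pipeline_config() else config)
  rels <- list.files(image_dir, pattern = "\\.(tif|tiff|png)$", recursive = TRUE,
                     ignore.case = TRUE)
  if (length(rels) == 0) stop("no TIFF/PNG images found under ", image_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  log_lines <- c(sprintf("nucmorph run, config checksum %d, %d image(s)",
                         sum(utf8ToInt(cfg_yaml)), length(rels)))

  all_contours <- list(); all_metrics <- list(); all_profiles <- list()
  all_cnt_flat <- list(); groups <- character(0)
  for (rel in rels) {
    f <- file.path(image_dir, rel)
    grp <- if (grepl("/", rel)) strsplit(rel, "/")[[1]][1] else "all"
    img <- tryCatch(read_gray(f, channel = channel), error = function(e) {
      log_lines <<- c(log_lines, sprintf("ERROR reading %s: %s", rel, conditionMessage(e)))
      NULL
    })
    if (is.null(img)) next
    cnts <- withCallingHandlers(
      extract_nuclei(img, cfg),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("WARN %s: %s", rel, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (!is.null(exclusions)) {
      ex <- exclusions[exclusions$image == rel, c("x", "y"), drop = FALSE]
      if (nrow(ex)) cnts <- suppressWarnings(curate(cnts, ex))
    }
    all_contours[[rel]] <- cnts
    if (length(cnts)) {
      im <- image_metrics(cnts, img, cfg, image_id = rel)
      all_metrics[[rel]] <- im$metrics
      all_profiles <- c(all_profiles, im$profiles)
      all_cnt_flat <- c(all_cnt_flat, cnts)
      groups <- c(groups, rep(grp, length(cnts)))
    }
    log_lines <- c(log_lines, sprintf("image %s: %d nucleus(ei)", rel, length(cnts)))
  }

  write_contours(all_contours, file.path(out_dir, "contours.json"))
  metrics <- if (length(all_metrics)) do.call(rbind, all_metrics) else NULL
  if (is.null(metrics)) {
    writeLines(c(log_lines, "no nuclei extracted"), log_path)
    warning("no nuclei extracted from ", image_dir)
    return(invisible(NULL))
  }
  pop <- population_table(metrics, all_profiles, all_cnt_flat, group = groups)
  write.csv(pop$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  hm <- heatmap_matrix(pop, cfg$population$heatmap_rows, cfg$population$curvature_cutoff)
  write.csv(unclass(hm), file.path(out_dir, "heatmap.csv"), row.names = FALSE)
  plot_heatmap(hm, file.path(out_dir, "heatmap.png"))
  write.csv(group_summary(pop), file.path(out_dir, "summary.csv"), row.names = FALSE)

  gs <- unique(groups)
  if (length(gs) >= 2) {
    tests <- list()
    for (i in seq_along(gs)) for (j in seq_along(gs)) if (i < j) {
      a <- pop$metrics$mnc[groups == gs[i]]
      b <- pop$metrics$mnc[groups == gs[j]]
      if (length(a) >= 2 && length(b) >= 2) {
        wt <- welch_t_one_tailed(a, b, "less")
        tests[[paste(gs[i], "vs", gs[j])]] <-
          c(list(metric = "mnc", direction = paste(gs[i], "<", gs[j])), wt)
      }
    }
    jsonlite::write_json(list(format = "nucmorph-stats", version = "1", tests = tests),
                         file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(log_lines, log_path)
  invisible(pop)
}
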