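#' Default pipeline configuration
#'
#' All numeric parameters of the extraction and analysis pipeline, grouped by
#' stage, with the published operating point as defaults. Serialize with
#' [write_config()] / [read_config()] (YAML).
#'
#' @return Nested named list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    version = "1",
    preprocess = list(
      tile_grid = c(8L, 8L), clip_limit = 0.02, rayleigh_alpha = 0.4,
      min_area = 800, outer_erode_r = 3, outer_dilate_r = 6, inner_erode_r = 2,
      saturate_frac = 0.01, low_frac = 0.7, high_frac = 1.3, crop_margin = 5L),
    snake = list(
      gvf_iterations = 80L, gvf_mu = 0.2, d_min = 0.5, d_max = 2,
      alpha = 0.02, beta = 0.05, gamma = 1, kappa = 0.6,
      batch_size = 75L, area_tol = 10, max_deformations = 50025L),
    metrics = list(curvature_offset = 25L, pixel_size = 1),
    population = list(heatmap_rows = 200L, curvature_cutoff = 0.15,
                      correlation = "pearson", linkage = "average")),
    class = "pipeline_config")
}

config_ranges <- function() list(
  preprocess = list(
    tile_grid = c(1, 64), clip_limit = c(0, 1), rayleigh_alpha = c(1e-6, 10),
    min_area = c(0, Inf), outer_erode_r = c(0, 50), outer_dilate_r = c(0, 50),
    inner_erode_r = c(0, 50), saturate_frac = c(0, 0.499), low_frac = c(0, 1),
    high_frac = c(1, 10), crop_margin = c(0, 100)),
  snake = list(
    gvf_iterations = c(1, 1e5), gvf_mu = c(1e-6, 0.25), d_min = c(0.01, 10),
    d_max = c(0.02, 50), alpha = c(1e-9, 100), beta = c(1e-9, 100),
    gamma = c(1e-9, 100), kappa = c(1e-9, 100), batch_size = c(1, 1e5),
    area_tol = c(0, 1e6), max_deformations = c(1, 1e8)),
  metrics = list(curvature_offset = c(2, 500), pixel_size = c(1e-9, 1e6)),
  population = list(heatmap_rows = c(10, 1e4), curvature_cutoff = c(1e-6, 10),
                    correlation = NULL, linkage = NULL))

#' Validate a pipeline configuration
#'
#' Checks every parameter against its allowed range and rejects unknown keys.
#'
#' @param cfg Nested list as produced by [pipeline_config()] or
#'   [read_config()].
#' @return The validated config (invisibly classed `pipeline_config`).
#' @export
validate_config <- function(cfg) {
  ref <- pipeline_config()
  ranges <- config_ranges()
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in setdiff(names(ref), "version")) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- ref[[sec]]; next }
    extra <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ", paste(extra, collapse = ", "))
    for (key in names(ref[[sec]])) {
      if (is.null(cfg[[sec]][[key]])) { cfg[[sec]][[key]] <- ref[[sec]][[key]]; next }
      rng <- ranges[[sec]][[key]]
      val <- cfg[[sec]][[key]]
      if (!is.null(rng)) {
        if (!is.numeric(val) || any(!is.finite(val)) ||
            any(val < rng[1]) || any(val > rng[2]))
          stop(sprintf("config %s.%s = %s outside allowed range [%g, %g]",
                       sec, key, paste(val, collapse = ","), rng[1], rng[2]))
      }
    }
  }
  if (cfg$snake$d_min >= cfg$snake$d_max) stop("config: d_min must be < d_max")
  if (cfg$preprocess$low_frac >= cfg$preprocess$high_frac)
    stop("config: low_frac must be < high_frac")
  if (is.null(cfg$version)) cfg$version <- "1"
  class(cfg) <- "pipeline_config"
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return Validated `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Write a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
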