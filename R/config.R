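#' Pipeline configuration
#'
#' Collects every tunable parameter of the quantification pipeline, with the
#' defaults used throughout the package.  Any subset can be overridden; the
#' result is validated.
#'
#' @param segmentation list: `smoothing_sigma_px`, `seed_min_distance_px`,
#'   `watershed_tolerance`, `min_nucleus_area_um2`, `max_nucleus_area_um2`.
#' @param tumor list: `threshold_method` (`"otsu"` or `"fixed:<v>"`),
#'   `smoothing_sigma_px`, `min_hole_um2`, `min_overlap_fraction`.
#' @param marker list: `background_radius_um`, `clahe_tile_px`,
#'   `clahe_clip_limit`, `clahe_bins`, `binarize_method`,
#'   `control_percentile`.
#' @param scoring list: `low`, `high` (strict trogocytic coverage bounds),
#'   `exclude_border`.
#' @param trogosome list: `diameter_range_um` (ordered positive pair),
#'   `large_cutoff_um` (within the range), `n_scales`, `response_threshold`.
#' @param seed integer seed recorded in run manifests.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = list(), tumor = list(),
                            marker = list(), scoring = list(),
                            trogosome = list(), seed = 1L) {
  cfg <- list(
    segmentation = modifyList(list(
      smoothing_sigma_px = 2,
      seed_min_distance_px = 5,
      watershed_tolerance = 1,
      min_nucleus_area_um2 = 8,
      max_nucleus_area_um2 = 150), segmentation),
    tumor = modifyList(list(
      threshold_method = "otsu",
      smoothing_sigma_px = 1,
      min_hole_um2 = 25,
      min_overlap_fraction = 0.5), tumor),
    marker = modifyList(list(
      background_radius_um = 12.5,
      clahe_tile_px = 64,
      clahe_clip_limit = 0.01,
      clahe_bins = 256L,
      binarize_method = "otsu",
      control_percentile = 99), marker),
    scoring = modifyList(list(
      low = 0.55,
      high = 0.90,
      exclude_border = FALSE), scoring),
    trogosome = modifyList(list(
      diameter_range_um = c(1, 10),
      large_cutoff_um = 5,
      n_scales = 12L,
      response_threshold = 0.05), trogosome),
    seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  s <- cfg$scoring
  if (!(s$low >= 0 && s$low < s$high && s$high <= 1))
    stop_validation("scoring bounds need 0 <= low < high <= 1")
  tr <- cfg$trogosome
  if (length(tr$diameter_range_um) != 2L || any(tr$diameter_range_um <= 0) ||
      diff(tr$diameter_range_um) <= 0)
    stop_validation("trogosome diameter_range_um must be a positive ordered pair")
  if (tr$large_cutoff_um < tr$diameter_range_um[1] ||
      tr$large_cutoff_um > tr$diameter_range_um[2])
    stop_validation("large_cutoff_um must lie within diameter_range_um")
  if (cfg$segmentation$min_nucleus_area_um2 < 0 ||
      cfg$segmentation$min_nucleus_area_um2 >=
        cfg$segmentation$max_nucleus_area_um2)
    stop_validation("need 0 <= min_nucleus_area_um2 < max_nucleus_area_um2")
  if (cfg$tumor$min_overlap_fraction < 0 || cfg$tumor$min_overlap_fraction > 1)
    stop_validation("min_overlap_fraction must lie in [0, 1]")
  if (cfg$marker$background_radius_um <= 0)
    stop_validation("background_radius_um must be > 0")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipeline_config()] sections; omitted entries keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(segmentation = y$segmentation %||% list(),
                  tumor = y$tumor %||% list(),
                  marker = y$marker %||% list(),
                  scoring = y$scoring %||% list(),
                  trogosome = y$trogosome %||% list(),
                  seed = y$seed %||% 1L)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
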