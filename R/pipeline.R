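#' Run the full per-cell marker quantification pipeline on one field
#'
#' Stages: nuclei segmentation (or external labels) and size filtering,
#' tumor-mask binarization, tumor-nucleus selection, Voronoi territories,
#' marker conditioning (rolling-ball background subtraction, optional
#' CLAHE), binarization, and per-cell scoring.
#'
#' @param img an [multichannel_image()] with roles `nuclei`, `tumor_marker`
#'   and `trogo_marker`.
#' @param config a [pipeline_config()].
#' @param labels optional externally produced [nuclei_labels()] (e.g. from
#'   [read_label_image()]); when given, the built-in detector is skipped but
#'   the size filter still applies.
#' @param gate optional [control_threshold()] gate for the expression call.
#' @return A list of class `quantify_result`: `nuclei` (filtered), `tumor`,
#'   `tumor_nuclei`, `cells`, `processed` (background-subtracted marker
#'   channel), `normalized` (CLAHE output or `NULL`), `marker`
#'   (the binary marker mask), `records` (per-cell table), `sample`
#'   (one-row summary), `config`.
#' @export
quantify_field <- function(img, config = pipeline_config(), labels = NULL,
                           gate = NULL) {
  stopifnot(inherits(img, "mc_image"), inherits(config, "pipeline_config"))
  require_roles(img, c("nuclei", "tumor_marker", "trogo_marker"))
  px <- img$pixel_size_um
  geo <- field_geometry(img, config, labels)
  proc <- subtract_background(channel(img, "trogo_marker"),
                              config$marker$background_radius_um, px)
  use_clahe <- config$marker$use_clahe %||% TRUE
  norm <- if (use_clahe)
    clahe_normalize(proc, config$marker$clahe_tile_px,
                    config$marker$clahe_clip_limit, config$marker$clahe_bins)
  else NULL
  marker <- binarize_marker(
    norm %||% proc,
    method = config$marker$binarize_method,
    gate = gate,
    provenance = list(background_radius_um = config$marker$background_radius_um,
                      clahe = use_clahe,
                      clahe_tile_px = config$marker$clahe_tile_px,
                      clahe_clip_limit = config$marker$clahe_clip_limit))
  records <- cell_records(geo$cells, marker, proc, px, gate = gate,
                          low = config$scoring$low, high = config$scoring$high,
                          source_id = img$source_id,
                          exclude_border = config$scoring$exclude_border)
  structure(list(nuclei = geo$nuclei, tumor = geo$tumor,
                 tumor_nuclei = geo$tumor_nuclei, cells = geo$cells,
                 processed = proc, normalized = norm, marker = marker,
                 records = records,
                 sample = summarize_sample(records),
                 config = config),
            class = "quantify_result")
}

# Shared geometry stages: nuclei -> filter -> tumor mask -> selection ->
# territories.
field_geometry <- function(img, config, labels = NULL) {
  px <- img$pixel_size_um
  seg <- config$segmentation
  nuclei <- labels %||% detect_nuclei(
    channel(img, "nuclei"),
    smoothing_sigma_px = seg$smoothing_sigma_px,
    seed_min_distance_px = seg$seed_min_distance_px,
    watershed_tolerance = seg$watershed_tolerance)
  nuclei <- filter_nuclei(nuclei, seg$min_nucleus_area_um2,
                          seg$max_nucleus_area_um2, px)
  tumor <- binarize_tumor_marker(channel(img, "tumor_marker"),
                                 method = config$tumor$threshold_method,
                                 smoothing_sigma_px = config$tumor$smoothing_sigma_px,
                                 min_hole_um2 = config$tumor$min_hole_um2,
                                 pixel_size_um = px)
  tumor_nuclei <- select_tumor_nuclei(nuclei, tumor,
                                      config$tumor$min_overlap_fraction)
  cells <- if (tumor_nuclei$count > 0L) voronoi_territories(tumor_nuclei, tumor)
  else suppressWarnings(voronoi_territories(tumor_nuclei, tumor))
  list(nuclei = nuclei, tumor = tumor, tumor_nuclei = tumor_nuclei,
       cells = cells)
}

#' @export
print.quantify_result <- function(x, ...) {
  s <- x$sample
  cat(sprintf(paste0("<quantify_result> %s: %d tumor cells, %s%% expressing, ",
                     "%.1f%% trogocytic\n"),
              s$source_id, s$n_tumor_cells,
              ifelse(is.na(s$pct_expressing), "NA",
                     sprintf("%.1f", s$pct_expressing)),
              s$pct_trogocytic))
  invisible(x)
}

#' Calibrate the expression gate from control fields
#'
#' Runs the geometry and marker-conditioning stages on secondary-antibody-
#' only control images, pools the per-cell mean intensities of the
#' background-subtracted marker channel, and returns the percentile gate.
#'
#' @param imgs list of control `mc_image`s (or a single one).
#' @param config a [pipeline_config()].
#' @param labels optional list of external [nuclei_labels()], parallel to
#'   `imgs`.
#' @return A [control_threshold()] gate.
#' @export
control_gate_from_fields <- function(imgs, config = pipeline_config(),
                                     labels = NULL) {
  if (inherits(imgs, "mc_image")) imgs <- list(imgs)
  ints <- unlist(lapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]
    geo <- field_geometry(img, config,
                          if (!is.null(labels)) labels[[i]] else NULL)
    if (geo$cells$n_cells == 0L) return(numeric(0))
    proc <- subtract_background(channel(img, "trogo_marker"),
                                config$marker$background_radius_um,
                                img$pixel_size_um)
    idx <- geo$cells$territories > 0L
    as.numeric(rowsum(as.numeric(proc[idx]), geo$cells$territories[idx],
                      reorder = TRUE)) / geo$cells$areas_px
  }))
  control_threshold(ints, config$marker$control_percentile)
}

#' Run the trogosome detection pipeline on one co-culture field
#'
#' Geometry stages as in [quantify_field()] (the `tumor_marker` role holds
#' the cell-body stain for co-cultures), then background subtraction and
#' scale-space trogosome detection with per-timepoint summary.
#'
#' @inheritParams quantify_field
#' @param timepoint timepoint label carried into the summary.
#' @return A list of class `trogosome_result`: geometry stages plus
#'   `trogosomes` (detection table) and `summary` (one-row
#'   [summarize_timepoint()] table).
#' @export
trogosome_field <- function(img, config = pipeline_config(), labels = NULL,
                            timepoint = NA_character_) {
  stopifnot(inherits(img, "mc_image"), inherits(config, "pipeline_config"))
  require_roles(img, c("nuclei", "tumor_marker", "trogo_marker"))
  px <- img$pixel_size_um
  geo <- field_geometry(img, config, labels)
  proc <- subtract_background(channel(img, "trogo_marker"),
                              config$marker$background_radius_um, px)
  tr <- config$trogosome
  trogosomes <- detect_trogosomes(proc, geo$cells, geo$tumor_nuclei, px,
                                  diameter_range_um = tr$diameter_range_um,
                                  large_cutoff_um = tr$large_cutoff_um,
                                  n_scales = tr$n_scales,
                                  response_threshold = tr$response_threshold,
                                  source_id = img$source_id)
  structure(list(nuclei = geo$nuclei, tumor = geo$tumor,
                 tumor_nuclei = geo$tumor_nuclei, cells = geo$cells,
                 processed = proc, trogosomes = trogosomes,
                 summary = summarize_timepoint(trogosomes, geo$cells,
                                               timepoint, tr$large_cutoff_um),
                 config = config),
            class = "trogosome_result")
}

#' @export
print.trogosome_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<trogosome_result> %d cells, %d trogosome(s), ",
                     "%.1f%% of cells with a large trogosome\n"),
              s$n_cells, s$n_trogosomes, s$pct_with_large_trogosome))
  invisible(x)
}

#' Build a reproducibility manifest for a run
#'
#' Records the package version, full configuration snapshot, seed, input
#' file MD5 hashes and timestamps; for the deterministic stages the
#' manifest fully determines the outputs.
#'
#' @param config a [pipeline_config()].
#' @param input_paths character vector of input files (hashed if they
#'   exist).
#' @param seed the seed used for any stochastic stage.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, input_paths = character(0),
                         seed = config$seed) {
  hashes <- if (length(input_paths))
    unname(tools::md5sum(input_paths[file.exists(input_paths)])) else
    character(0)
  structure(list(package = "trogoscan",
                 version = as.character(utils::packageVersion("trogoscan")),
                 created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                 seed = seed,
                 config = unclass(config),
                 inputs = data.frame(
                   path = input_paths[file.exists(input_paths)],
                   md5 = hashes)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
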