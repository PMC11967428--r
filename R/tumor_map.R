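#' Binarize the tumor-marker (pan-cytokeratin) channel into a tumor mask
#'
#' Smooths the channel, applies a global threshold (Otsu or fixed), and
#' fills interior holes smaller than `min_hole_um2`.  With a fixed
#' threshold the mask is monotone: raising the threshold never grows it.
#'
#' @param tumor_channel intensity raster of the tumor marker.
#' @param method `"otsu"`, `"fixed:<value>"`, or a numeric threshold.
#' @param smoothing_sigma_px Gaussian smoothing scale in pixels (0 = none).
#' @param min_hole_um2 fill interior holes smaller than this area.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return An object of class `tumor_mask` with elements `mask` (logical
#'   raster), `area_px`, `threshold_used`.
#' @export
binarize_tumor_marker <- function(tumor_channel, method = "otsu",
                                  smoothing_sigma_px = 2, min_hole_um2 = 0,
                                  pixel_size_um = 1) {
  assert_raster(tumor_channel)
  sm <- if (smoothing_sigma_px > 0)
    as_raster(EBImage::gblur(tumor_channel, sigma = smoothing_sigma_px))
  else tumor_channel
  thr <- parse_threshold(method, sm, what = "tumor")
  mask <- if (is.na(thr)) sm & FALSE else sm >= thr
  if (min_hole_um2 > 0 && any(mask) && !all(mask)) {
    min_hole_px <- min_hole_um2 / pixel_size_um^2
    mask <- fill_small_holes(mask, min_hole_px)
  }
  structure(list(mask = mask, area_px = sum(mask), threshold_used = thr),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d/%d px (%.1f%%), threshold %.5g\n",
              x$area_px, length(x$mask), 100 * x$area_px / length(x$mask),
              x$threshold_used))
  invisible(x)
}

# Resolve "otsu" / "fixed:<v>" / numeric into a threshold value.
# A flat raster under Otsu yields NA (empty mask) with a warning.
parse_threshold <- function(method, raster, what = "marker") {
  if (is.numeric(method)) return(as.numeric(method))
  if (identical(method, "otsu")) {
    rng <- range(raster)
    if (diff(rng) == 0) {
      warning(sprintf("flat %s channel: Otsu threshold undefined, mask empty",
                      what), call. = FALSE)
      return(NA_real_)
    }
    return(EBImage::otsu(EBImage::Image(raster), range = rng, levels = 256L))
  }
  if (is.character(method) && grepl("^fixed:", method)) {
    v <- suppressWarnings(as.numeric(sub("^fixed:", "", method)))
    if (is.na(v)) stop_validation("invalid fixed threshold: %s", method)
    return(v)
  }
  stop_validation("unknown threshold method: %s", as.character(method))
}

# Fill 4-connected background holes (components not touching the border)
# smaller than min_hole_px pixels.
fill_small_holes <- function(mask, min_hole_px) {
  bg <- cc_label_cpp(matrix(as.integer(!mask), nrow(mask), ncol(mask)), 4L)
  n <- max(bg)
  if (n == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  areas <- tabulate(bg[bg > 0L], nbins = n)
  fill <- setdiff(which(areas < min_hole_px), border)
  if (length(fill)) mask[bg %in% fill] <- TRUE
  mask
}

#' Select the nuclei encapsulated by the tumor mask
#'
#' Retains exactly the nuclei whose fraction of pixels inside the tumor mask
#' is at least `min_overlap_fraction`, isolating tumor cells from stromal or
#' immune nuclei outside the pan-cytokeratin-positive tissue.
#'
#' @param nuclei a [nuclei_labels()] object.
#' @param tumor a [binarize_tumor_marker()] result (or logical raster).
#' @param min_overlap_fraction required in-mask pixel fraction in `[0, 1]`;
#'   the default 0.5 reads "encapsulated" as majority-inside.
#' @return A `nuclei_labels` object with survivors relabeled consecutively.
#' @export
select_tumor_nuclei <- function(nuclei, tumor, min_overlap_fraction = 0.5) {
  stopifnot(inherits(nuclei, "nuclei_labels"))
  mask <- if (inherits(tumor, "tumor_mask")) tumor$mask else tumor
  assert_same_shape(nuclei$labels, mask, "nuclei and tumor rasters")
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1)
    stop_validation("min_overlap_fraction must lie in [0, 1]")
  if (nuclei$count == 0L) return(nuclei)
  inside <- tabulate(nuclei$labels[mask & nuclei$labels > 0L],
                     nbins = nuclei$count)
  frac <- inside / nuclei$areas_px
  keep_labels(nuclei, which(frac >= min_overlap_fraction))
}

#' Voronoi cell territories of tumor nuclei
#'
#' Assigns every tumor-mask pixel to the nucleus whose instance is nearest
#' in Euclidean distance (distance to the nearest pixel of the instance,
#' i.e. the generalized Voronoi tessellation of regions), with equidistant
#' pixels assigned to the lower nucleus id.  Distance is computed in the
#' full plane and then masked.  Each nucleus's own pixels always belong to
#' its territory, so the territory support is the union of the tumor mask
#' and the retained nuclei.
#'
#' @param tumor_nuclei a [nuclei_labels()] object of the selected nuclei.
#' @param tumor a [binarize_tumor_marker()] result (or logical raster).
#' @return An object of class `cell_map`: `territories` (integer raster, 0 =
#'   non-tumor), `n_cells`, `areas_px` (per territory), `on_border` (logical,
#'   territory touches the image border), `nucleus_id` (territory id to
#'   nucleus id; identity here).  Zero nuclei yield an empty map with a
#'   warning.
#' @export
voronoi_territories <- function(tumor_nuclei, tumor) {
  stopifnot(inherits(tumor_nuclei, "nuclei_labels"))
  mask <- if (inherits(tumor, "tumor_mask")) tumor$mask else tumor
  assert_same_shape(tumor_nuclei$labels, mask, "nuclei and tumor rasters")
  lab <- tumor_nuclei$labels
  if (tumor_nuclei$count == 0L) {
    warning("no nuclei: empty cell map", call. = FALSE)
    terr <- matrix(0L, nrow(lab), ncol(lab))
    return(new_cell_map(terr, 0L))
  }
  support <- mask | lab > 0L
  owner <- nearest_site_cpp(lab, support)$owner
  new_cell_map(owner, tumor_nuclei$count)
}

new_cell_map <- function(territories, n_cells) {
  areas <- tabulate(territories[territories > 0L], nbins = n_cells)
  on_border <- rep(FALSE, n_cells)
  if (n_cells > 0L) {
    b <- unique(c(territories[1, ], territories[nrow(territories), ],
                  territories[, 1], territories[, ncol(territories)]))
    on_border[b[b > 0L]] <- TRUE
  }
  structure(list(territories = territories,
                 n_cells = as.integer(n_cells),
                 areas_px = areas,
                 on_border = on_border,
                 nucleus_id = seq_len(n_cells)),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d territories covering %d px\n",
              x$n_cells, sum(x$areas_px)))
  invisible(x)
}

#' Export cell territories as a label TIFF for audit overlays
#'
#' @param cells a [voronoi_territories()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_territory_image <- function(cells, path) {
  stopifnot(inherits(cells, "cell_map"))
  write_label_image(cells$territories, path)
}
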