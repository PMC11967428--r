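#' Nuclei instance label container
#'
#' Wraps an integer label raster (0 = background, k > 0 = nucleus k) with
#' per-instance centroids and areas.  Labels are consecutive `1..count` and
#' each label forms one 4-connected region; by default the raster is
#' canonicalized so labels are numbered in row-major raster-scan order of
#' each instance's first pixel, making segmentations comparable bit-exactly.
#'
#' @param labels integer matrix of instance labels.
#' @param canonicalize split labels into 4-connected components and renumber
#'   them in raster-scan order (default `TRUE`).
#' @return An object of class `nuclei_labels` with elements `labels`,
#'   `count`, `centroids` (0-based x/y), `areas_px`.
#' @export
nuclei_labels <- function(labels, canonicalize = TRUE) {
  if (!is.matrix(labels)) stop_validation("labels must be a matrix")
  if (is.double(labels)) {
    if (any(abs(labels - round(labels)) > 1e-9))
      stop_validation("labels must be integer-valued")
    labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  }
  if (any(labels < 0L)) stop_validation("labels must be nonnegative")
  if (canonicalize) {
    labels <- cc_label_cpp(labels, 4L)
  } else {
    n <- max(labels, 0L)
    if (n > 0L && !all(seq_len(n) %in% labels))
      stop_validation("labels must be consecutive 1..count")
  }
  n <- max(labels, 0L)
  areas <- tabulate(labels[labels > 0L], nbins = n)
  structure(list(labels = labels,
                 count = n,
                 centroids = label_centroids(labels, n),
                 areas_px = areas),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d instance(s) on a %dx%d raster\n",
              x$count, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Detect nuclei in a nuclear-stain channel
#'
#' Classical deterministic detector: Gaussian smoothing, Otsu threshold,
#' hole filling, Euclidean distance transform, and seeded watershed to split
#' touching nuclei.  An external instance segmentation can be supplied
#' instead through [read_label_image()].
#'
#' @param nuclei_channel intensity raster of the nuclear stain.
#' @param smoothing_sigma_px Gaussian smoothing scale in pixels (> 0).
#' @param seed_min_distance_px minimum separation between watershed seed
#'   peaks, in pixels; nearer maxima of the distance map are merged.
#' @param watershed_tolerance minimum depth (in distance-map units, i.e.
#'   pixels) separating two objects before they are split.
#' @return A [nuclei_labels()] object.  A flat (constant) channel yields 0
#'   instances with a warning.
#' @export
detect_nuclei <- function(nuclei_channel, smoothing_sigma_px = 2,
                          seed_min_distance_px = 5, watershed_tolerance = 1) {
  assert_raster(nuclei_channel)
  if (smoothing_sigma_px <= 0)
    stop_validation("smoothing_sigma_px must be > 0")
  empty <- function() {
    nuclei_labels(matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)),
                  canonicalize = FALSE)
  }
  if (diff(range(nuclei_channel)) == 0) {
    warning("nuclei channel is constant; no nuclei detected", call. = FALSE)
    return(empty())
  }
  sm <- as_raster(EBImage::gblur(nuclei_channel, sigma = smoothing_sigma_px))
  rng <- range(sm)
  if (diff(rng) == 0) {
    warning("smoothed nuclei channel is constant; no nuclei detected",
            call. = FALSE)
    return(empty())
  }
  thr <- EBImage::otsu(EBImage::Image(sm), range = rng, levels = 256L)
  bw <- sm > thr
  if (!any(bw)) {
    warning("no foreground above the nuclei threshold", call. = FALSE)
    return(empty())
  }
  bw <- as_raster(EBImage::fillHull(bw * 1L)) > 0
  dm <- as_raster(EBImage::distmap(bw * 1L))
  ext <- max(1L, as.integer(floor(seed_min_distance_px / 2)))
  ws <- as_raster(EBImage::watershed(EBImage::Image(dm),
                                     tolerance = watershed_tolerance,
                                     ext = ext))
  nuclei_labels(matrix(as.integer(ws), nrow(ws), ncol(ws)))
}

#' Filter nuclei instances by physical area
#'
#' Removes instances whose area falls outside `[min_area_um2, max_area_um2]`
#' (used to reject debris such as bright paraffin specks and under- or
#' over-segmented clumps); survivors are relabeled consecutively, preserving
#' canonical order.
#'
#' @param nuclei a [nuclei_labels()] object.
#' @param min_area_um2,max_area_um2 area window in square micrometres,
#'   `0 <= min < max`.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return A filtered `nuclei_labels` object.
#' @export
filter_nuclei <- function(nuclei, min_area_um2, max_area_um2, pixel_size_um) {
  stopifnot(inherits(nuclei, "nuclei_labels"))
  if (!(min_area_um2 >= 0 && min_area_um2 < max_area_um2))
    stop_validation("need 0 <= min_area_um2 < max_area_um2")
  if (nuclei$count == 0L) return(nuclei)
  area_um2 <- nuclei$areas_px * pixel_size_um^2
  keep <- which(area_um2 >= min_area_um2 & area_um2 <= max_area_um2)
  keep_labels(nuclei, keep)
}

# Retain the listed instance ids, relabeling consecutively in the same order.
keep_labels <- function(nuclei, keep) {
  map <- integer(nuclei$count)
  map[keep] <- seq_along(keep)
  lab <- nuclei$labels
  sel <- lab > 0L
  lab[sel] <- map[lab[sel]]
  nuclei_labels(lab, canonicalize = FALSE)
}
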