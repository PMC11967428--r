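#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the channel with a disk structuring element of the given physical radius
#' and subtracts it.  A flat image maps to all zeros; features much smaller
#' than the radius are preserved.
#'
#' @param channel intensity raster.
#' @param radius_um ball radius in micrometres (must span at least 1 px).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return The background-subtracted raster (nonnegative).
#' @export
subtract_background <- function(channel, radius_um, pixel_size_um) {
  assert_raster(channel)
  if (radius_um <= 0) stop_validation("radius_um must be > 0")
  r_px <- radius_um / pixel_size_um
  if (r_px < 1)
    stop_validation("background radius %.3g um is smaller than one pixel",
                    radius_um)
  brush <- EBImage::makeBrush(2L * as.integer(floor(r_px)) + 1L, "disc")
  bg <- as_raster(EBImage::opening(channel, brush))
  pmax(channel - bg, 0)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Normalizes local contrast per tile with clipping of the tile histogram
#' and bilinear interpolation between tiles.  The input is first rescaled to
#' `[0, 1]`; the output always lies in `[0, 1]`.  A constant image is
#' returned unchanged (clamped); a tile larger than the image falls back to
#' global histogram equalization with a warning.
#'
#' @param channel intensity raster.
#' @param tile_px tile side length in pixels (>= 8).
#' @param clip_limit histogram clip limit as a fraction of the tile's pixel
#'   count (the common 0.01 default).
#' @param bins number of histogram bins.
#' @return The equalized raster in `[0, 1]`.
#' @export
clahe_normalize <- function(channel, tile_px = 64, clip_limit = 0.01,
                            bins = 256L) {
  assert_raster(channel)
  if (tile_px < 8) stop_validation("tile_px must be >= 8")
  if (clip_limit <= 0) stop_validation("clip_limit must be > 0")
  rng <- range(channel)
  if (diff(rng) == 0) return(pmin(pmax(channel, 0), 1))
  xn <- (channel - rng[1]) / (rng[2] - rng[1])
  if (tile_px > min(dim(channel))) {
    warning("CLAHE tile larger than image; using global histogram equalization",
            call. = FALSE)
    return(as_raster(EBImage::equalize(EBImage::Image(xn), range = c(0, 1),
                                       levels = bins)))
  }
  nx <- max(1L, as.integer(round(nrow(channel) / tile_px)))
  ny <- max(1L, as.integer(round(ncol(channel) / tile_px)))
  # the tile grid must divide the image evenly; pad by edge replication
  nr_pad <- as.integer(ceiling(nrow(channel) / nx) * nx)
  nc_pad <- as.integer(ceiling(ncol(channel) / ny) * ny)
  xp <- xn[c(seq_len(nrow(xn)), rep(nrow(xn), nr_pad - nrow(xn))),
           c(seq_len(ncol(xn)), rep(ncol(xn), nc_pad - ncol(xn))),
           drop = FALSE]
  out <- EBImage::clahe(EBImage::Image(xp), nx = nx, ny = ny, bins = bins,
                        limit = clip_limit * bins, keep.range = FALSE)
  out <- as_raster(out)[seq_len(nrow(channel)), seq_len(ncol(channel)),
                        drop = FALSE]
  pmin(pmax(out, 0), 1)
}

#' Binarize the processed trogocytic-marker channel
#'
#' @param channel processed intensity raster (after background subtraction
#'   and CLAHE).
#' @param method `"otsu"`, `"fixed:<value>"`, a numeric threshold, or
#'   `"control_gate"` (threshold taken from `gate`).
#' @param gate a [control_threshold()] result; required for
#'   `method = "control_gate"`.
#' @param provenance optional list of upstream processing parameters to
#'   record alongside the threshold.
#' @return An object of class `marker_mask`: `mask` (logical raster, TRUE
#'   where intensity >= threshold) and `method` (the full method record).
#' @export
binarize_marker <- function(channel, method = "otsu", gate = NULL,
                            provenance = list()) {
  assert_raster(channel)
  if (identical(method, "control_gate")) {
    if (is.null(gate))
      stop_validation("method 'control_gate' requires a control gate")
    stopifnot(inherits(gate, "control_gate"))
    thr <- gate$intensity_threshold
    method_name <- "control_gate"
  } else {
    thr <- parse_threshold(method, channel, what = "marker")
    method_name <- if (is.numeric(method)) "fixed" else
      sub(":.*$", "", as.character(method))
  }
  mask <- if (is.na(thr)) channel & FALSE else channel >= thr
  structure(list(mask = mask,
                 method = c(list(method = method_name, threshold = thr),
                            provenance)),
            class = "marker_mask")
}

#' @export
print.marker_mask <- function(x, ...) {
  cat(sprintf("<marker_mask> %d/%d px positive (method %s, threshold %.5g)\n",
              sum(x$mask), length(x$mask), x$method$method,
              x$method$threshold))
  invisible(x)
}

#' Expression gate from secondary-antibody-only controls
#'
#' The expression threshold is a percentile (linear-interpolation
#' definition, R quantile type 7) of the per-cell mean marker intensities
#' measured on secondary-antibody-only control images — the imaging analog
#' of an isotype/FMO gate.
#'
#' @param control_cell_intensities numeric vector of per-cell mean
#'   intensities from control fields (at least 10 cells).
#' @param percentile percentile in `(0, 100)`; default 99.
#' @return An object of class `control_gate`: `intensity_threshold`,
#'   `percentile_used`, `n_control_cells`.
#' @export
control_threshold <- function(control_cell_intensities, percentile = 99) {
  x <- control_cell_intensities[!is.na(control_cell_intensities)]
  if (length(x) < 10L)
    stop_validation(paste0("only %d control cells; at least 10 are needed - ",
                           "supply more control fields"), length(x))
  if (percentile <= 0 || percentile > 100)
    stop_validation("percentile must lie in (0, 100]")
  thr <- unname(stats::quantile(x, percentile / 100, type = 7, names = FALSE))
  structure(list(intensity_threshold = thr,
                 percentile_used = percentile,
                 n_control_cells = length(x)),
            class = "control_gate")
}

#' @export
print.control_gate <- function(x, ...) {
  cat(sprintf("<control_gate> threshold %.5g (p%.4g of %d control cells)\n",
              x$intensity_threshold, x$percentile_used, x$n_control_cells))
  invisible(x)
}
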