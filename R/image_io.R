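#' Multichannel fluorescence image container
#'
#' Holds one field of view as a list of equally sized 2D intensity rasters
#' together with the mapping from channel roles to channel indices, the
#' physical pixel size, and a source identifier.  Recognised roles are
#' `nuclei` (nuclear stain, e.g. Hoechst/DAPI), `tumor_marker`
#' (pan-cytokeratin) and `trogo_marker` (the trogocytic marker, e.g. CD45RA).
#'
#' @param channels list of numeric matrices, all with identical dimensions.
#' @param channel_roles named integer vector mapping roles to 1-based channel
#'   indices, names drawn from `nuclei`, `tumor_marker`, `trogo_marker`.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param source_id sample/image identifier string.
#' @return An object of class `mc_image`.
#' @export
multichannel_image <- function(channels, channel_roles, pixel_size_um,
                               source_id = "image") {
  if (!is.list(channels) || length(channels) == 0L)
    stop_validation("channels must be a nonempty list of matrices")
  for (i in seq_along(channels)) {
    assert_raster(channels[[i]], sprintf("channel %d", i))
    assert_same_shape(channels[[1]], channels[[i]], "channels")
  }
  known <- c("nuclei", "tumor_marker", "trogo_marker")
  if (is.null(names(channel_roles)) || !all(names(channel_roles) %in% known))
    stop_validation("channel_roles must be named with roles among: %s",
                    paste(known, collapse = ", "))
  channel_roles <- vapply(channel_roles, as.integer, integer(1))
  if (any(channel_roles < 1L | channel_roles > length(channels)))
    stop_validation("channel_roles reference channel indices outside 1..%d",
                    length(channels))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_validation("pixel_size_um must be a positive scalar")
  structure(
    list(channels = lapply(channels, function(ch) {
           ch <- as.matrix(ch); dimnames(ch) <- NULL; ch
         }),
         channel_roles = channel_roles,
         pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id)),
    class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %s: %d channel(s), %dx%d px, %.4g um/px\n",
              x$source_id, length(x$channels), d[1], d[2], x$pixel_size_um))
  cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a channel raster by role
#'
#' @param img an [multichannel_image()] object.
#' @param role one of `nuclei`, `tumor_marker`, `trogo_marker`.
#' @return The channel's intensity matrix.
#' @export
channel <- function(img, role) {
  stopifnot(inherits(img, "mc_image"))
  if (!role %in% names(img$channel_roles))
    stop_validation("image '%s' has no channel with role '%s'",
                    img$source_id, role)
  img$channels[[img$channel_roles[[role]]]]
}

has_role <- function(img, role) role %in% names(img$channel_roles)

require_roles <- function(img, roles) {
  missing <- setdiff(roles, names(img$channel_roles))
  if (length(missing))
    stop_validation("image '%s' is missing required channel role(s): %s",
                    img$source_id, paste(missing, collapse = ", "))
  invisible(img)
}

#' Read a multichannel TIFF image
#'
#' Reads a single- or multi-page grayscale TIFF and wraps it as an
#' [multichannel_image()].  If the file carries resolution metadata and a
#' pixel size is also supplied, the supplied value wins with a warning.
#'
#' @param path path to a TIFF / OME-TIFF file of 2D grayscale pages.
#' @param channel_roles named integer vector, role to 1-based page index.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param source_id identifier; defaults to the file name without extension.
#' @return An `mc_image`.
#' @export
read_multichannel <- function(path, channel_roles, pixel_size_um,
                              source_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) > 2L) {
      if (dim(pages[[i]])[3] == 1L) pages[[i]] <- pages[[i]][, , 1]
      else stop_validation("page %d of %s is not grayscale", i, basename(path))
    }
  }
  info <- attributes(pages[[1]])
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
      info$x.resolution > 0) {
    unit_um <- switch(as.character(info$resolution.unit %||% "inch"),
                      inch = 25400, cm = 10000, 25400)
    meta_px <- unit_um / info$x.resolution
    if (abs(meta_px - pixel_size_um) > 1e-6 * pixel_size_um)
      warning(sprintf(paste0("pixel size in file metadata (%.5g um/px) ",
                             "differs from supplied value (%.5g um/px); ",
                             "using the supplied value"),
                      meta_px, pixel_size_um), call. = FALSE)
  }
  pages <- lapply(pages, function(p) { attributes(p) <- list(dim = dim(p)); p })
  multichannel_image(pages, channel_roles, pixel_size_um,
                     source_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a multichannel image as a 16-bit multi-page TIFF
#'
#' Channel intensities must lie in `[0, 1]`; they are stored on the 16-bit
#' integer grid, so values produced by the synthetic generator (which are
#' already on that grid) round-trip bit-exactly.
#'
#' @param img an `mc_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multichannel <- function(img, path) {
  stopifnot(inherits(img, "mc_image"))
  rng <- range(unlist(lapply(img$channels, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop_validation("channel intensities must lie in [0, 1] for 16-bit output")
  tiff::writeTIFF(img$channels, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label image
#'
#' Reads a single-page integer-valued raster (0 = background) such as the
#' output of an external nuclei instance segmenter, and relabels the
#' instances to consecutive positive integers (ascending original value).
#' The partition is preserved: two pixels share a label after reading iff
#' they shared a value in the file.
#'
#' @param path path to a TIFF label image.
#' @param pixel_size_um optional pixel size stored on the result.
#' @return A [nuclei_labels()] object.
#' @export
read_label_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) > 2L)
    stop_validation("label image %s is not a single grayscale plane",
                    basename(path))
  if (!is.integer(x)) {
    if (any(abs(x - round(x)) > 1e-6))
      stop_validation("label image %s contains non-integer values",
                      basename(path))
    x <- matrix(as.integer(round(x)), nrow(x), ncol(x))
  }
  if (any(x < 0L))
    stop_validation("label image %s contains negative values", basename(path))
  vals <- sort(unique(x[x > 0L]))
  relab <- x
  if (length(vals)) relab[] <- match(x, vals, nomatch = 0L)
  nuclei_labels(relab, canonicalize = FALSE)
}

#' Write an integer label raster as a 16-bit TIFF
#'
#' @param labels a `nuclei_labels` object or integer matrix (max 65535).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  m <- if (inherits(labels, "nuclei_labels")) labels$labels else labels
  if (max(m) > 65535L) stop_validation("more than 65535 labels")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

cell_table_columns <- c("source_id", "cell_id", "centroid_x_px",
                        "centroid_y_px", "territory_area_um2",
                        "mean_marker_intensity", "coverage_fraction",
                        "expresses_marker", "is_trogocytic", "on_border")

trogosome_table_columns <- c("source_id", "cell_id", "trogosome_id",
                             "centroid_x_px", "centroid_y_px", "diameter_um",
                             "is_large", "hollowness", "response")

#' Write per-cell, trogosome, and per-sample result tables
#'
#' Tables are written as UTF-8 CSV with a header row; numbers are serialized
#' at full double precision so a write/read round trip reproduces values to
#' better than 1e-12 relative error.
#'
#' @param records data frame of cell records (see [cell_records()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  missing <- setdiff(cell_table_columns, names(records))
  if (length(missing))
    stop_validation("cell table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  write_table(records[, c(cell_table_columns,
                          setdiff(names(records), cell_table_columns))], path)
}

#' @rdname write_cell_table
#' @export
write_trogosome_table <- function(records, path) {
  missing <- setdiff(trogosome_table_columns, names(records))
  if (length(missing))
    stop_validation("trogosome table is missing column(s): %s",
                    paste(missing, collapse = ", "))
  write_table(records, path)
}

#' @rdname write_cell_table
#' @export
write_sample_table <- function(records, path) {
  write_table(records, path)
}

write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.17g", x))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read back a result table written by the table writers
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
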