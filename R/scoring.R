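#' Per-cell marker coverage fractions
#'
#' For each cell territory, the fraction of its pixels that are
#' marker-positive: an integer pixel count divided once by the integer
#' territory area, so values are exact ratios in `[0, 1]`.
#'
#' @param cells a [voronoi_territories()] result.
#' @param marker a [binarize_marker()] result (or logical raster).
#' @return Numeric vector of coverage fractions, one per territory id.
#' @export
coverage_fraction <- function(cells, marker) {
  stopifnot(inherits(cells, "cell_map"))
  mask <- if (inherits(marker, "marker_mask")) marker$mask else marker
  assert_same_shape(cells$territories, mask, "territories and marker mask")
  if (cells$n_cells == 0L) return(numeric(0))
  if (any(cells$areas_px == 0L))
    stop("cell map contains a zero-area territory; invalid cell map")
  pos <- tabulate(cells$territories[mask & cells$territories > 0L],
                  nbins = cells$n_cells)
  pos / cells$areas_px
}

#' Trogocytic flag from marker coverage
#'
#' A cell is flagged trogocytic when its marker coverage lies strictly
#' between `low` and `high` (defaults 0.55 and 0.90).  Both bounds are
#' strict: coverage exactly at a bound is not flagged.  The upper bound
#' discards cells dominated by autofluorescence or bright anomalies such as
#' paraffin debris.
#'
#' @param coverage numeric vector of coverage fractions.
#' @param low,high strict bounds with `0 <= low < high <= 1`.
#' @return Logical vector.
#' @export
flag_trogocytic <- function(coverage, low = 0.55, high = 0.90) {
  if (!(low >= 0 && low < high && high <= 1))
    stop_validation("need 0 <= low < high <= 1 (got %g, %g)", low, high)
  coverage > low & coverage < high
}

#' Assemble per-cell records for one field of view
#'
#' @param cells a [voronoi_territories()] result.
#' @param marker a [binarize_marker()] result.
#' @param intensity_channel raster on which per-cell mean marker intensity
#'   is measured (the background-subtracted channel; CLAHE rescales
#'   intensities image-adaptively, so gated intensities are taken upstream
#'   of it).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param gate optional [control_threshold()] gate; when absent,
#'   `expresses_marker` is `NA`.
#' @param low,high trogocytic coverage bounds (strict).
#' @param source_id sample identifier.
#' @param exclude_border drop cells whose territory touches the image
#'   border (their truncated territories bias coverage); default keeps them
#'   flagged in the `on_border` column.
#' @return Data frame with one row per cell: `source_id`, `cell_id`,
#'   `centroid_x_px`, `centroid_y_px` (0-based territory centroid),
#'   `territory_area_um2`, `mean_marker_intensity`, `coverage_fraction`,
#'   `expresses_marker`, `is_trogocytic`, `on_border`.
#' @export
cell_records <- function(cells, marker, intensity_channel, pixel_size_um,
                         gate = NULL, low = 0.55, high = 0.90,
                         source_id = "image", exclude_border = FALSE) {
  stopifnot(inherits(cells, "cell_map"))
  assert_same_shape(cells$territories, intensity_channel,
                    "territories and intensity channel")
  n <- cells$n_cells
  if (n == 0L) {
    return(data.frame(source_id = character(0), cell_id = integer(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      territory_area_um2 = numeric(0),
                      mean_marker_intensity = numeric(0),
                      coverage_fraction = numeric(0),
                      expresses_marker = logical(0),
                      is_trogocytic = logical(0), on_border = logical(0)))
  }
  cov <- coverage_fraction(cells, marker)
  cent <- label_centroids(cells$territories, n)
  idx <- cells$territories > 0L
  sums <- rowsum(as.numeric(intensity_channel[idx]),
                 cells$territories[idx], reorder = TRUE)
  mean_int <- as.numeric(sums) / cells$areas_px
  expresses <- if (is.null(gate)) rep(NA, n) else
    mean_int > gate$intensity_threshold
  rec <- data.frame(source_id = source_id,
                    cell_id = seq_len(n),
                    centroid_x_px = cent[, "x"],
                    centroid_y_px = cent[, "y"],
                    territory_area_um2 = cells$areas_px * pixel_size_um^2,
                    mean_marker_intensity = mean_int,
                    coverage_fraction = cov,
                    expresses_marker = expresses,
                    is_trogocytic = flag_trogocytic(cov, low, high),
                    on_border = cells$on_border)
  if (exclude_border) rec <- rec[!rec$on_border, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Summarize one sample's cell records
#'
#' @param records data frame of cell records (one `source_id`).
#' @param group group label (e.g. tumor stage or timepoint).
#' @return One-row data frame: `source_id`, `group`, `n_tumor_cells`,
#'   `n_expressing`, `pct_expressing`, `n_trogocytic`, `pct_trogocytic`,
#'   `flag_empty`.  Percentages are `NA` (and `flag_empty` is `TRUE`) when
#'   there are no cells.
#' @export
summarize_sample <- function(records, group = NA_character_) {
  n <- nrow(records)
  if (n > 0L && length(unique(records$source_id)) != 1L)
    stop_validation("records mix multiple source_ids; summarize per sample")
  src <- if (n > 0L) records$source_id[[1]] else NA_character_
  n_exp <- if (n > 0L && !all(is.na(records$expresses_marker)))
    sum(records$expresses_marker, na.rm = TRUE) else NA_integer_
  n_tro <- if (n > 0L) sum(records$is_trogocytic) else NA_integer_
  data.frame(source_id = src,
             group = group,
             n_tumor_cells = n,
             n_expressing = n_exp,
             pct_expressing = if (n > 0L) 100 * n_exp / n else NA_real_,
             n_trogocytic = n_tro,
             pct_trogocytic = if (n > 0L) 100 * n_tro / n else NA_real_,
             flag_empty = n == 0L)
}

#' Summarize samples by group
#'
#' Tidy per-group table of sample counts and the mean and standard deviation
#' of the per-sample expressing and trogocytic percentages, ready for
#' downstream significance testing in any statistics tool.
#'
#' @param samples data frame of [summarize_sample()] rows with a `group`
#'   column.
#' @return Data frame with one row per group.
#' @export
summarize_groups <- function(samples) {
  stopifnot(is.data.frame(samples), "group" %in% names(samples))
  groups <- unique(samples$group)
  out <- lapply(groups, function(g) {
    s <- samples[samples$group %in% g & !samples$flag_empty, , drop = FALSE]
    data.frame(group = g,
               n_samples = nrow(s),
               mean_pct_expressing = mean(s$pct_expressing),
               sd_pct_expressing = if (nrow(s) > 1L) sd(s$pct_expressing)
                                   else NA_real_,
               mean_pct_trogocytic = mean(s$pct_trogocytic),
               sd_pct_trogocytic = if (nrow(s) > 1L) sd(s$pct_trogocytic)
                                   else NA_real_)
  })
  do.call(rbind, out)
}
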