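# Discrete scale-normalized Laplacian-of-Gaussian kernel (zero-sum).
log_kernel <- function(sigma) {
  half <- max(2L, as.integer(ceiling(3.2 * sigma)))
  ax <- -half:half
  g <- exp(-ax^2 / (2 * sigma^2))
  r2 <- outer(ax^2, ax^2, "+")
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k * sigma^2 / (2 * pi * sigma^2)   # scale-normalized, unit-Gaussian mass
  k - mean(k)                             # zero response on flat input
}

# TRUE at pixels that are >= all 8 neighbours (replicated borders).
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  best <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    best <- pmax(best, pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  m >= best
}

#' Detect trogosomes inside cell territories
#'
#' Multiscale blob detection on the processed trogocytic-marker channel:
#' scale-normalized Laplacian-of-Gaussian responses are computed on a
#' geometric scale grid spanning `diameter_range_um`, local maxima in
#' position and scale are collected inside cell territories (and outside
#' the owning cell's nucleus), overlapping detections are merged keeping
#' the stronger response, and each survivor's diameter is refined as the
#' equivalent-circle diameter of the locally segmented blob (falling back
#' to the LoG scale estimate `2 * sigma * sqrt(2)` when the local
#' segmentation is degenerate, e.g. for a fully hollow ring interior).
#'
#' @param marker_channel processed (background-subtracted) intensity raster.
#' @param cells a [voronoi_territories()] result.
#' @param nuclei the matching [nuclei_labels()] (detections whose centroid
#'   falls inside a nucleus are rejected).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param diameter_range_um ordered positive pair of diameters to search.
#' @param large_cutoff_um strict cutoff: `is_large` is `diameter_um >
#'   large_cutoff_um`.
#' @param n_scales number of scales on the geometric grid.
#' @param response_threshold minimum scale-normalized LoG response.
#' @param source_id sample identifier.
#' @return Data frame with one row per detection: `source_id`, `cell_id`,
#'   `trogosome_id`, `centroid_x_px`, `centroid_y_px`, `diameter_um`,
#'   `is_large`, `hollowness`, `response`.
#' @export
detect_trogosomes <- function(marker_channel, cells, nuclei, pixel_size_um,
                              diameter_range_um = c(1, 10),
                              large_cutoff_um = 5, n_scales = 12L,
                              response_threshold = 0.05,
                              source_id = "image") {
  assert_raster(marker_channel)
  stopifnot(inherits(cells, "cell_map"), inherits(nuclei, "nuclei_labels"))
  assert_same_shape(marker_channel, cells$territories,
                    "marker channel and territories")
  if (length(diameter_range_um) != 2L || any(diameter_range_um <= 0) ||
      diff(diameter_range_um) <= 0)
    stop_validation("diameter_range_um must be a positive ordered pair")
  empty <- data.frame(source_id = character(0), cell_id = integer(0),
                      trogosome_id = integer(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), diameter_um = numeric(0),
                      is_large = logical(0), hollowness = numeric(0),
                      response = numeric(0))
  if (cells$n_cells == 0L) return(empty)

  sigmas <- exp(seq(log(diameter_range_um[1]), log(diameter_range_um[2]),
                    length.out = n_scales)) / pixel_size_um / (2 * sqrt(2))
  resp <- array(0, c(nrow(marker_channel), ncol(marker_channel), n_scales))
  for (i in seq_len(n_scales)) {
    k <- log_kernel(sigmas[i])
    resp[, , i] <- -as_raster(EBImage::filter2(marker_channel, k,
                                               boundary = "replicate"))
  }
  cand <- NULL
  for (i in seq_len(n_scales)) {
    m <- resp[, , i]
    ok <- local_maxima(m) & m > response_threshold
    if (i > 1L) ok <- ok & m >= resp[, , i - 1L]
    if (i < n_scales) ok <- ok & m >= resp[, , i + 1L]
    idx <- which(ok)
    if (length(idx))
      cand <- rbind(cand, cbind(idx = idx, scale = i, value = m[idx]))
  }
  if (is.null(cand)) return(empty)

  nr <- nrow(marker_channel)
  rows <- (cand[, "idx"] - 1L) %% nr + 1L
  cols <- (cand[, "idx"] - 1L) %/% nr + 1L
  owner <- cells$territories[cand[, "idx"]]
  in_nucleus <- nuclei$labels[cand[, "idx"]] > 0L
  keep <- owner > 0L & !in_nucleus
  if (!any(keep)) return(empty)
  rows <- rows[keep]; cols <- cols[keep]; owner <- owner[keep]
  val <- cand[keep, "value"]; scl <- cand[keep, "scale"]

  # strongest first; row-major position then scale breaks exact ties
  ord <- order(-val, rows, cols, scl)
  rows <- rows[ord]; cols <- cols[ord]; owner <- owner[ord]
  val <- val[ord]; scl <- scl[ord]
  diam_px <- 2 * sigmas[scl] * sqrt(2)

  kept <- integer(0)
  for (j in seq_along(val)) {
    if (length(kept)) {
      d <- sqrt((rows[kept] - rows[j])^2 + (cols[kept] - cols[j])^2)
      lim <- 0.5 * pmin(diam_px[kept], diam_px[j])
      if (any(d < lim)) next
    }
    kept <- c(kept, j)
  }
  rows <- rows[kept]; cols <- cols[kept]; owner <- owner[kept]
  val <- val[kept]; diam_px <- diam_px[kept]

  diam_um <- vapply(seq_along(kept), function(j) {
    refine_diameter(marker_channel, cells$territories, rows[j], cols[j],
                    owner[j], diam_px[j]) * pixel_size_um
  }, numeric(1))

  # overlap suppression on refined geometry: the rim of a marker-coated
  # sphere produces small-scale ridge responses along and just outside the
  # shell; a detection whose refined disk overlaps a larger kept detection
  # is the same object (distinct trogosomes have disjoint footprints)
  ord2 <- order(-diam_um, -val, rows, cols)
  keep2 <- integer(0)
  for (j in ord2) {
    if (length(keep2)) {
      d <- sqrt((rows[keep2] - rows[j])^2 + (cols[keep2] - cols[j])^2)
      r_kept <- diam_um[keep2] / 2 / pixel_size_um
      r_j <- diam_um[j] / 2 / pixel_size_um
      if (any(d < 0.95 * (r_kept + r_j))) next
    }
    keep2 <- c(keep2, j)
  }
  keep2 <- sort(keep2)
  rows <- rows[keep2]; cols <- cols[keep2]; owner <- owner[keep2]
  val <- val[keep2]; diam_um <- diam_um[keep2]

  hol <- vapply(seq_along(keep2), function(j) {
    hollowness_at(marker_channel, cols[j] - 1, rows[j] - 1, diam_um[j],
                  pixel_size_um)
  }, numeric(1))

  out <- data.frame(source_id = source_id,
                    cell_id = owner,
                    trogosome_id = seq_along(keep2),
                    centroid_x_px = cols - 1,
                    centroid_y_px = rows - 1,
                    diameter_um = diam_um,
                    is_large = diam_um > large_cutoff_um,
                    hollowness = hol,
                    response = val)
  rownames(out) <- NULL
  out
}

# Equivalent-circle diameter (px) of the locally segmented blob at
# (row, col); falls back to the LoG scale diameter when degenerate.
refine_diameter <- function(channel, territories, row, col, owner, diam_px) {
  r <- diam_px / 2
  half <- as.integer(ceiling(1.6 * r)) + 2L
  r0 <- max(1L, row - half); r1 <- min(nrow(channel), row + half)
  c0 <- max(1L, col - half); c1 <- min(ncol(channel), col + half)
  win <- channel[r0:r1, c0:c1, drop = FALSE]
  bg <- as.numeric(stats::quantile(win, 0.2, names = FALSE))
  peak <- max(win)
  if (peak - bg <= 0) return(diam_px)
  bw <- win >= bg + 0.1 * (peak - bg)
  bw <- as_raster(EBImage::fillHull(bw * 1L)) > 0
  comp <- cc_label_cpp(matrix(as.integer(bw), nrow(bw), ncol(bw)), 4L)
  centre <- comp[row - r0 + 1L, col - c0 + 1L]
  if (centre == 0L) return(diam_px)
  sel <- comp == centre &
    territories[r0:r1, c0:c1, drop = FALSE] == owner
  area <- sum(sel)
  if (area < 4L) return(diam_px)
  # component leaking out of the window: the local estimate is unreliable
  edge <- any(sel[1, ]) || any(sel[nrow(sel), ]) ||
    any(sel[, 1]) || any(sel[, ncol(sel)])
  if (edge && (r1 - r0 + 1L) == (2L * half + 1L) &&
      (c1 - c0 + 1L) == (2L * half + 1L)) return(diam_px)
  2 * sqrt(area / pi)
}

hollowness_at <- function(channel, x_px, y_px, diameter_um, pixel_size_um) {
  r <- diameter_um / 2 / pixel_size_um
  if (r < 2) return(NA_real_)
  half <- as.integer(ceiling(r)) + 1L
  row <- as.integer(round(y_px)) + 1L
  col <- as.integer(round(x_px)) + 1L
  r0 <- max(1L, row - half); r1 <- min(nrow(channel), row + half)
  c0 <- max(1L, col - half); c1 <- min(ncol(channel), col + half)
  rr <- outer((r0:r1) - row, rep(1, c1 - c0 + 1L))
  cc <- outer(rep(1, r1 - r0 + 1L), (c0:c1) - col)
  d <- sqrt(rr^2 + cc^2)
  win <- channel[r0:r1, c0:c1, drop = FALSE]
  centre <- d <= 0.4 * r
  ring <- d >= 0.7 * r & d <= r
  if (!any(centre) || !any(ring)) return(NA_real_)
  ring_mean <- mean(win[ring])
  if (ring_mean <= 0) return(NA_real_)
  mean(win[centre]) / ring_mean
}

#' Hollowness of a detected trogosome
#'
#' Ratio of the mean intensity in the central disk (radius `0.4 r`) to the
#' mean intensity in the ring annulus (`0.7 r` to `r`).  Values below 1
#' indicate a hollow (marker-coated) sphere; a uniform disk gives 1 and a
#' perfect ring with empty interior gives 0.  Radii under 2 px give `NA`.
#'
#' @param marker_channel intensity raster.
#' @param record one-row data frame with `centroid_x_px`, `centroid_y_px`,
#'   `diameter_um` (as returned by [detect_trogosomes()]).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return Scalar hollowness ratio (or `NA`).
#' @export
hollowness <- function(marker_channel, record, pixel_size_um) {
  stopifnot(nrow(record) == 1L)
  hollowness_at(marker_channel, record$centroid_x_px, record$centroid_y_px,
                record$diameter_um, pixel_size_um)
}

#' Summarize trogosome detections for one timepoint
#'
#' A cell counts once however many large trogosomes it contains.  Both the
#' per-trogosome diameter distribution and the mean of per-cell average
#' diameters are reported.
#'
#' @param records data frame from [detect_trogosomes()].
#' @param cells the matching [voronoi_territories()] result.
#' @param timepoint timepoint label (e.g. `"4h"`).
#' @param large_cutoff_um strict diameter cutoff for a "large" trogosome.
#' @return One-row data frame: `timepoint`, `n_cells`, `n_trogosomes`,
#'   `n_cells_with_large_trogosome`, `pct_with_large_trogosome`,
#'   `mean_diameter_um`, `sd_diameter_um`, `mean_cell_diameter_um`,
#'   `flag_empty`.
#' @export
summarize_timepoint <- function(records, cells, timepoint = NA_character_,
                                large_cutoff_um = 5) {
  stopifnot(inherits(cells, "cell_map"))
  n_cells <- cells$n_cells
  if (nrow(records) && any(!records$cell_id %in% seq_len(n_cells)))
    stop_validation("trogosome records reference cells absent from the map")
  if (n_cells == 0L) {
    return(data.frame(timepoint = timepoint, n_cells = 0L, n_trogosomes = 0L,
                      n_cells_with_large_trogosome = NA_integer_,
                      pct_with_large_trogosome = NA_real_,
                      mean_diameter_um = NA_real_, sd_diameter_um = NA_real_,
                      mean_cell_diameter_um = NA_real_, flag_empty = TRUE))
  }
  large_cells <- unique(records$cell_id[records$diameter_um > large_cutoff_um])
  per_cell <- if (nrow(records))
    tapply(records$diameter_um, records$cell_id, mean) else numeric(0)
  data.frame(timepoint = timepoint,
             n_cells = n_cells,
             n_trogosomes = nrow(records),
             n_cells_with_large_trogosome = length(large_cells),
             pct_with_large_trogosome = 100 * length(large_cells) / n_cells,
             mean_diameter_um = if (nrow(records)) mean(records$diameter_um)
                                else NA_real_,
             sd_diameter_um = if (nrow(records) > 1L) sd(records$diameter_um)
                              else NA_real_,
             mean_cell_diameter_um = if (length(per_cell)) mean(per_cell)
                                     else NA_real_,
             flag_empty = FALSE)
}
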