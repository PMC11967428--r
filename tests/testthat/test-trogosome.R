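coculture_fixture <- function(seed, spec, ...) {
  trogoscan:::generate_field(coculture_params(seed = seed, noise = noiseless,
                                              trogosome_spec = spec, ...))
}

test_that("a blank marker channel yields no detections", {
  f <- coculture_fixture(51, spec = NULL, image_size_px = c(320L, 320L),
                         n_tumor_cells = 9L)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "0h")
  expect_identical(nrow(res$trogosomes), 0L)
  expect_equal(res$summary$pct_with_large_trogosome, 0)
})

test_that("a single planted 6 um sphere is found once, large, within 10%", {
  f <- coculture_fixture(3, spec = list(diameters_um = c(6, rep(NA, 8))),
                         image_size_px = c(320L, 320L), n_tumor_cells = 9L)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "x")
  d <- res$trogosomes
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$diameter_um - 6) / 6, 0.1)
  expect_true(d$is_large)
  tt <- f$truth$trogosomes
  expect_lte(abs(d$centroid_x_px - tt$centroid_x_px), 1)
  expect_lte(abs(d$centroid_y_px - tt$centroid_y_px), 1)
  # detection sits inside its cell territory and outside the nucleus
  expect_identical(d$cell_id, tt$cell_id)
})

test_that("mixed diameters give one detection each and correct large calls", {
  f <- coculture_fixture(52, spec = list(diameters_um =
                                           c(2, 4, 5.5, 8, rep(NA, 5))),
                         image_size_px = c(500L, 500L), n_tumor_cells = 9L,
                         min_spacing_um = 40, footprint_radius_um = 16)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "x")
  d <- res$trogosomes
  expect_identical(nrow(d), 4L)
  expect_identical(sum(d$is_large), 2L)
  m <- merge(d, f$truth$trogosomes, by = "cell_id")
  expect_identical(nrow(m), 4L)
  tol <- pmax(0.1 * m$diameter_um.y, f$image$pixel_size_um)
  expect_true(all(abs(m$diameter_um.x - m$diameter_um.y) <= tol))
})

test_that("hollowness is 1 for a uniform disk, 0 for an empty ring, planted otherwise", {
  ch <- matrix(0, 60, 60)
  rr <- sqrt(outer((1:60 - 30)^2, (1:60 - 30)^2, "+"))
  ch[rr <= 10] <- 0.8
  rec <- data.frame(centroid_x_px = 29, centroid_y_px = 29,
                    diameter_um = 20 * 0.5)
  expect_equal(hollowness(ch, rec, 0.5), 1)
  ring <- matrix(0, 60, 60)
  ring[rr >= 7 & rr <= 10] <- 0.8
  expect_equal(hollowness(ring, rec, 0.5), 0)
  tiny <- data.frame(centroid_x_px = 29, centroid_y_px = 29,
                     diameter_um = 1 * 0.5)
  expect_true(is.na(hollowness(ch, tiny, 0.5)))
  # planted 30% interior recovered from a generated sphere
  f <- coculture_fixture(3, spec = list(diameters_um = c(6, rep(NA, 8))),
                         image_size_px = c(320L, 320L), n_tumor_cells = 9L)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "x")
  expect_lt(abs(res$trogosomes$hollowness - 0.3), 0.05)
})

test_that("timepoint summaries count each cell once and flag empties", {
  f <- coculture_fixture(53, spec = list(large_fraction = 0.35,
                                         large_diameter_um = c(5.5, 7),
                                         small_per_cell = c(0L, 2L),
                                         small_diameter_um = c(1.5, 4)),
                         image_size_px = c(500L, 500L), n_tumor_cells = 16L,
                         min_spacing_um = 30, footprint_radius_um = 12)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "8h")
  s <- res$summary
  tt <- f$truth$trogosomes
  expect_identical(s$n_cells_with_large_trogosome,
                   length(unique(tt$cell_id[tt$is_large])))
  expect_equal(s$pct_with_large_trogosome,
               100 * s$n_cells_with_large_trogosome / s$n_cells)
  # empty cell map
  ecm <- suppressWarnings(voronoi_territories(
    nuclei_labels(matrix(0L, 10, 10), canonicalize = FALSE),
    matrix(FALSE, 10, 10)))
  es <- summarize_timepoint(res$trogosomes[0, ], ecm, "0h")
  expect_true(es$flag_empty)
  # every cell holding one large trogosome -> 100%
  all_large <- data.frame(cell_id = seq_len(s$n_cells), diameter_um = 6)
  expect_equal(summarize_timepoint(all_large, res$cells,
                                   "x")$pct_with_large_trogosome, 100)
})

test_that("raising the large cutoff never increases the large-cell percentage", {
  f <- coculture_fixture(54, spec = list(large_fraction = 0.4,
                                         large_diameter_um = c(5.5, 7),
                                         small_per_cell = c(0L, 2L),
                                         small_diameter_um = c(1.5, 4)),
                         image_size_px = c(500L, 500L), n_tumor_cells = 16L,
                         min_spacing_um = 30, footprint_radius_um = 12)
  res <- trogosome_field(f$image, pipeline_config(), timepoint = "x")
  cuts <- c(1, 2, 3, 5, 6, 8)
  pct <- vapply(cuts, function(cc)
    summarize_timepoint(res$trogosomes, res$cells, "x",
                        large_cutoff_um = cc)$pct_with_large_trogosome,
    numeric(1))
  expect_true(all(diff(pct) <= 0))
})
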