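test_that("the same seed reproduces a field bit-identically", {
  p <- synthetic_params(image_size_px = c(300L, 300L), n_tumor_cells = 16L,
                        seed = 61)
  a <- generate_ffpe_field(p)
  b <- generate_ffpe_field(p)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$truth$territories, b$truth$territories)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_ffpe_field(synthetic_params(
    image_size_px = c(300L, 300L), n_tumor_cells = 9L, seed = 62)))
  expect_identical(runif(3), before)
})

test_that("planted coverage equals the realized pixel ratio exactly", {
  f <- small_ffpe(63, n_cells = 16L, size = 300L)
  terr <- f$truth$territories
  # re-count marker-positive pixels per territory on the pre-noise channel
  mk <- channel(f$image, "trogo_marker")
  pos <- mk >= 0.4
  got <- tabulate(terr[pos & terr > 0L], nbins = nrow(f$truth$cells)) /
    tabulate(terr[terr > 0L], nbins = nrow(f$truth$cells))
  expect_equal(got, f$truth$cells$planted_coverage, tolerance = 1e-12)
})

test_that("infeasible packing fails with a helpful error", {
  expect_error(generate_ffpe_field(synthetic_params(
    image_size_px = c(200L, 200L), n_tumor_cells = 500L, seed = 1)),
    "cannot fit")
})

test_that("single-cell noiseless field round-trips coverage end to end", {
  f <- generate_ffpe_field(synthetic_params(
    image_size_px = c(220L, 220L), n_tumor_cells = 1L, min_spacing_um = 12,
    coverage_spec = list(fraction = 1, hi = c(0.6, 0.6), lo = c(0, 0)),
    seed = 64, noise = noiseless))
  res <- quantify_field(f$image, recovery_config(),
                        labels = gt_labels(f$truth))
  expect_identical(nrow(res$records), 1L)
  expect_lte(abs(res$records$coverage_fraction - 0.6), 0.02)
})

test_that("control fields carry no planted signal", {
  f <- generate_control_field(synthetic_params(
    image_size_px = c(300L, 300L), n_tumor_cells = 16L, seed = 65,
    noise = noiseless))
  expect_true(all(f$truth$cells$planted_coverage == 0))
  expect_false(any(f$truth$cells$planted_expressing))
  expect_identical(nrow(f$truth$trogosomes), 0L)
})

test_that("a zero-trogosome timecourse yields zero detections and pct", {
  pl <- list(coculture_params(seed = 66, noise = noiseless,
                              image_size_px = c(320L, 320L),
                              n_tumor_cells = 9L, timepoint = "4h",
                              trogosome_spec = NULL),
             coculture_params(seed = 67, noise = noiseless,
                              image_size_px = c(320L, 320L),
                              n_tumor_cells = 9L, timepoint = "8h",
                              trogosome_spec = list(
                                large_fraction = 0,
                                small_per_cell = c(1L, 1L),
                                small_diameter_um = c(3, 3))))
  tc <- generate_coculture_timecourse(pl)
  expect_named(tc, c("4h", "8h"))
  r1 <- trogosome_field(tc[["4h"]]$image, pipeline_config(), timepoint = "4h")
  expect_identical(nrow(r1$trogosomes), 0L)
  # all-3um trogosomes are never large at the 5 um cutoff
  r2 <- trogosome_field(tc[["8h"]]$image, pipeline_config(), timepoint = "8h")
  expect_gt(nrow(r2$trogosomes), 0L)
  expect_equal(r2$summary$pct_with_large_trogosome, 0)
})

test_that("written fixtures re-read cleanly with matching ground truth", {
  f <- small_ffpe(68, n_cells = 9L, size = 220L)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_field(f, dir)
  expect_true(all(file.exists(paths)))
  img <- read_multichannel(paths[["image"]], f$image$channel_roles,
                           f$image$pixel_size_um)
  expect_identical(img$channels, f$image$channels)
  labs <- read_label_image(paths[["labels"]])
  expect_identical(labs$labels, f$truth$nucleus_raster)
  cells <- read_result_table(paths[["cells"]])
  expect_equal(cells$planted_coverage, f$truth$cells$planted_coverage,
               tolerance = 1e-12)
})
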