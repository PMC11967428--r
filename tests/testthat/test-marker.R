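test_that("background subtraction zeroes flat input and preserves small spots", {
  expect_true(all(subtract_background(matrix(0.3, 60, 60), 10, 0.5) == 0))
  spot <- matrix(0, 80, 80); spot[40, 40:41] <- 1
  out <- subtract_background(spot, 25, 0.5)  # 50 px ball >> 2 px spot
  expect_true(all(abs(out[40, 40:41] - 1) < 0.01))
  expect_true(all(out >= 0))
  expect_error(subtract_background(spot, 0.2, 0.5), "smaller than one pixel")
})

test_that("background subtraction is idempotent on flat-background input", {
  spot <- matrix(0, 80, 80)
  spot[30:32, 50:52] <- 0.8
  once <- subtract_background(spot, 25, 0.5)
  twice <- subtract_background(once, 25, 0.5)
  expect_lte(max(abs(twice - once)), 1 / 65535)
})

test_that("a planted shading gradient is removed to under 5% of foreground", {
  f <- generate_ffpe_field(synthetic_params(
    image_size_px = c(480L, 480L), n_tumor_cells = 40L, seed = 5,
    autofluor = NULL,
    coverage_spec = list(fraction = 0.4, hi = c(0.55, 0.9), lo = c(0, 0)),
    noise = list(photons = 0, read_sd = 0, shading_amplitude = 0.15)))
  proc <- subtract_background(channel(f$image, "trogo_marker"), 12.5, 0.25)
  bg <- f$truth$territories == 0L
  expect_lt(mean(proc[bg]), 0.05 * 0.8)
})

test_that("CLAHE respects its range contract and handles degenerate input", {
  set.seed(4)
  x <- matrix(runif(100 * 90, 0.2, 4), 100, 90)
  out <- clahe_normalize(x, tile_px = 32)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  k <- matrix(0.4, 40, 40)
  expect_identical(clahe_normalize(k, tile_px = 16), k)
  expect_warning(g <- clahe_normalize(x, tile_px = 512), "global")
  expect_gte(min(g), 0); expect_lte(max(g), 1)
  expect_error(clahe_normalize(x, tile_px = 4), "tile_px")
  expect_error(clahe_normalize(x, clip_limit = 0), "clip_limit")
})

test_that("CLAHE restores local dynamic range in dim and bright halves", {
  set.seed(1)
  x <- cbind(matrix(runif(64 * 64, 0.18, 0.22), 64),
             matrix(runif(64 * 64, 0.78, 0.82), 64))
  # per-half histogram equalization (the reference oracle) spans [0, 1] in
  # each half; CLAHE with per-half tiles must recover at least half of that
  eq <- function(v) (rank(v) - 1) / (length(v) - 1)
  expect_gte(diff(range(eq(x[, 1:64]))), 0.5)
  out <- clahe_normalize(x, tile_px = 32, clip_limit = 0.05)
  expect_gte(diff(range(out[, 1:64])), 0.5)
  expect_gte(diff(range(out[, 65:128])), 0.5)
})

test_that("marker binarization thresholds exactly and records its method", {
  chk <- matrix(c(0.4, 0.6), 8, 8)
  mm <- binarize_marker(chk, method = 0.5)
  expect_identical(mm$mask, chk >= 0.5)
  expect_identical(mm$method$threshold, 0.5)
  expect_warning(e <- binarize_marker(matrix(0.2, 10, 10), "otsu"), "flat")
  expect_false(any(e$mask))
  expect_error(binarize_marker(chk, method = "control_gate"), "control gate")
  gate <- control_threshold(runif(20, 0.1, 0.2), 99)
  mg <- binarize_marker(chk, method = "control_gate", gate = gate)
  expect_identical(mg$method$method, "control_gate")
  expect_identical(mg$mask, chk >= gate$intensity_threshold)
})

test_that("marker masks are reproducible from channel and config alone", {
  f <- small_ffpe(108, n_cells = 16L, size = 300L)
  ch <- channel(f$image, "trogo_marker")
  run <- function() {
    proc <- subtract_background(ch, 12.5, 0.25)
    norm <- clahe_normalize(proc, 64, 0.01)
    binarize_marker(norm, "otsu")
  }
  a <- run(); b <- run()
  expect_identical(a$mask, b$mask)
  expect_identical(a$method, b$method)
})

test_that("control threshold is the linear-interpolation percentile", {
  expect_identical(control_threshold(rep(3.2, 50), 80)$intensity_threshold,
                   3.2)
  expect_equal(control_threshold(1:100, 100)$intensity_threshold, 100)
  expect_identical(control_threshold(1:100, 50)$intensity_threshold, 50.5)
  expect_error(control_threshold(1:5, 99), "at least 10")
  expect_error(control_threshold(1:100, 0), "percentile")
})

test_that("the sampled control gate matches the analytic autofluorescence quantile", {
  x <- withr::with_seed(7, rautofluor(5000))
  g <- control_threshold(x, 99)
  expect_identical(g$n_control_cells, 5000L)
  expect_lt(abs(g$intensity_threshold - qautofluor(0.99)) / qautofluor(0.99),
            0.02)
})

test_that("planted constant coverages are recovered through fixed-threshold binarization", {
  for (cov in c(0.3, 0.6, 0.95)) {
    f <- small_ffpe(110 + round(100 * cov), n_cells = 9L, size = 250L,
                    coverage_spec = list(fraction = 1, hi = c(cov, cov),
                                         lo = c(0, 0)))
    proc <- subtract_background(channel(f$image, "trogo_marker"), 12.5, 0.25)
    mm <- binarize_marker(proc, method = 0.4)
    cells <- voronoi_territories(gt_labels(f$truth), f$truth$tumor_region)
    got <- coverage_fraction(cells, mm)
    expect_true(all(abs(got - f$truth$cells$planted_coverage) <= 0.02))
  }
})
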