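test_that("fixed-threshold binarization honors trivial bounds and monotonicity", {
  set.seed(3)
  x <- matrix(runif(60 * 60, 0.05, 0.9), 60, 60)
  expect_true(all(binarize_tumor_marker(x, method = 0,
                                        smoothing_sigma_px = 0)$mask))
  expect_false(any(binarize_tumor_marker(x, method = "fixed:1.5",
                                         smoothing_sigma_px = 0)$mask))
  # raising a fixed threshold never grows the mask (randomized thresholds)
  thr <- sort(runif(8))
  areas <- vapply(thr, function(t)
    binarize_tumor_marker(x, method = t, smoothing_sigma_px = 1)$area_px,
    integer(1))
  expect_true(all(diff(areas) <= 0L))
  expect_warning(b <- binarize_tumor_marker(matrix(0.4, 30, 30)), "flat")
  expect_identical(b$area_px, 0L)
})

test_that("the tumor mask of a noiseless field matches the planted region", {
  f <- small_ffpe(107, n_cells = 30L, size = 400L)
  tm <- binarize_tumor_marker(channel(f$image, "tumor_marker"),
                              smoothing_sigma_px = 1, min_hole_um2 = 25,
                              pixel_size_um = 0.25)
  jacc <- sum(tm$mask & f$truth$tumor_region) /
    sum(tm$mask | f$truth$tumor_region)
  expect_gte(jacc, 0.99)
  expect_identical(tm$area_px, sum(tm$mask))
})

test_that("small holes are filled, larger ones are kept", {
  m <- matrix(0.9, 80, 80)
  m[10:11, 10:11] <- 0   # 4 px hole
  m[40:49, 40:49] <- 0   # 100 px hole
  tm <- binarize_tumor_marker(m, method = 0.5, smoothing_sigma_px = 0,
                              min_hole_um2 = 50, pixel_size_um = 1)
  expect_true(all(tm$mask[10:11, 10:11]))
  expect_false(any(tm$mask[40:49, 40:49]))
})

test_that("tumor-nucleus selection keeps exactly the encapsulated nuclei", {
  f <- generate_ffpe_field(synthetic_params(
    image_size_px = c(480L, 480L), n_tumor_cells = 12L,
    n_stromal_cells = 8L, tumor_region_fraction = 0.4, seed = 13,
    noise = noiseless))
  labs <- gt_labels(f$truth)
  expect_identical(labs$count, 20L)
  sel <- select_tumor_nuclei(labs, f$truth$tumor_region, 0.5)
  expect_identical(sel$count, 12L)
  # trivial bounds
  expect_identical(select_tumor_nuclei(labs, f$truth$tumor_region, 0)$count,
                   20L)
  none <- matrix(FALSE, 480, 480)
  expect_identical(select_tumor_nuclei(labs, none, 0.5)$count, 0L)
})

test_that("a single nucleus claims the whole mask; zero nuclei warn", {
  lab <- matrix(0L, 40, 40); lab[20, 20] <- 1L
  mask <- matrix(TRUE, 40, 40)
  cm <- voronoi_territories(nuclei_labels(lab), mask)
  expect_identical(cm$areas_px, 1600L)
  expect_warning(e <- voronoi_territories(
    nuclei_labels(matrix(0L, 40, 40), canonicalize = FALSE), mask),
    "no nuclei")
  expect_identical(e$n_cells, 0L)
})

test_that("two point nuclei split a uniform mask at the perpendicular bisector", {
  lab <- matrix(0L, 21, 31)
  lab[11, 6] <- 1L   # x = 5 (0-based)
  lab[11, 26] <- 2L  # x = 25
  cm <- voronoi_territories(nuclei_labels(lab, canonicalize = FALSE),
                            matrix(TRUE, 21, 31))
  # bisector at x = 15 (column 16); equidistant column goes to label 1
  expect_true(all(cm$territories[, 1:16] == 1L))
  expect_true(all(cm$territories[, 17:31] == 2L))
})

test_that("territory assignment matches the brute-force oracle on random fixtures", {
  set.seed(77)
  for (i in 1:40) {
    fx <- random_voronoi_fixture()
    cm <- voronoi_territories(fx$nuclei, fx$support)
    expect_identical(cm$territories, bf_voronoi(fx$nuclei$labels, fx$support))
  }
})

test_that("territories partition the support and never grow when the mask shrinks", {
  set.seed(15)
  for (i in 1:10) {
    fx <- random_voronoi_fixture()
    cm <- voronoi_territories(fx$nuclei, fx$support)
    support <- fx$support | fx$nuclei$labels > 0L
    expect_identical(sum(cm$areas_px), sum(support))
    # every nucleus inside its own territory
    nz <- fx$nuclei$labels > 0L
    expect_true(all(cm$territories[nz] == fx$nuclei$labels[nz]))
    # monotone containment under mask shrinkage
    shrunk <- fx$support & matrix(runif(length(fx$support)) > 0.3,
                                  nrow(fx$support))
    cm2 <- voronoi_territories(fx$nuclei, shrunk)
    expect_true(all(tabulate(cm2$territories[cm2$territories > 0L],
                             fx$nuclei$count) <=
                      tabulate(cm$territories[cm$territories > 0L],
                               fx$nuclei$count)))
  }
})
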