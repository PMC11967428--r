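test_that("coverage is the exact integer pixel ratio", {
  lab <- matrix(0L, 10, 20)
  lab[, 1:10] <- 1L
  cm <- voronoi_territories(nuclei_labels(lab, canonicalize = FALSE),
                            lab > 0L)
  expect_identical(coverage_fraction(cm, matrix(TRUE, 10, 20)), 1)
  expect_identical(coverage_fraction(cm, matrix(FALSE, 10, 20)), 0)
  mk <- matrix(FALSE, 10, 20); mk[1:6, 1:10] <- TRUE   # 60 of 100 px
  expect_identical(coverage_fraction(cm, mk), 0.6)
})

test_that("the trogocytic flag is strict at both bounds", {
  expect_false(flag_trogocytic(0.55))
  expect_false(flag_trogocytic(0.90))
  expect_true(flag_trogocytic(0.70))
  expect_identical(flag_trogocytic(c(0, 0.551, 0.899, 1)),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(flag_trogocytic(0.5, low = 0.9, high = 0.5), "low < high")
})

test_that("widening the flag window never decreases trogocytic counts", {
  set.seed(21)
  for (i in 1:20) {
    cov <- runif(200)
    low <- sort(runif(4, 0, 0.5), decreasing = TRUE)
    high <- sort(runif(4, 0.6, 1))
    counts <- vapply(1:4, function(j)
      sum(flag_trogocytic(cov, low[j], high[j])), integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("sample summaries count and percentage correctly", {
  rec <- data.frame(source_id = "s", expresses_marker = rep(c(TRUE, FALSE),
                                                            c(42, 58)),
                    is_trogocytic = rep(c(TRUE, FALSE), c(30, 70)))
  s <- summarize_sample(rec, group = "II")
  expect_identical(s$n_tumor_cells, 100L)
  expect_equal(s$pct_expressing, 42)
  expect_equal(s$pct_trogocytic, 30)
  expect_false(s$flag_empty)
  e <- summarize_sample(rec[0, ])
  expect_true(e$flag_empty)
  expect_true(is.na(e$pct_trogocytic))
  expect_identical(e$n_tumor_cells, 0L)
  expect_true(s$n_expressing <= s$n_tumor_cells)
  expect_true(s$n_trogocytic <= s$n_tumor_cells)
})

test_that("group summaries aggregate sample percentages", {
  one <- summarize_sample(data.frame(source_id = "a",
                                     expresses_marker = c(TRUE, FALSE),
                                     is_trogocytic = c(TRUE, FALSE)), "I")
  two <- one; two$source_id <- "b"
  g <- summarize_groups(rbind(one, two))
  expect_identical(g$n_samples, 2L)
  expect_equal(g$mean_pct_expressing, 50)
  expect_equal(g$sd_pct_expressing, 0)
  solo <- summarize_groups(one)
  expect_equal(solo$mean_pct_trogocytic, one$pct_trogocytic)
  expect_true(is.na(solo$sd_pct_trogocytic))
})

test_that("a field with 30% of cells planted in the flag window scores exactly 30%", {
  f <- small_ffpe(120, n_cells = 100L, size = 640L,
                  coverage_spec = list(fraction = 0.3, hi = c(0.60, 0.85),
                                       lo = c(0, 0.40)))
  res <- quantify_field(f$image, recovery_config(),
                        labels = gt_labels(f$truth))
  expect_equal(res$sample$pct_trogocytic, 30)
  expect_identical(res$sample$n_tumor_cells, 100L)
})

test_that("planted group means are recovered at the generator's default noise", {
  planted <- c(I = 20, II = 35, III = 50, IV = 60)
  samples <- list()
  seed0 <- 3000
  for (g in seq_along(planted)) {
    for (r in 1:3) {
      f <- generate_ffpe_field(synthetic_params(
        image_size_px = c(560L, 560L), n_tumor_cells = 60L,
        seed = seed0 + 10 * g + r,
        coverage_spec = list(fraction = planted[g] / 100,
                             hi = c(0.60, 0.85), lo = c(0, 0)),
        source_id = sprintf("s%d_%d", g, r)))
      res <- quantify_field(f$image, recovery_config(),
                            labels = gt_labels(f$truth))
      samples[[length(samples) + 1L]] <-
        summarize_sample(res$records, names(planted)[g])
    }
  }
  gs <- summarize_groups(do.call(rbind, samples))
  expect_true(all(abs(gs$mean_pct_trogocytic -
                        planted[gs$group]) <= 3))
})
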