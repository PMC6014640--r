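# Helper: a maxmin_points frame with prescribed amplitudes (spans fixed).
points_from_amps <- function(amps, n_samples = 20L) {
  structure(data.frame(max_idx = seq_along(amps) * 100L,
                       min_idx = seq_along(amps) * 100L + n_samples,
                       max_val = amps, min_val = 0,
                       amplitude = amps, n_samples = n_samples,
                       product = amps * n_samples),
            class = c("maxmin_points", "data.frame"))
}

test_that("degenerate histogram: identical amplitudes pile into the last bin", {
  summ <- amplitude_distribution(points_from_amps(rep(1.0, 10)))
  expect_equal(summ$MA, 1.0)
  expect_equal(summ$normalized[50], 1.0)
  expect_equal(sum(summ$normalized), 1.0, tolerance = 1e-9)
  expect_equal(diff(summ$bin_edges), rep(1 / 50, 50), tolerance = 1e-12)
})

test_that("fewer than 2 points is an error", {
  expect_error(amplitude_distribution(points_from_amps(1.0)), "sparse")
  expect_error(select_feature(points_from_amps(1.0)), "sparse")
})

test_that("well-separated bimodal-beyond-noise distribution triggers case 1", {
  set.seed(10)
  amps <- c(abs(rnorm(300, 0.02, 0.01)),      # noise mode
            rnorm(80, 0.30, 0.02),            # fetal mode
            rnorm(50, 0.97, 0.02))            # maternal mode
  ch <- select_feature(points_from_amps(amps))
  expect_equal(ch$case_id, "case1")
  expect_equal(ch$feature_name, "amplitude")
  expect_equal(ch$scenario, "scenario1")
  expect_gt(ch$summary$dmax_max, 0.35 * ch$summary$MA)
  expect_equal(ch$feature_values, amps)
})

test_that("close post-minimum modes trigger case 2 and the product feature", {
  set.seed(11)
  amps <- c(abs(rnorm(300, 0.02, 0.01)),
            rnorm(80, 0.72, 0.015),
            rnorm(80, 0.95, 0.015))
  ch <- select_feature(points_from_amps(amps))
  expect_equal(ch$case_id, "case2")
  expect_equal(ch$feature_name, "product")
  expect_equal(ch$scenario, "scenario2")
})

test_that("a single post-minimum mode triggers case 3 and the product feature", {
  set.seed(12)
  amps <- c(abs(rnorm(300, 0.02, 0.01)), rnorm(160, 0.92, 0.02))
  ch <- select_feature(points_from_amps(amps))
  expect_equal(ch$case_id, "case3")
  expect_equal(ch$feature_name, "product")
})

test_that("three prominent post-minimum modes fall back to amplitude", {
  set.seed(13)
  amps <- c(abs(rnorm(300, 0.02, 0.008)),
            rnorm(100, 0.30, 0.015),
            rnorm(100, 0.60, 0.015),
            rnorm(100, 0.95, 0.015))
  ch <- select_feature(points_from_amps(amps))
  expect_equal(ch$case_id, "fallback")
  expect_equal(ch$feature_name, "amplitude")
})

test_that("the case decision is invariant to amplitude rescaling", {
  set.seed(14)
  amps <- c(abs(rnorm(200, 0.02, 0.01)), rnorm(60, 0.3, 0.02),
            rnorm(40, 0.95, 0.02))
  base <- select_feature(points_from_amps(amps))
  for (c_ in c(0.1, 3, 250)) {
    scaled <- select_feature(points_from_amps(amps * c_))
    expect_equal(scaled$case_id, base$case_id)
  }
})

test_that("feature selection is deterministic", {
  synth <- short_synth("scenario1", seed = 4, duration_s = 30)
  pts <- find_maxmin_points(denoise(synth$record))
  a <- select_feature(pts)
  b <- select_feature(pts)
  expect_identical(a$case_id, b$case_id)
  expect_identical(a$feature_values, b$feature_values)
})

test_that("scenario fixtures drive the selector to the right feature", {
  s1 <- short_synth("scenario1", seed = 6, duration_s = 60)
  ch1 <- select_feature(find_maxmin_points(denoise(s1$record)))
  expect_equal(ch1$case_id, "case1")
  expect_equal(ch1$feature_name, "amplitude")

  s2 <- short_synth("scenario2", seed = 6, duration_s = 60)
  ch2 <- select_feature(find_maxmin_points(denoise(s2$record)))
  expect_true(ch2$case_id %in% c("case2", "case3"))
  expect_equal(ch2$feature_name, "product")
})
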