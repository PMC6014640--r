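# Build a pipeline context (points, clustering, summary) for a fixture.
window_context <- function(synth, seed = 1L) {
  den <- denoise(synth$record)
  pts <- find_maxmin_points(den)
  ch <- select_feature(pts)
  km <- assign_roles(kmedoids_pp(ch$feature_values,
                                 cluster_config(seed = seed)))
  list(den = den, pts = pts, choice = ch, km = km)
}

test_that("refinement drops fetal-labelled points violating the limits", {
  synth <- short_synth("scenario1", seed = 3, duration_s = 60)
  ctx <- window_context(synth, seed = 3)
  fet <- refine_fetal_cluster(ctx$pts, ctx$km, ctx$choice$summary,
                              refine_config(), fs = 1000)
  # explicit lower bound above the fetal amplitudes removes everything
  none <- refine_fetal_cluster(ctx$pts, ctx$km, ctx$choice$summary,
                               refine_config(amp_low = 10), fs = 1000)
  expect_equal(nrow(none), 0L)
  # a tight RS-span limit removes everything too
  narrow <- refine_fetal_cluster(ctx$pts, ctx$km, ctx$choice$summary,
                                 refine_config(rs_width_max_ms = 1),
                                 fs = 1000)
  expect_equal(nrow(narrow), 0L)
  # default limits: surviving candidates are ordered and within bounds
  expect_true(!is.unsorted(fet$max_idx, strictly = TRUE))
  expect_true(all(fet$n_samples <= 60))
})

test_that("refinement keeps near-truth candidates on a low-noise fixture", {
  synth <- short_synth("scenario2", seed = 5, duration_s = 60)
  ctx <- window_context(synth, seed = 5)
  before <- ctx$pts[ctx$km$roles[ctx$km$labels] == "fetal", ]
  after <- refine_fetal_cluster(ctx$pts, ctx$km, ctx$choice$summary,
                                refine_config(), fs = 1000)
  near <- function(df) df$max_idx[vapply(df$max_idx, function(i)
    min(abs(synth$fetal_truth$indices - i)) <= 50, logical(1))]
  expect_setequal(near(after), near(before))
})

test_that("a spurious extra beat is removed by the short-RR rule", {
  fs <- 1000
  beats <- seq(1000, by = 430, length.out = 20)
  extra <- 5000 + 80                      # 80 ms after a true beat
  tpl <- make_qrs_template(fs, 30, 1.0)
  small <- make_qrs_template(fs, 30, 0.4)
  x <- numeric(11000)
  off <- attr(tpl, "r_offset")
  for (b in beats) x[(b - off):(b - off + length(tpl) - 1)] <-
    x[(b - off):(b - off + length(tpl) - 1)] + tpl
  x[(extra - off):(extra - off + length(small) - 1)] <-
    x[(extra - off):(extra - off + length(small) - 1)] + small
  rec <- ecg_record(x, fs)
  cand <- sort(c(beats, extra)) - 1L      # 0-based
  out <- correct_fp_fn(cand, rec)
  expect_false((extra - 1L) %in% out)
  expect_true(all((beats - 1L) %in% out))
  audit <- attr(out, "audit")
  expect_true(any(audit$action == "remove" & audit$index == extra - 1L))
})

test_that("a missed beat is reinserted from the max-min points in the gap", {
  fs <- 1000
  beats <- seq(1000, by = 430, length.out = 20)
  tpl <- make_qrs_template(fs, 30, 1.0)
  x <- numeric(11000)
  off <- attr(tpl, "r_offset")
  for (b in beats) x[(b - off):(b - off + length(tpl) - 1)] <-
    x[(b - off):(b - off + length(tpl) - 1)] + tpl
  rec <- ecg_record(x, fs)
  dropped <- beats[10]
  cand <- beats[-10] - 1L
  out <- correct_fp_fn(cand, rec)
  expect_true(any(abs(out - (dropped - 1L)) <= 50))
  expect_true(any(attr(out, "audit")$action == "insert"))
})

test_that("short trains and already-clean trains pass through unchanged", {
  rec <- ecg_record(sin(1:2000 / 3), fs = 1000)
  one <- correct_fp_fn(500L, rec)
  expect_equal(as.integer(one), 500L)

  synth <- short_synth("scenario1", seed = 12, duration_s = 60)
  den <- denoise(synth$record)
  truth <- synth$fetal_truth$indices
  pts <- find_maxmin_points(den)
  # snap truth to actual detected max-min points so input is self-consistent
  snapped <- vapply(truth, function(b)
    pts$max_idx[which.min(abs(pts$max_idx - b))], numeric(1))
  snapped <- sort(unique(as.integer(snapped)))
  out <- correct_fp_fn(snapped, den, points = pts)
  expect_equal(as.integer(out), snapped)
})

test_that("corrected trains are strictly increasing and auditable", {
  synth <- short_synth("scenario2", seed = 9, duration_s = 60)
  ctx <- window_context(synth, seed = 9)
  fet <- refine_fetal_cluster(ctx$pts, ctx$km, ctx$choice$summary,
                              refine_config(), fs = 1000)
  out <- correct_fp_fn(fet$max_idx, ctx$den, points = ctx$pts)
  expect_false(is.unsorted(out, strictly = TRUE))
  expect_true(all(out %in% ctx$pts$max_idx))
  expect_s3_class(attr(out, "audit"), "data.frame")
})
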