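# Reference coefficients below were computed independently with PyWavelets
# (wavedec, mode="symmetric", db6) and frozen.

test_that("multilevel decomposition reproduces the reference coefficients", {
  i <- 0:39
  x <- sin(2 * pi * i / 9) + 0.3 * cos(2 * pi * i / 4.1)
  a2_ref <- c(-1.07344416969272, 0.888249120484727, 1.53460107474113,
              0.0126563132553082, -2.28322964958841, 0.327096321188681,
              0.938370876146787, 1.44440596666781, -1.63154639510629,
              1.69739233539766, -1.55850904214858, 1.23157026443322,
              -0.758347730130927, 0.208056529071137, 0.335732424207112,
              -0.799778632806035, 0.99663932435272, 1.75109999425366)
  d2_ref <- c(0.257629849698337, 0.437354461620528, -0.173630206940395,
              0.315881980018451, 0.848219388806998, -0.0435327987764141,
              0.549222587753427, 0.463739968602228, -0.24717217266587,
              0.984410814709531, -0.845254739607792, 1.10879117666402,
              -1.27636207718286, 0.852962931278156, -0.0880447401772321,
              -0.250085120581145, -0.326772567092598, 0.198175305936808)
  d1_ref <- c(-0.00210707661166004, -0.184782097265123, 0.0563426845810353,
              0.0104769279900838, 0.0557133967084599, -0.126468888020088,
              0.102360462936928, -0.0942494033277623, 0.167405476656435,
              -0.194565224457622, 0.154396131857142, -0.181321427714961,
              0.249753404455288, -0.233934617236742, 0.202923229104012,
              -0.258305677518258, 0.295574228133735, -0.249288005735401,
              0.246552785818999, -0.308557750417097, 0.295606061298444,
              -0.189101020550257, 0.057163193741678, 0.0725165222588569,
              -0.126095532092493)
  wd <- wavedec(x, "db6", level = 2)
  expect_equal(wd$a, a2_ref, tolerance = 1e-10)
  expect_equal(wd$d[[2]], d2_ref, tolerance = 1e-10)
  expect_equal(wd$d[[1]], d1_ref, tolerance = 1e-10)
})

test_that("decomposition/reconstruction is a perfect-reconstruction pair", {
  set.seed(12)
  for (n in c(33, 64, 100, 257)) {
    for (w in c("db6", "db3", "sym6")) {
      x <- rnorm(n)
      lev <- max(1, floor(log2(n / (length(fhrcluster:::.wavelet_dec_lo[[w]]) - 1))))
      wd <- wavedec(x, w, lev)
      expect_equal(waverec(wd), x, tolerance = 1e-9)
    }
  }
  expect_error(wavedec(rnorm(32), "haar9"), "unknown wavelet")
})

test_that("universal threshold follows the MAD closed form", {
  expect_equal(universal_threshold(rep(0, 100), 100), 0)
  expect_equal(universal_threshold(c(-1, 1, -1, 1), 4),
               (1 / 0.6745) * sqrt(2 * log(4)))
  expect_error(universal_threshold(numeric(0), 10), "empty")
  # Monte-Carlo: i.i.d. N(0,1) details, n_total = 1e4 -> thr ~ sqrt(2 ln 1e4)
  set.seed(42)
  thrs <- replicate(100, universal_threshold(rnorm(5000), 1e4))
  target <- sqrt(2 * log(1e4))
  expect_true(all(abs(thrs - target) / target < 0.10))
})

test_that("denoising removes DC and baseline wander, preserves length", {
  dc <- ecg_record(rep(5.0, 8192), fs = 1000)
  out <- denoise(dc)
  expect_equal(out$n, 8192L)
  expect_lt(max(abs(out$samples)), 1e-6)

  t <- (0:8191) / 1000
  bw <- ecg_record(sin(2 * pi * 0.25 * t), fs = 1000)
  outbw <- denoise(bw)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(outbw$samples) / rms(bw$samples), 0.05)
})

test_that("short signals fall back to the largest feasible depth", {
  x <- ecg_record(sin(1:300 / 5) + 2, fs = 100)
  expect_warning(out <- denoise(x), "at most")
  expect_equal(out$n, 300L)
})

test_that("denoising preserves QRS amplitude and peak positions", {
  cfg <- synth_config(duration_s = 30, noise_sd = 0, wander_amp = 0, seed = 8)
  clean <- generate_aecg(cfg)
  den <- denoise(clean$record)
  pts_before <- find_maxmin_points(clean$record)
  pts_after <- find_maxmin_points(den)
  for (b in clean$maternal_truth$indices) {
    near_b <- pts_before[abs(pts_before$max_idx - b) <= 5, ]
    near_a <- pts_after[abs(pts_after$max_idx - b) <= 5, ]
    expect_gt(max(near_a$amplitude), 0.8 * max(near_b$amplitude))
  }
  # with wander present, denoising shifts each beat's nearest peak by
  # <= 5 samples relative to the clean signal's peak
  cfgw <- synth_config(duration_s = 30, noise_sd = 0, wander_amp = 0.5,
                       seed = 8)
  ptsw <- find_maxmin_points(denoise(generate_aecg(cfgw)$record))
  for (b in clean$fetal_truth$indices) {
    p_clean <- pts_before$max_idx[which.min(abs(pts_before$max_idx - b))]
    p_den <- ptsw$max_idx[which.min(abs(ptsw$max_idx - b))]
    expect_lte(abs(p_den - p_clean), 5)
  }
})

test_that("denoising is nearly idempotent", {
  synth <- short_synth("scenario1", seed = 14, duration_s = 30)
  d1 <- denoise(synth$record)
  thr <- attr(d1, "denoise_threshold")
  d2 <- denoise(d1)
  rms_diff <- sqrt(mean((d2$samples - d1$samples)^2))
  expect_lt(rms_diff, thr)
})
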