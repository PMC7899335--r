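test_that("threshold calibration averages per-image background thresholds", {
  # identical control images: threshold equals the single-image value
  g <- gen_dual_channel(reporter_truth(background_mean = 100, noise_sd = 4,
                                       seed = 2))
  trio <- list(list(sep = g$sep, mcherry = g$mcherry),
               list(sep = g$sep, mcherry = g$mcherry),
               list(sep = g$sep, mcherry = g$mcherry))
  ts <- calibrate_thresholds(trio)
  one <- glrquant:::estimate_background_2d(g$sep)
  expect_equal(ts$t_sep, one$bg_mean + 4 * one$bg_sd, tolerance = 1e-12)

  # two noiseless backgrounds 100 and 200 -> channel threshold 150
  mk <- function(level) channel_image(matrix(level, 30, 30), "SEP")
  pairs <- list(list(sep = mk(100), mcherry = mk(100)),
                list(sep = mk(200), mcherry = mk(200)),
                list(sep = mk(150), mcherry = mk(150)))
  expect_equal(calibrate_thresholds(pairs)$t_sep, 150)

  # synthetic wild-type set: threshold within 2% of bg_mean + 4 bg_sd
  wt <- lapply(1:5, function(i) {
    gg <- gen_dual_channel(reporter_truth(background_mean = 100,
                                          noise_sd = 6, total_per_pixel = 400,
                                          seed = 100 + i))
    list(sep = gg$sep, mcherry = gg$mcherry)
  })
  ts2 <- calibrate_thresholds(wt)
  expect_lt(abs(ts2$t_mcherry - (100 + 4 * 6)) / (100 + 4 * 6), 0.02)

  expect_error(calibrate_thresholds(trio[1:2]), ">= 3")
})

test_that("integrated density equals the brute-force pixel sum", {
  # uniform image, 50-px ROI, threshold 5 -> 500
  img <- matrix(10, 10, 10)
  r <- roi(rows = c(0L, 5L), cols = c(0L, 10L))
  expect_equal(integrated_density(img, r, 5), 500)
  # threshold above the maximum -> 0
  expect_equal(integrated_density(img, r, 10), 0)

  # random image vs explicit double loop
  set.seed(8)
  rimg <- matrix(runif(400, 0, 100), 20, 20)
  rr <- roi(rows = c(3L, 17L), cols = c(2L, 20L))
  thr <- 40
  acc <- 0
  for (i in 4:17) for (j in 3:20)
    if (rimg[i, j] > thr) acc <- acc + rimg[i, j]
  expect_equal(integrated_density(rimg, rr, thr), acc)

  expect_error(roi(rows = c(3L, 3L), cols = c(0L, 5L)), "empty")
  expect_error(integrated_density(img, roi(rows = c(0L, 20L),
                                           cols = c(0L, 5L))),
               "bounds")
})

test_that("pair quantification reproduces the forward-model ratio", {
  # hand ratio
  thr <- list(t_sep = 0, t_mcherry = 0)
  a <- channel_image(matrix(4, 10, 10), "SEP")
  b <- channel_image(matrix(8, 10, 10), "mCherry")
  q1 <- quantify_pair(a, b, roi_full(a), thr)
  expect_equal(q1$ratio, 0.5)

  # identical images, same threshold -> ratio exactly 1
  q2 <- quantify_pair(channel_image(matrix(7, 5, 5), "SEP"),
                      channel_image(matrix(7, 5, 5), "mCherry"),
                      roi(rows = c(0L, 5L), cols = c(0L, 5L)),
                      list(t_sep = 2, t_mcherry = 2))
  expect_equal(q2$ratio, 1.0)

  # synthetic pair, noiseless, q = 1: ratio = f_surf to 1e-6
  g <- gen_dual_channel(reporter_truth(f_surf = 0.6, q = 1,
                                       total_per_pixel = 300))
  band <- g$truth$band_rows
  r <- roi(rows = c(min(band) - 1L, max(band)), cols = c(0L, ncol(g$sep)))
  q3 <- quantify_pair(g$sep, g$mcherry, r, list(t_sep = 1, t_mcherry = 1))
  expect_equal(q3$ratio, 0.6, tolerance = 1e-6)

  # zero mCherry signal: flagged, not an exception
  z <- quantify_pair(channel_image(matrix(5, 4, 4), "SEP"),
                     channel_image(matrix(0, 4, 4), "mCherry"),
                     roi(rows = c(0L, 4L), cols = c(0L, 4L)),
                     list(t_sep = 0, t_mcherry = 0))
  expect_true(is.na(z$ratio) && !z$ratio_defined)

  expect_error(quantify_pair(a, channel_image(matrix(1, 3, 3), "mCherry"),
                             roi_full(a), thr), "shapes")
})

test_that("ratio is invariant to a common gain and increasing in f_surf", {
  g <- gen_dual_channel(reporter_truth(f_surf = 0.4, q = 0.9,
                                       total_per_pixel = 250,
                                       background_mean = 50, noise_sd = 3,
                                       seed = 6))
  r <- roi_full(g$sep)
  thr <- list(t_sep = 80, t_mcherry = 80)
  q1 <- quantify_pair(g$sep, g$mcherry, r, thr)
  gain <- 2.5
  q2 <- quantify_pair(channel_image(unclass(g$sep) * gain, "SEP"),
                      channel_image(unclass(g$mcherry) * gain, "mCherry"),
                      r, list(t_sep = 80 * gain, t_mcherry = 80 * gain))
  expect_equal(q2$ratio, q1$ratio, tolerance = 1e-12)

  ratios <- vapply(seq(0.1, 0.9, by = 0.2), function(f) {
    gg <- gen_dual_channel(reporter_truth(f_surf = f, q = 0.8))
    quantify_pair(gg$sep, gg$mcherry, roi_full(gg$sep),
                  list(t_sep = 1, t_mcherry = 1))$ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("control normalization maps the control mean to 1", {
  qs <- data.frame(ratio = c(0.4, 0.6, 0.435),
                   genotype = c("WT", "WT", "mut"))
  out <- normalize_to_control(qs, "WT")
  expect_equal(out$ratio_norm, c(0.8, 1.2, 0.87))
  expect_equal(mean(out$ratio_norm[out$genotype == "WT"]), 1.0)

  same <- data.frame(ratio = rep(0.5, 6),
                     genotype = rep(c("WT", "mut"), 3))
  expect_true(all(normalize_to_control(same, "WT")$ratio_norm == 1))

  # per-day normalization uses only same-day controls
  byday <- data.frame(ratio = c(0.5, 0.25, 1.0, 0.5),
                      genotype = c("WT", "mut", "WT", "mut"),
                      acquisition_day = c("d1", "d1", "d2", "d2"))
  out2 <- normalize_to_control(byday, "WT")
  expect_equal(out2$ratio_norm, c(1, 0.5, 1, 0.5))

  expect_error(normalize_to_control(qs, "absent"), "control")
})

test_that("two-genotype batch recovers the ratio of surface fractions", {
  sim_group <- function(f, n, seed0) {
    vapply(seq_len(n), function(i) {
      g <- gen_dual_channel(reporter_truth(f_surf = f, q = 1,
                                           total_per_pixel = 200,
                                           noise_sd = 4, seed = seed0 + i))
      band <- g$truth$band_rows
      r <- roi(rows = c(min(band) - 1L, max(band)),
               cols = c(0L, ncol(g$sep)))
      quantify_pair(g$sep, g$mcherry, r, list(t_sep = 20,
                                              t_mcherry = 20))$ratio
    }, 0)
  }
  wt <- sim_group(0.5, 25, 1000)
  mut <- sim_group(0.35, 25, 2000)
  qs <- data.frame(ratio = c(wt, mut),
                   genotype = rep(c("WT", "mut"), each = 25))
  out <- normalize_to_control(qs, "WT")
  mut_norm <- mean(out$ratio_norm[out$genotype == "mut"])
  se <- sd(out$ratio_norm[out$genotype == "mut"]) / sqrt(25)
  expect_lt(abs(mut_norm - 0.7), 3 * se + 1e-3)
})

test_that("surface-fraction inversion is the exact inverse of the model", {
  expect_equal(estimate_surface_fraction(1.0, q = 1)$f_hat, 1.0)
  expect_equal(estimate_surface_fraction(0.55, q = 0.9)$f_hat, 0.5,
               tolerance = 1e-12)
  expect_error(estimate_surface_fraction(0.5, q = 0), "non-identifiable")

  # inversion o forward = identity on a grid, multiple quench efficiencies
  for (q in c(0.5, 0.9, 1.0)) {
    for (f in seq(0, 1, by = 0.1)) {
      ratio <- f + (1 - f) * (1 - q)
      expect_equal(estimate_surface_fraction(ratio, q = q)$f_hat, f,
                   tolerance = 1e-9)
    }
  }

  # clamping is flagged, not fatal
  cl <- estimate_surface_fraction(1.2, q = 1)
  expect_equal(cl$f_hat, 1)
  expect_true(cl$clamped)
})

test_that("surface fraction recovered from noisy synthetic sweeps", {
  errs <- vapply(seq(0.1, 0.9, by = 0.1), function(f) {
    f_hats <- vapply(1:25, function(i) {
      g <- gen_dual_channel(reporter_truth(f_surf = f, q = 0.95,
                                           total_per_pixel = 200,
                                           noise_sd = 4,
                                           seed = round(f * 1e4) + i))
      band <- g$truth$band_rows
      r <- roi(rows = c(min(band) - 1L, max(band)),
               cols = c(0L, ncol(g$sep)))
      ratio <- quantify_pair(g$sep, g$mcherry, r,
                             list(t_sep = 20, t_mcherry = 20))$ratio
      estimate_surface_fraction(ratio, q = 0.95)$f_hat
    }, 0)
    abs(mean(f_hats) - f)
  }, 0)
  expect_lt(mean(errs), 0.02)
})

test_that("soma totals are plain sums with area", {
  img <- matrix(10, 20, 20)
  st <- soma_total(img, roi(rows = c(0L, 10L), cols = c(0L, 10L)))
  expect_equal(st$area_px, 100)
  expect_equal(st$intden, 1000)
  z <- soma_total(matrix(0, 5, 5), roi(rows = c(0L, 5L), cols = c(0L, 5L)))
  expect_equal(z$intden, 0)
  set.seed(4)
  rimg <- matrix(rexp(900, 0.1), 30, 30)
  mask <- matrix(runif(900) < 0.3, 30, 30); mask[1, 1] <- TRUE
  st2 <- soma_total(rimg, roi(mask = mask))
  expect_equal(st2$intden, sum(rimg[mask]))
  expect_equal(st2$area_px, sum(mask))
})

test_that("16-bit TIFF round trip preserves integer gray levels", {
  g <- gen_dual_channel(reporter_truth(total_per_pixel = 431.7,
                                       background_mean = 99.2,
                                       noise_sd = 7, seed = 12))
  path <- withr::local_tempfile(fileext = ".tif")
  write_channel_tiff(g$mcherry, path)
  back <- read_channel_tiff(path, channel = "mCherry")
  expect_equal(unclass(back), round(unclass(g$mcherry)),
               ignore_attr = TRUE, tolerance = 1e-9)
})
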