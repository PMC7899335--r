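test_that("bleach geometry follows the nested central-interval rule", {
  # 32 um image: 16 um bleach inset 8 um per side, 8 um quant inset 4 um
  g <- make_geometry(32)
  expect_equal(g$bleach_um, c(8, 24))
  expect_equal(g$quant_um, c(12, 20))

  g40 <- make_geometry(40)
  expect_equal(g40$bleach_um, c(10, 30))
  expect_equal(g40$quant_um, c(15, 25))

  expect_error(make_geometry(0), "> 0")

  # proportional rule on arbitrary lengths: widths 1/2 and 1/4, quant
  # strictly inside bleach
  for (L in c(5, 17.3, 64, 100)) {
    gg <- make_geometry(L)
    expect_equal(diff(gg$bleach_um), L / 2)
    expect_equal(diff(gg$quant_um), L / 4)
    expect_gt(gg$quant_um[1], gg$bleach_um[1])
    expect_lt(gg$quant_um[2], gg$bleach_um[2])
  }

  expect_equal(interval_to_px(c(12, 20), 0.1), c(120L, 200L))
})

test_that("recovery normalization divides by the pre-bleach total", {
  s <- frap_series("SEP", pre_total = 1000, t_min = c(0, 2.5, 5, 10),
                   total = c(400, 550, 650, 800))
  rc <- recovery_fraction(s)
  expect_equal(rc$normalized, c(0.40, 0.55, 0.65, 0.80))

  flat <- frap_series("mCherry", pre_total = 700, t_min = c(0, 2.5, 5, 10),
                      total = rep(700, 4))
  expect_equal(recovery_fraction(flat)$normalized, rep(1, 4))

  z <- frap_series("SEP", pre_total = 0, t_min = 0:2, total = rep(0, 3))
  expect_error(recovery_fraction(z), "pre-bleach")

  # invariance to a global gain
  s2 <- frap_series("SEP", pre_total = 3000, t_min = c(0, 2.5, 5, 10),
                    total = 3 * c(400, 550, 650, 800))
  expect_equal(recovery_fraction(s2)$normalized, rc$normalized)
})

test_that("simulated series match an independent Euler integration", {
  tr <- frap_truth(f_surf = 0.4, q = 0.85, beta = 0.8, k_exo = 0.15,
                   k_endo = 0.1, k_ext = 0.05)
  g <- gen_frap_series(tr)
  got_sep <- recovery_fraction(g$sep)$normalized
  got_mch <- recovery_fraction(g$mcherry)$normalized
  pre_sep <- 0.4 + (1 - 0.85) * 0.6
  y0_sep <- c(0.2 * 0.4, 0.8 * 0.4, 0.6, 0)
  y0_mch <- c(0.2 * 0.4, 0.8 * 0.4, 0.2 * 0.6, 0.8 * 0.6)
  for (i in seq_along(tr$timepoints_min)) {
    t <- tr$timepoints_min[i]
    ys <- oracle_frap_euler(y0_sep, 0.4, 0.15, 0.1, 0.05, t)
    ym <- oracle_frap_euler(y0_mch, 0.4, 0.15, 0.1, 0.05, t)
    expect_equal(got_sep[i], (ys[1] + 0.15 * ys[3]) / pre_sep,
                 tolerance = 1e-5)
    expect_equal(got_mch[i], ym[1] + ym[3], tolerance = 1e-5)
  }
})

test_that("image-level extraction reproduces the ODE signal", {
  # build per-timepoint images whose quant-ROI signal follows the model
  tr <- frap_truth(f_surf = 0.5, q = 1, beta = 0.5)
  g <- gen_frap_series(tr)
  px <- 0.1
  L <- 32
  ncol_img <- round(L / px)
  qpx <- interval_to_px(make_geometry(L)$quant_um, px)
  mk_img <- function(level) {
    img <- matrix(50, 20, ncol_img) # background 50 everywhere
    img[9:12, (qpx[1] + 1):qpx[2]] <- level
    img
  }
  lvl <- c(g$sep$pre_total, g$sep$total)
  imgs <- lapply(lvl, mk_img)
  s <- frap_series_from_images(imgs[[1]], imgs[-1],
                               t_min = tr$timepoints_min, pixel_size_um = px,
                               channel = "SEP", threshold = 60)
  expect_equal(recovery_fraction(s)$normalized,
               recovery_fraction(g$sep)$normalized, tolerance = 1e-9)
})

test_that("exponential fit is exact on noiseless curves and flags flat ones", {
  t <- c(0, 2.5, 5, 10)
  exact <- data.frame(t_min = t,
                      normalized = 0.4 + 0.3 * (1 - exp(-0.2 * t)))
  fit <- fit_recovery(exact)
  expect_true(fit$fit_ok)
  expect_equal(fit$A, 0.3, tolerance = 1e-6)
  expect_equal(fit$k, 0.2, tolerance = 1e-6)
  expect_equal(fit$n0, 0.4)

  flat <- data.frame(t_min = t, normalized = rep(0.35, 4))
  ffit <- fit_recovery(flat)
  expect_false(ffit$fit_ok)
  expect_equal(ffit$A, 0)
  expect_true(is.na(ffit$k))

  expect_error(fit_recovery(exact[1:2, ]), ">= 3")
})

test_that("rate recovered from noisy cohorts at the 4-timepoint design", {
  tr <- frap_truth(f_surf = 0.5, q = 1, beta = 1, k_exo = 0.2,
                   k_endo = 0, k_ext = 0, noise_sd = 0.02)
  cohort <- simulate_frap_group(tr, n_worms = 100, seed = 77)
  ks <- vapply(cohort, function(w)
    fit_recovery(recovery_fraction(w$sep))$k, 0)
  expect_lt(abs(median(ks) - 0.2) / 0.2, 0.15)
})

test_that("SEP recovery lags mCherry when influx dominates", {
  # lateral influx large, no recycling: arriving SEP surface fluorescence
  # is endocytosed into the quenched pool, mCherry stays visible
  tr <- frap_truth(f_surf = 0.5, q = 1, beta = 0.9, k_exo = 0,
                   k_endo = 2, k_ext = 2,
                   timepoints_min = c(0, 0.25, 0.5, 1, 2.5, 5, 10))
  g <- gen_frap_series(tr)
  sep <- recovery_fraction(g$sep)$normalized
  mch <- recovery_fraction(g$mcherry)$normalized
  gain_sep <- sep - sep[1L]
  gain_mch <- mch - mch[1L]
  expect_true(all(gain_mch[-1L] > gain_sep[-1L]))
  # time to rise 0.3 above the floor: SEP strictly later
  t <- tr$timepoints_min
  t_rise <- function(gain) {
    i <- which(gain >= 0.3)
    if (length(i) == 0L) Inf else t[i[1L]]
  }
  expect_gt(t_rise(gain_sep), t_rise(gain_mch))
})

test_that("zero recovery pathways give no SEP signal gain", {
  # without exocytosis or influx the SEP signal can only be lost to
  # endocytic quenching, never regained
  tr <- frap_truth(f_surf = 0.5, q = 1, beta = 0.9, k_exo = 0, k_ext = 0,
                   k_endo = 0.2)
  sep <- recovery_fraction(gen_frap_series(tr)$sep)$normalized
  expect_true(all(diff(sep) <= 1e-9))
  # and with every pathway off it is exactly constant
  tr0 <- frap_truth(f_surf = 0.5, q = 1, beta = 0.9, k_exo = 0, k_ext = 0,
                    k_endo = 0)
  sep0 <- recovery_fraction(gen_frap_series(tr0)$sep)$normalized
  expect_equal(diff(sep0), rep(0, 3), tolerance = 1e-9)
})

test_that("group comparison calibrates and detects", {
  t4 <- c(0, 2.5, 5, 10)
  sim_curves <- function(k_exo, n, seed0, label) {
    tr <- frap_truth(f_surf = 0.5, q = 1, beta = 0.9, k_exo = k_exo,
                     k_endo = 0.2, k_ext = 0.05, noise_sd = 0.02)
    cohort <- simulate_frap_group(tr, n, seed = seed0)
    do.call(rbind, lapply(seq_along(cohort), function(i) {
      rc <- recovery_fraction(cohort[[i]]$sep)
      data.frame(worm_id = sprintf("%s%03d", label, i), genotype = label,
                 t_min = rc$t_min, normalized = rc$normalized)
    }))
  }

  # identical parameters: genotype effect rejected at close to alpha
  nrep <- 400
  rej <- 0
  for (r in seq_len(nrep)) {
    cur <- rbind(sim_curves(0.2, 15, 2 * r, "a"),
                 sim_curves(0.2, 15, 2 * r + 1, "b"))
    p <- compare_recovery(cur)$anova
    if (p$p[p$effect == "between"] < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nrep, 0.02)
  expect_lt(rej / nrep, 0.08)

  # recycling-dead group: detected nearly always
  hit <- 0
  for (r in 1:50) {
    cur <- rbind(sim_curves(0.2, 15, 5000 + 2 * r, "wt"),
                 sim_curves(0, 15, 5001 + 2 * r, "mut"))
    p <- compare_recovery(cur)$anova
    if (min(p$p[p$effect %in% c("between", "interaction")]) < 0.001)
      hit <- hit + 1
  }
  expect_gte(hit / 50, 0.95)

  # a group compared with its own copy: genotype F ~ 0
  one <- sim_curves(0.2, 10, 31, "a")
  dup <- one
  dup$genotype <- "b"
  dup$worm_id <- paste0("copy", dup$worm_id)
  cmp <- compare_recovery(rbind(one, dup))
  expect_lt(cmp$anova$F[cmp$anova$effect == "between"], 1e-20)
})

test_that("reference-ROI correction removes acquisition photofading", {
  t4 <- c(0, 2.5, 5, 10)
  clean <- c(0.4, 0.55, 0.65, 0.8)
  fade <- 0.97^seq_along(t4)
  s <- frap_series("SEP", pre_total = 1000, t_min = t4,
                   total = 1000 * clean * fade)
  ref <- frap_series("mCherry", pre_total = 500, t_min = t4,
                     total = 500 * fade)
  expect_equal(recovery_fraction(s, reference = ref)$normalized, clean,
               tolerance = 1e-12)
  bad_ref <- frap_series("mCherry", pre_total = 500, t_min = c(0, 1, 2, 3),
                         total = rep(500, 4))
  expect_error(recovery_fraction(s, reference = bad_ref), "timepoints")
})
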