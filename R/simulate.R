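## Synthetic-data generators with ground-truth records.
##
## Every generator takes a *truth* object holding the full generative
## parameter set (including the RNG seed) and returns the simulated data
## together with that truth record, so parameter-recovery tests can compare
## estimates against the exact values used for generation. Fixed seed implies
## byte-identical output; the caller's RNG state is never disturbed.

#' Ground truth for a synthetic fluorescence line scan
#'
#' Describes a 1-D scan as Gaussian intensity peaks (synaptic puncta) on a
#' flat background with additive Gaussian camera noise, mimicking line scans
#' drawn along the ventral nerve cord.
#'
#' @param length_um Scan length (um).
#' @param pixel_size_um Pixel size (um/px).
#' @param background_mean,background_sd Background level and noise SD (AU).
#' @param puncta Data frame with columns `center_um`, `amplitude` (AU above
#'   background), `sigma_um`; may have zero rows.
#' @param bead_mean Same-day fluorescent-bead mean intensity (AU), the
#'   normalizer for peak intensities.
#' @param noise_model `"gaussian"` (additive, camera read-noise regime,
#'   default) or `"poisson"` (shot noise: pixel values drawn as Poisson with
#'   the noiseless profile as mean).
#' @param seed Integer RNG seed.
#' @return An object of class `scan_truth`.
#' @export
scan_truth <- function(length_um = 60, pixel_size_um = 0.1,
                       background_mean = 100, background_sd = 5,
                       puncta = data.frame(center_um = numeric(),
                                           amplitude = numeric(),
                                           sigma_um = numeric()),
                       bead_mean = 250, noise_model = c("gaussian", "poisson"),
                       seed = 1L) {
  check_scalar(length_um, "length_um", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(background_mean, "background_mean", nonneg = TRUE)
  check_scalar(background_sd, "background_sd", nonneg = TRUE)
  check_scalar(bead_mean, "bead_mean", positive = TRUE)
  noise_model <- match.arg(noise_model)
  puncta <- as.data.frame(puncta)
  req <- c("center_um", "amplitude", "sigma_um")
  if (!all(req %in% names(puncta)))
    stopf("'puncta' needs columns %s", paste(req, collapse = ", "))
  if (nrow(puncta) > 0) {
    if (any(puncta$amplitude < 0)) stopf("puncta amplitudes must be >= 0")
    if (any(puncta$sigma_um <= 0)) stopf("puncta sigma_um must be > 0")
    if (any(puncta$center_um < 0 | puncta$center_um > length_um))
      stopf("puncta centers must lie in [0, length_um]")
  }
  structure(list(length_um = length_um, pixel_size_um = pixel_size_um,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 puncta = puncta[order(puncta$center_um), , drop = FALSE],
                 bead_mean = bead_mean, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "scan_truth")
}

#' Generate a synthetic line scan
#'
#' Pixel intensities are the superposition of the background mean and all
#' Gaussian puncta, plus noise:
#' `I(x) = bg + sum_j A_j exp(-(x - c_j)^2 / (2 s_j^2)) + eps`.
#'
#' @param truth A [scan_truth()].
#' @return A list with elements `scan` (a [line_scan()]) and `truth`.
#' @examples
#' tr <- scan_truth(puncta = data.frame(center_um = 30, amplitude = 50,
#'                                      sigma_um = 0.5),
#'                  background_sd = 0)
#' max(gen_linescan(tr)$scan$intensity)  # 150 at the punctum center
#' @export
gen_linescan <- function(truth) {
  stopifnot(inherits(truth, "scan_truth"))
  n <- round(truth$length_um / truth$pixel_size_um)
  x <- (seq_len(n) - 1L) * truth$pixel_size_um
  mu <- rep(truth$background_mean, n)
  for (j in seq_len(nrow(truth$puncta))) {
    p <- truth$puncta[j, ]
    mu <- mu + p$amplitude * exp(-(x - p$center_um)^2 / (2 * p$sigma_um^2))
  }
  intensity <- with_seed(truth$seed, {
    if (truth$noise_model == "poisson") stats::rpois(n, lambda = mu)
    else mu + stats::rnorm(n, 0, truth$background_sd)
  })
  intensity <- pmax(intensity, 0)
  list(scan = line_scan(intensity, truth$pixel_size_um, position_um = x,
                        bead_mean = truth$bead_mean),
       truth = truth)
}

#' Ground truth for a paired SEP/mCherry reporter image
#'
#' The dual reporter places a pH-sensitive SEP (superecliptic pHluorin) and a
#' pH-insensitive mCherry on the same receptor. mCherry reports total
#' receptor; SEP is quenched in acidic endosomes with efficiency `q`, so the
#' SEP channel reports `f_surf + (1 - f_surf) * (1 - q)` of the total.
#' Signal occupies a horizontal neurite band through the image center; the
#' rest of the frame is background.
#'
#' @param total_per_pixel Total receptor fluorescence density in the neurite
#'   band (AU/px, mCherry-equivalent).
#' @param f_surf Surface pool fraction, in `[0, 1]`.
#' @param q SEP quench efficiency in acidic compartments, in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD (AU), both channels.
#' @param roi_shape Image shape `c(nrow, ncol)` in pixels.
#' @param background_mean Background level outside the band (AU).
#' @param band_frac Fraction of rows occupied by the neurite band.
#' @param seed Integer RNG seed.
#' @return An object of class `reporter_truth`.
#' @export
reporter_truth <- function(total_per_pixel = 200, f_surf = 0.5, q = 1,
                           noise_sd = 0, roi_shape = c(40L, 100L),
                           background_mean = 0, band_frac = 0.2, seed = 1L) {
  check_scalar(total_per_pixel, "total_per_pixel", nonneg = TRUE)
  check_scalar(f_surf, "f_surf", frac = TRUE)
  check_scalar(q, "q", frac = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(background_mean, "background_mean", nonneg = TRUE)
  check_scalar(band_frac, "band_frac", frac = TRUE)
  if (length(roi_shape) != 2L || any(roi_shape < 1))
    stopf("'roi_shape' must be c(nrow, ncol), both >= 1")
  nr <- as.integer(roi_shape[1L])
  half <- max(1L, round(nr * band_frac / 2))
  mid <- (nr + 1L) / 2
  band_rows <- seq_len(nr)[abs(seq_len(nr) - mid) < half]
  structure(list(total_per_pixel = total_per_pixel, f_surf = f_surf, q = q,
                 noise_sd = noise_sd, roi_shape = as.integer(roi_shape),
                 background_mean = background_mean, band_rows = band_rows,
                 seed = as.integer(seed)),
            class = "reporter_truth")
}

#' Generate a paired SEP/mCherry image set
#'
#' Per pixel in the neurite band: `mcherry = total + noise` and
#' `sep = total * (f_surf + (1 - f_surf) * (1 - q)) + noise`; both channels
#' share the spatial layout. Outside the band both channels carry
#' `background_mean + noise`.
#'
#' @param truth A [reporter_truth()].
#' @return A list with `sep` and `mcherry` ([channel_image()] objects) and
#'   `truth` (which records `band_rows`, the signal rows).
#' @export
gen_dual_channel <- function(truth) {
  stopifnot(inherits(truth, "reporter_truth"))
  nr <- truth$roi_shape[1L]; nc <- truth$roi_shape[2L]
  base <- matrix(truth$background_mean, nr, nc)
  in_band <- matrix(FALSE, nr, nc)
  in_band[truth$band_rows, ] <- TRUE
  mch_mu <- base
  mch_mu[in_band] <- truth$background_mean + truth$total_per_pixel
  sep_visible <- truth$f_surf + (1 - truth$f_surf) * (1 - truth$q)
  sep_mu <- base
  sep_mu[in_band] <- truth$background_mean +
    truth$total_per_pixel * sep_visible
  noise <- with_seed(truth$seed, list(
    sep = matrix(stats::rnorm(nr * nc, 0, truth$noise_sd), nr, nc),
    mch = matrix(stats::rnorm(nr * nc, 0, truth$noise_sd), nr, nc)))
  list(sep = channel_image(pmax(sep_mu + noise$sep, 0), channel = "SEP"),
       mcherry = channel_image(pmax(mch_mu + noise$mch, 0),
                               channel = "mCherry"),
       truth = truth)
}

#' Ground truth for a dual-channel FRAP experiment
#'
#' Receptor in the quantification ROI is split into surface and internal
#' pools; each pool carries an unbleached and a bleached label fraction per
#' channel. The bleach multiplies mCherry unbleached pools by `1 - beta` in
#' both compartments, but the SEP unbleached pool only at the surface:
#' quenched SEP in acidic endosomes absorbs no light and is therefore
#' protected from the bleach. Recycling (`k_exo`), endocytosis (`k_endo`)
#' and exchange with the unbleached pool outside the ROI (`k_ext`) then
#' redistribute labels.
#'
#' `f_surf` is the pre-bleach surface fraction; the bleach-free signal is
#' stationary when `f_surf = k_exo / (k_exo + k_endo)` (the kinetic steady
#' state), which the defaults satisfy.
#'
#' @param f_surf Pre-bleach surface pool fraction.
#' @param q SEP quench efficiency in acidic compartments.
#' @param beta Bleach efficiency in `[0, 1]`.
#' @param k_exo Internal-to-surface recycling rate (1/min).
#' @param k_endo Surface-to-internal endocytosis rate (1/min).
#' @param k_ext Exchange rate with unbleached receptor outside the ROI
#'   (1/min): pools relax toward the unbleached reservoir composition.
#' @param timepoints_min Post-bleach imaging times (min), strictly
#'   increasing, the first being the immediate post-bleach image at 0.
#' @param noise_sd Multiplicative measurement noise SD (fraction of signal).
#' @param pre_total Pre-bleach mCherry ROI total (AU), the intensity scale.
#' @param seed Integer RNG seed.
#' @return An object of class `frap_truth`.
#' @export
frap_truth <- function(f_surf = 0.5, q = 1, beta = 0.9,
                       k_exo = 0.2, k_endo = 0.2, k_ext = 0.05,
                       timepoints_min = c(0, 2.5, 5, 10),
                       noise_sd = 0, pre_total = 1000, seed = 1L) {
  check_scalar(f_surf, "f_surf", frac = TRUE)
  check_scalar(q, "q", frac = TRUE)
  check_scalar(beta, "beta", frac = TRUE)
  check_scalar(k_exo, "k_exo", nonneg = TRUE)
  check_scalar(k_endo, "k_endo", nonneg = TRUE)
  check_scalar(k_ext, "k_ext", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(pre_total, "pre_total", positive = TRUE)
  if (length(timepoints_min) < 1L || any(diff(timepoints_min) <= 0))
    stopf("'timepoints_min' must be strictly increasing")
  if (timepoints_min[1L] < 0) stopf("timepoints must be >= 0")
  structure(list(f_surf = f_surf, q = q, beta = beta, k_exo = k_exo,
                 k_endo = k_endo, k_ext = k_ext,
                 timepoints_min = as.numeric(timepoints_min),
                 noise_sd = noise_sd, pre_total = pre_total,
                 seed = as.integer(seed)),
            class = "frap_truth")
}

## Label kinetics for the four pools of one channel.
## y = (S_u, S_b, I_u, I_b); external reservoir is all-unbleached with
## composition (f_surf, 1 - f_surf), so unbleached pools relax toward it and
## bleached pools wash out, both at rate k_ext.
frap_ode <- function(t, y, p) {
  exch_Su <- p$k_exo * y[3L] - p$k_endo * y[1L]
  exch_Sb <- p$k_exo * y[4L] - p$k_endo * y[2L]
  list(c(
    exch_Su + p$k_ext * (p$f_surf - y[1L]),
    exch_Sb - p$k_ext * y[2L],
    -exch_Su + p$k_ext * ((1 - p$f_surf) - y[3L]),
    -exch_Sb - p$k_ext * y[4L]))
}

## Deterministic pool trajectories for both channels at the requested
## post-bleach times. Returns a list with matrices `sep` and `mch`
## (rows = timepoints, cols = S_u, S_b, I_u, I_b). Solutions are cached on
## the kinetic parameters: cohort simulations re-use one solve.
.frap_pool_cache <- new.env(parent = emptyenv())

frap_pools <- function(truth, times = truth$timepoints_min) {
  key <- paste(c(truth$f_surf, truth$beta, truth$k_exo, truth$k_endo,
                 truth$k_ext, times), collapse = "|")
  hit <- get0(key, envir = .frap_pool_cache)
  if (!is.null(hit)) return(hit)
  out <- frap_pools_solve(truth, times)
  assign(key, out, envir = .frap_pool_cache)
  out
}

frap_pools_solve <- function(truth, times) {
  f <- truth$f_surf; b <- truth$beta
  init <- list(
    mch = c(S_u = (1 - b) * f, S_b = b * f,
            I_u = (1 - b) * (1 - f), I_b = b * (1 - f)),
    sep = c(S_u = (1 - b) * f, S_b = b * f, I_u = 1 - f, I_b = 0))
  solve_one <- function(y0) {
    tt <- unique(c(0, times))
    out <- deSolve::lsoda(y0, tt, frap_ode, truth,
                          rtol = 1e-8, atol = 1e-10)
    out[match(times, out[, "time"]), -1L, drop = FALSE]
  }
  list(sep = solve_one(init$sep), mch = solve_one(init$mch))
}

## Channel signals from pool matrices: quenched internal SEP is invisible.
frap_signal <- function(pools, q) {
  list(sep = pools$sep[, "S_u"] + (1 - q) * pools$sep[, "I_u"],
       mch = pools$mch[, "S_u"] + pools$mch[, "I_u"])
}

#' Generate a dual-channel FRAP series
#'
#' Solves the pool kinetics (deterministically, to relative tolerance 1e-8)
#' and reports per-channel ROI totals at the pre-bleach image and each
#' post-bleach timepoint, with optional multiplicative measurement noise.
#' The reported SEP signal is `S_u + (1 - q) * I_u`, the mCherry signal
#' `S_u + I_u`, each scaled so that the pre-bleach mCherry total equals
#' `pre_total`.
#'
#' @param truth A [frap_truth()].
#' @return A list with `sep` and `mcherry` ([frap_series()] objects) and
#'   `truth`.
#' @export
gen_frap_series <- function(truth) {
  stopifnot(inherits(truth, "frap_truth"))
  pools <- frap_pools(truth)
  sig <- frap_signal(pools, truth$q)
  pre <- list(sep = truth$f_surf + (1 - truth$q) * (1 - truth$f_surf),
              mch = 1)
  scale <- truth$pre_total
  raw <- list(sep = c(pre$sep, sig$sep) * scale,
              mch = c(pre$mch, sig$mch) * scale)
  if (truth$noise_sd > 0) {
    raw <- with_seed(truth$seed, lapply(raw, function(v)
      pmax(v * (1 + stats::rnorm(length(v), 0, truth$noise_sd)), 0)))
  }
  mk <- function(v, ch) frap_series(channel = ch, pre_total = v[1L],
                                    t_min = truth$timepoints_min,
                                    total = v[-1L])
  list(sep = mk(raw$sep, "SEP"), mcherry = mk(raw$mch, "mCherry"),
       truth = truth)
}

#' Simulate a FRAP cohort
#'
#' Independent worms sharing one parameter set; each worm gets its own noise
#' draw via a seed derived from `seed`.
#'
#' @param truth A [frap_truth()] (its `seed` field is ignored here).
#' @param n_worms Number of worms.
#' @param seed Cohort seed.
#' @return A list of `n_worms` results of [gen_frap_series()].
#' @export
simulate_frap_group <- function(truth, n_worms, seed = 1L) {
  stopifnot(inherits(truth, "frap_truth"), n_worms >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_worms))
  lapply(seeds, function(s) {
    truth$seed <- s
    gen_frap_series(truth)
  })
}

#' Ground truth for synthetic behavioral assays
#'
#' One row per genotype; the columns are the generative parameters of the
#' four assays scored by the behavior module.
#'
#' @param genotypes Data frame with columns `genotype`, `p_resp` (response
#'   probability per nose-touch trial or light pulse), `lambda_thrash`
#'   (expected thrashes per 30 s), `lambda_rev` (expected spontaneous
#'   reversals per 5 min), `paralysis_rate` (exponential hazard on aldicarb,
#'   1/min), `n_worms`.
#' @param n_trials Nose-touch trials per worm (10 in the assay).
#' @param n_pulses Light pulses per worm in the optogenetic ASH assay.
#' @param thrash_period_s Thrash counting window (s).
#' @param reversal_period_min Reversal counting window (min).
#' @param aldicarb_check_min Paralysis check interval (min).
#' @param aldicarb_end_min Assay end / censoring time (min).
#' @param worms_per_plate Worms per aldicarb plate.
#' @param paralysis_shape Weibull shape of the paralysis-time distribution;
#'   1 (default) is the memoryless exponential hazard, > 1 an accelerating
#'   hazard. `paralysis_rate` stays the inverse scale.
#' @param seed Integer RNG seed.
#' @return An object of class `behavior_truth`.
#' @export
behavior_truth <- function(genotypes = data.frame(
                             genotype = c("WT", "mutant"),
                             p_resp = c(0.9, 0.5),
                             lambda_thrash = c(40, 25),
                             lambda_rev = c(12, 6),
                             paralysis_rate = c(0.02, 0.02),
                             n_worms = c(30L, 30L)),
                           n_trials = 10L, n_pulses = 5L,
                           thrash_period_s = 30, reversal_period_min = 5,
                           aldicarb_check_min = 15, aldicarb_end_min = 120,
                           worms_per_plate = 20L, paralysis_shape = 1,
                           seed = 1L) {
  check_scalar(paralysis_shape, "paralysis_shape", positive = TRUE)
  genotypes <- as.data.frame(genotypes)
  req <- c("genotype", "p_resp", "lambda_thrash", "lambda_rev",
           "paralysis_rate", "n_worms")
  if (!all(req %in% names(genotypes)))
    stopf("'genotypes' needs columns %s", paste(req, collapse = ", "))
  if (any(genotypes$p_resp < 0 | genotypes$p_resp > 1))
    stopf("p_resp must be in [0, 1]")
  if (any(genotypes$lambda_thrash < 0) || any(genotypes$lambda_rev < 0) ||
      any(genotypes$paralysis_rate < 0))
    stopf("rates must be >= 0")
  if (any(genotypes$n_worms < 1)) stopf("n_worms must be >= 1")
  structure(list(genotypes = genotypes, n_trials = as.integer(n_trials),
                 n_pulses = as.integer(n_pulses),
                 thrash_period_s = thrash_period_s,
                 reversal_period_min = reversal_period_min,
                 aldicarb_check_min = aldicarb_check_min,
                 aldicarb_end_min = aldicarb_end_min,
                 worms_per_plate = as.integer(worms_per_plate),
                 paralysis_shape = paralysis_shape,
                 seed = as.integer(seed)),
            class = "behavior_truth")
}

#' Generate synthetic behavioral assay tables
#'
#' Nose-touch and optogenetic responses are Bernoulli per trial, thrash and
#' reversal counts Poisson over the stated window, and aldicarb paralysis
#' times exponential (right-censored at assay end, tallied per plate at the
#' check interval).
#'
#' @param truth A [behavior_truth()].
#' @return A list of tables: `nose_touch` and `opto` (worm_id, genotype,
#'   trial, response), `thrash` and `reversal` (worm_id, genotype, count,
#'   period, assay), `aldicarb` (plate_id, genotype, time_min, n_paralyzed,
#'   n_total), plus `truth`.
#' @export
gen_behavior <- function(truth) {
  stopifnot(inherits(truth, "behavior_truth"))
  g <- truth$genotypes
  with_seed(truth$seed, {
    trial_tab <- function(n_tr) {
      do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
        n <- g$n_worms[i]
        data.frame(
          worm_id = rep(sprintf("%s_w%03d", g$genotype[i], seq_len(n)),
                        each = n_tr),
          genotype = g$genotype[i],
          trial = rep(seq_len(n_tr), times = n),
          response = stats::rbinom(n * n_tr, 1L, g$p_resp[i]))
      }))
    }
    nose <- trial_tab(truth$n_trials)
    opto <- trial_tab(truth$n_pulses)

    count_tab <- function(lambda_col, period, assay) {
      do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
        n <- g$n_worms[i]
        data.frame(
          worm_id = sprintf("%s_w%03d", g$genotype[i], seq_len(n)),
          genotype = g$genotype[i],
          count = stats::rpois(n, g[[lambda_col]][i]),
          period = period, assay = assay)
      }))
    }
    thrash <- count_tab("lambda_thrash", truth$thrash_period_s, "thrash")
    reversal <- count_tab("lambda_rev", truth$reversal_period_min, "reversal")

    checks <- seq(truth$aldicarb_check_min, truth$aldicarb_end_min,
                  by = truth$aldicarb_check_min)
    aldicarb <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n_worms[i]
      times <- if (g$paralysis_rate[i] <= 0) rep(Inf, n)
      else if (truth$paralysis_shape == 1)
        stats::rexp(n, g$paralysis_rate[i])
      else stats::rweibull(n, shape = truth$paralysis_shape,
                           scale = 1 / g$paralysis_rate[i])
      plate <- ceiling(seq_len(n) / truth$worms_per_plate)
      do.call(rbind, lapply(unique(plate), function(pl) {
        tp <- times[plate == pl]
        data.frame(
          plate_id = sprintf("%s_p%02d", g$genotype[i], pl),
          genotype = g$genotype[i],
          time_min = checks,
          n_paralyzed = vapply(checks, function(ck) sum(tp <= ck), 0L),
          n_total = length(tp))
      }))
    }))
    list(nose_touch = nose, opto = opto, thrash = thrash,
         reversal = reversal, aldicarb = aldicarb, truth = truth)
  })
}

#' Simulate a cohort of line scans for parameter-recovery benchmarking
#'
#' The study conditions of the puncta-recovery benchmark: each scan carries
#' a handful of bright, well-separated Gaussian puncta (amplitudes drawn
#' from 12-24 background SDs, widths sigma 0.3-1.0 um, adjacent centers at
#' least `4 * (sigma_i + sigma_j)` apart plus a random extra gap) on a
#' noisy background, at the default 0.1 um pixel size.
#'
#' @param n_scans Number of scans.
#' @param seed Cohort seed.
#' @param k_range Range of puncta counts per scan.
#' @param sigma_range Range of punctum widths (um).
#' @param amp_sd_range Amplitude range in units of the background SD.
#' @param background_mean,background_sd Background level and noise (AU).
#' @param gap_extra Range of extra spacing beyond `4 * (sigma_i + sigma_j)`
#'   between adjacent centers (um).
#' @param min_length_um Minimum scan length (um).
#' @param pixel_size_um Pixel size (um/px).
#' @return List of [gen_linescan()] results (each with `scan` and `truth`).
#' @export
simulate_scan_cohort <- function(n_scans = 200, seed = 1L,
                                 k_range = c(4L, 6L),
                                 sigma_range = c(0.3, 1.0),
                                 amp_sd_range = c(12, 24),
                                 background_mean = 100, background_sd = 5,
                                 gap_extra = c(2, 5),
                                 min_length_um = 60,
                                 pixel_size_um = 0.1) {
  with_seed(seed, {
    lapply(seq_len(n_scans), function(i) {
      k <- sample(seq(k_range[1L], k_range[2L]), 1L)
      sig <- stats::runif(k, sigma_range[1L], sigma_range[2L])
      gaps <- if (k > 1L)
        4 * (sig[-k] + sig[-1L]) + stats::runif(k - 1L, gap_extra[1L], gap_extra[2L])
      else numeric()
      cen <- cumsum(c(stats::runif(1L, 4, 7), gaps))
      amp <- stats::runif(k, amp_sd_range[1L], amp_sd_range[2L]) * background_sd
      tr <- scan_truth(
        length_um = max(min_length_um, max(cen) + 5),
        pixel_size_um = pixel_size_um,
        background_mean = background_mean, background_sd = background_sd,
        puncta = data.frame(center_um = cen, amplitude = amp, sigma_um = sig),
        seed = sample.int(.Machine$integer.max, 1L))
      gen_linescan(tr)
    })
  })
}
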