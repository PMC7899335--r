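## Dual-channel FRAP quantification: nested ROI geometry, pre-bleach
## normalization, single-exponential recovery fits, and group comparison by
## two-way repeated-measures ANOVA.

#' Nested bleach/quantification geometry
#'
#' The bleached region is the central 50% of the imaged neurite segment
#' (inset one quarter of the image length from each edge) and the
#' quantification ROI is the central 50% of the bleached region (the central
#' quarter of the image) — the inner inset avoids measuring receptors that
#' diffused laterally into the bleached area. For a 32 um image this gives a
#' 16 um bleach interval 8 um from each image edge and an 8 um
#' quantification interval 4 um from each bleach edge.
#'
#' @param image_length_um Imaged segment length (um), > 0.
#' @return A list of class `bleach_geometry` with half-open um intervals
#'   `bleach_um = [L/4, 3L/4)` and `quant_um = [3L/8, 5L/8)`.
#' @export
make_geometry <- function(image_length_um) {
  check_scalar(image_length_um, "image_length_um", positive = TRUE)
  L <- image_length_um
  structure(list(image_length_um = L,
                 bleach_um = c(L / 4, 3 * L / 4),
                 quant_um = c(3 * L / 8, 5 * L / 8)),
            class = "bleach_geometry")
}

#' Convert a um interval to 0-based half-open pixel bounds
#'
#' Floors both endpoints, so a pixel belongs to the interval when its left
#' edge does.
#'
#' @param interval_um Half-open um interval `c(from, to)`.
#' @param pixel_size_um Pixel size (um/px).
#' @return Integer `c(from, to)`, 0-based half-open.
#' @export
interval_to_px <- function(interval_um, pixel_size_um) {
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  as.integer(floor(interval_um / pixel_size_um))
}

#' Construct a FRAP ROI-total series
#'
#' Thresholded total fluorescence in the quantification ROI at the
#' pre-bleach image and each post-bleach timepoint, for one channel of one
#' worm.
#'
#' @param channel `"SEP"` or `"mCherry"`.
#' @param pre_total Pre-bleach ROI total (AU), > 0 for normalization.
#' @param t_min Post-bleach times (min), strictly increasing, first is the
#'   immediate post-bleach image (0).
#' @param total ROI totals at `t_min` (AU).
#' @param threshold_used Threshold applied to every timepoint (AU); fixed
#'   from the pre-bleach image.
#' @return An object of class `frap_series`.
#' @export
frap_series <- function(channel = c("SEP", "mCherry"), pre_total, t_min,
                        total, threshold_used = NA_real_) {
  channel <- match.arg(channel)
  check_scalar(pre_total, "pre_total", nonneg = TRUE)
  if (length(t_min) != length(total))
    stopf("'t_min' and 'total' lengths differ")
  if (any(diff(t_min) <= 0)) stopf("'t_min' must be strictly increasing")
  if (any(total < 0)) stopf("ROI totals must be >= 0")
  structure(list(channel = channel, pre_total = pre_total,
                 t_min = as.numeric(t_min), total = as.numeric(total),
                 threshold_used = threshold_used),
            class = "frap_series")
}

#' Extract a FRAP series from per-timepoint images
#'
#' Applies one threshold (set on the pre-bleach image as
#' `bg_mean + k_sd * bg_sd` unless given) to every timepoint and sums the
#' supra-threshold pixels inside the quantification ROI. Images are matrices
#' whose columns span the neurite axis.
#'
#' @param pre_img Pre-bleach image (matrix / [channel_image()]).
#' @param post_imgs List of post-bleach images, in time order.
#' @param t_min Post-bleach times (min), same length as `post_imgs`.
#' @param pixel_size_um Pixel size along the neurite axis (um/px).
#' @param channel Channel label.
#' @param threshold Fixed threshold (AU); default derives it from the
#'   pre-bleach image background.
#' @param k_sd Threshold SD multiple when deriving from background.
#' @return A [frap_series()].
#' @export
frap_series_from_images <- function(pre_img, post_imgs, t_min, pixel_size_um,
                                    channel = c("SEP", "mCherry"),
                                    threshold = NULL, k_sd = 4) {
  channel <- match.arg(channel)
  if (length(post_imgs) != length(t_min))
    stopf("'post_imgs' and 't_min' lengths differ")
  geom <- make_geometry(ncol(pre_img) * pixel_size_um)
  qpx <- interval_to_px(geom$quant_um, pixel_size_um)
  r <- roi(rows = c(0L, nrow(pre_img)), cols = qpx)
  if (is.null(threshold)) {
    bg <- estimate_background_2d(pre_img)
    threshold <- bg$bg_mean + k_sd * bg$bg_sd
  }
  tot <- function(img) {
    if (!identical(dim(img), dim(pre_img)))
      stopf("timepoint image shape differs from pre-bleach image")
    integrated_density(img, r, threshold)
  }
  frap_series(channel = channel, pre_total = tot(pre_img), t_min = t_min,
              total = vapply(post_imgs, tot, 0),
              threshold_used = threshold)
}

#' Normalized fluorescence recovery
#'
#' Each post-bleach ROI total divided by the pre-bleach total — the percent
#' fluorescence recovery curve (as fractions). Optionally the curve is
#' divided by the same quantity from an unbleached reference ROI, which
#' corrects acquisition photofading across timepoints; the default applies
#' no correction.
#'
#' @param series A [frap_series()].
#' @param reference Optional [frap_series()] from an unbleached reference
#'   region with the same timepoints.
#' @return Data frame with `t_min` and `normalized`.
#' @export
recovery_fraction <- function(series, reference = NULL) {
  stopifnot(inherits(series, "frap_series"))
  if (series$pre_total <= 0) stopf("pre-bleach total must be > 0")
  norm <- series$total / series$pre_total
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "frap_series"))
    if (!identical(reference$t_min, series$t_min))
      stopf("reference timepoints differ from the series")
    if (reference$pre_total <= 0 || any(reference$total <= 0))
      stopf("reference totals must be > 0")
    norm <- norm / (reference$total / reference$pre_total)
  }
  data.frame(t_min = series$t_min, normalized = norm)
}

#' Fit a single-exponential recovery model
#'
#' Least squares of `normalized(t) = n0 + A * (1 - exp(-k * t))` with `n0`
#' fixed at the observed t = 0 value. `A` enters linearly, so the fit
#' profiles over `k`: for each `k` the optimal `A` is closed-form, and the
#' profiled residual sum of squares is minimized over `k` by golden-section
#' search — deterministic, with no convergence failures on sparse designs.
#' A flat curve leaves `k` unidentifiable: `A` is reported as 0 and
#' `fit_ok = FALSE`.
#'
#' @param curve Data frame from [recovery_fraction()] (needs the t = 0
#'   point and >= 3 post-bleach timepoints).
#' @param k_max Upper bound of the rate search (1/min), default 10.
#' @return A list of class `recovery_fit`: `n0`, `A`, `k`, `fitted`,
#'   `rss`, `fit_ok`, `note`.
#' @export
fit_recovery <- function(curve, k_max = 10) {
  stopifnot(is.data.frame(curve), all(c("t_min", "normalized") %in% names(curve)))
  if (nrow(curve) < 3L) stopf("recovery fit needs >= 3 post-bleach timepoints")
  t <- curve$t_min
  if (min(t) != 0) stopf("recovery fit expects a t = 0 post-bleach point")
  y <- curve$normalized
  n0 <- y[t == 0][1L]
  dy <- y - n0
  basis <- function(k) 1 - exp(-k * t)
  a_for <- function(k) {
    b <- basis(k)
    s <- sum(b^2)
    if (s == 0) 0 else sum(b * dy) / s
  }
  rss_for <- function(k) {
    a <- a_for(k)
    sum((dy - a * basis(k))^2)
  }
  flat <- stats::sd(y) < 1e-12 || all(abs(dy) < 1e-12)
  if (flat) {
    fit <- list(n0 = n0, A = 0, k = NA_real_, fitted = rep(n0, length(t)),
                rss = sum(dy^2), fit_ok = FALSE,
                note = "flat curve: k unidentifiable")
  } else {
    opt <- stats::optimize(rss_for, c(0, k_max), tol = 1e-10)
    k <- opt$minimum
    a <- a_for(k)
    fit <- list(n0 = n0, A = a, k = k, fitted = n0 + a * basis(k),
                rss = opt$objective, fit_ok = TRUE, note = "")
    # near-zero amplitude means the rate carries no information
    if (abs(a) < 1e-8) {
      fit$A <- 0; fit$k <- NA_real_; fit$fit_ok <- FALSE
      fit$note <- "zero amplitude: k unidentifiable"
    }
  }
  class(fit) <- "recovery_fit"
  fit
}

#' Compare recovery curves between genotypes
#'
#' Two-way repeated-measures ANOVA on the normalized recovery values —
#' genotype as the between-worm factor, time as the within-worm factor —
#' followed by per-timepoint Tukey HSD contrasts between genotypes.
#'
#' @param curves Data frame with columns `worm_id`, `genotype`, `t_min`,
#'   `normalized`; every worm must have the full timepoint grid.
#' @param alpha Significance level for the Tukey contrasts.
#' @return A list with `anova` (the [rm_anova_two_way()] table) and
#'   `tukey_by_time` (a data frame of pairwise contrasts per timepoint).
#' @export
compare_recovery <- function(curves, alpha = 0.05) {
  req <- c("worm_id", "genotype", "t_min", "normalized")
  if (!all(req %in% names(curves)))
    stopf("'curves' needs columns %s", paste(req, collapse = ", "))
  if (length(unique(curves$genotype)) < 2L)
    stopf("need >= 2 genotypes to compare")
  counts <- table(unique(curves[c("worm_id", "genotype")])$genotype)
  if (any(counts < 2L)) stopf("need >= 2 worms per genotype")
  aov_tab <- rm_anova_two_way(curves, value = "normalized", unit = "worm_id",
                              between = "genotype", within = "t_min")
  tk <- do.call(rbind, lapply(sort(unique(curves$t_min)), function(tt) {
    sub <- curves[curves$t_min == tt, ]
    groups <- split(sub$normalized, sub$genotype)
    out <- tukey_hsd(groups, alpha = alpha)
    out$t_min <- tt
    out
  }))
  list(anova = aov_tab, tukey_by_time = tk)
}
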