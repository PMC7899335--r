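## Surface vs total receptor quantification from paired SEP/mCherry images.
##
## mCherry fluorescence reports total tagged receptor regardless of
## compartment; SEP fluorescence is quenched in acidic endosomes and so
## reports (mostly) the cell-surface pool. The SEP/mCherry ratio of
## thresholded integrated densities over a shared ROI is the study's proxy
## for the surface fraction.

#' Construct a channel image
#'
#' @param pixels Numeric matrix of pixel intensities (AU), non-negative.
#' @param channel `"SEP"` or `"mCherry"`.
#' @param acquisition_day Optional batch/day label for within-day
#'   normalization.
#' @return An object of class `channel_image` (the matrix with attributes).
#' @export
channel_image <- function(pixels, channel = c("SEP", "mCherry"),
                          acquisition_day = NA_character_) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stopf("pixel values must be finite and >= 0")
  structure(pixels, channel = channel, acquisition_day = acquisition_day,
            class = c("channel_image", "matrix", "array"))
}

#' Rectangular or mask region of interest
#'
#' Either a rectangle in 0-based half-open pixel bounds (rows `[r0, r1)`,
#' columns `[c0, c1)`) or an explicit logical mask.
#'
#' @param rows,cols Length-2 integer vectors `c(from, to)`, 0-based
#'   half-open. Ignored when `mask` is given.
#' @param mask Logical matrix; `TRUE` pixels belong to the ROI.
#' @return An object of class `roi`.
#' @export
roi <- function(rows = NULL, cols = NULL, mask = NULL) {
  if (!is.null(mask)) {
    if (!is.logical(mask) || !is.matrix(mask)) stopf("'mask' must be a logical matrix")
    if (!any(mask)) stopf("ROI mask is empty")
    return(structure(list(mask = mask), class = "roi"))
  }
  if (is.null(rows) || is.null(cols) || length(rows) != 2L || length(cols) != 2L)
    stopf("give either 'mask' or both 'rows' and 'cols' as c(from, to)")
  if (rows[2L] <= rows[1L] || cols[2L] <= cols[1L]) stopf("ROI is empty")
  if (rows[1L] < 0 || cols[1L] < 0) stopf("ROI bounds must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "roi")
}

## Logical mask of an roi for a given image, validating bounds.
roi_mask <- function(r, img) {
  stopifnot(inherits(r, "roi"))
  d <- dim(img)
  if (!is.null(r$mask)) {
    if (!identical(dim(r$mask), d)) stopf("ROI mask shape differs from image")
    return(r$mask)
  }
  if (r$rows[2L] > d[1L] || r$cols[2L] > d[2L])
    stopf("ROI exceeds image bounds")
  m <- matrix(FALSE, d[1L], d[2L])
  m[(r$rows[1L] + 1L):r$rows[2L], (r$cols[1L] + 1L):r$cols[2L]] <- TRUE
  m
}

#' Full-image ROI
#' @param img A [channel_image()] or matrix.
#' @return An [roi()] covering every pixel.
#' @export
roi_full <- function(img) roi(rows = c(0L, nrow(img)), cols = c(0L, ncol(img)))

## Sigma-clipped background of a 2-D pixel population: same clipping rule as
## the line-scan estimator, applied to the flattened image.
estimate_background_2d <- function(img, clip_sd = 3, max_iter = 10L) {
  fake <- line_scan(pmax(as.numeric(img), 0), pixel_size_um = 1)
  bg <- estimate_background(fake, clip_sd = clip_sd, max_iter = max_iter)
  bg
}

#' Calibrate channel thresholds from control image pairs
#'
#' For each calibration image the background is estimated by iterative sigma
#' clipping of the full pixel population and a per-image threshold
#' `bg_mean + k_sd * bg_sd` computed; the channel threshold is the mean of
#' the per-image thresholds. Mirrors deriving one average background
#' threshold per channel from a representative subset of wild-type image
#' sets, then applying it to all images.
#'
#' @param control_pairs List of >= 3 image pairs, each a list with elements
#'   `sep` and `mcherry` ([channel_image()] objects).
#' @param k_sd Threshold in background SDs (default 4).
#' @return A list of class `threshold_set`: `t_sep`, `t_mcherry`, `k_sd`,
#'   `n_images`.
#' @export
calibrate_thresholds <- function(control_pairs, k_sd = 4) {
  if (length(control_pairs) < 3L)
    stopf("threshold calibration needs >= 3 control image pairs")
  one <- function(img) {
    bg <- estimate_background_2d(img)
    bg$bg_mean + k_sd * bg$bg_sd
  }
  t_sep <- mean(vapply(control_pairs, function(p) one(p$sep), 0))
  t_mch <- mean(vapply(control_pairs, function(p) one(p$mcherry), 0))
  structure(list(t_sep = t_sep, t_mcherry = t_mch, k_sd = k_sd,
                 n_images = length(control_pairs)),
            class = "threshold_set")
}

#' Thresholded integrated density over an ROI
#'
#' Sum of pixel values over ROI pixels strictly above the threshold
#' (equivalently, count times mean of those pixels — the ImageJ
#' "limit to threshold" integrated density). Zero when no pixel passes.
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param r An [roi()].
#' @param threshold Threshold (AU); pixels must exceed it to count.
#' @return Integrated density (AU * px).
#' @export
integrated_density <- function(img, r, threshold = 0) {
  m <- roi_mask(r, img)
  v <- img[m]
  sum(v[v > threshold])
}

#' Quantify a SEP/mCherry image pair
#'
#' Integrated densities over the shared ROI with the per-channel calibrated
#' thresholds; the SEP/mCherry ratio is the surface-fraction proxy.
#'
#' @param sep,mcherry Paired [channel_image()]s of identical shape.
#' @param r Shared [roi()].
#' @param thresholds A [calibrate_thresholds()] result, or a list with
#'   `t_sep` and `t_mcherry`.
#' @return One-row data frame: `sep_intden`, `mch_intden`, `ratio`
#'   (`NA` with `ratio_defined = FALSE` when the mCherry density is 0),
#'   `acquisition_day`.
#' @export
quantify_pair <- function(sep, mcherry, r, thresholds) {
  if (!identical(dim(sep), dim(mcherry)))
    stopf("SEP and mCherry image shapes differ")
  s <- integrated_density(sep, r, thresholds$t_sep)
  m <- integrated_density(mcherry, r, thresholds$t_mcherry)
  data.frame(sep_intden = s, mch_intden = m,
             ratio = if (m > 0) s / m else NA_real_,
             ratio_defined = m > 0,
             acquisition_day = attr(mcherry, "acquisition_day") %||%
               NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize SEP/mCherry ratios to the control group
#'
#' Each sample's ratio is divided by the mean control-group ratio of its
#' batch (acquisition day); the control group mean maps to 1.0 by
#' construction. Samples without a day label, or when `by_day = FALSE`,
#' are normalized to the global control mean.
#'
#' @param quants Data frame with columns `ratio`, `genotype` and optionally
#'   `acquisition_day` (rows from [quantify_pair()] plus a genotype label).
#' @param control_label Genotype label of the control group.
#' @param by_day Normalize within acquisition day when day labels are
#'   present (default `TRUE`).
#' @return `quants` with a `ratio_norm` column appended.
#' @export
normalize_to_control <- function(quants, control_label, by_day = TRUE) {
  if (!all(c("ratio", "genotype") %in% names(quants)))
    stopf("'quants' needs columns ratio, genotype")
  if (!any(quants$genotype == control_label))
    stopf("no samples with control label '%s'", control_label)
  day <- if (by_day && "acquisition_day" %in% names(quants) &&
             !all(is.na(quants$acquisition_day)))
    as.character(quants$acquisition_day) else rep("all", nrow(quants))
  quants$ratio_norm <- NA_real_
  for (d in unique(day)) {
    in_day <- day == d
    ctrl <- quants$ratio[in_day & quants$genotype == control_label]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) == 0L)
      stopf("no control ratios in batch '%s'", d)
    cm <- mean(ctrl)
    if (cm == 0) stopf("control mean ratio is zero in batch '%s'", d)
    quants$ratio_norm[in_day] <- quants$ratio[in_day] / cm
  }
  quants
}

#' Model-based surface fraction from a SEP/mCherry ratio
#'
#' The forward model for the visible SEP fraction is
#' `ratio / cal = f + (1 - f) * (1 - q)`, where `q` is the quench efficiency
#' of SEP in acidic compartments and `cal` the relative SEP vs mCherry
#' brightness scale (1 for synthetic data). Inverting,
#' `f_hat = (ratio / cal - (1 - q)) / q`, clamped to `[0, 1]` with a flag —
#' noise can push the raw estimate slightly outside the unit interval.
#'
#' @param ratio SEP/mCherry ratio(s).
#' @param q Quench efficiency, in `(0, 1]`; `q = 0` makes the surface
#'   fraction non-identifiable and is an error.
#' @param cal Brightness calibration scale (> 0), default 1.
#' @return Data frame with `f_hat` and `clamped`.
#' @export
estimate_surface_fraction <- function(ratio, q = 1, cal = 1) {
  check_scalar(q, "q", frac = TRUE)
  if (q == 0) stopf("q = 0: surface fraction is non-identifiable")
  check_scalar(cal, "cal", positive = TRUE)
  raw <- (ratio / cal - (1 - q)) / q
  data.frame(f_hat = pmin(pmax(raw, 0), 1),
             clamped = !is.na(raw) & (raw < 0 | raw > 1))
}

#' Un-thresholded ROI total for soma quantification
#'
#' ROI area and integrated density (product of area and mean gray
#' intensity, i.e. the plain pixel sum) over a soma ROI of a max-projected
#' mCherry image.
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param r An [roi()].
#' @return One-row data frame: `area_px`, `intden`.
#' @export
soma_total <- function(img, r) {
  m <- roi_mask(r, img)
  data.frame(area_px = sum(m), intden = sum(img[m]))
}

#' Read a 16-bit grayscale TIFF as a channel image
#'
#' @param path TIFF file path (single-plane grayscale).
#' @param channel,acquisition_day Passed to [channel_image()].
#' @param bit_depth Bit depth used to rescale the `[0, 1]` TIFF samples
#'   back to integer gray levels (default 16).
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, channel = c("SEP", "mCherry"),
                              acquisition_day = NA_character_,
                              bit_depth = 16L) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L) stopf("'%s' is not single-channel grayscale", path)
    px <- px[, , 1L]
  }
  channel_image(round(px * (2^bit_depth - 1)), channel = match.arg(channel),
                acquisition_day = acquisition_day)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Values are clipped to `[0, 2^bit_depth - 1]` and stored as gray levels.
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param path Output file path.
#' @param bit_depth Bit depth (default 16).
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path, bit_depth = 16L) {
  mx <- 2^bit_depth - 1
  # writeTIFF truncates when quantizing; the half-gray-level offset makes
  # the stored sample exactly round(value)
  px <- pmin((round(pmin(pmax(unclass(img), 0), mx)) + 0.5) / mx, 1)
  attributes(px) <- list(dim = dim(img))
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}
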