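#' Construct a fluorescence line scan
#'
#' A line scan is a 1-D intensity profile sampled on a uniform spatial grid,
#' the substrate for puncta calling along the ventral nerve cord (VNC) or
#' nerve ring. Positions are in micrometres, intensities in arbitrary units
#' (AU) of the camera.
#'
#' @param intensity Numeric vector of fluorescence intensities (AU), one per
#'   pixel. Must be finite and non-negative.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param position_um Optional explicit positions; defaults to a uniform grid
#'   starting at 0 with step `pixel_size_um`. If supplied it must be strictly
#'   increasing with constant step equal to `pixel_size_um`.
#' @param bead_mean Optional same-day fluorescent-bead mean intensity (AU)
#'   used to normalize peak intensities across acquisition days.
#'
#' @return An object of class `line_scan`: a data frame with columns
#'   `position_um` and `intensity`, with attributes `pixel_size_um` and
#'   `bead_mean`.
#' @examples
#' scan <- line_scan(rep(100, 50), pixel_size_um = 0.1)
#' scan_length_um(scan)
#' @export
line_scan <- function(intensity, pixel_size_um, position_um = NULL,
                      bead_mean = NULL) {
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.numeric(intensity) || length(intensity) < 1L)
    stopf("'intensity' must be a non-empty numeric vector")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensities must be finite and >= 0")
  n <- length(intensity)
  if (is.null(position_um)) {
    position_um <- (seq_len(n) - 1L) * pixel_size_um
  } else {
    if (length(position_um) != n)
      stopf("'position_um' and 'intensity' lengths differ")
    steps <- diff(position_um)
    if (any(steps <= 0) ||
        max(abs(steps - pixel_size_um)) > 1e-6 * pixel_size_um)
      stopf("'position_um' must be uniform with step pixel_size_um")
  }
  if (!is.null(bead_mean)) check_scalar(bead_mean, "bead_mean", positive = TRUE)
  out <- data.frame(position_um = position_um, intensity = as.numeric(intensity))
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "bead_mean") <- bead_mean
  class(out) <- c("line_scan", "data.frame")
  out
}

#' Scan length in micrometres
#'
#' Length of the sampled segment, counting each pixel as one `pixel_size_um`
#' wide (so a 600-pixel scan at 0.1 um/px is 60 um long).
#'
#' @param scan A [line_scan()].
#' @return Length in micrometres.
#' @export
scan_length_um <- function(scan) {
  stopifnot(inherits(scan, "line_scan"))
  nrow(scan) * attr(scan, "pixel_size_um")
}

#' Read a line scan from CSV
#'
#' Expects columns `position_um` and `intensity` (header required), the
#' interchange format written by [write_linescan_csv()].
#'
#' @param path CSV file path.
#' @param bead_mean Optional bead normalizer to attach (AU).
#' @return A [line_scan()].
#' @export
read_linescan_csv <- function(path, bead_mean = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(df)))
    stopf("'%s' must have columns position_um, intensity", path)
  step <- diff(df$position_um)
  if (length(step) < 1L) stopf("line scan needs >= 2 pixels")
  line_scan(df$intensity, pixel_size_um = step[1L],
            position_um = df$position_um, bead_mean = bead_mean)
}

#' Write a line scan to CSV
#'
#' @param scan A [line_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_linescan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "line_scan"))
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}
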