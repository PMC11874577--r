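#' Pixel-to-micron calibration
#'
#' Stores the physical edge length of one pixel. All area computations in the
#' package scale pixel counts by `microns_per_pixel^2`. The default of
#' 0.25 um/pixel corresponds to a 400x whole-slide scan.
#'
#' @param microns_per_pixel Edge length of a pixel in micrometers. Must be a
#'   single positive number.
#' @return An object of class `"calibration"`.
#' @examples
#' cal <- calibration(0.25)
#' area_um2(16, cal)  # 1 um^2
#' @export
calibration <- function(microns_per_pixel = 0.25) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("'microns_per_pixel' must be a single positive number")
  }
  structure(list(microns_per_pixel = as.numeric(microns_per_pixel)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration:", x$microns_per_pixel, "um/pixel (",
      x$microns_per_pixel^2, "um^2/pixel )\n")
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "calibration")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(calibration(x))
  stop("expected a 'calibration' object or a single microns-per-pixel value")
}

#' Convert a pixel count to an area in square microns
#'
#' @param pixel_count Non-negative pixel count(s).
#' @param cal A [calibration()] object (or a bare microns-per-pixel value).
#' @return `pixel_count * microns_per_pixel^2`, in um^2.
#' @examples
#' area_um2(16, calibration(0.25))
#' @export
area_um2 <- function(pixel_count, cal = calibration()) {
  cal <- as_calibration(cal)
  if (any(!is.finite(pixel_count)) || any(pixel_count < 0)) {
    stop("'pixel_count' must be non-negative and finite")
  }
  pixel_count * cal$microns_per_pixel^2
}

#' Region-of-interest geometry
#'
#' Describes the fixed-area image crop analyzed per tumor location. The
#' defaults (0.1185 mm^2 at a 4:3 aspect ratio) correspond to half a
#' standardized high-power field.
#'
#' @param area_mm2 ROI area in mm^2 (> 0).
#' @param aspect_ratio Width over height of the crop.
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(area_mm2 = 0.1185, aspect_ratio = 4 / 3) {
  if (!is.numeric(area_mm2) || length(area_mm2) != 1L || area_mm2 <= 0) {
    stop("'area_mm2' must be a single positive number")
  }
  if (!is.numeric(aspect_ratio) || length(aspect_ratio) != 1L || aspect_ratio <= 0) {
    stop("'aspect_ratio' must be a single positive number")
  }
  structure(list(area_mm2 = area_mm2, aspect_ratio = aspect_ratio),
            class = "roi_spec")
}

#' Pixel dimensions of an ROI at a given calibration
#'
#' @param spec A [roi_spec()].
#' @param cal A [calibration()].
#' @return Integer vector `c(height, width)` in pixels.
#' @export
roi_pixel_shape <- function(spec = roi_spec(), cal = calibration()) {
  cal <- as_calibration(cal)
  area_px <- spec$area_mm2 * 1e6 / cal$microns_per_pixel^2
  w <- sqrt(area_px * spec$aspect_ratio)
  h <- w / spec$aspect_ratio
  c(height = as.integer(round(h)), width = as.integer(round(w)))
}
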