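#' Instance label mask
#'
#' A per-pixel integer matrix in which 0 is background and each positive
#' value identifies one nucleus instance. Labels need not be contiguous but
#' must be unique per instance. The matrix is stored with rows = image rows
#' (y) and columns = image columns (x); pixel indices are 1-based in R but
#' reported 0-based in coordinate output for interoperability with the
#' polygon convention (x = column, y = row, origin top-left).
#'
#' @param labels Integer matrix (height x width) of instance labels.
#' @param cal A [calibration()].
#' @param binary Logical; `TRUE` marks a mask whose foreground has not yet
#'   been separated into instances (a binary segmentation output).
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(labels, cal = calibration(), binary = FALSE) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  if (nrow(labels) < 1L || ncol(labels) < 1L) stop("mask dimensions must be positive")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  structure(list(labels = labels, calibration = as_calibration(cal),
                 binary = isTRUE(binary)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d px, %d instance(s)%s, %.3g um/px\n",
              ncol(x$labels), nrow(x$labels), n_instances(x),
              if (x$binary) " [binary/unlabeled]" else "",
              x$calibration$microns_per_pixel))
  invisible(x)
}

#' Number of instances in a label mask
#' @param mask A [label_mask()].
#' @return Integer count of distinct positive labels.
#' @export
n_instances <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  length(instance_ids(mask))
}

#' Distinct instance labels present in a mask
#' @param mask A [label_mask()].
#' @return Sorted integer vector of positive labels.
#' @export
instance_ids <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  u <- unique(as.vector(mask$labels))
  sort(u[u > 0L])
}

#' Pixel areas of each instance, in pixels
#' @param mask A [label_mask()].
#' @return Named integer vector (names = labels) of pixel counts.
#' @export
instance_pixel_counts <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  v <- as.vector(mask$labels)
  v <- v[v > 0L]
  if (length(v) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a label or binary mask from a PNG or TIFF file
#'
#' Accepts single-channel 8- or 16-bit images. Pixel values are interpreted
#' as instance labels (0 = background). A mask whose only positive value is
#' a single constant is flagged as binary (instances not yet separated); use
#' [label_components()] to split it.
#'
#' @param path Path to a `.png`, `.tif`, or `.tiff` file.
#' @param cal A [calibration()].
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, cal = calibration()) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L) stop("multi-channel image is not a label mask: ", path)
    info <- attr(img, "info")
    depth <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else NA
    # readPNG returns values in [0,1]; recover the integer codes
    scale <- if (is.finite(depth)) 2^depth - 1 else guess_png_scale(img)
    labels <- img * scale
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) stop("multi-channel image is not a label mask: ", path)
    labels <- img
  } else {
    stop("unsupported mask format '", ext, "' (use PNG or TIFF)")
  }
  labels <- matrix(as.integer(round(labels)), nrow = nrow(labels))
  pos <- unique(labels[labels > 0L])
  label_mask(labels, cal, binary = length(pos) == 1L)
}

# readPNG drops the bit depth attribute in some versions; infer the integer
# scale from the value grid (8- vs 16-bit quantization).
guess_png_scale <- function(img) {
  v <- unique(as.vector(img))
  v <- v[v > 0]
  if (length(v) == 0L) return(255)
  err8 <- max(abs(v * 255 - round(v * 255)))
  if (err8 < 1e-6) 255 else 65535
}

#' Write a label mask to a PNG or TIFF file
#'
#' Masks with more than 255 labels are written as 16-bit TIFF; PNG output is
#' limited to 8-bit and refused above 255 labels.
#'
#' @param mask A [label_mask()].
#' @param path Output path ending in `.png`, `.tif`, or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  ext <- tolower(tools::file_ext(path))
  mx <- max(mask$labels, 1L)
  if (ext == "png") {
    if (mx > 255L) stop("PNG output is 8-bit; use TIFF for masks with >255 labels")
    png::writePNG(mask$labels / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    bits <- if (mx > 255L) 16L else 8L
    tiff::writeTIFF(mask$labels / (2^bits - 1), path, bits.per.sample = bits)
  } else {
    stop("unsupported mask format '", ext, "'")
  }
  invisible(path)
}
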