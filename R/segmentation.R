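#' Segmentation post-processing configuration
#'
#' Controls how a binary segmentation mask is turned into filtered nucleus
#' instances: the connectivity used for component labeling, the minimum
#' plausible nucleus area (objects below it are discarded as debris or
#' partial nuclei), and whether instances touching the image border are
#' kept.
#'
#' @param min_area_um2 Minimum instance area in um^2 (strict `<` removal;
#'   default 7).
#' @param connectivity 4 or 8 (default 8).
#' @param border_policy `"keep"` (default) or `"drop"` for instances
#'   touching the image border.
#' @return An object of class `"segmentation_config"`.
#' @export
segmentation_config <- function(min_area_um2 = 7, connectivity = 8,
                                border_policy = c("keep", "drop")) {
  if (!is.numeric(min_area_um2) || min_area_um2 < 0) {
    stop("'min_area_um2' must be >= 0")
  }
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  structure(list(min_area_um2 = min_area_um2,
                 connectivity = as.integer(connectivity),
                 border_policy = match.arg(border_policy)),
            class = "segmentation_config")
}

#' Label connected foreground components
#'
#' Splits a binary mask into maximal connected components under the
#' configured connectivity. Components are labeled 1..K in raster-scan
#' order (row by row, left to right) of their first pixel.
#'
#' @param mask A [label_mask()] with values in \{0, 1\} (or flagged binary),
#'   or a plain 0/1 matrix.
#' @param config A [segmentation_config()].
#' @param cal Calibration used when `mask` is a plain matrix.
#' @return A [label_mask()] with one label per component.
#' @export
label_components <- function(mask, config = segmentation_config(),
                             cal = calibration()) {
  if (inherits(mask, "label_mask")) {
    m <- mask$labels
    cal <- mask$calibration
    if (!mask$binary && length(unique(m[m > 0L])) > 1L) {
      stop("mask already carries instance labels; use read_label_mask() / ",
           "filter_small() directly")
    }
    m <- m > 0L
  } else if (is.matrix(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("non-binary input; read it with read_label_mask() first")
    }
    m <- mask > 0
  } else {
    stop("'mask' must be a label_mask or a binary matrix")
  }
  h <- nrow(m); w <- ncol(m)
  fg <- which(m)                       # column-major linear indices
  labels <- matrix(0L, h, w)
  if (length(fg) > 0L) {
    vid <- integer(h * w)
    vid[fg] <- seq_along(fg)
    edges <- integer(0)
    add_edges <- function(di, dj) {
      # neighbor at (row + di, col + dj); keep pairs where both are foreground
      r <- ((fg - 1L) %% h) + 1L
      c <- ((fg - 1L) %/% h) + 1L
      ok <- r + di >= 1L & r + di <= h & c + dj >= 1L & c + dj <= w
      nb <- (c[ok] + dj - 1L) * h + (r[ok] + di)
      both <- vid[nb] > 0L
      rbind(vid[fg[ok]][both], vid[nb][both])
    }
    offs <- list(c(1L, 0L), c(0L, 1L))
    if (config$connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
    epairs <- do.call(cbind, lapply(offs, function(o) add_edges(o[1L], o[2L])))
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (!is.null(epairs) && length(epairs) > 0L) {
      g <- igraph::add_edges(g, as.vector(epairs))
    }
    comp <- igraph::components(g)$membership
    # relabel components by raster-scan order of their first pixel
    r <- ((fg - 1L) %% h) + 1L
    c <- ((fg - 1L) %/% h) + 1L
    scan_pos <- (r - 1L) * w + c
    first_pos <- tapply(scan_pos, comp, min)
    new_id <- integer(length(first_pos))
    new_id[order(first_pos)] <- seq_along(first_pos)
    labels[fg] <- new_id[comp]
  }
  out <- label_mask(labels, cal)
  if (config$border_policy == "drop") out <- drop_border_instances(out)
  out
}

drop_border_instances <- function(mask) {
  lb <- mask$labels
  border <- unique(c(lb[1L, ], lb[nrow(lb), ], lb[, 1L], lb[, ncol(lb)]))
  border <- border[border > 0L]
  if (length(border) > 0L) lb[lb %in% border] <- 0L
  relabel_contiguous(label_mask(lb, mask$calibration))
}

relabel_contiguous <- function(mask) {
  lb <- mask$labels
  ids <- sort(unique(lb[lb > 0L]))
  if (length(ids) > 0L) lb[] <- match(lb, ids, nomatch = 0L)
  label_mask(matrix(as.integer(lb), nrow(mask$labels)), mask$calibration)
}

#' Remove implausibly small instances
#'
#' Drops every instance whose calibrated area is strictly below
#' `config$min_area_um2` (default 7 um^2, the scale below which a segmented
#' object cannot be a complete nucleus). Remaining labels are re-indexed
#' contiguously in ascending original-label order; the number of removed
#' instances is attached as attribute `"n_removed"`.
#'
#' @param mask A labeled [label_mask()].
#' @param config A [segmentation_config()].
#' @return Filtered [label_mask()] with attribute `n_removed`.
#' @export
filter_small <- function(mask, config = segmentation_config()) {
  stopifnot(inherits(mask, "label_mask"))
  counts <- instance_pixel_counts(mask)
  areas <- area_um2(as.numeric(counts), mask$calibration)
  drop <- as.integer(names(counts))[areas < config$min_area_um2]
  lb <- mask$labels
  if (length(drop) > 0L) lb[lb %in% drop] <- 0L
  out <- relabel_contiguous(label_mask(lb, mask$calibration))
  attr(out, "n_removed") <- length(drop)
  out
}

#' Classical stand-in nucleus segmenter
#'
#' A deterministic threshold-plus-watershed segmenter for images with dark
#' nuclei on a lighter background (as produced by [generate_roi()] in RGB
#' mode). It is a demonstration-grade baseline for end-to-end runs, not a
#' substitute for a learned segmentation model: global Otsu thresholding of
#' the intensity image, distance-transform watershed splitting of touching
#' nuclei, component labeling, and small-object filtering.
#'
#' @param img Numeric matrix in \[0, 1\] (grayscale) or an h x w x 3 array
#'   (averaged to grayscale).
#' @param config A [segmentation_config()].
#' @param cal A [calibration()].
#' @return A [label_mask()]; a uniform image yields an empty mask with a
#'   warning.
#' @export
baseline_segment <- function(img, config = segmentation_config(),
                             cal = calibration()) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("baseline_segment() requires the EBImage package")
  }
  if (length(dim(img)) == 3L) img <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  if (!is.matrix(img)) stop("'img' must be a matrix or h x w x 3 array")
  rng <- range(img)
  if (diff(rng) < 1e-12) {
    warning("uniform image; returning empty mask")
    return(label_mask(matrix(0L, nrow(img), ncol(img)), cal))
  }
  # EBImage works on transposed Image objects; keep our row/col layout by
  # transposing in and out.
  eb <- EBImage::Image(t(img))
  thr <- EBImage::otsu(eb, range = rng)
  fg <- eb < thr                       # nuclei are dark
  dm <- EBImage::distmap(fg)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- t(EBImage::imageData(ws))
  labels <- matrix(as.integer(labels), nrow = nrow(img))
  out <- relabel_raster_scan(label_mask(labels, cal))
  if (config$border_policy == "drop") out <- drop_border_instances(out)
  filter_small(out, config)
}

# Relabel an arbitrary label mask 1..K by raster-scan order of first pixel.
relabel_raster_scan <- function(mask) {
  lb <- mask$labels
  fg <- which(lb > 0L)
  if (length(fg) == 0L) return(mask)
  h <- nrow(lb); w <- ncol(lb)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  scan_pos <- (r - 1L) * w + c
  first_pos <- tapply(scan_pos, lb[fg], min)
  ord <- order(first_pos)
  map <- stats::setNames(seq_along(ord), names(first_pos)[ord])
  lb[fg] <- as.integer(map[as.character(lb[fg])])
  label_mask(lb, mask$calibration)
}
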