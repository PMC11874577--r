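#' Nucleus contour polygon
#'
#' One closed polygon delineating a nuclear membrane, in pixel coordinates
#' (x = column, y = row, 0-based, origin top-left). The ring is stored open
#' (first vertex not repeated).
#'
#' @param vertices Numeric matrix with two columns (x, y) and >= 3 rows.
#' @param id Optional identifier carried through IO.
#' @param label Optional class label string.
#' @return An object of class `"nucleus_polygon"`.
#' @export
nucleus_polygon <- function(vertices, id = NA, label = NA_character_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("'vertices' must have two columns (x, y)")
  # drop a repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 distinct vertices")
  if (any(!is.finite(vertices))) stop("polygon vertices must be finite")
  colnames(vertices) <- c("x", "y")
  structure(list(id = id, label = label, vertices = vertices),
            class = "nucleus_polygon")
}

#' @export
print.nucleus_polygon <- function(x, ...) {
  cat(sprintf("nucleus_polygon id=%s, %d vertices\n",
              as.character(x$id), nrow(x$vertices)))
  invisible(x)
}

#' Read nucleus polygons from JSON
#'
#' The file must contain a top-level array of objects
#' `{"id": ..., "label": ..., "points": [[x, y], ...]}` with points in pixel
#' coordinates. Record order and ids are preserved. A `units` flag is
#' exposed because annotation exports do not always state whether
#' coordinates are pixel- or micron-denominated; micron input is divided by
#' the calibration before use.
#'
#' @param path Path to a JSON file.
#' @param units `"pixel"` (default) or `"micron"`.
#' @param cal A [calibration()]; used only when `units = "micron"`.
#' @return List of [nucleus_polygon()] objects (possibly empty).
#' @export
read_polygons <- function(path, units = c("pixel", "micron"), cal = calibration()) {
  units <- match.arg(units)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("polygon JSON must be a top-level array")
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    pts <- r$points
    if (is.null(pts) || length(pts) < 3L) {
      stop(sprintf("polygon record %d has fewer than 3 vertices", i))
    }
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p)[1:2])))
    if (units == "micron") m <- m / as_calibration(cal)$microns_per_pixel
    out[[i]] <- nucleus_polygon(m,
                                id = if (is.null(r$id)) i else r$id,
                                label = if (is.null(r$label)) NA_character_ else r$label)
  }
  out
}

#' Write nucleus polygons to JSON
#'
#' Inverse of [read_polygons()] (pixel units).
#'
#' @param polygons List of [nucleus_polygon()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path) {
  recs <- lapply(polygons, function(p) {
    list(id = p$id, label = p$label,
         points = lapply(seq_len(nrow(p$vertices)),
                         function(i) as.numeric(p$vertices[i, ])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd crossing test: is each point strictly inside the polygon ring?
# px, py vectors; vx, vy polygon vertices (open ring).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterize polygons into a label mask
#'
#' Each polygon is painted with a unique label equal to its position in the
#' input list; where polygons overlap, later polygons overwrite earlier
#' ones. A pixel is covered when its center lies inside the ring under the
#' even-odd rule. By default pixel centers sit at integer coordinates; set
#' `centers = "half"` for the (col + 0.5, row + 0.5) convention.
#'
#' @param polygons List of [nucleus_polygon()] objects.
#' @param width,height Mask dimensions in pixels.
#' @param cal A [calibration()].
#' @param centers `"integer"` (default) or `"half"`.
#' @return A [label_mask()]; polygons with no covered pixels after clipping
#'   are skipped with a warning.
#' @export
rasterize <- function(polygons, width, height, cal = calibration(),
                      centers = c("integer", "half")) {
  centers <- match.arg(centers)
  off <- if (centers == "half") 0.5 else 0
  labels <- matrix(0L, nrow = height, ncol = width)
  skipped <- integer(0)
  for (k in seq_along(polygons)) {
    p <- polygons[[k]]
    vx <- p$vertices[, 1L]; vy <- p$vertices[, 2L]
    # candidate pixels: bounding box clipped to image (0-based pixel indices)
    x0 <- max(0L, floor(min(vx) - off)); x1 <- min(width - 1L, ceiling(max(vx)))
    y0 <- max(0L, floor(min(vy) - off)); y1 <- min(height - 1L, ceiling(max(vy)))
    if (x0 > x1 || y0 > y1) { skipped <- c(skipped, k); next }
    xs <- x0:x1; ys <- y0:y1
    g <- expand.grid(x = xs, y = ys)
    ins <- point_in_polygon(g$x + off, g$y + off, vx, vy)
    if (!any(ins)) { skipped <- c(skipped, k); next }
    labels[cbind(g$y[ins] + 1L, g$x[ins] + 1L)] <- k
  }
  if (length(skipped) > 0L) {
    warning(sprintf("%d polygon(s) covered no pixels and were skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  label_mask(labels, cal)
}

#' Extract instance pixel coordinates from a label mask
#'
#' @param mask A [label_mask()].
#' @param id Instance label.
#' @return Two-column matrix of 0-based (x, y) pixel indices.
#' @export
instance_pixels <- function(mask, id) {
  stopifnot(inherits(mask, "label_mask"))
  w <- which(mask$labels == id, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("no pixels with label ", id)
  cbind(x = w[, 2L] - 1L, y = w[, 1L] - 1L)
}
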