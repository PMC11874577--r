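#' Morphometry configuration
#'
#' Thresholds for the karyomegaly and indentation proxies. The large-nucleus
#' cutoffs (37.8 and 50.3 um^2) are case-independent reference sizes (the
#' 90th percentile and twice the median area of a reference annotation set);
#' the solidity cutoffs (0.913, 0.936, 0.943) are the 2nd, 5th, and 10th
#' percentiles of the same reference set.
#'
#' @param large_nucleus_thresholds_um2 Areas (um^2) above which a nucleus
#'   counts as large (strict `>`).
#' @param indentation_thresholds Solidity values below which a nucleus
#'   counts as indented (strict `<`).
#' @param top_fraction Fraction of largest nuclei averaged for the
#'   "mean of the largest" statistic (default 0.10).
#' @return An object of class `"morphometry_config"`.
#' @export
morphometry_config <- function(large_nucleus_thresholds_um2 = c(37.8, 50.3),
                               indentation_thresholds = c(0.913, 0.936, 0.943),
                               top_fraction = 0.10) {
  stopifnot(all(large_nucleus_thresholds_um2 > 0),
            all(indentation_thresholds > 0),
            top_fraction > 0, top_fraction < 1)
  structure(list(large_nucleus_thresholds_um2 = large_nucleus_thresholds_um2,
                 indentation_thresholds = indentation_thresholds,
                 top_fraction = top_fraction),
            class = "morphometry_config")
}

#' Shape and size descriptors of one nucleus
#'
#' Computes the calibrated area, the eccentricity of the region's
#' equivalent ellipse (focal distance over major axis length, from the
#' second central moments of the pixel coordinates; 0 = circular, close to
#' 1 = elongated), the solidity (pixel count over convex-hull pixel count;
#' 1 = no indentation), and the centroid.
#'
#' @param pixels Two-column matrix of (x, y) pixel coordinates (any origin).
#' @param cal A [calibration()].
#' @return A list of class `"nucleus_features"` with `area`, `eccentricity`,
#'   `solidity`, `centroid`, and `n_px`.
#' @export
nucleus_features <- function(pixels, cal = calibration()) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set")
  x <- as.numeric(pixels[, 1L]); y <- as.numeric(pixels[, 2L])
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  if (n == 1L) {
    ecc <- 0; sol <- 1
  } else {
    mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
    mu11 <- mean((x - cx) * (y - cy))
    tr <- (mu20 + mu02) / 2
    d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    l1 <- tr + d; l2 <- tr - d
    ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
    sol <- n / convex_hull_pixel_count(x, y)
  }
  structure(list(area = area_um2(n, cal),
                 eccentricity = ecc,
                 solidity = min(1, sol),
                 centroid = c(x = cx, y = cy),
                 n_px = n),
            class = "nucleus_features")
}

# Pixels (centers) covered by the convex hull of the pixel centers,
# boundary-inclusive. Convexity allows a signed-area half-plane test.
convex_hull_pixel_count <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  if (length(h) <= 2L) return(length(x))   # collinear set: hull degenerates
  nh <- length(hx)
  # orientation of the hull ring (chull's winding is not relied upon)
  j <- nh
  signed2 <- 0
  for (i in seq_len(nh)) {
    signed2 <- signed2 + (hx[j] * hy[i] - hx[i] * hy[j])
    j <- i
  }
  orient <- if (signed2 >= 0) 1 else -1
  xs <- seq(min(x), max(x)); ys <- seq(min(y), max(y))
  g <- expand.grid(px = xs, py = ys)
  inside <- rep(TRUE, nrow(g))
  j <- nh
  eps <- 1e-9
  for (i in seq_len(nh)) {
    cross <- (hx[i] - hx[j]) * (g$py - hy[j]) - (hy[i] - hy[j]) * (g$px - hx[j])
    inside <- inside & (orient * cross >= -eps)
    j <- i
  }
  sum(inside)
}

#' Per-nucleus feature table for every instance in a mask
#'
#' @param mask A labeled [label_mask()].
#' @return Data frame with one row per instance: `id`, `area`,
#'   `eccentricity`, `solidity`, `x`, `y`, `n_px`, `on_border`.
#' @export
measure_instances <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  ids <- instance_ids(mask)
  if (length(ids) == 0L) {
    return(data.frame(id = integer(0), area = numeric(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      x = numeric(0), y = numeric(0), n_px = integer(0),
                      on_border = logical(0)))
  }
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  res <- lapply(ids, function(id) {
    px <- instance_pixels(mask, id)
    f <- nucleus_features(px, mask$calibration)
    data.frame(id = id, area = f$area, eccentricity = f$eccentricity,
               solidity = f$solidity, x = f$centroid[["x"]],
               y = f$centroid[["y"]], n_px = f$n_px,
               on_border = any(px[, "x"] == 0L | px[, "x"] == w - 1L |
                                 px[, "y"] == 0L | px[, "y"] == h - 1L))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Adjusted Fisher-Pearson skewness; NA for n < 3 or zero spread.
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  m3 <- mean((x - mean(x))^3)
  m2 <- mean((x - mean(x))^2)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Per-ROI morphometric parameter suite
#'
#' Aggregates per-nucleus features into the full distributional parameter
#' set: for area the mean, median, SD, 90th percentile, 90th
#' percentile/median ratio, mean of the largest `top_fraction`, percentage
#' of large nuclei per threshold (strict `>`), and skewness; for
#' eccentricity and solidity the mean, SD, and skewness; plus the
#' percentage of indented nuclei per solidity threshold (strict `<`).
#' Sample (n-1) SD, linear-interpolation percentiles, and the adjusted
#' Fisher-Pearson skewness are used; statistics that need more data than
#' supplied (SD: 2, skewness: 3) are reported as `NA`.
#'
#' @param features Data frame with columns `area`, `eccentricity`,
#'   `solidity` (one row per nucleus), as from [measure_instances()].
#' @param config A [morphometry_config()].
#' @return A named list of class `"roi_morphometry"`.
#' @export
roi_morphometry <- function(features, config = morphometry_config()) {
  if (NROW(features) == 0L) stop("no nuclei to summarize")
  a <- features$area; e <- features$eccentricity; s <- features$solidity
  if (is.null(a) || is.null(e) || is.null(s)) {
    stop("'features' needs columns area, eccentricity, solidity")
  }
  n <- length(a)
  p90 <- as.numeric(stats::quantile(a, 0.90, type = 7))
  med <- stats::median(a)
  k_top <- ceiling(config$top_fraction * n)
  top <- mean(sort(a, decreasing = TRUE)[seq_len(k_top)])
  pct_large <- vapply(config$large_nucleus_thresholds_um2,
                      function(t) 100 * mean(a > t), numeric(1))
  names(pct_large) <- paste0("pct_large_", config$large_nucleus_thresholds_um2)
  pct_ind <- vapply(config$indentation_thresholds,
                    function(t) 100 * mean(s < t), numeric(1))
  names(pct_ind) <- paste0("pct_indented_", config$indentation_thresholds)
  out <- c(list(n_nuclei = n,
                area_mean = mean(a), area_median = med,
                area_sd = if (n >= 2L) stats::sd(a) else NA_real_,
                area_p90 = p90,
                area_p90_over_median = if (med > 0) p90 / med else NA_real_,
                area_mean_top10 = top,
                area_skewness = sample_skewness(a),
                ecc_mean = mean(e),
                ecc_sd = if (n >= 2L) stats::sd(e) else NA_real_,
                ecc_skewness = sample_skewness(e),
                sol_mean = mean(s),
                sol_sd = if (n >= 2L) stats::sd(s) else NA_real_,
                sol_skewness = sample_skewness(s)),
           as.list(pct_large), as.list(pct_ind))
  structure(out, class = "roi_morphometry")
}

#' @export
print.roi_morphometry <- function(x, ...) {
  cat(sprintf("roi_morphometry over %d nuclei\n", x$n_nuclei))
  v <- unlist(x[names(x) != "n_nuclei"])
  print(round(v, 4))
  invisible(x)
}

#' Inverted mean solidity across a case's ROIs
#'
#' One minus the mean of the per-ROI mean solidities; larger values mean
#' more indented nuclei, orienting the score so that higher = more
#' malignant like the size parameters.
#'
#' @param roi_list List of [roi_morphometry()] objects (or anything with a
#'   `sol_mean` element).
#' @return Single numeric score.
#' @export
invert_mean_solidity <- function(roi_list) {
  sm <- vapply(roi_list, function(r) r$sol_mean, numeric(1))
  if (length(sm) == 0L || any(is.na(sm))) stop("sol_mean undefined for some ROI")
  1 - mean(sm)
}

#' Case-level parameter vector from per-ROI morphometry
#'
#' The unweighted mean of every ROI-level parameter across the case's
#' (1 to 5) ROIs. Undefined (`NA`) ROI statistics propagate to `NA`.
#'
#' @param roi_list List of [roi_morphometry()] objects with identical
#'   parameter sets.
#' @return Named numeric vector of case-level parameters.
#' @export
case_morphometry <- function(roi_list) {
  if (length(roi_list) < 1L) stop("need at least one ROI")
  nms <- names(roi_list[[1L]])
  for (r in roi_list) {
    if (!identical(names(r), nms)) stop("ROIs carry mismatched parameter sets")
  }
  vals <- vapply(nms, function(p) {
    mean(vapply(roi_list, function(r) as.numeric(r[[p]]), numeric(1)))
  }, numeric(1))
  names(vals) <- nms
  vals
}

#' Pairwise Pearson correlations between case-level parameters
#'
#' @param case_table Numeric data frame or matrix, one row per case, one
#'   column per parameter (>= 3 cases).
#' @return Symmetric correlation matrix; zero-variance columns yield `NA`
#'   entries with a warning.
#' @export
parameter_correlations <- function(case_table) {
  m <- as.matrix(case_table)
  if (nrow(m) < 3L) stop("need at least 3 cases")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero-variance column(s): correlations reported as NA")
  }
  suppressWarnings(stats::cor(m, method = "pearson", use = "pairwise.complete.obs"))
}
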