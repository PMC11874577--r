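# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by brute force or simple
# enumeration, sharing no code with the implementation paths they check.

# --- pixel-set builders -------------------------------------------------

px_disk <- function(r, cx = 0, cy = 0) {
  g <- expand.grid(x = floor(cx - r - 1):ceiling(cx + r + 1),
                   y = floor(cy - r - 1):ceiling(cy + r + 1))
  as.matrix(g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ])
}

px_ellipse <- function(a, b, cx = 0, cy = 0) {
  g <- expand.grid(x = floor(cx - a - 1):ceiling(cx + a + 1),
                   y = floor(cy - b - 1):ceiling(cy + b + 1))
  as.matrix(g[((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1, ])
}

# Paint 0-based pixel coordinate sets into a label matrix.
mask_from_pixels <- function(pixel_sets, h, w, cal = calibration()) {
  m <- matrix(0L, h, w)
  for (k in seq_along(pixel_sets)) {
    p <- pixel_sets[[k]]
    m[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- k
  }
  label_mask(m, cal)
}

# --- connected components by breadth-first flood fill -------------------

oracle_components <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (m[i, j] > 0 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (o in seq_len(nrow(offs))) {
          ni <- cur[1] + offs[o, 1]; nj <- cur[2] + offs[o, 2]
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              m[ni, nj] > 0 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- nxt
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  lab
}

# --- brute-force distribution statistics --------------------------------

oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics (type-7 definition,
  # written out directly)
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_roi_stats <- function(a, thresholds = c(37.8, 50.3)) {
  n <- length(a)
  mean_a <- sum(a) / n
  med <- oracle_quantile(a, 0.5)
  sd_a <- sqrt(sum((a - mean_a)^2) / (n - 1))
  p90 <- oracle_quantile(a, 0.9)
  k <- ceiling(0.1 * n)
  top <- mean(sort(a, decreasing = TRUE)[1:k])
  pct <- vapply(thresholds, function(t) 100 * sum(a > t) / n, numeric(1))
  m2 <- sum((a - mean_a)^2) / n
  m3 <- sum((a - mean_a)^3) / n
  skew <- if (n >= 3 && sd_a > 0) {
    (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  } else NA_real_
  list(mean = mean_a, median = med, sd = sd_a, p90 = p90,
       ratio = p90 / med, top = top, pct = pct, skew = skew)
}

# --- AUC by concordant-pair enumeration ---------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# --- empirical survival function (no censoring) -------------------------

oracle_empirical_surv <- function(times, t_eval) {
  vapply(t_eval, function(t) mean(times > t), numeric(1))
}

# --- point-in-polygon by winding number ---------------------------------

oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (vy[i] <= py) {
      if (vy[j] > py &&
          (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) > 0) {
        wn <- wn + 1
      }
    } else if (vy[j] <= py &&
               (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i]) < 0) {
      wn <- wn - 1
    }
  }
  wn != 0
}

# --- grid-sampling replay -----------------------------------------------

# Re-derives the center-out serpentine field order and replays the
# collection rules directly on the mask.
oracle_grid_sample <- function(mask, rows = 5, cols = 6, target = 100) {
  lb <- mask$labels
  h <- nrow(lb); w <- ncol(lb)
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  fields <- expand.grid(row = 1:rows, col = 1:cols)
  fields$ring <- pmax(abs(fields$row - cr), abs(fields$col - cc))
  ordered <- NULL
  for (rg in sort(unique(fields$ring))) {
    sub <- fields[fields$ring == rg, ]
    rws <- sort(unique(sub$row))
    for (k in seq_along(rws)) {
      rf <- sub[sub$row == rws[k], ]
      rf <- rf[order(rf$col, decreasing = (k %% 2 == 0)), ]
      ordered <- rbind(ordered, rf)
    }
  }
  border <- unique(c(lb[1, ], lb[h, ], lb[, 1], lb[, w]))
  collected <- integer(0); used <- 0
  for (q in seq_len(nrow(ordered))) {
    used <- used + 1
    fr <- ordered$row[q]; fc <- ordered$col[q]
    rsel <- which(ceiling(seq_len(h) * rows / h) == fr)
    csel <- which(ceiling(seq_len(w) * cols / w) == fc)
    here <- unique(as.vector(lb[rsel, csel]))
    here <- setdiff(here[here > 0], c(collected, border))
    collected <- c(collected, sort(here))
    if (length(collected) >= target) break
  }
  list(ids = collected, n = length(collected), fields_used = used)
}
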