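#' Specification of a synthetic nucleus population
#'
#' Defaults emulate the size statistics of mast-cell-tumor nuclei at
#' 0.25 um/pixel: a right-skewed lognormal area distribution whose
#' default mean 26.5 um^2 and SD 8.6 um^2 put the median near 25 um^2 and
#' the 90th percentile near 37.8 um^2 (the reference values behind the
#' karyomegaly cutoffs), a Beta-distributed eccentricity mapped to
#' \[0, e_max\], and an optional probability of a circular indentation
#' "bite" that lowers solidity. A gamma area distribution is available
#' behind a flag.
#'
#' @param n_nuclei Number of nuclei to place (default 455, a typical
#'   per-ROI annotation count).
#' @param area_mean,area_sd Mean and SD of the nuclear area in um^2.
#' @param area_family `"lognormal"` (default) or `"gamma"`.
#' @param ecc_shape Two Beta shape parameters for eccentricity.
#' @param e_max Upper bound of eccentricity (< 1).
#' @param indent_prob Probability that a nucleus carries an indentation.
#' @param indent_depth Bite radius as a fraction of the minor semi-axis.
#' @param seed Integer seed.
#' @return An object of class `"nucleus_population_spec"`.
#' @export
nucleus_population_spec <- function(n_nuclei = 455L, area_mean = 26.5,
                                    area_sd = 8.6,
                                    area_family = c("lognormal", "gamma"),
                                    ecc_shape = c(5, 3), e_max = 0.95,
                                    indent_prob = 0.05, indent_depth = 0.4,
                                    seed = 1L) {
  area_family <- match.arg(area_family)
  stopifnot(area_mean > 0, area_sd > 0, e_max > 0, e_max < 1,
            indent_prob >= 0, indent_prob <= 1, indent_depth >= 0)
  structure(list(n_nuclei = as.integer(n_nuclei), area_mean = area_mean,
                 area_sd = area_sd, area_family = area_family,
                 ecc_shape = ecc_shape, e_max = e_max,
                 indent_prob = indent_prob, indent_depth = indent_depth,
                 seed = as.integer(seed)),
            class = "nucleus_population_spec")
}

# Draw areas with the requested mean/SD from the chosen family.
draw_areas <- function(n, spec) {
  m <- spec$area_mean; s <- spec$area_sd
  if (spec$area_family == "lognormal") {
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  } else {
    shape <- (m / s)^2
    stats::rgamma(n, shape = shape, rate = shape / m)
  }
}

#' Generate a synthetic ROI with known per-nucleus truth
#'
#' Places non-overlapping deformed ellipses by seeded dart-throwing:
#' nuclei are drawn from the population spec, sorted large-to-small, and
#' placed at uniformly random positions/orientations, rejecting positions
#' that would touch an existing nucleus (a one-pixel separation is
#' enforced so instances stay distinct under 8-connectivity). A nucleus
#' that cannot be placed within 200 attempts is skipped and reported.
#'
#' @param spec A [nucleus_population_spec()].
#' @param image_shape `c(height, width)` in pixels; default is the full
#'   ROI shape from [roi_pixel_shape()].
#' @param cal A [calibration()].
#' @param render Logical; also return a pseudo-stained RGB image (dark
#'   nuclei on a textured light background with granule speckle).
#' @return List with `mask` (a [label_mask()]), `manifest` (per-nucleus
#'   truth: sampled area/eccentricity, indentation flag, realized pixel
#'   count and centroid), `n_skipped`, and optionally `rgb`.
#' @export
generate_roi <- function(spec = nucleus_population_spec(),
                         image_shape = NULL, cal = calibration(),
                         render = FALSE) {
  cal <- as_calibration(cal)
  if (is.null(image_shape)) image_shape <- roi_pixel_shape(cal = cal)
  h <- as.integer(image_shape[[1L]]); w <- as.integer(image_shape[[2L]])
  mpp <- cal$microns_per_pixel
  total_area_px <- spec$n_nuclei * spec$area_mean / mpp^2
  if (total_area_px > 0.4 * h * w) {
    stop(sprintf("infeasible packing: %d nuclei of mean %.1f um^2 exceed 40%% of the ROI; at most %d fit",
                 spec$n_nuclei, spec$area_mean,
                 floor(0.4 * h * w * mpp^2 / spec$area_mean)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_nuclei
  if (n == 0L) {
    return(list(mask = label_mask(matrix(0L, h, w), cal),
                manifest = empty_manifest(), n_skipped = 0L))
  }
  areas <- draw_areas(n, spec)
  eccs <- spec$e_max * stats::rbeta(n, spec$ecc_shape[1L], spec$ecc_shape[2L])
  indent <- stats::runif(n) < spec$indent_prob
  ord <- order(-areas)                  # place large nuclei first
  labels <- matrix(0L, h, w)
  rows <- vector("list", n)
  n_skipped <- 0L
  for (j in seq_len(n)) {
    i <- ord[j]
    a_px <- areas[i] / mpp^2
    semi_b <- sqrt(a_px / pi * sqrt(1 - eccs[i]^2))
    semi_a <- a_px / (pi * semi_b)
    theta <- stats::runif(1, 0, pi)
    placed <- FALSE
    if (semi_a + 2 >= w - semi_a - 1 || semi_a + 2 >= h - semi_a - 1) {
      n_skipped <- n_skipped + 1L   # nucleus larger than the image allows
      next
    }
    for (att in seq_len(200L)) {
      cx <- stats::runif(1, semi_a + 2, w - semi_a - 1)
      cy <- stats::runif(1, semi_a + 2, h - semi_a - 1)
      px <- ellipse_pixels(cx, cy, semi_a, semi_b, theta, h, w)
      if (nrow(px) == 0L) next
      if (indent[i]) {
        phi <- stats::runif(1, 0, 2 * pi)
        bx <- cx + semi_a * cos(phi) * cos(theta) - semi_b * sin(phi) * sin(theta)
        by <- cy + semi_a * cos(phi) * sin(theta) + semi_b * sin(phi) * cos(theta)
        r_bite <- spec$indent_depth * semi_b
        keep <- (px[, 1L] - bx)^2 + (px[, 2L] - by)^2 > r_bite^2
        if (sum(keep) >= 3L) px <- px[keep, , drop = FALSE]
      }
      # candidate plus 1-px halo must be free
      halo <- dilate_coords(px, h, w)
      if (all(labels[halo] == 0L)) {
        labels[cbind(px[, 2L], px[, 1L])] <- i
        rows[[i]] <- data.frame(id = i, area_true = areas[i],
                                eccentricity_true = eccs[i],
                                indented = indent[i],
                                n_px = nrow(px),
                                cx = mean(px[, 1L]) - 1, cy = mean(px[, 2L]) - 1)
        placed <- TRUE
        break
      }
    }
    if (!placed) n_skipped <- n_skipped + 1L
  }
  manifest <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(manifest)) manifest <- empty_manifest()
  manifest <- manifest[order(manifest$id), , drop = FALSE]
  rownames(manifest) <- NULL
  if (n_skipped > 0L) {
    warning(sprintf("%d of %d nuclei could not be placed and were skipped",
                    n_skipped, n))
  }
  out <- list(mask = label_mask(labels, cal), manifest = manifest,
              n_skipped = n_skipped)
  if (render) out$rgb <- render_roi(labels, h, w)
  out
}

empty_manifest <- function() {
  data.frame(id = integer(0), area_true = numeric(0),
             eccentricity_true = numeric(0), indented = logical(0),
             n_px = integer(0), cx = numeric(0), cy = numeric(0))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Pixel centers (1-based (x, y) columns) inside a rotated ellipse.
ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  x0 <- max(1L, floor(cx - a)); x1 <- min(w, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(h, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(cbind(x = integer(0), y = integer(0)))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  ins <- u^2 + v^2 <= 1
  cbind(x = g$x[ins], y = g$y[ins])
}

# Coordinates of the 8-neighborhood dilation of a pixel set, as matrix
# linear indices (clipped to bounds).
dilate_coords <- function(px, h, w) {
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  xs <- outer(px[, 1L], offs$dx, "+")
  ys <- outer(px[, 2L], offs$dy, "+")
  ok <- xs >= 1L & xs <= w & ys >= 1L & ys <= h
  unique((xs[ok] - 1L) * h + ys[ok])
}

# Pseudo-stained RGB rendering: light textured background, dark nuclei,
# granule speckle.
render_roi <- function(labels, h, w) {
  bg <- matrix(0.88 + stats::rnorm(h * w, 0, 0.02), h, w)
  speckle <- stats::runif(h * w) < 0.01
  bg[speckle] <- bg[speckle] - 0.25
  nuc <- labels > 0L
  base <- bg
  base[nuc] <- 0.35 + stats::rnorm(sum(nuc), 0, 0.03)
  base <- pmin(pmax(base, 0), 1)
  rgb <- array(0, c(h, w, 3L))
  rgb[, , 1L] <- pmin(1, base * 1.02)
  rgb[, , 2L] <- base * 0.85
  rgb[, , 3L] <- pmin(1, base * 1.05)
  rgb
}

#' Specification of a synthetic outcome cohort
#'
#' Defaults mirror the analyzed study population: 96 surgically treated
#' cases with 5 ROIs each (4 cases with 4, one with 3), follow-up
#' censoring uniform on 12-45.3 months, an 11/96 unrelated-death rate,
#' and tumor-specific survival that is exponential with log-hazard linear
#' in the case's latent area-SD severity. The default effect size `beta`
#' and baseline `alpha` were fixed so that the generating
#' (truth-ledger) AUC of the area-SD score for tumor-related death is
#' about 0.9 and roughly 13% of cases die of the tumor, matching the
#' cohort the statistics are designed for. `beta = 0` produces a
#' no-signal cohort.
#'
#' @param n_cases Number of cases.
#' @param rois_per_case Integer vector recycled/sampled to one ROI count
#'   per case (default `c(rep(5, 91), rep(4, 4), 3)` scaled to
#'   `n_cases`).
#' @param severity_meanlog,severity_sdlog Lognormal parameters of the
#'   latent case severity (the true case-level area SD, um^2).
#' @param roi_noise_sdlog Between-ROI lognormal noise on the severity.
#' @param alpha Log baseline monthly hazard at the reference severity.
#' @param beta Log-hazard increase per um^2 of area SD.
#' @param severity_ref Reference severity at which `alpha` applies.
#' @param unrelated_rate Probability that a case is at risk of an
#'   unrelated death (exponential with median ~8.5 months).
#' @param followup_range Censoring window in months.
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cases = 96L, rois_per_case = NULL,
                        severity_meanlog = log(6.5), severity_sdlog = 0.45,
                        roi_noise_sdlog = 0.15,
                        alpha = -6.5, beta = 0.52, severity_ref = 6.5,
                        unrelated_rate = 11 / 96,
                        followup_range = c(12, 45.3), seed = 1L) {
  if (is.null(rois_per_case)) {
    base <- c(rep(5L, 91L), rep(4L, 4L), 3L)
    rois_per_case <- rep_len(base, n_cases)
  }
  structure(list(n_cases = as.integer(n_cases),
                 rois_per_case = as.integer(rep_len(rois_per_case, n_cases)),
                 severity_meanlog = severity_meanlog,
                 severity_sdlog = severity_sdlog,
                 roi_noise_sdlog = roi_noise_sdlog,
                 alpha = alpha, beta = beta, severity_ref = severity_ref,
                 unrelated_rate = unrelated_rate,
                 followup_range = followup_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic outcome cohort with truth ledger
#'
#' Draws a latent severity per case (the true case-level SD of nuclear
#' area), per-ROI measurements around it (lognormal between-ROI noise,
#' plus a correlated mean-area column), and outcomes: tumor-specific
#' survival exponential in the severity, an independent unrelated-death
#' process, and uniform administrative censoring at 12-45.3 months.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cases` (case table including outcome columns and
#'   the truth columns `severity`, `hazard`), `roi` (long table: one row
#'   per case x ROI with `area_sd` and `area_mean` measurements), and
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_cases
  sev <- stats::rlnorm(n, spec$severity_meanlog, spec$severity_sdlog)
  hazard <- exp(spec$alpha + spec$beta * (sev - spec$severity_ref))
  t_tumor <- stats::rexp(n, rate = hazard)
  at_risk_unrel <- stats::runif(n) < spec$unrelated_rate
  t_unrel <- ifelse(at_risk_unrel,
                    stats::rexp(n, rate = log(2) / 8.5), Inf)
  t_cens <- stats::runif(n, spec$followup_range[1L], spec$followup_range[2L])
  t_first <- pmin(t_tumor, t_unrel, t_cens)
  cause <- ifelse(t_first == t_tumor, "tumor_related_death",
                  ifelse(t_first == t_unrel, "unrelated_death", "alive_or_lost"))
  cases <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                      survival_time_months = ifelse(cause == "alive_or_lost",
                                                    NA_real_, t_first),
                      cause = cause,
                      followup_months = t_cens,
                      severity = sev, hazard = hazard,
                      stringsAsFactors = FALSE)
  k <- spec$rois_per_case
  roi <- data.frame(
    case_id = rep(cases$case_id, k),
    roi_index = unlist(lapply(k, seq_len)),
    stringsAsFactors = FALSE)
  sev_roi <- rep(sev, k) * exp(stats::rnorm(nrow(roi), 0, spec$roi_noise_sdlog))
  roi$area_sd <- sev_roi
  roi$area_mean <- 15 + 1.6 * sev_roi * exp(stats::rnorm(nrow(roi), 0, 0.08))
  list(cases = cases, roi = roi, spec = spec)
}

#' Case-level scores from a cohort's ROI table
#'
#' Mean of a per-ROI measurement across each case's ROIs, in case order.
#'
#' @param cohort Result of [generate_cohort()] (or a compatible list).
#' @param parameter ROI column to average (default `"area_sd"`).
#' @return Named numeric vector, one score per case.
#' @export
case_scores <- function(cohort, parameter = "area_sd") {
  v <- tapply(cohort$roi[[parameter]], cohort$roi$case_id, mean)
  as.numeric(v[cohort$cases$case_id])
}

#' Per-case ROI value lists from a cohort
#'
#' @param cohort Result of [generate_cohort()].
#' @param parameter ROI column (default `"area_sd"`).
#' @return List of per-ROI value vectors in case order (ROI order
#'   preserved).
#' @export
case_roi_values <- function(cohort, parameter = "area_sd") {
  sp <- split(cohort$roi[[parameter]],
              factor(cohort$roi$case_id, levels = cohort$cases$case_id))
  lapply(sp, as.numeric)
}

#' Specification of simulated raters
#'
#' Each rater carries fixed personal category thresholds (base cutpoints
#' plus a per-rater offset) applied to a noisy reading of the case's
#' latent severity — the "same latent, different thresholds" structure
#' that drives low inter-rater agreement of categorical estimates.
#' Numeric measurements receive multiplicative lognormal noise.
#'
#' @param n_raters Number of raters (default 9).
#' @param cutpoints Base thresholds separating the 3 categories on the
#'   severity scale.
#' @param offset_sd SD of the per-rater threshold offsets.
#' @param reading_sd SD of the per-case perceptual noise added to the
#'   latent severity before categorization.
#' @param measurement_sdlog SD of log measurement noise for numeric
#'   tables.
#' @param time_points Number of repeated sessions (thresholds fixed,
#'   noise fresh).
#' @param seed Integer seed.
#' @return An object of class `"rater_spec"`.
#' @export
rater_spec <- function(n_raters = 9L, cutpoints = c(5.5, 9.0),
                       offset_sd = 1.2, reading_sd = 1.0,
                       measurement_sdlog = 0.2, time_points = 1L,
                       seed = 1L) {
  structure(list(n_raters = as.integer(n_raters), cutpoints = cutpoints,
                 offset_sd = offset_sd, reading_sd = reading_sd,
                 measurement_sdlog = measurement_sdlog,
                 time_points = as.integer(time_points),
                 seed = as.integer(seed)),
            class = "rater_spec")
}

#' Simulate categorical and numeric rater tables for a cohort
#'
#' @param cohort Result of [generate_cohort()].
#' @param spec A [rater_spec()].
#' @return List with `categorical` (cases x raters x time_points integer
#'   array of 3-tier estimates), `numeric` (same shape, noisy severity
#'   measurements), and `offsets` (per-rater threshold offsets).
#' @export
generate_raters <- function(cohort, spec = rater_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  n <- nrow(cohort$cases)
  r <- spec$n_raters; tp <- spec$time_points
  offsets <- stats::rnorm(r, 0, spec$offset_sd)
  sev <- cohort$cases$severity
  cat_arr <- array(NA_integer_, c(n, r, tp),
                   dimnames = list(cohort$cases$case_id,
                                   paste0("R", seq_len(r)), NULL))
  num_arr <- array(NA_real_, dim(cat_arr), dimnames = dimnames(cat_arr))
  for (t in seq_len(tp)) {
    for (j in seq_len(r)) {
      reading <- sev + stats::rnorm(n, 0, spec$reading_sd)
      cuts <- spec$cutpoints + offsets[j]
      cat_arr[, j, t] <- findInterval(reading, cuts) + 1L
      num_arr[, j, t] <- sev * exp(stats::rnorm(n, 0, spec$measurement_sdlog))
    }
  }
  list(categorical = cat_arr, numeric = num_arr, offsets = offsets)
}
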