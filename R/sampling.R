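#' Grid sampling protocol specification
#'
#' A 5 x 6 grid is overlaid on the ROI and whole grid fields are annotated
#' completely, central fields first, until at least `target_n` nuclei are
#' collected. Nuclei touching grid borders are included (once); nuclei cut
#' off at the outer image border are excluded.
#'
#' @param rows,cols Grid dimensions (default 5 x 6).
#' @param target_n Number of nuclei to reach (default 100).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(rows = 5L, cols = 6L, target_n = 100L) {
  stopifnot(rows >= 1L, cols >= 1L, target_n >= 1L)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 target_n = as.integer(target_n)),
            class = "grid_spec")
}

#' Deterministic center-out meander over grid fields
#'
#' The visiting order used by [grid_sample()]: fields are grouped into
#' rings by Chebyshev distance from the grid center, inner rings first;
#' within a ring fields are taken row by row, alternating the column
#' direction (serpentine). This is one concrete, reproducible realization
#' of a "central fields first, border fields last" meander.
#'
#' @param rows,cols Grid dimensions.
#' @return Integer matrix with columns `row`, `col`, one row per field, in
#'   visiting order.
#' @export
meander_order <- function(rows = 5L, cols = 6L) {
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  g <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  g$ring <- pmax(abs(g$row - cr), abs(g$col - cc))
  rings <- sort(unique(g$ring))
  out <- NULL
  for (rg in rings) {
    sub <- g[g$ring == rg, , drop = FALSE]
    rws <- sort(unique(sub$row))
    for (k in seq_along(rws)) {
      rowfields <- sub[sub$row == rws[k], , drop = FALSE]
      ord <- order(rowfields$col, decreasing = (k %% 2L == 0L))
      out <- rbind(out, rowfields[ord, c("row", "col")])
    }
  }
  rownames(out) <- NULL
  as.matrix(out)
}

#' Grid-based complete sampling of nuclei
#'
#' Emulates the manual gold-standard protocol: visit grid fields in the
#' [meander_order()], include every instance whose pixel set intersects the
#' field (instances spanning several fields are counted once, on first
#' encounter), exclude instances touching the outer image border, and stop
#' once at least `target_n` distinct nuclei are collected.
#'
#' @param mask A labeled [label_mask()].
#' @param spec A [grid_spec()].
#' @return List with `ids` (instance labels in collection order), `n`,
#'   `fields_used`, and `shortfall` (`TRUE` when the whole image holds
#'   fewer than `target_n` eligible nuclei).
#' @export
grid_sample <- function(mask, spec = grid_spec()) {
  stopifnot(inherits(mask, "label_mask"))
  lb <- mask$labels
  h <- nrow(lb); w <- ncol(lb)
  ids <- instance_ids(mask)
  if (length(ids) == 0L) {
    return(list(ids = integer(0), n = 0L, fields_used = 0L, shortfall = TRUE))
  }
  border <- unique(c(lb[1L, ], lb[h, ], lb[, 1L], lb[, w]))
  border <- border[border > 0L]
  # field membership of every pixel (fields partition the image)
  fg <- which(lb > 0L)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  frow <- as.integer(pmin(spec$rows, ceiling(r * spec$rows / h)))
  fcol <- as.integer(pmin(spec$cols, ceiling(c * spec$cols / w)))
  fid <- (frow - 1L) * spec$cols + fcol
  inst <- lb[fg]
  # instance -> set of fields it intersects
  pairs <- unique(cbind(inst, fid))
  ord <- meander_order(spec$rows, spec$cols)
  ord_fid <- (ord[, "row"] - 1L) * spec$cols + ord[, "col"]
  collected <- integer(0)
  fields_used <- 0L
  for (f in ord_fid) {
    fields_used <- fields_used + 1L
    here <- pairs[pairs[, 2L] == f, 1L]
    here <- setdiff(here, c(collected, border))
    if (length(here) > 0L) collected <- c(collected, sort(here))
    if (length(collected) >= spec$target_n) break
  }
  shortfall <- length(collected) < spec$target_n
  if (shortfall) fields_used <- spec$rows * spec$cols
  list(ids = collected, n = length(collected), fields_used = fields_used,
       shortfall = shortfall)
}

#' Stratified sampling protocol specification
#'
#' @param n_total Total nuclei to select (default 12).
#' @param strata Number of area strata (default 3: small, intermediate,
#'   large).
#' @param per_stratum Nuclei per stratum (default 4); must satisfy
#'   `strata * per_stratum == n_total`.
#' @param seed Integer seed for the within-stratum draw.
#' @return An object of class `"stratified_spec"`.
#' @export
stratified_spec <- function(n_total = 12L, strata = 3L, per_stratum = 4L,
                            seed = 1L) {
  if (strata * per_stratum != n_total) {
    stop("strata * per_stratum must equal n_total")
  }
  structure(list(n_total = as.integer(n_total), strata = as.integer(strata),
                 per_stratum = as.integer(per_stratum), seed = as.integer(seed)),
            class = "stratified_spec")
}

# Tercile (generally: stratum) membership by area rank; boundaries at
# floor(n/3) and floor(2n/3), ties broken by id.
stratum_ranks <- function(n, strata) {
  bounds <- floor(seq_len(strata - 1L) * n / strata)
  findInterval(seq_len(n), c(0L, bounds, n), left.open = TRUE)
}

#' Stratified selection of 12 nuclei
#'
#' Emulates the practicable manual protocol: nuclei are sorted by area
#' (ties broken by id), split into lower/middle/upper terciles, and
#' `per_stratum` nuclei are drawn uniformly from each tercile with a
#' seeded generator.
#'
#' @param features Data frame with columns `id` and `area`.
#' @param spec A [stratified_spec()].
#' @param weights Optional per-nucleus selection weights (same order as
#'   `features`); used by the rater simulator to tilt the draw toward
#'   large nuclei. `NULL` (default) draws uniformly.
#' @return List with `selection` (the selected rows of `features`),
#'   `mean_area`, `sd_area`, `max_area`, and `shortfall`.
#' @export
stratified_sample_12 <- function(features, spec = stratified_spec(),
                                 weights = NULL) {
  n <- NROW(features)
  if (n == 0L) stop("no nuclei to sample")
  if (is.null(features$area)) stop("'features' needs an 'area' column")
  if (is.null(features$id)) features$id <- seq_len(n)
  if (n < spec$n_total) {
    sel <- features
    return(list(selection = sel, mean_area = mean(sel$area),
                sd_area = stats::sd(sel$area), max_area = max(sel$area),
                shortfall = TRUE))
  }
  ord <- order(features$area, features$id)
  sorted <- features[ord, , drop = FALSE]
  wts <- if (is.null(weights)) NULL else weights[ord]
  stratum <- stratum_ranks(n, spec$strata)
  pick <- integer(0)
  rng <- local_rng(spec$seed)
  for (s in seq_len(spec$strata)) {
    idx <- which(stratum == s)
    if (is.null(wts)) {
      pick <- c(pick, rng$sample(idx, spec$per_stratum))
    } else {
      pick <- c(pick, rng$sample(idx, spec$per_stratum, prob = wts[idx]))
    }
  }
  sel <- sorted[sort(pick), , drop = FALSE]
  rownames(sel) <- NULL
  list(selection = sel, mean_area = mean(sel$area),
       sd_area = stats::sd(sel$area), max_area = max(sel$area),
       shortfall = FALSE)
}

# Seeded draws that do not disturb the caller's RNG state.
local_rng <- function(seed) {
  state <- NULL
  run <- function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    res <- expr_fn()
    state <<- get(".Random.seed", globalenv())
    res
  }
  list(
    sample = function(x, size, prob = NULL, replace = FALSE) run(function() {
      x[sample.int(length(x), size, replace = replace, prob = prob)]
    }),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max))
  )
}

#' Simulate one rater's 12-nucleus measurement
#'
#' A noise model for studying reproducibility of the stratified protocol:
#' the within-tercile draw can be tilted toward large nuclei
#' (area-proportional weight `area^tilt`, emulating the documented human
#' tendency to oversample large cells) and each measured area receives
#' multiplicative lognormal noise (boundary-tracing error). With
#' `tilt = 0` and `noise_sd = 0` the result equals
#' [stratified_sample_12()].
#'
#' @param features Data frame with columns `id` and `area`.
#' @param bias_config List with `noise_sd` (SD of log measured/true area)
#'   and `tilt` (>= 0; 0 = uniform draw).
#' @param seed Integer seed.
#' @return Same structure as [stratified_sample_12()], with the noisy
#'   `area` in `selection$area` (true areas kept as `area_true`).
#' @export
simulate_rater_measurement <- function(features,
                                       bias_config = list(noise_sd = 0.1, tilt = 0),
                                       seed = 1L) {
  tilt <- bias_config$tilt %||% 0
  noise_sd <- bias_config$noise_sd %||% 0
  spec <- stratified_spec(seed = seed)
  w <- if (tilt > 0) features$area^tilt else NULL
  res <- stratified_sample_12(features, spec, weights = w)
  sel <- res$selection
  sel$area_true <- sel$area
  if (noise_sd > 0) {
    rng <- local_rng(seed + 1e6L)
    sel$area <- sel$area * exp(rng$rnorm(nrow(sel), 0, noise_sd))
  }
  res$selection <- sel
  res$mean_area <- mean(sel$area)
  res$sd_area <- stats::sd(sel$area)
  res$max_area <- max(sel$area)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
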