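#' Coefficient of variation across a case's ROIs
#'
#' Sample SD of the per-ROI parameter divided by its mean; a unitless
#' measure of intratumoral heterogeneity.
#'
#' @param values Per-ROI parameter values (>= 2).
#' @return SD/mean, or `NA` with a warning when the mean is 0.
#' @export
roi_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 ROIs")
  m <- mean(values)
  if (m == 0) {
    warning("mean of ROI values is 0; CV undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Between-ROI SD as a prognostic score
#'
#' Sample SD of a parameter across a case's ROIs; location-invariant, so
#' it isolates the spread between tumor regions.
#'
#' @param values Per-ROI parameter values.
#' @return Sample SD; `NA` for a single ROI.
#' @export
roi_sd_score <- function(values) {
  if (length(values) < 2L) return(NA_real_)
  stats::sd(values)
}

#' Proportion of hotspot ROIs
#'
#' Fraction of a case's ROIs whose measurement meets or exceeds the
#' sensitive prognostic cutoff (threshold 1). The boundary is inclusive
#' (`>=`), consistent with the positivity rule used for case-level
#' dichotomization.
#'
#' @param values Per-ROI parameter values (>= 1).
#' @param threshold1 Hotspot cutoff.
#' @return Fraction in \[0, 1\].
#' @export
hotspot_proportion <- function(values, threshold1) {
  if (length(values) < 1L) stop("need at least 1 ROI")
  mean(values >= threshold1)
}

#' Outcome distribution by hotspot-ROI proportion
#'
#' Bins cases by the exact proportion of hotspot ROIs (cases with no
#' hotspot ROI form one bin regardless of their ROI count; other
#' proportions are kept distinct, e.g. 2/5 vs 2/4) and tabulates
#' tumor-related deaths (TRM) against other outcomes. The death
#' probability per bin is `TRM / (TRM + other)`, rounded to a whole
#' percent.
#'
#' @param roi_values List of per-ROI value vectors, one per case.
#' @param trm Logical vector: tumor-related death per case.
#' @param threshold1 Hotspot cutoff (inclusive).
#' @return Data frame with columns `proportion`, `n_hotspot`, `n_roi`
#'   (from the first case observed in the bin), `trm`, `other`,
#'   `death_probability_pct`, ordered by proportion. Empty bins are
#'   omitted.
#' @export
death_probability_table <- function(roi_values, trm, threshold1) {
  stopifnot(length(roi_values) == length(trm))
  k <- vapply(roi_values, function(v) sum(v >= threshold1), integer(1))
  n <- lengths(roi_values)
  prop <- ifelse(k == 0L, 0, k / n)
  bins <- sort(unique(prop))
  rows <- lapply(bins, function(p) {
    idx <- which(prop == p)
    data.frame(proportion = p,
               n_hotspot = k[idx[1L]], n_roi = n[idx[1L]],
               trm = sum(trm[idx]), other = sum(!trm[idx]))
  })
  out <- do.call(rbind, rows)
  out$death_probability_pct <- round(100 * out$trm / (out$trm + out$other))
  out
}

#' Prognostic AUC as a function of the number of ROIs used
#'
#' For k = 1..`max_k`, scores each case by the mean of its first k ROIs
#' (in selection order; cases with fewer ROIs contribute the mean of all
#' they have) and computes the ROC AUC against the outcome labels.
#'
#' @param roi_values List of per-ROI value vectors, one per case, in
#'   selection order.
#' @param labels Logical outcome labels per case.
#' @param max_k Largest ROI count to evaluate (default: max available).
#' @return Named numeric vector of AUCs (`k1`..`kmax`).
#' @export
auc_vs_n_rois <- function(roi_values, labels, max_k = max(lengths(roi_values))) {
  stopifnot(length(roi_values) == length(labels))
  aucs <- vapply(seq_len(max_k), function(k) {
    scores <- vapply(roi_values, function(v) mean(utils::head(v, k)), numeric(1))
    roc_auc(scores, labels, n_boot = 0L)$auc
  }, numeric(1))
  stats::setNames(aucs, paste0("k", seq_len(max_k)))
}
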