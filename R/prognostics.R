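#' Derive outcome labels from case records
#'
#' Implements the censoring conventions of surgical-outcome tumor cohorts. For classification
#' (ROC / confusion metrics), deaths not attributed to the tumor are
#' grouped with survivors:
#' \itemize{
#'   \item `tumor_related_death_anytime`: positive iff the cause of death
#'     is tumor-related, at any time during follow-up.
#'   \item `tumor_specific_12mo`: positive iff a tumor-related death
#'     occurred within the first 12 months.
#'   \item `overall_12mo`: positive iff any death (regardless of cause)
#'     occurred within the first 12 months.
#' }
#' For survival analysis the event is tumor-related death; unrelated
#' deaths are censored at the time of death and survivors at the end of
#' follow-up.
#'
#' @param cases Data frame with columns `case_id`, `survival_time_months`,
#'   `cause` (one of `"tumor_related_death"`, `"unrelated_death"`,
#'   `"alive_or_lost"`), and `followup_months`.
#' @param metric One of `"tumor_related_death_anytime"`,
#'   `"tumor_specific_12mo"`, `"overall_12mo"`.
#' @return List with `label` (logical, classification positives), `time`
#'   and `event` (survival representation), and `metric`.
#' @export
label_outcomes <- function(cases,
                           metric = c("tumor_related_death_anytime",
                                      "tumor_specific_12mo", "overall_12mo")) {
  metric <- match.arg(metric)
  need <- c("case_id", "survival_time_months", "cause", "followup_months")
  miss <- setdiff(need, names(cases))
  if (length(miss) > 0L) stop("cases table lacks column(s): ", paste(miss, collapse = ", "))
  causes <- c("tumor_related_death", "unrelated_death", "alive_or_lost")
  bad <- which(!cases$cause %in% causes)
  if (length(bad) > 0L) stop("unknown cause for case ", cases$case_id[bad[1L]])
  died <- cases$cause != "alive_or_lost"
  t_obs <- ifelse(died, cases$survival_time_months, cases$followup_months)
  bad <- which(!is.finite(t_obs) | t_obs < 0)
  if (length(bad) > 0L) stop("missing or negative time for case ", cases$case_id[bad[1L]])
  trm <- cases$cause == "tumor_related_death"
  label <- switch(metric,
                  tumor_related_death_anytime = trm,
                  tumor_specific_12mo = trm & t_obs <= 12,
                  overall_12mo = died & t_obs <= 12)
  list(label = label, time = t_obs, event = trm, metric = metric)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC over all distinct cutoffs, computed by the Mann-Whitney statistic
#' with midrank tie correction (equivalent to the trapezoidal area under
#' the empirical ROC curve). The 95% CI is a seeded percentile bootstrap
#' over cases; resamples that lose one outcome class are dropped.
#'
#' @param scores Numeric marker values; larger = more malignant.
#' @param labels Logical (or 0/1) outcome labels; both classes required.
#' @param n_boot Bootstrap replicates (default 2000); 0 skips the CI.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `"roc_auc"`: `auc`, `ci_low`, `ci_high`,
#'   `n_boot_used`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels must be paired")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) stop("both outcome classes must be present")
  auc <- auc_mw(scores, labels)
  ci <- c(NA_real_, NA_real_); used <- 0L
  if (n_boot > 0L) {
    rng <- local_rng(seed)
    n <- length(scores)
    reps <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- rng$sample(seq_len(n), n_resample(n), replace = TRUE)
      lb <- labels[idx]
      if (any(lb) && any(!lb)) {
        used <- used + 1L
        reps[used] <- auc_mw(scores[idx], lb)
      }
    }
    if (used > 0L) {
      ci <- as.numeric(stats::quantile(reps[seq_len(used)], c(0.025, 0.975), type = 7))
    }
  }
  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
                 n_boot_used = used, n_pos = npos, n_neg = nneg),
            class = "roc_auc")
}

n_resample <- function(n) n  # bootstrap resamples keep the cohort size

auc_mw <- function(scores, labels) {
  r <- rank(scores)
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @export
print.roc_auc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f; %d+/%d-)\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Candidate cutoff grid over a marker's range
#'
#' The marker range is divided into 200 equal intervals (0.5% steps),
#' yielding the 201 cutoffs `min + k (max - min) / 200`, k = 0..200.
#'
#' @param scores Numeric marker values with at least 2 distinct values.
#' @param n_intervals Number of intervals (default 200).
#' @return Numeric vector of length `n_intervals + 1`.
#' @export
threshold_grid <- function(scores, n_intervals = 200L) {
  rng <- range(scores, finite = TRUE)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    stop("scores are constant; no threshold grid exists")
  }
  rng[1L] + (0:n_intervals) * diff(rng) / n_intervals
}

#' Select the sensitivity-matched cutoff on the grid
#'
#' Scans the [threshold_grid()] cutoffs (a case is positive when its score
#' is >= the cutoff) for those whose sensitivity exactly equals the target
#' and returns the highest such cutoff with its full confusion metrics.
#' The target is matched as a true-positive count, avoiding floating-point
#' percentage comparisons: pass either `c(tp, n_pos)` or a fraction that is
#' expressible as `tp / n_pos`.
#'
#' @param scores Numeric marker values.
#' @param labels Logical outcome labels.
#' @param target_sensitivity Either a length-2 integer vector `c(tp, npos)`
#'   or a single fraction.
#' @param n_intervals Grid resolution (default 200).
#' @return A `"threshold_result"` (see [confusion_metrics()]) with the
#'   selected `cutoff` attached.
#' @export
select_threshold <- function(scores, labels, target_sensitivity,
                             n_intervals = 200L) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  if (npos == 0L) stop("no positive cases")
  if (length(target_sensitivity) == 2L) {
    if (target_sensitivity[2L] != npos) {
      stop(sprintf("target denominator %d does not match the %d positives",
                   target_sensitivity[2L], npos))
    }
    target_tp <- as.integer(target_sensitivity[1L])
  } else {
    tp_exact <- target_sensitivity * npos
    target_tp <- as.integer(round(tp_exact))
    if (abs(tp_exact - target_tp) > 1e-9) {
      stop(sprintf("target sensitivity %.6f is not a multiple of 1/%d",
                   target_sensitivity, npos))
    }
  }
  grid <- threshold_grid(scores, n_intervals)
  tp_at <- vapply(grid, function(ct) sum(scores[labels] >= ct), integer(1))
  hits <- which(tp_at == target_tp)
  if (length(hits) == 0L) {
    ach <- sort(unique(tp_at))
    stop(sprintf("no grid cutoff reaches sensitivity %d/%d; achievable: %s",
                 target_tp, npos,
                 paste(sprintf("%d/%d", ach, npos), collapse = ", ")))
  }
  cutoff <- max(grid[hits])
  tp <- sum(scores[labels] >= cutoff)
  fp <- sum(scores[!labels] >= cutoff)
  fn <- npos - tp
  tn <- sum(!labels) - fp
  res <- confusion_metrics(tp, fp, fn, tn)
  res$cutoff <- cutoff
  res
}

#' Confusion-matrix rates for a dichotomized test
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision (positive
#' predictive value) `tp/(tp+fp)`, and false omission rate `fn/(fn+tn)`
#' (the event rate among test-negative cases). Rates with a zero
#' denominator are `NA` and flagged in `$undefined`.
#'
#' @param tp,fp,fn,tn Non-negative counts (not all zero).
#' @return List of class `"threshold_result"`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              precision = rate(tp, tp + fp),
              false_omission_rate = rate(fn, fn + tn),
              cutoff = NA_real_)
  out$undefined <- names(which(vapply(out[c("sensitivity", "specificity",
                                            "precision", "false_omission_rate")],
                                      is.na, logical(1))))
  structure(out, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result%s: TP=%d FP=%d FN=%d TN=%d\n",
              if (is.finite(x$cutoff)) sprintf(" (cutoff >= %.4g)", x$cutoff) else "",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  Sen=%.1f%% Sp=%.1f%% Pre=%.1f%% FOR=%.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$precision,
              100 * x$false_omission_rate))
  if (length(x$undefined) > 0L) cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via [survival::survfit()]); the median
#' survival is the first time at which the estimated survival drops to
#' 0.5 or below, `NA` if it never does.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical/0-1 event indicators (1 = death, 0 = censored).
#' @return List of class `"km_fit"`: step function points (`time`,
#'   `surv`, `n_risk`, `n_event`), `median`, and the underlying `survfit`
#'   object.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- {
    drop <- which(fit$surv <= 0.5)
    if (length(drop) == 0L) NA_real_ else fit$time[min(drop)]
  }
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, fit = fit),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `"km_fit"`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (right-continuous step function,
#'   `S(t) = 1` before the first event).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- which(km$time <= ti & km$n_event > 0)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d time point(s), median survival %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Univariate Cox proportional-hazards ratio between two groups
#'
#' Partial-likelihood fit with Breslow tie handling (via
#' [survival::coxph()]); Wald 95% CI and p-value. When one group has no
#' events the estimate is unstable: the fit is still reported but flagged.
#'
#' @param group Logical/0-1 group indicator (1 = test-positive group).
#' @param times Follow-up times.
#' @param events Event indicators.
#' @return List of class `"cox_hr"`: `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `events_by_group`, `unstable`.
#' @export
cox_hr <- function(group, times, events) {
  group <- as.integer(as.logical(group))
  events <- as.integer(events)
  if (sum(events) < 1L) stop("need at least one event")
  fit <- survival::coxph(survival::Surv(times, events) ~ group,
                         ties = "breslow")
  co <- summary(fit)$coefficients
  beta <- co[1L, "coef"]; se <- co[1L, "se(coef)"]
  ebg <- tapply(events, group, sum)
  ebg <- stats::setNames(as.integer(ebg[c("0", "1")]), c("0", "1"))
  ebg[is.na(ebg)] <- 0L
  unstable <- any(ebg == 0L) || se > 10
  structure(list(hazard_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p_value = co[1L, "Pr(>|z|)"],
                 log_hr = beta, se = se,
                 events_by_group = ebg,
                 unstable = unstable),
            class = "cox_hr")
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf("Cox HR = %.3g (95%% CI %.3g-%.3g, p = %.3g)%s\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p_value,
              if (x$unstable) " [unstable: group without events or huge SE]" else ""))
  invisible(x)
}
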