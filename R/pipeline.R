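#' Read and write case outcome tables
#'
#' The case CSV carries one row per case with the documented columns
#' `case_id, survival_time_months, cause, followup_months` plus optional
#' benchmark columns (`mc`, `grade`, estimate columns). The ROI CSV is a
#' long table with `case_id, roi_index` and one column per morphometric
#' parameter.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_case_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "survival_time_months", "cause", "followup_months")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("case table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_case_table
#' @param df Data frame to write.
#' @export
write_case_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Drives the package end to end on a simulated cohort (or user-supplied
#' case/ROI tables): morphometry feature tables, prognostic statistics
#' (AUC with bootstrap CI, sensitivity-matched threshold, Kaplan-Meier
#' and Cox by threshold group), intratumoral heterogeneity statistics,
#' and rater-agreement statistics. All randomness is derived from
#' `config$seed`, so reruns with the same configuration are reproducible;
#' numeric output is serialized at fixed precision.
#'
#' @param config Either a path to a YAML file or a named list. Recognized
#'   keys (defaults in parentheses): `seed` (1), `output_dir` (omit to
#'   skip writing), `microns_per_pixel` (required), `parameter` ("area_sd"),
#'   `metric` ("tumor_related_death_anytime"), `target_sensitivity_tp`
#'   (`round(0.769 * n_pos)`), `n_boot` (2000), `cohort` (sub-list of
#'   [cohort_spec()] arguments), `raters` (sub-list of [rater_spec()]
#'   arguments), `cases_csv`/`roi_csv` (use existing tables instead of
#'   simulating), `write` (TRUE when `output_dir` given).
#' @return Invisibly, a list with `features`, `prognosis`,
#'   `heterogeneity`, `agreement`, and `log`; written as CSV/JSON files
#'   when an output directory is configured.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$microns_per_pixel)) {
    stop("config key 'microns_per_pixel' is missing")
  }
  mpp <- config$microns_per_pixel
  parameter <- config$parameter %||% "area_sd"
  metric <- config$metric %||% "tumor_related_death_anytime"
  n_boot <- as.integer(config$n_boot %||% 2000L)

  if (!is.null(config$cases_csv)) {
    cases <- read_case_table(config$cases_csv)
    roi <- utils::read.csv(config$roi_csv, stringsAsFactors = FALSE)
    cohort <- list(cases = cases, roi = roi)
  } else {
    cs_args <- config$cohort %||% list()
    cs_args$seed <- cs_args$seed %||% seed
    cohort <- generate_cohort(do.call(cohort_spec, cs_args))
  }
  if (!parameter %in% names(cohort$roi)) {
    stop("ROI table has no column '", parameter, "'")
  }

  scores <- case_scores(cohort, parameter)
  out <- label_outcomes(cohort$cases, metric)
  npos <- sum(out$label)
  target_tp <- as.integer(config$target_sensitivity_tp %||% round(0.769 * npos))

  auc <- roc_auc(scores, out$label, n_boot = n_boot, seed = seed)
  thr <- tryCatch(select_threshold(scores, out$label, c(target_tp, npos)),
                  error = function(e) e)
  prognosis <- list(parameter = parameter, metric = metric,
                    auc = auc$auc, auc_ci = c(auc$ci_low, auc$ci_high),
                    n_pos = auc$n_pos, n_neg = auc$n_neg)
  if (!inherits(thr, "error")) {
    grp <- scores >= thr$cutoff
    km_hi <- kaplan_meier(out$time[grp], out$event[grp])
    km_lo <- kaplan_meier(out$time[!grp], out$event[!grp])
    cx <- cox_hr(grp, out$time, out$event)
    prognosis <- c(prognosis, list(
      threshold = thr$cutoff,
      sensitivity = thr$sensitivity, specificity = thr$specificity,
      precision = thr$precision, false_omission_rate = thr$false_omission_rate,
      hazard_ratio = cx$hazard_ratio, hr_ci = c(cx$ci_low, cx$ci_high),
      hr_p = cx$p_value, hr_unstable = cx$unstable,
      km_median_high = km_hi$median, km_median_low = km_lo$median))
  } else {
    prognosis$threshold_error <- conditionMessage(thr)
  }

  rv <- case_roi_values(cohort, parameter)
  trm <- cohort$cases$cause == "tumor_related_death"
  het <- list(parameter = parameter,
              cv = vapply(rv, roi_cv, numeric(1)),
              sd_score = vapply(rv, roi_sd_score, numeric(1)))
  if (!inherits(thr, "error")) {
    het$hotspot_proportion <- vapply(rv, hotspot_proportion, numeric(1),
                                     threshold1 = thr$cutoff)
    het$death_probability <- death_probability_table(rv, trm, thr$cutoff)
    het$sd_score_auc <- roc_auc(het$sd_score, out$label, n_boot = 0L)$auc
    het$hotspot_auc <- roc_auc(het$hotspot_proportion, out$label, n_boot = 0L)$auc
    het$auc_vs_n_rois <- auc_vs_n_rois(rv, out$label)
  }

  agreement <- NULL
  if (!is.null(cohort$cases$severity)) {
    rs_args <- config$raters %||% list()
    rs_args$seed <- rs_args$seed %||% (seed + 1L)
    raters <- generate_raters(cohort, do.call(rater_spec, rs_args))
    lk <- lights_kappa(raters$categorical[, , 1L], weighting = "linear")
    icc <- icc_2way_single(raters$numeric[, , 1L])
    agreement <- list(
      lights_kappa = lk$kappa,
      lights_kappa_label = interpret_agreement(lk$kappa, "kappa"),
      icc = icc$icc, icc_ci = c(icc$ci_low, icc$ci_high),
      icc_label = interpret_agreement(icc$icc, "icc"))
  }

  log <- list(package_version = as.character(utils::packageVersion("karyometry")),
              r_version = as.character(getRversion()),
              seed = seed, microns_per_pixel = mpp,
              parameter = parameter, metric = metric,
              timestamp = NA_character_)

  result <- list(features = cohort$roi, cases = cohort$cases,
                 prognosis = prognosis, heterogeneity = het,
                 agreement = agreement, log = log)

  outdir <- config$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(round_numeric(cohort$roi), file.path(outdir, "features.csv"),
                     row.names = FALSE)
    write_case_table(round_numeric(cohort$cases), file.path(outdir, "cases.csv"))
    jsonlite::write_json(round_numeric(prognosis),
                         file.path(outdir, "prognosis.json"),
                         auto_unbox = TRUE, digits = 10, na = "null")
    jsonlite::write_json(round_numeric(het),
                         file.path(outdir, "heterogeneity.json"),
                         auto_unbox = TRUE, digits = 10, na = "null",
                         dataframe = "columns")
    if (!is.null(agreement)) {
      jsonlite::write_json(round_numeric(agreement),
                           file.path(outdir, "agreement.json"),
                           auto_unbox = TRUE, digits = 10, na = "null")
    }
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, na = "null")
  }
  invisible(result)
}

# Round all numeric leaves to 10 significant digits so that rerun outputs
# are byte-identical across platforms.
round_numeric <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, round_numeric))
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = 10)
    return(x)
  }
  if (is.numeric(x)) return(signif(x, 10))
  x
}
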