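make_cases <- function(cause, t, fup = 24) {
  data.frame(case_id = sprintf("c%02d", seq_along(cause)),
             survival_time_months = t, cause = cause,
             followup_months = fup, stringsAsFactors = FALSE)
}

test_that("outcome labeling applies the censoring conventions", {
  cases <- make_cases(
    c("unrelated_death", "tumor_related_death", "alive_or_lost",
      "tumor_related_death", "unrelated_death"),
    c(8.5, 4.3, NA, 14, 6),
    fup = c(NA, NA, 24, NA, NA))
  trm <- label_outcomes(cases, "tumor_related_death_anytime")
  expect_equal(trm$label, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # survival representation: unrelated deaths censored at death time
  expect_equal(trm$time, c(8.5, 4.3, 24, 14, 6))
  expect_equal(trm$event, c(FALSE, TRUE, FALSE, TRUE, FALSE))

  t12 <- label_outcomes(cases, "tumor_specific_12mo")
  expect_equal(t12$label, c(FALSE, TRUE, FALSE, FALSE, FALSE))

  o12 <- label_outcomes(cases, "overall_12mo")
  expect_equal(o12$label, c(TRUE, TRUE, FALSE, FALSE, TRUE))

  bad <- make_cases("tumor_related_death", NA_real_)
  expect_error(label_outcomes(bad), "c01")
})

test_that("AUC equals concordant-pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)$auc, 0.75)
  # perfect separation
  expect_equal(roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)$auc, 1)

  set.seed(77)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- round(rnorm(n), 1)            # ties likely
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auc(sc, lb, n_boot = 0)$auc, oracle_auc(sc, lb))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(sc), lb, n_boot = 0)$auc,
                 roc_auc(sc, lb, n_boot = 0)$auc)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4), n_boot = 0), "both outcome classes")
})

test_that("AUC agrees with an established implementation and null scores give 0.5", {
  skip_if_not_installed("pROC")
  set.seed(88)
  sc <- rnorm(200); lb <- runif(200) < 0.5
  ours <- roc_auc(sc, lb, n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)

  set.seed(99)
  big <- roc_auc(rnorm(2000), runif(2000) < 0.5, n_boot = 0)$auc
  expect_lt(abs(big - 0.5), 0.05)
})

test_that("bootstrap CI brackets the point estimate and is seed-stable", {
  set.seed(3)
  sc <- c(rnorm(60, 1), rnorm(60))
  lb <- rep(c(TRUE, FALSE), each = 60)
  a1 <- roc_auc(sc, lb, n_boot = 400, seed = 11)
  a2 <- roc_auc(sc, lb, n_boot = 400, seed = 11)
  expect_identical(a1$ci_low, a2$ci_low)
  expect_lt(a1$ci_low, a1$auc)
  expect_gt(a1$ci_high, a1$auc)
})

test_that("threshold grid divides the range into 200 intervals", {
  g <- threshold_grid(c(0, 0.25, 1))
  expect_length(g, 201)
  expect_equal(g[1], 0); expect_equal(g[201], 1)
  expect_equal(g[2] - g[1], 0.005)
  g2 <- threshold_grid(c(10, 30))
  expect_equal(unique(round(diff(g2), 10)), 0.1)
  expect_error(threshold_grid(rep(5, 4)), "constant")
})

test_that("threshold selection picks the highest sensitivity-matched cutoff", {
  # separation: positives 10, negatives 1; target 100%
  sc <- c(rep(10, 5), rep(1, 8)); lb <- rep(c(TRUE, FALSE), c(5, 8))
  res <- select_threshold(sc, lb, c(5, 5))
  expect_equal(res$sensitivity, 1)
  expect_equal(res$tp, 5); expect_equal(res$fp, 0)
  expect_equal(res$cutoff, 10)          # max score is on the grid

  # 13 positives at 5..17, target 10/13: verify against exhaustive search
  sc2 <- c(5:17, rep(1, 20)); lb2 <- rep(c(TRUE, FALSE), c(13, 20))
  res2 <- select_threshold(sc2, lb2, c(10, 13))
  grid <- threshold_grid(sc2)
  ok <- grid[sapply(grid, function(ct) sum(sc2[lb2] >= ct) == 10)]
  expect_equal(res2$cutoff, max(ok))
  expect_equal(res2$tp, 10); expect_equal(res2$fn, 3)
  expect_equal(res2$sensitivity, 10 / 13, tolerance = 1e-12)

  # fractional targets must be expressible as a count
  expect_error(select_threshold(sc2, lb2, 0.5), "not a multiple")
  expect_equal(select_threshold(sc2, lb2, 10 / 13)$cutoff, res2$cutoff)

  # unachievable target reports achievable sensitivities
  sc3 <- c(5, 5, 5, 1, 1); lb3 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_error(select_threshold(sc3, lb3, c(1, 3)), "achievable")
})

test_that("selected cutoff is always >= any grid cutoff achieving the target", {
  set.seed(41)
  for (i in 1:10) {
    sc <- round(rlnorm(40, 2, 0.5), 2)
    lb <- runif(40) < 0.3
    if (sum(lb) < 2 || sum(!lb) < 2) next
    grid <- threshold_grid(sc)
    c0 <- sample(grid, 1)
    tp0 <- sum(sc[lb] >= c0)
    if (tp0 == 0) next
    res <- select_threshold(sc, lb, c(tp0, sum(lb)))
    expect_gte(res$cutoff, c0)
  }
})

test_that("confusion metrics reproduce the printed worked examples", {
  expect_equal(confusion_metrics(10, 0, 3, 0)$sensitivity, 0.769, tolerance = 1e-3)
  cm <- confusion_metrics(10, 9, 3, 74)
  expect_equal(100 * cm$sensitivity, 76.9, tolerance = 0.05)
  expect_equal(100 * cm$specificity, 89.2, tolerance = 0.05)
  expect_equal(100 * cm$precision, 52.6, tolerance = 0.05)
  expect_equal(100 * cm$false_omission_rate, 3.9, tolerance = 0.05)

  p0 <- confusion_metrics(0, 0, 2, 5)
  expect_true(is.na(p0$precision))
  expect_true("precision" %in% p0$undefined)
  expect_error(confusion_metrics(0, 0, 0, 0), "all counts")
})

test_that("Kaplan-Meier matches hand product-limit and empirical survival", {
  # events at 1 and 2, n = 2: S = 0.5 on [1,2), 0 after
  km <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km_surv_at(km, c(0.5, 1, 1.9, 2, 3)), c(1, 0.5, 0.5, 0, 0))
  expect_equal(km$median, 1)

  # no events: S == 1
  km0 <- kaplan_meier(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))

  # extending a censored follow-up beyond the last event leaves the
  # curve unchanged
  kmA <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  kmB <- kaplan_meier(c(1, 2, 9), c(1, 1, 0))
  expect_equal(km_surv_at(kmA, c(1, 2, 2.5)), km_surv_at(kmB, c(1, 2, 2.5)))

  # no censoring: equals the empirical survival function
  set.seed(4)
  t <- round(rexp(40, 0.2), 2)
  km2 <- kaplan_meier(t, rep(1, 40))
  grid <- sort(unique(t))
  expect_equal(km_surv_at(km2, grid), oracle_empirical_surv(t, grid),
               tolerance = 1e-12)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Cox regression recovers group hazard ratios", {
  # exchangeable groups: HR ~ 1, CI covers 1
  set.seed(10)
  t <- rexp(200, 0.1); g <- rep(0:1, 100)
  fit <- cox_hr(g, t, rep(1, 200))
  expect_gt(fit$ci_high, 1); expect_lt(fit$ci_low, 1)

  # true HR = 2 at n = 2000, no censoring
  set.seed(20)
  n <- 2000; g <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = 0.1 * 2^g)
  fit2 <- cox_hr(g, t, rep(1, n))
  expect_lt(abs(fit2$log_hr - log(2)), 3 * fit2$se)

  # single-event data flagged unstable
  fit3 <- suppressWarnings(cox_hr(c(0, 0, 1, 1), c(5, 6, 1, 7), c(0, 0, 1, 0)))
  expect_true(fit3$unstable)
})
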