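test_that("shape descriptors behave analytically on disks and ellipses", {
  d <- px_disk(40)
  f <- nucleus_features(d, calibration(0.25))
  expect_lt(abs(f$eccentricity), 0.05)
  expect_gte(f$solidity, 0.98)

  # semi-axes 5 um and 3 um at 0.05 um/px -> 100 x 60 px
  e <- px_ellipse(100, 60)
  fe <- nucleus_features(e, calibration(0.05))
  expect_equal(fe$area, pi * 15, tolerance = 0.01)
  expect_equal(fe$eccentricity, 0.8, tolerance = 0.02)

  # convex instance: solidity exactly 1 in pixel counts
  sq <- expand.grid(x = 0:9, y = 0:9)
  fs <- nucleus_features(as.matrix(sq))
  expect_identical(fs$solidity, 1)

  # degenerate 1-px instance
  f1 <- nucleus_features(cbind(3, 4))
  expect_equal(f1$eccentricity, 0)
  expect_equal(f1$solidity, 1)

  expect_error(nucleus_features(matrix(numeric(0), 0, 2)), "empty")
})

test_that("indentation lowers solidity below the convex value", {
  d <- px_disk(15, 20, 20)
  bite <- (d[, 1] - 35)^2 + (d[, 2] - 20)^2 > 64
  f_full <- nucleus_features(d)
  f_bitten <- nucleus_features(d[bite, ])
  expect_identical(f_full$solidity, 1)
  expect_lt(f_bitten$solidity, 0.95)
})

test_that("ROI statistics match brute-force recomputation", {
  # worked example: areas 10,12,...,28
  a <- seq(10, 28, by = 2)
  m <- roi_morphometry(data.frame(area = a, eccentricity = a * 0, solidity = a * 0 + 1))
  expect_equal(m$area_mean_top10, 28)
  expect_equal(m$area_p90, oracle_quantile(a, 0.9))

  # {30, 40, 60} with threshold 50.3 -> 33.33% large
  m2 <- roi_morphometry(data.frame(area = c(30, 40, 60),
                                   eccentricity = c(0.1, 0.2, 0.3),
                                   solidity = c(1, 1, 1)))
  expect_equal(m2$pct_large_50.3, 100 / 3)

  # degenerate equal-area ROI
  m3 <- roi_morphometry(data.frame(area = rep(20, 5), eccentricity = rep(0.5, 5),
                                   solidity = rep(0.97, 5)))
  expect_equal(m3$area_sd, 0)
  expect_equal(m3$area_p90_over_median, 1)
  expect_true(is.na(m3$area_skewness))

  # property: random lists against the brute-force oracle
  set.seed(101)
  for (i in 1:25) {
    a <- rlnorm(sample(3:200, 1), log(25), 0.4)
    f <- data.frame(area = a, eccentricity = runif(length(a), 0, 0.9),
                    solidity = runif(length(a), 0.85, 1))
    m <- roi_morphometry(f)
    o <- oracle_roi_stats(a)
    expect_equal(m$area_mean, o$mean, tolerance = 1e-9)
    expect_equal(m$area_median, o$median, tolerance = 1e-9)
    expect_equal(m$area_sd, o$sd, tolerance = 1e-9)
    expect_equal(m$area_p90, o$p90, tolerance = 1e-9)
    expect_equal(m$area_p90_over_median, o$ratio, tolerance = 1e-9)
    expect_equal(m$area_mean_top10, o$top, tolerance = 1e-9)
    expect_equal(m$area_skewness, o$skew, tolerance = 1e-9)
    expect_equal(unname(c(m$pct_large_37.8, m$pct_large_50.3)), o$pct,
                 tolerance = 1e-9)
  }
  expect_error(roi_morphometry(data.frame()), "no nuclei")
})

test_that("percentage of large nuclei is non-increasing in its threshold", {
  set.seed(5)
  a <- rlnorm(500, log(25), 0.4)
  f <- data.frame(area = a, eccentricity = a * 0, solidity = a * 0 + 1)
  pcts <- sapply(c(10, 20, 37.8, 50.3, 80), function(t) {
    roi_morphometry(f, morphometry_config(large_nucleus_thresholds_um2 = t))[[paste0("pct_large_", t)]]
  })
  expect_true(all(diff(pcts) <= 0))
})

test_that("area statistics are scale-equivariant in the calibration", {
  set.seed(21)
  d <- list(px_disk(6, 10, 10), px_ellipse(9, 5, 30, 12), px_disk(8, 50, 30))
  feats <- function(cal) {
    do.call(rbind, lapply(d, function(p) {
      f <- nucleus_features(p, cal)
      data.frame(area = f$area, eccentricity = f$eccentricity, solidity = f$solidity)
    }))
  }
  m1 <- roi_morphometry(feats(calibration(0.25)))
  m2 <- roi_morphometry(feats(calibration(0.5)))
  for (p in c("area_mean", "area_median", "area_sd", "area_p90", "area_mean_top10")) {
    expect_equal(m2[[p]], 4 * m1[[p]], tolerance = 1e-12)
  }
  expect_equal(m2$ecc_mean, m1$ecc_mean)
  expect_equal(m2$sol_mean, m1$sol_mean)
  expect_equal(m2$area_p90_over_median, m1$area_p90_over_median)
})

test_that("case aggregation averages ROI parameters unweighted", {
  f1 <- data.frame(area = c(10, 20, 30), eccentricity = c(0.2, 0.3, 0.4),
                   solidity = c(0.95, 0.96, 0.97))
  f2 <- data.frame(area = c(20, 30, 40), eccentricity = c(0.3, 0.4, 0.5),
                   solidity = c(0.93, 0.94, 0.95))
  r1 <- roi_morphometry(f1); r2 <- roi_morphometry(f2)
  cm <- case_morphometry(list(r1, r2))
  expect_equal(unname(cm["area_sd"]), mean(c(r1$area_sd, r2$area_sd)))
  # single ROI: identity
  cm1 <- case_morphometry(list(r1))
  expect_equal(unname(cm1["area_mean"]), r1$area_mean)
  # five ROIs, one extreme
  mk <- function(pct) structure(list(pct_large_50.3 = pct), class = "roi_morphometry")
  cm5 <- case_morphometry(lapply(c(0, 0, 0, 0, 100), mk))
  expect_equal(unname(cm5["pct_large_50.3"]), 20)
  expect_error(case_morphometry(list(r1, structure(list(a = 1), class = "roi_morphometry"))),
               "mismatched")
})

test_that("inverted mean solidity orients indentation upward", {
  mk <- function(s) structure(list(sol_mean = s), class = "roi_morphometry")
  expect_equal(invert_mean_solidity(lapply(c(0.95, 0.97, 0.96), mk)), 0.04)
  expect_equal(invert_mean_solidity(list(mk(1), mk(1))), 0)
  expect_equal(invert_mean_solidity(list(mk(0.9))), 0.1)
})

test_that("parameter correlations recover known structure", {
  x <- c(1, 3, 2, 5, 4, 6)
  tab <- data.frame(a = x, b = x, c = -x)
  r <- parameter_correlations(tab)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_equal(unname(diag(r)), rep(1, 3))

  set.seed(33)
  n <- 10000
  u <- rnorm(n); v <- 0.9 * u + sqrt(1 - 0.81) * rnorm(n)
  r2 <- parameter_correlations(data.frame(u = u, v = v))
  expect_equal(unname(r2["u", "v"]), 0.9, tolerance = 0.02)

  expect_warning(rz <- parameter_correlations(data.frame(a = x, z = rep(1, 6))),
                 "zero-variance")
  expect_true(is.na(rz["a", "z"]))
  expect_error(parameter_correlations(data.frame(a = 1:2, b = 2:1)), "3 cases")
})
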