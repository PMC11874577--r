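test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohens_kappa(c(1, 2, 3), c(1, 2, 3))$kappa, 1)

  # 2x2 table a=20, b=5, c=10, d=15: po=0.7, pe=0.5 -> kappa 0.4
  r1 <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  r2 <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)

  # independent uniform ratings: kappa ~ 0
  set.seed(14)
  a <- sample(1:3, 10000, replace = TRUE)
  b <- sample(1:3, 10000, replace = TRUE)
  expect_equal(cohens_kappa(a, b)$kappa, 0, tolerance = 0.03)

  # degenerate: both raters constant and identical
  dg <- cohens_kappa(rep(1, 5), rep(1, 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$kappa))
})

test_that("kappa weighting penalizes distant disagreements less/more", {
  set.seed(15)
  a <- sample(1:3, 500, replace = TRUE)
  b <- pmin(3, pmax(1, a + sample(c(-1, 0, 1), 500, replace = TRUE, prob = c(.2, .6, .2))))
  ku <- cohens_kappa(a, b, "none")$kappa
  kl <- cohens_kappa(a, b, "linear")$kappa
  kq <- cohens_kappa(a, b, "quadratic")$kappa
  # adjacent-only disagreement: quadratic >= linear >= unweighted
  expect_gte(kq, kl)
  expect_gte(kl, ku)
  # unweighted kappa invariant under consistent relabeling
  relab <- c(a = "III", b = "I", c = "II")
  map <- function(x) relab[letters[x]]
  expect_equal(cohens_kappa(map(a), map(b), "none")$kappa, ku, tolerance = 1e-12)
})

test_that("Light's kappa is the mean pairwise Cohen's kappa", {
  m <- cbind(c(1, 2, 3, 1, 2), c(1, 2, 3, 1, 2), c(1, 2, 3, 1, 2))
  expect_equal(lights_kappa(m)$kappa, 1)

  set.seed(16)
  two <- cbind(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  expect_equal(lights_kappa(two)$kappa, cohens_kappa(two[, 1], two[, 2])$kappa)

  three <- cbind(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  lk <- lights_kappa(three)
  pairwise <- c(cohens_kappa(three[, 1], three[, 2])$kappa,
                cohens_kappa(three[, 1], three[, 3])$kappa,
                cohens_kappa(three[, 2], three[, 3])$kappa)
  expect_equal(lk$kappa, mean(pairwise), tolerance = 1e-12)
})

test_that("ICC(2,1) recovers known variance components", {
  m <- cbind(c(1, 5, 2, 8), c(1, 5, 2, 8))
  expect_equal(icc_2way_single(m)$icc, 1)

  # pure noise columns: ICC ~ 0
  set.seed(17)
  noise <- matrix(rnorm(5000 * 3), 5000, 3)
  expect_equal(icc_2way_single(noise)$icc, 0, tolerance = 0.05)

  # case SD 2, rater effect 0, noise SD 1 -> ICC = 4/5
  set.seed(18)
  case <- rnorm(2000, 0, 2)
  tab <- sapply(1:3, function(j) case + rnorm(2000))
  icc <- icc_2way_single(tab)
  expect_equal(icc$icc, 0.8, tolerance = 0.05)
  expect_lt(icc$ci_low, icc$icc); expect_gt(icc$ci_high, icc$icc)

  # a systematic rater offset lowers absolute agreement
  tab2 <- tab; tab2[, 2] <- tab2[, 2] + 2
  expect_lt(icc_2way_single(tab2)$icc, icc$icc)

  # listwise deletion is reported
  tab3 <- tab; tab3[5, 2] <- NA
  expect_equal(icc_2way_single(tab3)$n_dropped, 1)
  expect_error(icc_2way_single(tab[, 1, drop = FALSE]), "2 cases and 2 raters")
})

test_that("agreement bands follow the published interpretation scales", {
  expect_equal(interpret_agreement(0.226, "kappa"), "fair")
  expect_equal(interpret_agreement(0.654, "icc"), "good")
  expect_equal(interpret_agreement(0, "kappa"), "poor")
  expect_equal(interpret_agreement(-0.3, "kappa"), "poor")
  expect_equal(interpret_agreement(0.51, "kappa"), "moderate")
  expect_equal(interpret_agreement(0.85, "kappa"), "almost perfect")
  expect_equal(interpret_agreement(0.39, "icc"), "poor")
  expect_equal(interpret_agreement(0.75, "icc"), "excellent")
})

test_that("consensus counting respects the agreement quorum", {
  all_same <- matrix(1, 10, 9)
  expect_equal(consensus_count(all_same, 8), 10)

  split54 <- matrix(rep(c(1, 1, 1, 1, 1, 2, 2, 2, 2), 4), 4, 9, byrow = TRUE)
  expect_equal(consensus_count(split54, 8), 0)

  # engineered: exactly 43 of 96 cases reach 8/9 consensus
  set.seed(19)
  tab <- matrix(1, 96, 9)
  dissent <- sample(96, 96 - 43)
  tab[dissent, 1:2] <- 2           # two dissenters -> max multiplicity 7
  expect_equal(consensus_count(tab, 8), 43)
})

test_that("simulated raters show the same-latent different-thresholds structure", {
  co <- generate_cohort(cohort_spec(seed = 5))
  rt <- generate_raters(co, rater_spec(time_points = 2, seed = 7))
  expect_equal(dim(rt$categorical), c(96, 9, 2))

  # no noise, identical thresholds: perfect agreement
  rt0 <- generate_raters(co, rater_spec(offset_sd = 0, reading_sd = 0, seed = 2))
  expect_equal(lights_kappa(rt0$categorical[, , 1], "linear")$kappa, 1)

  # wide threshold offsets: inter-rater below intrarater agreement
  inter <- intra <- numeric(30)
  for (i in 1:30) {
    r <- generate_raters(co, rater_spec(offset_sd = 1.5, reading_sd = 0.8,
                                        time_points = 2, seed = 100 + i))
    inter[i] <- lights_kappa(r$categorical[, , 1], "linear")$kappa
    intra[i] <- mean(sapply(1:9, function(j) {
      cohens_kappa(r$categorical[, j, 1], r$categorical[, j, 2], "linear")$kappa
    }))
  }
  expect_gt(mean(intra), mean(inter))

  # less measurement noise raises the ICC monotonically
  iccs <- sapply(c(0.4, 0.2, 0.05), function(s) {
    r <- generate_raters(co, rater_spec(measurement_sdlog = s, seed = 31))
    icc_2way_single(r$numeric[, , 1])$icc
  })
  expect_true(all(diff(iccs) > 0))
})
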