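test_that("weighted percentile follows the cumulative-volume convention", {
  expect_equal(weighted_percentile(5, 1, 40), 5)
  # equal volumes reduce to the standard percentile
  expect_equal(weighted_percentile(1:10000, 1, 75), 7500,
               tolerance = 1e-3)
  # 75% of the volume sits at value 1
  expect_equal(weighted_percentile(c(1, 2), c(3, 1), 75), 1)
  # brute-force oracle on random weighted data: smallest x with
  # cumulative volume fraction >= q (up to the interpolation step)
  set.seed(21)
  x <- stats::runif(200); w <- stats::runif(200, 0.1, 2)
  q <- 60
  wp <- weighted_percentile(x, w, q)
  o <- order(x); cf <- cumsum(w[o]) / sum(w)
  k <- which(cf >= q / 100)[1]
  expect_gte(wp, if (k == 1) x[o][1] else x[o][k - 1])
  expect_lte(wp, x[o][k])
  expect_error(weighted_percentile(numeric(0)), "empty")
})

test_that("exceedance curves are exact monotone step functions", {
  cv <- exceedance_curve(c(1, 2, 3, 4), 1)
  expect_equal(exceedance_at(cv, 2.5), 0.5)
  expect_equal(exceedance_at(cv, 0), 1)       # below the minimum
  expect_equal(exceedance_at(cv, 4.0001), 0)  # beyond the maximum
  expect_true(all(diff(exceedance_at(cv, seq(0, 5, 0.1))) <= 0))
  one <- exceedance_curve(rep(3, 5), 2)
  expect_equal(exceedance_at(one, 3), 1)
  expect_equal(exceedance_at(one, 3.001), 0)
  expect_error(exceedance_curve(numeric(0)), "empty")
})

test_that("AUC from zero equals the volume-weighted mean exactly", {
  set.seed(31)
  for (k in 1:10) {
    x <- stats::rlnorm(500); w <- stats::runif(500, 0.5, 3)
    cv <- exceedance_curve(x, w)
    expect_equal(auc(cv, 0), sum(w * x) / sum(w), tolerance = 1e-10)
  }
  cv <- exceedance_curve(c(1, 5), c(1, 1))
  expect_equal(auc(cv, 10), 0)
})

test_that("uniform fields reproduce the closed-form exposure values", {
  a <- 8
  set.seed(41)
  x <- stats::runif(2e5, 0, a)
  ex <- tissue_exposure(x, rep(1, length(x)), 0.75 * a)
  # AUC ratio: (a - T)^2 / (2a) over a/2 = 6.25%
  expect_equal(ex$exposure_auc_pct, 6.25, tolerance = 0.15)
  expect_equal(ex$volume_fraction_above_pct, 25, tolerance = 0.3)
})

test_that("the fraction above a field's own 75th percentile is 25%", {
  set.seed(51)
  x <- stats::rlnorm(1e4, 0, 0.6); w <- stats::runif(1e4, 0.5, 2)
  thr <- weighted_percentile(x, w, 75)
  ex <- tissue_exposure(x, w, thr)
  expect_equal(ex$volume_fraction_above_pct, 25, tolerance = 0.02)
})

test_that("tissue exposure is scale-equivariant and monotone in threshold", {
  set.seed(61)
  x <- stats::rlnorm(2000); w <- stats::runif(2000, 0.5, 2)
  thr <- weighted_percentile(x, w, 70)
  e1 <- tissue_exposure(x, w, thr)
  c_ <- 37.5
  e2 <- tissue_exposure(c_ * x, w, c_ * thr)
  expect_equal(e1$exposure_auc_pct, e2$exposure_auc_pct, tolerance = 1e-10)
  expect_equal(e1$volume_fraction_above_pct, e2$volume_fraction_above_pct)
  # monotone non-increasing in the threshold
  ths <- seq(0, max(x), length.out = 40)
  aucs <- vapply(ths, function(t) tissue_exposure(x, w, t)$exposure_auc_pct,
                 numeric(1))
  vols <- vapply(ths, function(t)
    tissue_exposure(x, w, t)$volume_fraction_above_pct, numeric(1))
  expect_true(all(diff(aucs) <= 1e-12))
  expect_true(all(diff(vols) <= 1e-12))
  expect_equal(tissue_exposure(x, w, 0)$exposure_auc_pct, 100)
  expect_equal(tissue_exposure(x, w, max(x) + 1)$exposure_auc_pct, 0)
  expect_error(tissue_exposure(rep(0, 5), rep(1, 5), 1), "zero total")
})

test_that("weighted percentiles recover analytic lognormal quantiles", {
  set.seed(71)
  n <- 1e5; meanlog <- log(2); sdlog <- 0.5
  x <- stats::rlnorm(n, meanlog, sdlog)
  w <- stats::runif(n, 0.5, 1.5)   # volumes independent of values
  for (q in c(50, 75, 90)) {
    est <- weighted_percentile(x, w, q)
    thq <- stats::qlnorm(q / 100, meanlog, sdlog)
    se <- sqrt(q / 100 * (1 - q / 100) / n) /
      stats::dlnorm(thq, meanlog, sdlog) * sqrt(1 + (0.5 / sqrt(12))^2)
    expect_lt(abs(est - thq), 3 * se * 1.5)
  }
})

test_that("reference thresholds cover every tissue, pressure and quantity", {
  set.seed(81)
  fake <- function(scale) {
    layers <- rep(c("epidermis", "dermis", "adipose", "muscle"), each = 50)
    data.frame(layer = layers, volume = stats::runif(200, 0.5, 2),
               sigma_vm = stats::rlnorm(200) * scale,
               eps_eff = stats::rlnorm(200, -2, 0.4) * scale, roi = TRUE)
  }
  tab <- reference_thresholds(list(`2` = fake(0.3), `10` = fake(1)))
  expect_s3_class(tab, "exposure_thresholds")
  expect_equal(nrow(tab), 4 * 2 * 2)
  expect_true(all(tab$threshold >= 0))
  # single sample per selection returns that value
  one <- data.frame(layer = "muscle", volume = 1, sigma_vm = 4,
                    eps_eff = 0.2, roi = TRUE)
  t1 <- reference_thresholds(list(`10` = one), layers = "muscle")
  expect_equal(t1$threshold, c(4, 0.2))
  expect_error(
    tissueload:::lookup_threshold(tab, "muscle", 6, "stress"),
    "no unique threshold")
})

test_that("strain benchmark bands count the therapeutic and damage volumes", {
  all5 <- data.frame(layer = "muscle", volume = 1, sigma_vm = 1,
                     eps_eff = 0.05, roi = TRUE)
  f <- strain_benchmark_flags(all5)
  expect_equal(unname(f), c(100, 0))
  f <- strain_benchmark_flags(rep(0.10, 7))
  expect_equal(unname(f), c(0, 100))
  f <- strain_benchmark_flags(c(0.02, 0.05, 0.10))
  expect_equal(unname(f), c(100 / 3, 100 / 3), tolerance = 1e-12)
})
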