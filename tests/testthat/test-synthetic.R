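test_that("the confined-compression oracle is self-consistent", {
  for (E in c(2, 35, 1500)) for (p in c(0.3, 2, 10)) {
    m <- material_params("t", E, 0.48)
    ref <- uniaxial_strain_benchmark(m, p)
    resid <- m$mu * ref$J - m$mu / ref$J + m$lam * log(ref$J) / ref$J + p
    expect_lt(abs(resid), 1e-10 * max(1, p))
    expect_lt(ref$J, 1)        # compression shrinks volume
    expect_gt(ref$J, 0)
  }
  ref0 <- uniaxial_strain_benchmark(material_params("t", 2, 0.48), 0)
  expect_equal(ref0$J, 1)
  expect_equal(max(abs(ref0$sigma)), 0)
})

test_that("the oracle converges to linear confined compression at small load", {
  m <- material_params("t", 10, 0.3)
  M <- m$lam + 2 * m$mu        # confined (P-wave) modulus
  for (p in c(1e-4, 1e-5)) {
    ref <- uniaxial_strain_benchmark(m, p)
    eps <- log(ref$J)
    expect_equal(-p / M, eps, tolerance = 1e-3)
  }
})

test_that("half-space settlement formula has the documented scalings", {
  w0 <- circular_load_halfspace_benchmark(100, 0.3, 1, 5)
  expect_equal(w0, 0.091)
  expect_equal(circular_load_halfspace_benchmark(100, 0.3, 1, 10), 2 * w0)
  expect_equal(circular_load_halfspace_benchmark(200, 0.3, 1, 5), w0 / 2)
  expect_equal(circular_load_halfspace_benchmark(100, 0.3, 2, 5), 2 * w0)
})

test_that("synthetic fields are seeded, reproducible and well-calibrated", {
  spec <- synthetic_field_spec(list(
    muscle = list(stress = list(dist = "lognormal", p1 = log(2), p2 = 0.4),
                  strain = list(dist = "uniform", p1 = 0, p2 = 0.3),
                  volume = 500, n = 4000),
    dermis = list(stress = list(dist = "gamma", p1 = 4, p2 = 2),
                  strain = list(dist = "lognormal", p1 = -2, p2 = 0.3),
                  volume = 100, n = 4000)), seed = 7)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a, b)                       # bit-reproducible
  expect_equal(nrow(a), 8000)
  expect_equal(sum(a$volume[a$layer == "muscle"]), 500, tolerance = 1e-9)
  # empirical means within 3 sigma / sqrt(n) of the design means
  mus <- a$sigma_vm[a$layer == "muscle"]
  design_mean <- exp(log(2) + 0.4^2 / 2)
  expect_lt(abs(mean(mus) - design_mean),
            3 * stats::sd(mus) / sqrt(length(mus)))
  du <- a$eps_eff[a$layer == "muscle"]
  expect_lt(abs(mean(du) - 0.15), 3 * stats::sd(du) / sqrt(length(du)))
  # a degenerate lognormal collapses to its point mass
  d <- generate_field(synthetic_field_spec(list(
    muscle = list(stress = list(dist = "lognormal", p1 = 0, p2 = 0),
                  strain = list(dist = "lognormal", p1 = 0, p2 = 0),
                  volume = 1, n = 10))))
  expect_equal(d$sigma_vm, rep(1, 10))
  expect_error(synthetic_field_spec(list(
    muscle = list(stress = list(dist = "uniform", p1 = 1, p2 = 0),
                  strain = list(dist = "lognormal", p1 = 0, p2 = 1),
                  volume = 1, n = 5))), "uniform")
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  invisible(generate_field(synthetic_field_spec(list(
    muscle = list(stress = list(dist = "lognormal", p1 = 0, p2 = 1),
                  strain = list(dist = "lognormal", p1 = 0, p2 = 1),
                  volume = 1, n = 5)), seed = 99)))
  expect_identical(stats::runif(1), r1)
})

test_that("uniform synthetic fields flow through the exposure closed forms", {
  a <- 0.4
  spec <- synthetic_field_spec(list(
    muscle = list(stress = list(dist = "uniform", p1 = 0, p2 = a),
                  strain = list(dist = "uniform", p1 = 0, p2 = a),
                  volume = 1000, n = 2e5)), seed = 13)
  s <- generate_field(spec)
  ex <- tissue_exposure(s$eps_eff, s$volume, 0.75 * a)
  expect_equal(ex$exposure_auc_pct, 6.25, tolerance = 0.2)
  expect_equal(ex$volume_fraction_above_pct, 25, tolerance = 0.4)
})

test_that("two-cohort fixtures realize the designed deep-layer contrast", {
  # effect = 1: exposures agree within Monte-Carlo error
  fx1 <- two_cohort_fixture(effect = 1, seed = 5, n = 20000)
  thr <- weighted_percentile(fx1$A$eps_eff[fx1$A$layer == "muscle"],
                             fx1$A$volume[fx1$A$layer == "muscle"], 75)
  fr <- function(s, th) {
    sel <- s$layer == "muscle"
    100 * sum(s$volume[sel & s$eps_eff > th]) / sum(s$volume[sel])
  }
  expect_equal(fr(fx1$B, thr), 25, tolerance = 1.5)

  # effect = 1.3, lognormal: matches the analytic lognormal tail
  fx <- two_cohort_fixture(effect = 1.3, seed = 5, n = 20000)
  thr <- weighted_percentile(fx$A$eps_eff[fx$A$layer == "muscle"],
                             fx$A$volume[fx$A$layer == "muscle"], 75)
  # muscle strain is lognormal(log 0.25, 0.4) scaled by 1.3
  p_expect <- 100 * (1 - stats::plnorm(thr / 1.3, log(0.25), 0.4))
  expect_equal(fr(fx$B, thr), p_expect, tolerance = 1.5)
  expect_gt(fr(fx$B, thr), 25)   # stochastic dominance upward

  # effect < 1: cohort B is less exposed
  fxd <- two_cohort_fixture(effect = 0.8, seed = 5, n = 20000)
  thr <- weighted_percentile(fxd$A$eps_eff[fxd$A$layer == "muscle"],
                             fxd$A$volume[fxd$A$layer == "muscle"], 75)
  expect_lt(fr(fxd$B, thr), fr(fxd$A, thr))
})
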