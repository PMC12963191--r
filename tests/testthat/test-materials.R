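test_that("Lame conversions match the isotropic relations and round-trip", {
  lm <- lame_from_moduli(1500, 0.48)
  expect_equal(lm[["lam"]], 1500 * 0.48 / (1.48 * 0.04), tolerance = 1e-12)
  expect_equal(lm[["mu"]], 1500 / 2.96, tolerance = 1e-12)
  expect_equal(unname(lame_from_moduli(2, 0)), c(0, 1))
  expect_equal(unname(lame_from_moduli(1, 0.25)), c(0.4, 0.4))

  for (E in c(0.5, 35, 6480)) for (nu in c(0, 0.25, 0.33, 0.48)) {
    back <- moduli_from_lame(lame_from_moduli(E, nu)[["lam"]],
                             lame_from_moduli(E, nu)[["mu"]])
    expect_equal(back[["E"]], E, tolerance = 1e-12)
    expect_equal(back[["nu"]], nu, tolerance = 1e-12)
  }
  expect_error(lame_from_moduli(100, 0.5), "mixed formulation")
  expect_error(lame_from_moduli(-1, 0.3), "E must be")
})

test_that("Neo-Hookean energy matches direct evaluation and vanishes at rest", {
  m11 <- material_params("t", E = 2.5, nu = 0.25)  # mu = 1, lam = 1
  expect_equal(m11$mu, 1); expect_equal(m11$lam, 1)
  expect_equal(neo_hookean_energy(diag(3), m11), 0)
  # F = diag(1.2, 1, 1): I1 = 3.44, J = 1.2
  expect_equal(neo_hookean_energy(diag(c(1.2, 1, 1)), m11),
               0.5 * 0.44 - log(1.2) + 0.5 * log(1.2)^2, tolerance = 1e-14)
  # isochoric deformation: only the mu/2 (I1 - 3) term survives
  m <- material_params("t", E = 10, nu = 0.4)
  Fiso <- diag(c(2, 1 / sqrt(2), 1 / sqrt(2)))
  expect_equal(neo_hookean_energy(Fiso, m),
               m$mu / 2 * (sum(Fiso^2) - 3), tolerance = 1e-12)
  expect_error(neo_hookean_energy(diag(c(-1, 1, 1)), m), "inverted")
})

test_that("PK1 stress is the gradient of the energy and zero at rest", {
  m <- material_params("t", E = 10, nu = 0.3)
  expect_equal(pk1_stress(diag(3), m), matrix(0, 3, 3))
  set.seed(42)
  h <- 1e-6
  for (k in 1:25) {
    F <- random_F()
    P <- pk1_stress(F, m)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      fd <- (neo_hookean_energy(Fp, m) - neo_hookean_energy(Fm, m)) / (2 * h)
      expect_equal(P[i, j], fd, tolerance = 1e-6)
    }
  }
  # uniaxial-strain closed form P11 = mu J - mu/J + lam log(J)/J
  J <- 0.8
  P <- pk1_stress(diag(c(J, 1, 1)), m)
  expect_equal(P[1, 1], m$mu * J - m$mu / J + m$lam * log(J) / J,
               tolerance = 1e-12)
})

test_that("Cauchy push-forward is symmetric and rigid motion is stress-free", {
  m <- material_params("t", E = 4, nu = 0.35)
  set.seed(7)
  R <- random_rotation()
  sig <- cauchy_from_pk1(pk1_stress(R, m), R)
  expect_lt(max(abs(sig)), 1e-10)
  F <- random_F()
  sig <- cauchy_from_pk1(pk1_stress(F, m), F)
  expect_lt(max(abs(sig - t(sig))), 1e-10 * max(1, max(abs(sig))))
  # uniaxial strain: axial Cauchy equals axial PK1 (area unchanged)
  F <- diag(c(0.9, 1, 1))
  P <- pk1_stress(F, m)
  expect_equal(cauchy_from_pk1(P, F)[1, 1], P[1, 1], tolerance = 1e-12)
})

test_that("energy is objective under superposed rotations", {
  m <- material_params("t", E = 3, nu = 0.45)
  set.seed(11)
  for (k in 1:20) {
    F <- random_F()
    R <- random_rotation()
    expect_equal(neo_hookean_energy(R %*% F, m), neo_hookean_energy(F, m),
                 tolerance = 1e-10)
  }
})

test_that("small strains recover the linear isotropic stress law", {
  m <- material_params("t", E = 8, nu = 0.3)
  set.seed(3)
  H <- matrix(stats::runif(9, -1, 1), 3)
  err <- vapply(c(1e-3, 1e-4, 1e-5), function(eps) {
    F <- diag(3) + eps * H
    sig <- cauchy_from_pk1(pk1_stress(F, m), F)
    es <- eps * (H + t(H)) / 2
    lin <- m$lam * sum(diag(es)) * diag(3) + 2 * m$mu * es
    max(abs(sig - lin)) / max(abs(lin))
  }, numeric(1))
  expect_lt(err[2], err[1] / 5)   # first-order convergence in eps
  expect_lt(err[3], 1e-3)
})

test_that("Prony relaxation has the normalized relaxing form", {
  m <- material_params("t", 2, 0.48,
                       prony = list(gamma = c(0.2, 0.1), tau = c(1, 10)))
  expect_equal(prony_modulus(0, m), 1)
  expect_equal(prony_modulus(1e9, m), 0.7, tolerance = 1e-8)
  m1 <- material_params("t", 2, 0.48,
                        prony = list(gamma = 0.2, tau = 1))
  expect_equal(prony_modulus(1, m1), 1 - 0.2 * (1 - exp(-1)),
               tolerance = 1e-12)
  # monotone non-increasing, bounded in [1 - sum(gamma), 1]
  g <- prony_modulus(seq(0, 50, length.out = 200), m)
  expect_true(all(diff(g) <= 1e-12))
  expect_true(all(g <= 1 + 1e-12 & g >= 0.7 - 1e-12))
  # no Prony terms: quasi-static, g identically one
  m0 <- material_params("t", 2, 0.48)
  expect_equal(prony_modulus(c(0, 5, 100), m0), c(1, 1, 1))
  expect_error(prony_modulus(-1, m), ">= 0")
  expect_error(material_params("t", 2, 0.48,
                               prony = list(gamma = c(0.6, 0.5),
                                            tau = c(1, 2))), "sum")
  expect_error(material_params("t", 2, 0.48,
                               prony = list(gamma = 0.1, tau = -1)),
               "positive")
})

test_that("stiffness reduction rescales E and spares linear layers", {
  m <- material_params("dermis", 35, 0.48)
  r <- reduce_stiffness(m, 0.2)
  expect_equal(r$E, 28)
  expect_equal(r$nu, 0.48)
  expect_equal(r$mu, lame_from_moduli(28, 0.48)[["mu"]])
  expect_identical(reduce_stiffness(m, 0), m)
  bone <- material_params("bone", 6480, 0.33, is_linear = TRUE)
  expect_error(reduce_stiffness(bone, 0.1), "soft tissues only")
  expect_identical(reduce_stiffness(bone, 0.1, skip_linear = TRUE), bone)
  expect_error(reduce_stiffness(m, 1.2), "fraction")
})
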