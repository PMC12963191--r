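test_that("boundary conditions pin the base, axis and outer wall", {
  mesh <- build_mesh(builtin_model("model1"), "coarse")
  con <- apply_boundary_conditions(mesh)
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  base <- which(abs(z - max(z)) < 1e-9)
  expect_gt(length(base), 0)
  expect_true(all(con$fixed[2 * base]))      # uz fixed on base
  expect_true(all(con$fixed[2 * base - 1])) # ur fixed on base
  axis <- which(abs(r) < 1e-9)
  expect_true(all(con$fixed[2 * axis - 1]))
  expect_false(any(con$fixed[2 * setdiff(axis, base)]))
})

test_that("constrained tangent at rest is positive definite", {
  mesh <- soft_slab(nr = 4, nz = 4)
  con <- apply_boundary_conditions(mesh)
  dat <- tissueload:::precompute_fem(mesh)
  u <- numeric(dat$ndof)
  state <- tissueload:::assemble_state(u, dat, NULL, 0)
  K <- tissueload:::assemble_tangent(u, dat, NULL, 0, state)
  free <- !con$fixed
  Kf <- as.matrix(K[free, free])
  ev <- eigen((Kf + t(Kf)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("reference traction integrates to p * pi * a^2", {
  mesh <- build_mesh(builtin_model("model1"), "coarse")
  load <- apply_load(mesh, load_case(10, "traction_patch"))
  edat <- tissueload:::edge_data(mesh, load)
  fe <- tissueload:::edge_external(matrix(0, nrow(load$edges), 4), edat, 10)
  expect_equal(sum(fe[, 3:4]), 10 * pi * 25, tolerance = 1e-10)
  expect_equal(sum(fe[, 1:2]), 0, tolerance = 1e-10)  # flat: no radial pull
  expect_error(apply_load(mesh, load_case(1), patch_radius = 100),
               "exceeds")
})

test_that("the constant-strain patch test is exact", {
  m <- material_params("t", 10, 0.3)
  mesh <- slab_mesh(8, 4, m, nr = 5, nz = 4, grade_r = 2, grade_z = 1.7)
  con <- boundary_field_constraints(mesh,
                                    function(r, z) c(0.02 * r, -0.01 * z))
  sol <- fem_solve(mesh, NULL, constraints = con)
  exact <- cbind(0.02 * mesh$nodes[, "r"], -0.01 * mesh$nodes[, "z"])
  expect_lt(max(abs(sol$displacement - exact)), 1e-8)
  # recovered strain is uniform: Hencky diag(log(1.02), log(0.99), log(1.02))
  expect_equal(max(sol$fields$eps_eff), min(sol$fields$eps_eff),
               tolerance = 1e-7)
})

test_that("rigid body translation produces zero strain and stress", {
  mesh <- soft_slab(nr = 4, nz = 3)
  con <- boundary_field_constraints(mesh, function(r, z) c(0, 0.3))
  sol <- fem_solve(mesh, NULL, constraints = con)
  expect_lt(max(sol$fields$eps_eff), 1e-9)
  expect_lt(max(abs(sol$fields$J - 1)), 1e-9)
  expect_lt(max(sol$fields$sigma_vm), 1e-7)
})

test_that("confined compression matches the scalar Neo-Hookean oracle", {
  E <- 2; nu <- 0.48; p <- 0.5
  m <- material_params("slab", E, nu)
  mesh <- slab_mesh(10, 5, m, nr = 4, nz = 4)
  sol <- fem_solve(mesh, apply_load(mesh, load_case(p, "traction_patch"),
                                    patch_radius = 10))
  ref <- uniaxial_strain_benchmark(m, p)
  f <- sol$fields
  expect_equal(unique(round(f$J, 9)), round(ref$J, 9))
  expect_equal(max(abs(f$sig_zz + p)), 0, tolerance = 1e-6)
  expect_equal(weighted.mean(f$eps_2, f$volume), log(ref$J),
               tolerance = 5e-3)
  expect_equal(weighted.mean(f$eps_eff, f$volume), ref$eps_eff,
               tolerance = 5e-3)
  expect_equal(weighted.mean(f$sigma_vm, f$volume), ref$sigma_vm,
               tolerance = 5e-3)
  # surface settles by (1 - J) * thickness
  top <- which(mesh$nodes[, "z"] < 1e-9)
  expect_equal(mean(sol$displacement[top, "uz"]), 5 * (1 - ref$J),
               tolerance = 5e-3)
})

test_that("zero load returns the trivial solution in one increment", {
  mesh <- soft_slab(nr = 3, nz = 3)
  sol <- fem_solve(mesh, apply_load(mesh, load_case(0, "traction_patch")))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$increments_used, 1L)
})

test_that("response is linear at vanishing load", {
  mesh <- build_mesh(builtin_model("model1"), "coarse")
  s1 <- fem_solve(mesh, apply_load(mesh, load_case(1e-4, "traction_patch")))
  s2 <- fem_solve(mesh, apply_load(mesh, load_case(2e-4, "traction_patch")))
  ratio <- max(abs(s2$displacement)) / max(abs(s1$displacement))
  expect_equal(ratio, 2, tolerance = 0.02)
})

test_that("reactions balance the applied load", {
  mesh <- build_mesh(builtin_model("model1"), "coarse")
  sol <- fem_solve(mesh, apply_load(mesh, load_case(10, "traction_patch")))
  zi <- seq(2, length(sol$u), by = 2)
  rz <- sum(sol$reaction[zi]); fz <- sum(sol$fext[zi])
  expect_lt(abs(rz + fz), 1e-6 * abs(fz))
})

test_that("the rigid punch face stays flat and carries the full force", {
  case <- model1_10kPa("coarse")
  mesh <- case$mesh; sol <- case$solution
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  punch <- which(abs(z) < 1e-9 & r <= 5 + 1e-9)
  w <- sol$displacement[punch, "uz"]
  expect_lt(diff(range(w)), 1e-10 * max(abs(w)))
  # applied force is p * pi * a^2 and the base reaction balances it
  zi <- seq(2, length(sol$u), by = 2)
  expect_equal(sum(sol$fext[zi]), 10 * pi * 25, tolerance = 1e-9)
  base <- which(abs(z - max(z)) < 1e-9)
  expect_equal(sum(sol$reaction[2 * base]), -10 * pi * 25,
               tolerance = 1e-6)
})

test_that("external work matches stored energy on the elastic path", {
  mesh <- build_mesh(builtin_model("model1"), "coarse")
  settings <- solver_settings(initial_increment = 0.02,
                              max_increment = 0.02)
  sol <- fem_solve(mesh, apply_load(mesh, load_case(5, "traction_patch")),
                   settings = settings)
  expect_equal(sol$external_work, sol$strain_energy, tolerance = 0.01)
  expect_gte(sol$external_work, sol$strain_energy * (1 - 0.01))
})

test_that("non-convergence yields a diagnostic error, not garbage", {
  mesh <- soft_slab(nr = 4, nz = 3)
  settings <- solver_settings(min_increment = 2e-3, newton_max_iter = 8L)
  expect_error(
    fem_solve(mesh, apply_load(mesh, load_case(1e5, "traction_patch"),
                               patch_radius = 5), settings = settings),
    "min_increment")
})

test_that("postprocessed Cauchy stress is consistent with the material law", {
  # homogeneous confined compression: postprocess vs materials-module path
  m <- material_params("slab", 5, 0.4)
  mesh <- slab_mesh(6, 3, m, nr = 3, nz = 3)
  sol <- fem_solve(mesh, apply_load(mesh, load_case(0.8, "traction_patch"),
                                    patch_radius = 6))
  f <- sol$fields
  Fh <- diag(c(1, 1, f$J[1]))   # uniform uniaxial-strain state (z axis 3)
  sig <- cauchy_from_pk1(pk1_stress(Fh, m), Fh)
  expect_equal(f$sig_zz[1], sig[3, 3], tolerance = 1e-6)
  expect_equal(f$sig_rr[1], sig[1, 1], tolerance = 1e-6)
  expect_equal(f$sigma_vm[1], von_mises(sig), tolerance = 1e-6)
})
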