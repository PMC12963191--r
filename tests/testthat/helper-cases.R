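# Shared fixtures: expensive solves are memoised for the whole test run.

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .case_cache))
    assign(key, force(expr), envir = .case_cache)
  get(key, envir = .case_cache)
}

# the comparative sweep used by the exposure/acceptance checks
acceptance_study <- function() cached("study", run_study(
  pressures = c(2, 8, 10), fractions = c(0.1, 0.2),
  resolution = "medium"))

model1_10kPa <- function(resolution = "medium")
  cached(paste0("m1_", resolution),
         solve_case(builtin_model("model1"), 10, resolution))

# a small homogeneous near-incompressible slab for solver checks
soft_slab <- function(nr = 6, nz = 6, E = 2, nu = 0.48, radius = 10,
                      thickness = 5)
  slab_mesh(radius, thickness, material_params("slab", E, nu),
            nr = nr, nz = nz)

random_F <- function(jlim = c(0.5, 2)) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.3, 0.3), 3)
    if (det(F) >= jlim[1] && det(F) <= jlim[2]) return(F)
  }
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

study_total <- function(study, model, pressure, sf, quantity) {
  r <- study$report
  hit <- r$model == model & abs(r$pressure_kPa - pressure) < 1e-9 &
    abs(r$stiffness_factor - sf) < 1e-9 & r$tissue == "total" &
    r$quantity == quantity
  r$exposure_volume_pct[hit][1]
}

study_layer <- function(study, model, pressure, sf, tissue, quantity) {
  r <- study$report
  hit <- r$model == model & abs(r$pressure_kPa - pressure) < 1e-9 &
    abs(r$stiffness_factor - sf) < 1e-9 & r$tissue == tissue &
    r$quantity == quantity
  r$exposure_volume_pct[hit][1]
}
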