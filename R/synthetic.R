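# Analytic solver benchmarks (closed-form / scalar root-finding oracles,
# independent of the FEM implementation) and seeded synthetic field
# ensembles for exercising the exposure pipeline without the solver.

#' Confined-compression (uniaxial strain) Neo-Hookean benchmark
#'
#' Closed-form reference for a homogeneous slab compressed by pressure `p`
#' with fully constrained lateral motion: the deformation is
#' `F = diag(1, 1, J)` along the loading axis, and `J` solves the scalar
#' equation `P(J) = mu J - mu / J + lambda log(J) / J = -p` (bracketed
#' root-finding - no finite elements involved). Returns the full Cauchy
#' stress and Hencky strain tensors with the loading direction as axis 1.
#'
#' @param material A [material_params()] object.
#' @param pressure Compressive pressure (kPa), `>= 0`.
#' @return List with `J`, `sigma` (3x3 Cauchy, axis 1 = loading), `eps`
#'   (3x3 Hencky), `sigma_vm`, `eps_eff`, and `surface_displacement_factor`
#'   (`1 - J`, the fraction of slab thickness lost).
#' @export
uniaxial_strain_benchmark <- function(material, pressure) {
  stopifnot(inherits(material, "material_params"), pressure >= 0)
  mu <- material$mu; lam <- material$lam
  P11 <- function(J) mu * J - mu / J + lam * log(J) / J
  if (pressure == 0) {
    J <- 1
  } else {
    lo <- 1e-6
    if (P11(lo) + pressure > 0)
      stop("no bracket: pressure exceeds the material stability limit")
    J <- stats::uniroot(function(J) P11(J) + pressure, c(lo, 1),
                        tol = 1e-14)$root
  }
  sig_lat <- lam * log(J) / J
  sigma <- diag(c(-pressure, sig_lat, sig_lat))
  eps <- diag(c(log(J), 0, 0))
  list(J = J, sigma = sigma, eps = eps,
       sigma_vm = abs(-pressure - sig_lat),
       eps_eff = 2 / 3 * abs(log(J)),
       surface_displacement_factor = 1 - J)
}

#' Uniform circular pressure on an elastic half-space
#'
#' Linear-elasticity reference for the centre surface settlement under a
#' uniform pressure `p` on a circle of radius `a`:
#' `w0 = 2 p a (1 - nu^2) / E`. Valid for small loads; used to check the
#' solver on a deep homogeneous domain within a finite-domain tolerance.
#'
#' @param E Young's modulus (kPa).
#' @param nu Poisson ratio.
#' @param p Pressure (kPa).
#' @param a Load radius (mm).
#' @return Centre surface displacement `w0` (mm).
#' @export
#' @examples
#' circular_load_halfspace_benchmark(100, 0.3, 1, 5)  # 0.091 mm
circular_load_halfspace_benchmark <- function(E, nu, p, a) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, a > 0)
  2 * p * a * (1 - nu^2) / E
}

#' Specification for a synthetic element-field ensemble
#'
#' Declares, per layer, the sampling distribution of the stress and strain
#' fields plus the layer's volume budget and element count. Distributions
#' default to lognormal (positive and right-skewed, like indentation
#' stress fields); `"uniform"` and `"gamma"` are available. Parameters:
#' lognormal `(meanlog, sdlog)`, uniform `(min, max)`, gamma
#' `(shape, rate)`.
#'
#' @param layers Named list; each entry a list with elements `stress` and
#'   `strain` (each `list(dist =, p1 =, p2 =)`), `volume` (total layer
#'   volume, mm^3) and `n` (element count).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(layers, seed = 1L) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    if (is.null(ly$volume) || ly$volume <= 0)
      stop("layer '", nm, "': positive volume required")
    if (is.null(ly$n) || ly$n < 1)
      stop("layer '", nm, "': element count n >= 1 required")
    for (qt in c("stress", "strain")) {
      d <- ly[[qt]]
      if (is.null(d$dist) ||
          !d$dist %in% c("lognormal", "uniform", "gamma"))
        stop("layer '", nm, "' ", qt,
             ": dist must be lognormal, uniform or gamma")
      if (d$dist == "uniform" && d$p2 <= d$p1)
        stop("layer '", nm, "' ", qt, ": uniform needs p2 > p1")
      if (d$dist == "gamma" && (d$p1 <= 0 || d$p2 <= 0))
        stop("layer '", nm, "' ", qt, ": gamma needs positive parameters")
      if (d$dist == "lognormal" && d$p2 < 0)
        stop("layer '", nm, "' ", qt, ": sdlog must be >= 0")
    }
  }
  structure(list(layers = layers, seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

draw_dist <- function(d, n) {
  switch(d$dist,
         lognormal = stats::rlnorm(n, d$p1, d$p2),
         uniform = stats::runif(n, d$p1, d$p2),
         gamma = stats::rgamma(n, shape = d$p1, rate = d$p2))
}

#' Generate a synthetic element-field ensemble
#'
#' Draws per-element stress and strain values from the per-layer
#' distributions declared in `spec`, with equal element volumes summing
#' to each layer's budget. Output uses the same schema as [solution_to_samples()], so the
#' exposure pipeline is exercised end to end without running the solver.
#'
#' @param spec A [synthetic_field_spec()].
#' @return Per-element sample data.frame (`element_id`, `layer`, `r`, `z`,
#'   `volume`, `sigma_vm`, `eps_eff`, `roi`; positions are placeholders
#'   and `roi` is `TRUE`).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(old())
  out <- lapply(names(spec$layers), function(nm) {
    ly <- spec$layers[[nm]]
    n <- as.integer(ly$n)
    data.frame(element_id = seq_len(n), layer = nm,
               r = NA_real_, z = NA_real_,
               volume = rep(ly$volume / n, n),
               sigma_vm = draw_dist(ly$stress, n),
               eps_eff = draw_dist(ly$strain, n),
               roi = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$element_id <- seq_len(nrow(res))
  res
}

# Save/restore the RNG state so seeded generators do not disturb callers.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() rm(".Random.seed", envir = globalenv())
  }
}

#' Two-cohort synthetic fixture with a designed deep-layer strain shift
#'
#' Emulates the anatomical-contrast study design on synthetic fields:
#' cohort B equals cohort A except that the strain values in the deep
#' layers (adipose, muscle) are multiplied by `effect`. Thresholds derived
#' from cohort A then have analytically computable exceedance on cohort B
#' (for the lognormal default, a closed-form tail), giving the pipeline an
#' end-to-end oracle.
#'
#' @param effect Multiplicative deep-layer strain shift, `> 0`.
#' @param seed Integer seed.
#' @param n Elements per layer.
#' @return List with `A` and `B` (sample data.frames) and `spec`.
#' @export
two_cohort_fixture <- function(effect = 1.3, seed = 1L, n = 2000L) {
  stopifnot(effect > 0)
  base <- list(
    epidermis = list(stress = list(dist = "lognormal", p1 = log(80), p2 = 0.5),
                     strain = list(dist = "lognormal", p1 = log(0.05), p2 = 0.4),
                     volume = 70, n = n),
    dermis = list(stress = list(dist = "lognormal", p1 = log(2), p2 = 0.5),
                  strain = list(dist = "lognormal", p1 = log(0.06), p2 = 0.4),
                  volume = 1000, n = n),
    adipose = list(stress = list(dist = "lognormal", p1 = log(0.4), p2 = 0.5),
                   strain = list(dist = "lognormal", p1 = log(0.2), p2 = 0.4),
                   volume = 3000, n = n),
    muscle = list(stress = list(dist = "lognormal", p1 = log(0.5), p2 = 0.5),
                  strain = list(dist = "lognormal", p1 = log(0.25), p2 = 0.4),
                  volume = 4500, n = n))
  specA <- synthetic_field_spec(base, seed = seed)
  specB <- synthetic_field_spec(base, seed = seed + 1L)
  A <- generate_field(specA)
  B <- generate_field(specB)
  deep <- B$layer %in% c("adipose", "muscle")
  B$eps_eff[deep] <- B$eps_eff[deep] * effect
  list(A = A, B = B, spec = specA, effect = effect)
}
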