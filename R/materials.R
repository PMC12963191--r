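#' Construct material parameters for a tissue layer
#'
#' Bundles the isotropic elastic constants of one tissue (Young's modulus and
#' Poisson ratio, with the derived Lame parameters) together with optional
#' Prony-series relaxation terms. Soft tissues are modelled as near
#' incompressible Neo-Hookean solids; bone and the loading sensor are treated
#' as homogeneous linear-elastic isotropic materials (`is_linear = TRUE`),
#' which at their negligibly small strains coincides with the Neo-Hookean law
#' used by the solver.
#'
#' @param name Tissue label (e.g. `"dermis"`).
#' @param E Young's modulus in kPa, `> 0`.
#' @param nu Poisson ratio, in `[0, 0.5)`. The incompressible limit
#'   `nu = 0.5` is rejected: it requires a fully mixed formulation, not a
#'   material-constant change.
#' @param prony Optional list with numeric vectors `gamma` and `tau` (equal
#'   length): dimensionless relaxation weights (`sum(gamma) < 1`) and positive
#'   time constants. Empty by default (quasi-static analysis, `g(t)` is 1).
#' @param is_linear Flag marking layers reported as linear elastic.
#'
#' @return An object of class `material_params` with fields `name`, `E`, `nu`,
#'   `lam`, `mu`, `prony`, `is_linear`.
#' @seealso [lame_from_moduli()], [reduce_stiffness()], [prony_modulus()]
#' @export
#' @examples
#' material_params("dermis", E = 35, nu = 0.48)
material_params <- function(name, E, nu, prony = list(), is_linear = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("Young's modulus E must be a positive number (kPa)")
  lm <- lame_from_moduli(E, nu)
  prony <- validate_prony(prony)
  structure(
    list(name = name, E = E, nu = nu, lam = lm[["lam"]], mu = lm[["mu"]],
         prony = prony, is_linear = isTRUE(is_linear)),
    class = "material_params")
}

validate_prony <- function(prony) {
  if (length(prony) == 0L) return(list(gamma = numeric(0), tau = numeric(0)))
  if (!is.list(prony) || is.null(prony$gamma) || is.null(prony$tau))
    stop("prony must be a list with numeric vectors 'gamma' and 'tau'")
  gamma <- as.numeric(prony$gamma); tau <- as.numeric(prony$tau)
  if (length(gamma) != length(tau))
    stop("prony$gamma and prony$tau must have equal length")
  if (any(gamma < 0) || sum(gamma) >= 1)
    stop("prony weights must be nonnegative with sum(gamma) < 1")
  if (any(tau <= 0)) stop("prony time constants tau must be positive")
  list(gamma = gamma, tau = tau)
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material> %s: E = %g kPa, nu = %g (mu = %.4g, lam = %.4g)%s\n",
              x$name, x$E, x$nu, x$mu, x$lam,
              if (x$is_linear) " [linear]" else ""))
  if (length(x$prony$gamma))
    cat(sprintf("  prony: gamma = (%s), tau = (%s)\n",
                toString(x$prony$gamma), toString(x$prony$tau)))
  invisible(x)
}

#' Lame parameters from engineering moduli
#'
#' Standard isotropic conversion `lambda = E nu / ((1 + nu)(1 - 2 nu))`,
#' `mu = E / (2 (1 + nu))`.
#'
#' @param E Young's modulus (kPa), `> 0`.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return Named numeric vector with components `lam` and `mu` (kPa).
#' @export
#' @examples
#' lame_from_moduli(1500, 0.48)
lame_from_moduli <- function(E, nu) {
  if (!is.numeric(E) || !is.finite(E) || E <= 0) stop("E must be > 0")
  if (!is.numeric(nu) || !is.finite(nu) || nu < 0)
    stop("nu must be in [0, 0.5)")
  if (nu >= 0.5)
    stop("nu >= 0.5: incompressible limit requires a mixed formulation, ",
         "not a material-constant conversion")
  c(lam = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Engineering moduli from Lame parameters
#'
#' Inverse of [lame_from_moduli()].
#' @param lam,mu Lame parameters (kPa), `mu > 0`, `lam >= 0`.
#' @return Named numeric vector with components `E` and `nu`.
#' @export
moduli_from_lame <- function(lam, mu) {
  stopifnot(mu > 0, lam >= 0)
  nu <- lam / (2 * (lam + mu))
  c(E = mu * (3 * lam + 2 * mu) / (lam + mu), nu = nu)
}

deformation_invariants <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("inverted element: det(F) <= 0")
  list(F = F, I1 = sum(F * F), J = J)
}

#' Neo-Hookean strain energy density
#'
#' Compressible Neo-Hookean energy
#' `W = mu/2 (I1 - 3) - mu log J + lambda/2 (log J)^2`,
#' where `I1 = tr(F'F)` is the first invariant of the right Cauchy-Green
#' tensor and `J = det F`. Zero at the undeformed state, and reducing to
#' `mu/2 (I1 - 3)` for isochoric deformations.
#'
#' @param F Deformation gradient, 3x3 matrix with `det(F) > 0`.
#' @param m A [material_params()] object (fields `mu`, `lam` are used).
#' @return Energy density in kPa.
#' @export
#' @examples
#' m <- material_params("adipose", E = 2, nu = 0.48)
#' neo_hookean_energy(diag(3), m)  # 0 in the reference state
neo_hookean_energy <- function(F, m) {
  st <- deformation_invariants(F)
  lj <- log(st$J)
  m$mu / 2 * (st$I1 - 3) - m$mu * lj + m$lam / 2 * lj^2
}

#' First Piola-Kirchhoff stress of the Neo-Hookean law
#'
#' Analytic gradient of [neo_hookean_energy()] with respect to `F`:
#' `P = mu F - mu F^-T + lambda (log J) F^-T`. Exactly zero at the identity.
#'
#' @inheritParams neo_hookean_energy
#' @return 3x3 first Piola-Kirchhoff stress tensor (kPa).
#' @export
pk1_stress <- function(F, m) {
  st <- deformation_invariants(F)
  FinvT <- t(solve(st$F))
  m$mu * st$F + (m$lam * log(st$J) - m$mu) * FinvT
}

#' Cauchy stress from first Piola-Kirchhoff stress
#'
#' Push-forward `sigma = (1/J) P F'`. The result is symmetric for any stress
#' derived from an isotropic energy.
#'
#' @param P 3x3 first Piola-Kirchhoff tensor (kPa).
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @return 3x3 Cauchy stress tensor (kPa), symmetrized to machine precision.
#' @export
cauchy_from_pk1 <- function(P, F) {
  st <- deformation_invariants(F)
  sig <- P %*% t(st$F) / st$J
  (sig + t(sig)) / 2
}

#' Prony-series relaxation factor
#'
#' Normalized relaxation modulus
#' `g(t) = 1 - sum_i gamma_i (1 - exp(-t / tau_i))`,
#' monotonically non-increasing from `g(0) = 1` to the long-term plateau
#' `1 - sum(gamma)`. With no Prony terms (the quasi-static default) `g` is
#' identically 1, i.e. the instantaneous moduli apply.
#'
#' @param t Nonnegative time(s), same units as the `tau` constants.
#' @param m A [material_params()] object.
#' @return Numeric vector of relaxation factors, in `[1 - sum(gamma), 1]`.
#' @export
#' @examples
#' m <- material_params("muscle", E = 2, nu = 0.48,
#'                      prony = list(gamma = c(0.2, 0.1), tau = c(1, 10)))
#' prony_modulus(c(0, 1, Inf), m)
prony_modulus <- function(t, m) {
  if (any(t < 0)) stop("t must be >= 0")
  g <- m$prony$gamma; tau <- m$prony$tau
  if (!length(g)) return(rep(1, length(t)))
  vapply(t, function(ti) 1 - sum(g * (1 - exp(-ti / tau))), numeric(1))
}

#' Soften a material by a fractional stiffness reduction
#'
#' Scales the Young's modulus by `1 - fraction` (Poisson ratio unchanged,
#' Lame parameters recomputed), modelling age- or disease-related tissue
#' softening. Layers flagged `is_linear` (bone, sensor) are not soft tissue:
#' by default they raise an error; with `skip_linear = TRUE` they are
#' returned unchanged.
#'
#' @param m A [material_params()] object.
#' @param fraction Reduction fraction in `(0, 1)`; e.g. `0.2` for a -20%
#'   stiffness variant. `0` returns the material unchanged.
#' @param skip_linear If `TRUE`, linear-elastic (non-soft) layers are
#'   returned as-is instead of raising an error.
#' @return A new `material_params` object.
#' @export
#' @examples
#' reduce_stiffness(material_params("dermis", 35, 0.48), 0.2)$E  # 28
reduce_stiffness <- function(m, fraction, skip_linear = FALSE) {
  stopifnot(inherits(m, "material_params"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  if (fraction == 0) return(m)
  if (m$is_linear) {
    if (skip_linear) return(m)
    stop("stiffness reduction applies to soft tissues only; '", m$name,
         "' is linear elastic (bone/sensor)")
  }
  material_params(m$name, E = (1 - fraction) * m$E, nu = m$nu,
                  prony = m$prony, is_linear = FALSE)
}
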