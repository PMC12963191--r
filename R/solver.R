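# Nonlinear static axisymmetric finite element solver.
#
# Total-Lagrangian formulation on 4-node quadrilaterals (2x2 Gauss) with a
# mean-dilatation treatment of near-incompressibility: the deviatoric-coupled
# part of the Neo-Hookean energy, mu/2 (I1 - 3), is integrated pointwise
# while the volumetric part, -mu log J + lambda/2 (log J)^2, is evaluated at
# the element's volume-averaged J. This keeps the discrete residual the exact
# gradient of a discrete energy, passes the patch test, and removes the
# volumetric locking of fully integrated low-order elements at nu = 0.48.
# The resulting effective PK1 stress at a Gauss point is
#   P = mu F + pbar J F^-T,   pbar = (lambda log Jbar - mu) / Jbar,
# which reduces to the standard Neo-Hookean stress for homogeneous states.

GAUSS_2x2 <- local({
  s <- 1 / sqrt(3)
  xi <- c(-s, s, s, -s); eta <- c(-s, -s, s, s)
  corner_xi <- c(-1, 1, 1, -1); corner_eta <- c(-1, -1, 1, 1)
  list(
    N = t(vapply(seq_len(4), function(g)
      (1 + xi[g] * corner_xi) * (1 + eta[g] * corner_eta) / 4, numeric(4))),
    dNdxi = t(vapply(seq_len(4), function(g)
      corner_xi * (1 + eta[g] * corner_eta) / 4, numeric(4))),
    dNdeta = t(vapply(seq_len(4), function(g)
      corner_eta * (1 + xi[g] * corner_xi) / 4, numeric(4))))
})

#' Solver settings for adaptive load incrementation
#'
#' Defaults mirror a standard implicit static protocol: the load is scaled
#' by a pseudo-time running from 0 to `total_step`, applied in adaptive
#' increments (initial 0.05, bounds `[1e-6, 1]`, at most 1000 increments).
#' An increment is halved on Newton failure and grown by 1.5x after two
#' consecutive fast-converging increments. "Time" is purely a load-scaling
#' parameter: the default analysis is quasi-static hyperelastic.
#'
#' @param initial_increment,total_step,min_increment,max_increment,max_increments
#'   Incrementation controls (see above).
#' @param newton_tol_residual Relative force-residual tolerance; the
#'   reference is the gross (cancellation-free) nodal force norm, with an
#'   absolute floor so a zero-load problem converges immediately.
#' @param newton_max_iter Maximum Newton iterations per increment.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(initial_increment = 0.05, total_step = 1.0,
                            min_increment = 1e-6, max_increment = 1.0,
                            max_increments = 1000L,
                            newton_tol_residual = 1e-8,
                            newton_max_iter = 25L) {
  stopifnot(min_increment <= initial_increment,
            initial_increment <= max_increment,
            max_increment <= total_step,
            newton_tol_residual > 0, newton_max_iter >= 1)
  structure(list(initial_increment = initial_increment,
                 total_step = total_step, min_increment = min_increment,
                 max_increment = max_increment,
                 max_increments = as.integer(max_increments),
                 newton_tol_residual = newton_tol_residual,
                 newton_max_iter = as.integer(newton_max_iter)),
            class = "solver_settings")
}

#' Standard boundary conditions for the layered indentation problem
#'
#' Fully fixes the basal surface (bottom of the bone, approximating
#' attachment to deeper skeletal structures), constrains the outer lateral
#' boundary against radial displacement (free vertically), and applies the
#' axisymmetry condition (zero radial displacement) on the axis. Layer
#' interfaces are conforming shared-node ("tie") connections by mesh
#' construction.
#'
#' @param mesh A `tissue_mesh`.
#' @return A constraint set: list with `fixed` (logical per dof; dofs are
#'   interleaved `(ur, uz)` per node), `value` (prescribed displacement at
#'   full load, zero here), and `slave_of` (integer per dof, 0 if the dof
#'   is independent; used by the rigid-punch multipoint constraint).
#' @export
apply_boundary_conditions <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  n <- nrow(mesh$nodes)
  fixed <- logical(2L * n); value <- numeric(2L * n)
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  tol <- 1e-9
  on_axis <- abs(r) < tol
  on_outer <- abs(r - max(r)) < tol
  on_base <- abs(z - max(z)) < tol
  fixed[2L * which(on_axis | on_outer) - 1L] <- TRUE   # ur = 0
  fixed[2L * which(on_base) - 1L] <- TRUE
  fixed[2L * which(on_base)] <- TRUE                   # base fully fixed
  if (!any(fixed[seq(2L, 2L * n, by = 2L)]))
    stop("unconstrained rigid-body mode: no vertical dof is fixed")
  list(fixed = fixed, value = value, slave_of = integer(2L * n))
}

#' Build constraints prescribing a displacement field on the whole boundary
#'
#' Used by verification problems (e.g. the constant-strain patch test): all
#' boundary nodes receive Dirichlet values from `field`, scaled with the
#' load factor during incrementation.
#'
#' @param mesh A `tissue_mesh`.
#' @param field Function `(r, z) -> c(ur, uz)` giving the displacement at
#'   full load.
#' @return A constraint set as in [apply_boundary_conditions()].
#' @export
boundary_field_constraints <- function(mesh, field) {
  n <- nrow(mesh$nodes)
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  tol <- 1e-9
  bnd <- abs(r) < tol | abs(r - max(r)) < tol |
    abs(z - min(z)) < tol | abs(z - max(z)) < tol
  fixed <- logical(2L * n); value <- numeric(2L * n)
  for (i in which(bnd)) {
    uv <- field(r[i], z[i])
    fixed[2L * i - 1L] <- TRUE; value[2L * i - 1L] <- uv[1]
    fixed[2L * i] <- TRUE; value[2L * i] <- uv[2]
  }
  list(fixed = fixed, value = value)
}

#' Define the surface traction load
#'
#' Identifies the surface facets of the loaded patch (surface edges with
#' `r <= indenter_radius`) and attaches the pressure. The pressure acts as
#' a follower load: it remains normal to, and is integrated over, the
#' deforming surface, consistent with the large-deformation setting.
#'
#' @param mesh A `tissue_mesh`.
#' @param lc A [load_case()] (or a number, taken as pressure in kPa).
#' @param patch_radius Loaded radius; defaults to the mesh's indenter
#'   radius. Use the domain radius for whole-surface pressure.
#' @return A traction specification: list with `edges` (k x 2 node ids,
#'   ordered by increasing r), `pressure` (kPa), and `patch_radius`.
#' @export
apply_load <- function(mesh, lc, patch_radius = mesh$geometry$indenter_radius) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (is.numeric(lc)) lc <- load_case(lc)
  stopifnot(inherits(lc, "load_case"))
  if (patch_radius > mesh$geometry$domain_radius)
    stop("patch radius exceeds the domain radius")
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  tol <- 1e-9
  surf <- which(abs(z - min(z)) < tol)
  surf <- surf[order(r[surf])]
  keep <- r[surf] <= patch_radius + tol
  ids <- surf[keep]
  if (length(ids) < 2L)
    stop("loaded patch covers no surface facet; refine the mesh")
  edges <- cbind(ids[-length(ids)], ids[-1L])
  list(edges = edges, pressure = lc$pressure, patch_radius = patch_radius,
       point_load = NULL)
}

#' Set up a rigid frictionless punch load
#'
#' Models the loading electrode as a flat rigid frictionless disc: every
#' surface node under the punch shares one vertical degree of freedom
#' (a multipoint constraint tying them to the node on the axis, so the
#' contact face stays flat), radial sliding stays free, and the punch
#' force `p * pi * a^2` - the total force of a uniform pressure `p` over
#' the patch - is applied to the shared dof. This is a force-controlled
#' equivalent of displacing a rigid disc until its reaction equals
#' `p * pi * a^2`.
#'
#' @param mesh A `tissue_mesh`.
#' @param lc A [load_case()] or a pressure in kPa.
#' @param constraints Base constraint set to extend.
#' @return List with elements `load` (a traction specification with a
#'   `point_load` component and no pressure facets) and `constraints` (the
#'   extended constraint set).
#' @export
apply_punch <- function(mesh, lc,
                        constraints = apply_boundary_conditions(mesh)) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (is.numeric(lc)) lc <- load_case(lc, "rigid_punch")
  a <- mesh$geometry$indenter_radius
  r <- mesh$nodes[, "r"]; z <- mesh$nodes[, "z"]
  tol <- 1e-9
  punch_nodes <- which(abs(z - min(z)) < tol & r <= a + tol)
  if (length(punch_nodes) < 2L)
    stop("punch face covers fewer than two surface nodes; refine the mesh")
  master_node <- punch_nodes[which.min(r[punch_nodes])]
  master <- 2L * master_node
  slaves <- setdiff(2L * punch_nodes, master)
  if (any(constraints$fixed[c(master, slaves)]))
    stop("punch face overlaps fixed dofs")
  constraints$slave_of[slaves] <- master
  point_load <- numeric(2L * nrow(mesh$nodes))
  point_load[master] <- lc$pressure * pi * a^2  # downward (+z)
  list(load = list(edges = NULL, pressure = lc$pressure,
                   patch_radius = a, point_load = point_load),
       constraints = constraints)
}

# ---- element-level vectorized kernels ---------------------------------

precompute_fem <- function(mesh) {
  el <- mesh$elems
  m <- nrow(el)
  rmat <- matrix(mesh$nodes[el, "r"], ncol = 4L)
  zmat <- matrix(mesh$nodes[el, "z"], ncol = 4L)
  dr <- rmat[, 2L] - rmat[, 1L]
  dz <- zmat[, 4L] - zmat[, 1L]
  gp <- vector("list", 4L)
  for (g in seq_len(4L)) {
    rg <- as.vector(rmat %*% GAUSS_2x2$N[g, ])
    gp[[g]] <- list(
      N = GAUSS_2x2$N[g, ],
      dNdr = outer(2 / dr, GAUSS_2x2$dNdxi[g, ]),
      dNdz = outer(2 / dz, GAUSS_2x2$dNdeta[g, ]),
      rg = rg,
      wg = 2 * pi * rg * (dr * dz / 4))
  }
  mu <- vapply(mesh$layer, function(l) mesh$materials[[l]]$mu, numeric(1))
  lam <- vapply(mesh$layer, function(l) mesh$materials[[l]]$lam, numeric(1))
  eldof <- cbind(2L * el - 1L, 2L * el)  # cols 1:4 ur, 5:8 uz
  # characteristic nodal force magnitudes (stress scale mu x quadrature
  # weights x shape gradients): the cancellation noise floor of the
  # residual is machine epsilon times this, which bounds the achievable
  # absolute residual at vanishing loads.
  fmag <- matrix(0, m, 8L)
  for (g in seq_len(4L)) {
    q <- gp[[g]]
    contrib <- q$wg * (abs(q$dNdr) + abs(q$dNdz) +
                         outer(1 / q$rg, GAUSS_2x2$N[g, ]))
    fmag[, 1:4] <- fmag[, 1:4] + unname(mu) * contrib
    fmag[, 5:8] <- fmag[, 5:8] + unname(mu) * contrib
  }
  ii <- array(0L, c(m, 8L, 8L)); jj <- array(0L, c(m, 8L, 8L))
  for (a in 1:8) for (b in 1:8) {
    ii[, a, b] <- eldof[, a]; jj[, a, b] <- eldof[, b]
  }
  list(m = m, gp = gp, mu = unname(mu), lam = unname(lam), eldof = eldof,
       ii = as.integer(ii), jj = as.integer(jj),
       fmag = scatter_add(fmag, eldof, 2L * nrow(mesh$nodes)),
       ndof = 2L * nrow(mesh$nodes))
}

# Internal nodal forces (and energy) for all elements at once.
# Ue: m x 8 element displacement matrix. Returns NULL if any J <= 0.
elem_internal <- function(Ue, dat, want_energy = FALSE) {
  m <- dat$m
  Frr <- Frz <- Fzr <- Fzz <- Fth <- Jg <- vector("list", 4L)
  Vbar <- numeric(m); JV <- numeric(m)
  for (g in 1:4) {
    q <- dat$gp[[g]]
    ur <- Ue[, 1:4, drop = FALSE]; uz <- Ue[, 5:8, drop = FALSE]
    Frr[[g]] <- 1 + rowSums(q$dNdr * ur)
    Frz[[g]] <- rowSums(q$dNdz * ur)
    Fzr[[g]] <- rowSums(q$dNdr * uz)
    Fzz[[g]] <- 1 + rowSums(q$dNdz * uz)
    Fth[[g]] <- 1 + as.vector(ur %*% q$N) / q$rg
    J2 <- Frr[[g]] * Fzz[[g]] - Frz[[g]] * Fzr[[g]]
    Jg[[g]] <- Fth[[g]] * J2
    if (any(Jg[[g]] <= 0) || anyNA(Jg[[g]])) return(NULL)
    Vbar <- Vbar + q$wg
    JV <- JV + q$wg * Jg[[g]]
  }
  Jbar <- JV / Vbar
  pbar <- (dat$lam * log(Jbar) - dat$mu) / Jbar
  fe <- matrix(0, m, 8L)
  energy <- if (want_energy)
    Vbar * (-dat$mu * log(Jbar) + dat$lam / 2 * log(Jbar)^2) else NULL
  for (g in 1:4) {
    q <- dat$gp[[g]]
    J2 <- Jg[[g]] / Fth[[g]]
    Prr <- dat$mu * Frr[[g]] + pbar * Fth[[g]] * Fzz[[g]]
    Prz <- dat$mu * Frz[[g]] - pbar * Fth[[g]] * Fzr[[g]]
    Pzr <- dat$mu * Fzr[[g]] - pbar * Fth[[g]] * Frz[[g]]
    Pzz <- dat$mu * Fzz[[g]] + pbar * Fth[[g]] * Frr[[g]]
    Pth <- dat$mu * Fth[[g]] + pbar * J2
    fe[, 1:4] <- fe[, 1:4] + q$wg * (Prr * q$dNdr + Prz * q$dNdz) +
      tcrossprod(q$wg * Pth / q$rg, q$N)
    fe[, 5:8] <- fe[, 5:8] + q$wg * (Pzr * q$dNdr + Pzz * q$dNdz)
    if (want_energy) {
      I1 <- Frr[[g]]^2 + Frz[[g]]^2 + Fzr[[g]]^2 + Fzz[[g]]^2 + Fth[[g]]^2
      energy <- energy + q$wg * dat$mu / 2 * (I1 - 3)
    }
  }
  list(fe = fe, energy = if (want_energy) sum(energy) else NA_real_)
}

# Follower-pressure nodal forces for the loaded surface edges.
# Uedge: k x 4 (ur1, ur2, uz1, uz2); returns k x 4 in the same order.
edge_external <- function(Uedge, edat, p) {
  R1 <- edat$r1 + Uedge[, 1L]; R2 <- edat$r2 + Uedge[, 2L]
  Z1 <- edat$z1 + Uedge[, 3L]; Z2 <- edat$z2 + Uedge[, 4L]
  tr <- (R2 - R1) / 2; tz <- (Z2 - Z1) / 2
  fe <- matrix(0, nrow(Uedge), 4L)
  s <- 1 / sqrt(3)
  for (xi in c(-s, s)) {
    N1 <- (1 - xi) / 2; N2 <- (1 + xi) / 2
    Rg <- N1 * R1 + N2 * R2
    w <- 2 * pi * Rg * p
    fe[, 1L] <- fe[, 1L] + N1 * (-tz) * w
    fe[, 2L] <- fe[, 2L] + N2 * (-tz) * w
    fe[, 3L] <- fe[, 3L] + N1 * tr * w
    fe[, 4L] <- fe[, 4L] + N2 * tr * w
  }
  fe
}

scatter_add <- function(values, index, ndof) {
  out <- numeric(ndof)
  agg <- rowsum(as.vector(values), as.vector(index))
  out[as.integer(rownames(agg))] <- agg
  out
}

assemble_state <- function(u, dat, edat, p, pl = NULL, want_energy = FALSE) {
  Ue <- matrix(u[dat$eldof], ncol = 8L)
  int <- elem_internal(Ue, dat, want_energy)
  if (is.null(int)) return(NULL)
  fint <- scatter_add(int$fe, dat$eldof, dat$ndof)
  gross <- scatter_add(abs(int$fe), dat$eldof, dat$ndof)
  fext <- numeric(dat$ndof)
  if (!is.null(edat) && p != 0) {
    Uedge <- matrix(u[edat$edof], ncol = 4L)
    fed <- edge_external(Uedge, edat, p)
    fext <- scatter_add(fed, edat$edof, dat$ndof)
    gross <- gross + scatter_add(abs(fed), edat$edof, dat$ndof)
  }
  if (!is.null(pl)) {
    fext <- fext + pl
    gross <- gross + abs(pl)
  }
  list(fint = fint, fext = fext, res = fint - fext, gross = gross,
       energy = int$energy, fe0 = int$fe)
}

# Consistent tangent by columnwise finite differences of the vectorized
# element kernels (exact residual, approximate tangent; Newton converges to
# the residual tolerance regardless).
assemble_tangent <- function(u, dat, edat, p, state, h = 1e-7) {
  Ue <- matrix(u[dat$eldof], ncol = 8L)
  Kx <- array(0, c(dat$m, 8L, 8L))
  for (j in 1:8) {
    Up <- Ue; Up[, j] <- Up[, j] + h
    intp <- elem_internal(Up, dat, FALSE)
    if (is.null(intp)) { # backward step near an inversion limit
      Up[, j] <- Ue[, j] - h
      intp <- elem_internal(Up, dat, FALSE)
      if (is.null(intp)) return(NULL)
      Kx[, , j] <- (state$fe0 - intp$fe) / h
    } else Kx[, , j] <- (intp$fe - state$fe0) / h
  }
  K <- Matrix::sparseMatrix(i = dat$ii, j = dat$jj, x = as.vector(Kx),
                            dims = c(dat$ndof, dat$ndof))
  if (!is.null(edat) && p != 0) {
    Uedge <- matrix(u[edat$edof], ncol = 4L)
    fe0 <- edge_external(Uedge, edat, p)
    k <- nrow(Uedge)
    Kxe <- array(0, c(k, 4L, 4L))
    for (j in 1:4) {
      Up <- Uedge; Up[, j] <- Up[, j] + h
      Kxe[, , j] <- (edge_external(Up, edat, p) - fe0) / h
    }
    K <- K - Matrix::sparseMatrix(i = edat$ii, j = edat$jj,
                                  x = as.vector(Kxe),
                                  dims = c(dat$ndof, dat$ndof))
  }
  K
}

edge_data <- function(mesh, load) {
  if (is.null(load) || is.null(load$edges)) return(NULL)
  e <- load$edges
  edof <- cbind(2L * e[, 1L] - 1L, 2L * e[, 2L] - 1L,
                2L * e[, 1L], 2L * e[, 2L])
  k <- nrow(e)
  ii <- array(0L, c(k, 4L, 4L)); jj <- array(0L, c(k, 4L, 4L))
  for (a in 1:4) for (b in 1:4) {
    ii[, a, b] <- edof[, a]; jj[, a, b] <- edof[, b]
  }
  list(r1 = mesh$nodes[e[, 1L], "r"], r2 = mesh$nodes[e[, 2L], "r"],
       z1 = mesh$nodes[e[, 1L], "z"], z2 = mesh$nodes[e[, 2L], "z"],
       edof = edof, ii = as.integer(ii), jj = as.integer(jj))
}

#' Solve the nonlinear static problem
#'
#' Newton iterations within adaptive load increments: the pressure (and any
#' prescribed boundary displacement) is scaled by the load factor, the
#' increment is halved on non-convergence or element inversion and grown
#' 1.5x after two consecutive fast increments, within the bounds of
#' [solver_settings()]. Failure below the minimum increment raises a
#' diagnostic error.
#'
#' @param mesh A `tissue_mesh`.
#' @param load A traction specification from [apply_load()], a
#'   [load_case()], a number (pressure in kPa over the indenter patch), or
#'   `NULL` for a load-free (Dirichlet-driven) problem.
#' @param settings A [solver_settings()] object.
#' @param constraints A constraint set; defaults to
#'   [apply_boundary_conditions()].
#' @param verbose Print per-increment Newton diagnostics.
#' @return A `solution_field`: list with `u` (dof vector), `displacement`
#'   (n x 2, mm), `converged`, `increments_used`, `newton_iters`,
#'   `residual_norm`, `reaction` (nodal reaction forces at constrained
#'   dofs, kPa mm^2), `fext` (final external force vector),
#'   `strain_energy`, `external_work`, and the per-element fields added by
#'   [postprocess_kinematics()].
#' @export
fem_solve <- function(mesh, load = NULL, settings = solver_settings(),
                      constraints = apply_boundary_conditions(mesh),
                      verbose = FALSE, u0 = NULL) {
  stopifnot(inherits(mesh, "tissue_mesh"),
            inherits(settings, "solver_settings"))
  if (is.numeric(load) || inherits(load, "load_case"))
    load <- apply_load(mesh, load)
  dat <- precompute_fem(mesh)
  edat <- edge_data(mesh, load)
  p_full <- if (is.null(load)) 0 else load$pressure
  pl_full <- if (is.null(load)) NULL else load$point_load
  fixed <- constraints$fixed; ubar <- constraints$value
  slave_of <- constraints$slave_of
  if (is.null(slave_of)) slave_of <- integer(dat$ndof)
  if (any(fixed & slave_of > 0L) || any(fixed[slave_of[slave_of > 0L]]))
    stop("a dof cannot be both fixed and part of a multipoint tie")
  rtol <- settings$newton_tol_residual

  # reduction map: independent (free master) dofs -> full dof vector;
  # slaved dofs follow their master, fixed dofs carry prescribed values.
  indep <- which(!fixed & slave_of == 0L)
  col_of <- integer(dat$ndof); col_of[indep] <- seq_along(indep)
  rows <- which(!fixed)
  cols <- ifelse(slave_of[rows] > 0L, col_of[slave_of[rows]], col_of[rows])
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(dat$ndof, length(indep)))
  reduce <- function(v) as.vector(Matrix::crossprod(A, v))
  # absolute residual floor: well above the machine-level cancellation
  # noise of the internal-force sums, far below any physical residual
  atol <- 1e-12 * sqrt(sum(reduce(dat$fmag)^2)) + 1e-300

  u <- numeric(dat$ndof)
  t_now <- 0; dt <- settings$initial_increment
  if (!is.null(u0)) {
    # warm start: begin Newton from a nearby converged state and attempt
    # the full load in one increment; on failure restart from zero.
    stopifnot(length(u0) == dat$ndof)
    u <- u0
    dt <- settings$total_step
  }
  if (p_full == 0 && (is.null(pl_full) || all(pl_full == 0)) &&
      all(ubar[fixed] == 0))
    dt <- settings$total_step  # unloaded problem: trivial single increment
  increments <- 0L; total_iters <- 0L; fast_streak <- 0L
  ext_work <- 0; fext_prev <- numeric(dat$ndof); u_prev <- u
  res_norm <- NA_real_

  while (t_now < settings$total_step - 1e-12) {
    if (increments >= settings$max_increments)
      stop("increment budget exhausted (", settings$max_increments,
           ") at load factor ", signif(t_now / settings$total_step, 4))
    t_try <- min(t_now + dt, settings$total_step)
    lam <- t_try / settings$total_step
    u_try <- u
    u_try[fixed] <- lam * ubar[fixed]
    p_now <- lam * p_full
    pl_now <- if (is.null(pl_full)) NULL else lam * pl_full
    ok <- FALSE; iters <- 0L
    state <- assemble_state(u_try, dat, edat, p_now, pl_now)
    for (it in seq_len(settings$newton_max_iter)) {
      if (is.null(state)) break  # inverted element: cut the increment
      rred <- reduce(state$res)
      rnorm <- sqrt(sum(rred^2))
      refn <- sqrt(sum(reduce(state$gross)^2))
      res_norm <- rnorm
      if (rnorm <= rtol * refn + atol) {
        ok <- TRUE; iters <- it - 1L
        res_norm <- rnorm
        break
      }
      K <- assemble_tangent(u_try, dat, edat, p_now, state)
      if (is.null(K)) break
      Kred <- Matrix::crossprod(A, K %*% A)
      dq <- tryCatch(as.vector(Matrix::solve(Kred, -rred)),
                     error = function(e) NULL)
      if (is.null(dq) || anyNA(dq)) break
      du <- as.vector(A %*% dq)
      # backtracking line search: keep the residual finite and decreasing
      step <- 1; accepted <- NULL
      for (ls in 1:6) {
        cand <- assemble_state(u_try + step * du, dat, edat, p_now, pl_now)
        if (!is.null(cand)) {
          cn <- sqrt(sum(reduce(cand$res)^2))
          if (cn < rnorm || step < 1) { accepted <- cand; break }
        }
        step <- step / 2
      }
      if (is.null(accepted)) { state <- NULL; break }
      u_try <- u_try + step * du
      state <- accepted
      iters <- it
    }
    if (ok) {
      # trapezoidal external work along the load path
      ext_work <- ext_work +
        sum((state$fext + fext_prev) / 2 * (u_try - u_prev))
      fext_prev <- state$fext; u_prev <- u_try
      u <- u_try; t_now <- t_try; increments <- increments + 1L
      total_iters <- total_iters + iters
      if (verbose)
        message(sprintf("increment %d: t = %.4f (dt = %.4g), %d iterations",
                        increments, t_now, dt, iters))
      fast_streak <- if (iters <= 5L) fast_streak + 1L else 0L
      if (fast_streak >= 2L) {
        dt <- min(dt * 1.5, settings$max_increment)
        fast_streak <- 0L
      }
    } else {
      dt <- dt / 2
      if (!is.null(u0) && increments == 0L) {
        # failed warm start: restart cold with standard incrementation
        u <- numeric(dat$ndof); u_prev <- u
        u0 <- NULL
        dt <- settings$initial_increment
        next
      }
      if (verbose)
        message(sprintf("increment rejected at t = %.4f; dt cut to %.4g",
                        t_try, dt))
      if (dt < settings$min_increment)
        stop("no convergence: increment fell below min_increment (",
             settings$min_increment, ") at load factor ",
             signif(t_now / settings$total_step, 4),
             "; last residual ", signif(res_norm, 4))
    }
  }

  final <- assemble_state(u, dat, edat,
                          p_full * t_now / settings$total_step,
                          if (is.null(pl_full)) NULL else
                            pl_full * t_now / settings$total_step,
                          want_energy = TRUE)
  if (increments == 0L) increments <- 1L  # zero-load trivial solve
  constrained <- fixed | slave_of > 0L
  sol <- structure(list(
    u = u,
    displacement = matrix(u, ncol = 2L, byrow = TRUE,
                          dimnames = list(NULL, c("ur", "uz"))),
    converged = TRUE,
    increments_used = increments,
    newton_iters = total_iters,
    residual_norm = sqrt(sum(reduce(final$res)^2)),
    reaction = ifelse(constrained, final$res, 0),
    fext = final$fext,
    strain_energy = final$energy,
    external_work = ext_work,
    pressure = p_full,
    settings = settings), class = "solution_field")
  postprocess_kinematics(mesh, sol)
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(paste0("<solution_field> p = %g kPa: %d increments, ",
                     "%d Newton iterations, max |uz| = %.4g mm\n"),
              x$pressure, x$increments_used, x$newton_iters,
              max(abs(x$displacement[, "uz"]))))
  invisible(x)
}

#' Recover element kinematics and stress from a converged solution
#'
#' Evaluates the deformation gradient at each element centroid from the
#' shape-function gradients, forms the logarithmic (Hencky) strain from the
#' principal stretches of the right Cauchy-Green tensor, and the Cauchy
#' stress `sigma = (mu/J) B + pbar I` consistent with the solver's
#' mean-dilatation volumetric pressure. Scalar von Mises stress and
#' effective strain fields are attached for post-processing.
#'
#' @param mesh A `tissue_mesh`.
#' @param sol A `solution_field` from [fem_solve()].
#' @return `sol` with an added `fields` data.frame (one row per element):
#'   deformation gradient components, `J`, `Jbar`, Cauchy components
#'   (`sig_rr`, `sig_rz`, `sig_zz`, `sig_th`), principal logarithmic
#'   strains, `sigma_vm` and `eps_eff`.
#' @export
postprocess_kinematics <- function(mesh, sol) {
  dat <- precompute_fem(mesh)
  u <- sol$u
  Ue <- matrix(u[dat$eldof], ncol = 8L)
  # centroid shape-function data
  el <- mesh$elems
  rmat <- matrix(mesh$nodes[el, "r"], ncol = 4L)
  dr <- rmat[, 2L] - rmat[, 1L]
  dz <- matrix(mesh$nodes[el, "z"], ncol = 4L)[, 4L] -
    matrix(mesh$nodes[el, "z"], ncol = 4L)[, 1L]
  dNdr <- outer(2 / dr, c(-1, 1, 1, -1) / 4)
  dNdz <- outer(2 / dz, c(-1, -1, 1, 1) / 4)
  Nc <- rep(0.25, 4L)
  rc <- mesh$centroid[, "r"]
  ur <- Ue[, 1:4, drop = FALSE]; uz <- Ue[, 5:8, drop = FALSE]
  Frr <- 1 + rowSums(dNdr * ur)
  Frz <- rowSums(dNdz * ur)
  Fzr <- rowSums(dNdr * uz)
  Fzz <- 1 + rowSums(dNdz * uz)
  Fth <- 1 + as.vector(ur %*% Nc) / rc
  J2 <- Frr * Fzz - Frz * Fzr
  J <- Fth * J2
  if (any(J <= 0)) stop("inverted element in converged state")
  # element-mean J for the volumetric pressure (as in the solver)
  Vbar <- numeric(dat$m); JV <- numeric(dat$m)
  for (g in 1:4) {
    q <- dat$gp[[g]]
    frr <- 1 + rowSums(q$dNdr * ur); frz <- rowSums(q$dNdz * ur)
    fzr <- rowSums(q$dNdr * uz); fzz <- 1 + rowSums(q$dNdz * uz)
    fth <- 1 + as.vector(ur %*% q$N) / q$rg
    Vbar <- Vbar + q$wg
    JV <- JV + q$wg * fth * (frr * fzz - frz * fzr)
  }
  Jbar <- JV / Vbar
  pbar <- (dat$lam * log(Jbar) - dat$mu) / Jbar
  mu <- dat$mu
  Brr <- Frr^2 + Frz^2; Brz <- Frr * Fzr + Frz * Fzz
  Bzz <- Fzr^2 + Fzz^2; Bth <- Fth^2
  sig_rr <- mu / J * Brr + pbar
  sig_rz <- mu / J * Brz
  sig_zz <- mu / J * Bzz + pbar
  sig_th <- mu / J * Bth + pbar
  # principal logarithmic strains from C = F'F (in-plane 2x2 + hoop)
  Crr <- Frr^2 + Fzr^2; Crz <- Frr * Frz + Fzr * Fzz
  Czz <- Frz^2 + Fzz^2
  half_tr <- (Crr + Czz) / 2
  disc <- half_tr^2 - (Crr * Czz - Crz^2)
  if (any(disc < -1e-10)) stop("non-SPD right Cauchy-Green tensor")
  disc <- sqrt(pmax(disc, 0))
  lam1 <- half_tr + disc; lam2 <- pmax(half_tr - disc, 1e-300)
  e1 <- log(lam1) / 2; e2 <- log(lam2) / 2; e3 <- log(Fth)
  em <- (e1 + e2 + e3) / 3
  eps_eff <- sqrt(2 / 3 * ((e1 - em)^2 + (e2 - em)^2 + (e3 - em)^2))
  sm <- (sig_rr + sig_zz + sig_th) / 3
  sigma_vm <- sqrt(1.5 * ((sig_rr - sm)^2 + (sig_zz - sm)^2 +
                          (sig_th - sm)^2 + 2 * sig_rz^2))
  sol$fields <- data.frame(
    element_id = seq_len(dat$m), layer = mesh$layer,
    r = mesh$centroid[, "r"], z = mesh$centroid[, "z"],
    volume = mesh$vol, roi = mesh$roi,
    F_rr = Frr, F_rz = Frz, F_zr = Fzr, F_zz = Fzz, F_th = Fth,
    J = J, Jbar = Jbar,
    sig_rr = sig_rr, sig_rz = sig_rz, sig_zz = sig_zz, sig_th = sig_th,
    eps_1 = e1, eps_2 = e2, eps_3 = e3,
    sigma_vm = sigma_vm, eps_eff = eps_eff,
    stringsAsFactors = FALSE)
  sol
}
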