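# High-level orchestration: solve one case, run the full model x pressure
# x softening sweep, and assemble the exposure report.

#' Solve one anatomical case end to end
#'
#' Builds the mesh, applies boundary conditions and the load (rigid punch
#' by default, matching the rigid loading electrode of the study protocol;
#' or a uniform follower traction patch), solves, and returns the solution
#' with its per-element samples.
#'
#' @param model An [anatomy_model()].
#' @param pressure Load pressure in kPa, or a [load_case()].
#' @param resolution Mesh resolution (`"coarse"`, `"medium"`, `"fine"`).
#' @param settings [solver_settings()].
#' @param verbose Print solver diagnostics.
#' @return List with `mesh`, `solution`, `samples`, and `meta` (model id,
#'   pressure, stiffness factor, resolution, contact mode, increments,
#'   Newton iterations, residual).
#' @export
solve_case <- function(model, pressure, resolution = "medium",
                       settings = solver_settings(), verbose = FALSE) {
  lc <- if (inherits(pressure, "load_case")) pressure else
    load_case(pressure)
  mesh <- build_mesh(model, resolution)
  if (lc$contact_mode == "rigid_punch") {
    ps <- apply_punch(mesh, lc)
    sol <- fem_solve(mesh, ps$load, settings = settings,
                     constraints = ps$constraints, verbose = verbose)
  } else {
    sol <- fem_solve(mesh, apply_load(mesh, lc), settings = settings,
                     verbose = verbose)
  }
  list(mesh = mesh, solution = sol,
       samples = solution_to_samples(mesh, sol),
       meta = list(model_id = model$model_id, pressure_kPa = lc$pressure,
                   stiffness_factor = model$stiffness_factor,
                   resolution = resolution, contact_mode = lc$contact_mode,
                   increments = sol$increments_used,
                   newton_iters = sol$newton_iters,
                   residual_norm = sol$residual_norm))
}

layer_reference_volume <- function(samples, layer, domain_radius,
                                   denominator) {
  disc <- sum(samples$volume[samples$layer == layer])
  if (denominator == "disc") disc
  else disc * (2 * domain_radius)^2 / (pi * domain_radius^2)
}

#' Run the full exposure study
#'
#' The complete comparative sweep: every model is solved at baseline and
#' at each softened variant for every pressure; reference thresholds are
#' the ROI-restricted volume-weighted 75th percentiles of the designated
#' reference model at baseline stiffness; exposures of every case are then
#' scored against those fixed thresholds, per tissue, for both exposure
#' definitions (AUC ratio and volume fraction).
#'
#' Two reporting conventions matter and are documented choices:
#' \itemize{
#'   \item By default all pressures are scored against the thresholds
#'     derived at the highest pressure (`threshold_pressure = "max"`), the
#'     fixed yardstick under which exposure at low loads is negligible and
#'     grows with pressure. `"matched"` scores each pressure against its
#'     own-pressure thresholds instead (each case' exposure then measures
#'     redistribution rather than absolute growth).
#'   \item The volume-fraction denominator is the layer's square-footprint
#'     volume (`(2 R)^2 x thickness`, `denominator = "square"`), treating
#'     the axisymmetric solution as the core of a square domain whose
#'     corner volume is mechanically inert; `"disc"` uses the solved disc
#'     volume.
#' }
#'
#' @param models List of [anatomy_model()]s (baseline stiffness); the
#'   first whose id equals `threshold_model` provides the thresholds.
#' @param pressures Numeric vector of pressures (kPa).
#' @param fractions Stiffness-reduction fractions (e.g. `c(0.1, 0.2)`).
#' @param resolution Mesh resolution for every solve.
#' @param contact_mode `"rigid_punch"` (default) or `"traction_patch"`.
#' @param settings [solver_settings()].
#' @param threshold_model Model id supplying the reference thresholds.
#' @param threshold_pressure `"max"`, `"matched"`, or a number (kPa).
#' @param denominator `"square"` or `"disc"` (see above).
#' @param q Threshold percentile (default 75).
#' @param keep_samples Keep every case's per-element samples in the result.
#' @param verbose Progress messages.
#' @return An `exposure_study` list: `report` (tidy per-layer rows plus
#'   per-case `total` rows), `thresholds`, `summaries` (per-layer means),
#'   `cases` (solver diagnostics, including failures), `trends`
#'   ([check_trends()] output), and optionally `samples`.
#' @export
run_study <- function(models = list(builtin_model("model1"),
                                    builtin_model("model2")),
                      pressures = c(2, 6, 8, 10),
                      fractions = c(0.1, 0.2),
                      resolution = "medium",
                      contact_mode = c("rigid_punch", "traction_patch"),
                      settings = solver_settings(),
                      threshold_model = "model1",
                      threshold_pressure = "max",
                      denominator = c("square", "disc"),
                      q = 75, keep_samples = FALSE, verbose = FALSE) {
  contact_mode <- match.arg(contact_mode)
  denominator <- match.arg(denominator)
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (!threshold_model %in% ids)
    stop("threshold source model '", threshold_model,
         "' is not among the supplied models")
  variants <- list()
  for (m in models) {
    variants[[length(variants) + 1L]] <- m
    for (v in make_variants(m, fractions))
      variants[[length(variants) + 1L]] <- v
  }
  grid <- expand.grid(vi = seq_along(variants), p = pressures)
  cases <- vector("list", nrow(grid))
  samples_store <- vector("list", nrow(grid))
  meta_rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    m <- variants[[grid$vi[k]]]; p <- grid$p[k]
    if (verbose)
      message(sprintf("solving %s (factor %.2f) at %g kPa ...",
                      m$model_id, m$stiffness_factor, p))
    res <- tryCatch(
      solve_case(m, load_case(p, contact_mode), resolution, settings),
      error = function(e) e)
    if (inherits(res, "error")) {
      meta_rows[[k]] <- data.frame(
        model = m$model_id, pressure_kPa = p,
        stiffness_factor = m$stiffness_factor, resolution = resolution,
        contact_mode = contact_mode, increments = NA, newton_iters = NA,
        residual_norm = NA, failed = TRUE,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      cases[[k]] <- res
      samples_store[[k]] <- res$samples
      meta_rows[[k]] <- data.frame(
        model = m$model_id, pressure_kPa = p,
        stiffness_factor = m$stiffness_factor, resolution = resolution,
        contact_mode = contact_mode, increments = res$meta$increments,
        newton_iters = res$meta$newton_iters,
        residual_norm = res$meta$residual_norm, failed = FALSE,
        error = "", stringsAsFactors = FALSE)
    }
  }
  case_meta <- do.call(rbind, meta_rows)

  # thresholds from the reference model at baseline stiffness
  base_idx <- which(vapply(seq_len(nrow(grid)), function(k) {
    m <- variants[[grid$vi[k]]]
    m$model_id == threshold_model && m$stiffness_factor == 1 &&
      !case_meta$failed[k]
  }, logical(1)))
  if (!length(base_idx))
    stop("no successful baseline solves for threshold model '",
         threshold_model, "'")
  base_samples <- stats::setNames(
    lapply(base_idx, function(k) samples_store[[k]]),
    as.character(grid$p[base_idx]))
  thresholds <- reference_thresholds(base_samples, q = q,
                                     provenance = threshold_model)

  thr_pressure_for <- function(p) {
    if (identical(threshold_pressure, "matched")) p
    else if (identical(threshold_pressure, "max")) max(pressures)
    else as.numeric(threshold_pressure)
  }

  report_rows <- list(); summary_rows <- list()
  for (k in seq_len(nrow(grid))) {
    if (case_meta$failed[k]) next
    s <- samples_store[[k]]
    meta <- case_meta[k, ]
    pt <- thr_pressure_for(meta$pressure_kPa)
    R <- cases[[k]]$mesh$geometry$domain_radius
    summary_rows[[length(summary_rows) + 1L]] <-
      layer_summary(s, meta$model, meta$pressure_kPa,
                    meta$stiffness_factor)
    tot <- list(stress = 0, strain = 0)
    band <- strain_benchmark_flags(s[s$layer %in% SOFT_LAYERS, ])
    for (qt in c("stress", "strain")) {
      for (ly in SOFT_LAYERS) {
        sel <- s$layer == ly
        vals <- if (qt == "stress") s$sigma_vm[sel] else s$eps_eff[sel]
        vol <- s$volume[sel]
        th <- lookup_threshold(thresholds, ly, pt, qt)
        ex <- tissue_exposure(vals, vol, th)
        ref_vol <- layer_reference_volume(s, ly, R, denominator)
        vol_pct <- 100 * sum(vol[vals > th]) / ref_vol
        lyband <- strain_benchmark_flags(s[sel, ])
        report_rows[[length(report_rows) + 1L]] <- data.frame(
          model = meta$model, pressure_kPa = meta$pressure_kPa,
          stiffness_factor = meta$stiffness_factor, tissue = ly,
          quantity = qt, threshold = th,
          threshold_pressure_kPa = pt,
          auc_total = ex$auc_total,
          auc_from_threshold = ex$auc_from_threshold,
          exposure_auc_pct = ex$exposure_auc_pct,
          exposure_volume_pct = vol_pct,
          therapeutic_pct = if (qt == "strain")
            lyband[["therapeutic_pct"]] else NA_real_,
          damage_pct = if (qt == "strain")
            lyband[["damage_pct"]] else NA_real_,
          stringsAsFactors = FALSE)
        tot[[qt]] <- tot[[qt]] + vol_pct
      }
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        model = meta$model, pressure_kPa = meta$pressure_kPa,
        stiffness_factor = meta$stiffness_factor, tissue = "total",
        quantity = qt, threshold = NA_real_,
        threshold_pressure_kPa = pt,
        auc_total = NA_real_, auc_from_threshold = NA_real_,
        exposure_auc_pct = NA_real_,
        exposure_volume_pct = tot[[qt]],
        therapeutic_pct = if (qt == "strain")
          band[["therapeutic_pct"]] else NA_real_,
        damage_pct = if (qt == "strain")
          band[["damage_pct"]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- structure(list(
    report = do.call(rbind, report_rows),
    thresholds = thresholds,
    summaries = do.call(rbind, summary_rows),
    cases = case_meta,
    settings = list(resolution = resolution, contact_mode = contact_mode,
                    denominator = denominator,
                    threshold_pressure = threshold_pressure, q = q)),
    class = "exposure_study")
  out$trends <- check_trends(out)
  if (keep_samples) out$samples <- samples_store
  out
}

#' @export
print.exposure_study <- function(x, ...) {
  cat(sprintf("<exposure_study> %d cases (%d failed), %d report rows\n",
              nrow(x$cases), sum(x$cases$failed), nrow(x$report)))
  cat("trend checks:\n")
  print(x$trends, row.names = FALSE)
  invisible(x)
}

total_exposure <- function(report, model, pressure, sf, quantity) {
  hit <- report$model == model &
    abs(report$pressure_kPa - pressure) < 1e-9 &
    abs(report$stiffness_factor - sf) < 1e-9 &
    report$tissue == "total" & report$quantity == quantity
  if (!any(hit)) return(NA_real_)
  report$exposure_volume_pct[hit][1]
}

#' Ordinal trend checks on an exposure study
#'
#' Pass/fail assertions of the headline comparative trends: exposure grows
#' as stiffness falls (baseline to -10% to -20%) at the highest pressure;
#' the thinner-skinned model is at least as exposed as the reference at
#' the upper pressures; exposure at the lowest pressure is small next to
#' the highest.
#'
#' @param study An `exposure_study`.
#' @return Data.frame with columns `check`, `quantity`, `model`, `pass`.
#' @export
check_trends <- function(study) {
  rep <- study$report
  models <- unique(rep$model)
  pmax_ <- max(rep$pressure_kPa); pmin_ <- min(rep$pressure_kPa)
  sfs <- sort(unique(rep$stiffness_factor), decreasing = TRUE)
  rows <- list()
  add <- function(check, quantity, model, pass)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, quantity = quantity, model = model, pass = pass,
      stringsAsFactors = FALSE)
  for (qt in c("stress", "strain")) {
    for (m in models) {
      if (length(sfs) > 1L) {
        tots <- vapply(sfs, function(sf)
          total_exposure(rep, m, pmax_, sf, qt), numeric(1))
        add("exposure increases with softening", qt, m,
            !anyNA(tots) && all(diff(tots) > 0))
      }
      if (pmin_ < pmax_) {
        lo <- total_exposure(rep, m, pmin_, 1, qt)
        hi <- total_exposure(rep, m, pmax_, 1, qt)
        add("low-pressure exposure is small vs peak", qt, m,
            !is.na(lo) && !is.na(hi) && lo < 0.25 * hi)
      }
    }
    if (all(c("model1", "model2") %in% models)) {
      for (p in intersect(c(8, 10), unique(rep$pressure_kPa))) {
        t1 <- total_exposure(rep, "model1", p, 1, qt)
        t2 <- total_exposure(rep, "model2", p, 1, qt)
        add(sprintf("model2 >= model1 at %g kPa", p), qt, "both",
            !is.na(t1) && !is.na(t2) && t2 >= t1)
      }
    }
  }
  do.call(rbind, rows)
}
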