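# Format-stable outputs: per-element CSV tables, VTK legacy unstructured
# grids, JSON threshold tables, and run manifests. All numeric output is
# locale-independent (C locale via write.csv/format defaults) with fixed
# column order and units documented in the headers/docs.

SAMPLES_COLUMNS <- c("element_id", "layer", "r", "z", "volume",
                     "sigma_vm", "eps_eff", "roi")

#' Write per-element field samples to CSV
#'
#' Columns (fixed order): `element_id`, `layer`, `r` (mm), `z` (mm),
#' `volume` (mm^3), `sigma_vm` (kPa), `eps_eff` (dimensionless), `roi`.
#' Both solver output and synthetic fixtures use this schema.
#'
#' @param samples Sample data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  check_samples(samples)
  for (cn in setdiff(SAMPLES_COLUMNS, names(samples)))
    samples[[cn]] <- if (cn == "roi") TRUE else NA
  utils::write.csv(samples[, SAMPLES_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read per-element field samples from CSV
#'
#' @param path CSV path in the [write_samples_csv()] schema.
#' @return Sample data.frame.
#' @export
read_samples_csv <- function(path) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(SAMPLES_COLUMNS, names(s))
  if (length(miss))
    stop("samples file ", path, " lacks column(s): ", toString(miss))
  s$roi <- as.logical(s$roi)
  check_samples(s)
}

#' Export a mesh (and optionally a solution) as legacy-ASCII VTK
#'
#' Writes an unstructured grid of quadrilateral cells with the layer tag
#' and ROI flag as cell data; when a solution is supplied, nodal
#' displacements and the per-element von Mises stress, effective strain
#' and J are included, so fields are viewable in standard visualization
#' tools.
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output `.vtk` file.
#' @param sol Optional `solution_field`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, sol = NULL) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  wl <- function(...) writeLines(..., con = con)
  wl("# vtk DataFile Version 3.0")
  wl("axisymmetric layered tissue model (r z 0 coordinates, mm)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(sprintf("%.9g %.9g 0", mesh$nodes[, "r"], mesh$nodes[, "z"]))
  wl(sprintf("CELLS %d %d", m, 5L * m))
  wl(sprintf("4 %d %d %d %d", mesh$elems[, 1L] - 1L, mesh$elems[, 2L] - 1L,
             mesh$elems[, 3L] - 1L, mesh$elems[, 4L] - 1L))
  wl(sprintf("CELL_TYPES %d", m))
  wl(rep("9", m))  # VTK_QUAD
  if (!is.null(sol)) {
    wl(sprintf("POINT_DATA %d", n))
    wl("VECTORS displacement double")
    wl(sprintf("%.9g %.9g 0", sol$displacement[, "ur"],
               sol$displacement[, "uz"]))
  }
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS layer_id int 1")
  wl("LOOKUP_TABLE default")
  wl(sprintf("%d", as.integer(factor(mesh$layer,
                                     levels = unique(mesh$layer)))))
  wl("SCALARS roi int 1")
  wl("LOOKUP_TABLE default")
  wl(sprintf("%d", as.integer(mesh$roi)))
  if (!is.null(sol) && !is.null(sol$fields)) {
    for (fld in c("sigma_vm", "eps_eff", "J")) {
      wl(sprintf("SCALARS %s double 1", fld))
      wl("LOOKUP_TABLE default")
      wl(sprintf("%.9g", sol$fields[[fld]]))
    }
  }
  invisible(path)
}

#' Export / import a threshold table as JSON
#'
#' @param thresholds An `exposure_thresholds` data.frame.
#' @param path JSON file path.
#' @return `path` (write) or the threshold table (read).
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(as.data.frame(thresholds), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  if (!file.exists(path)) stop("threshold file not found: ", path)
  df <- jsonlite::fromJSON(path)
  need <- c("tissue", "pressure_kPa", "quantity", "threshold")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("threshold file lacks field(s): ", toString(miss))
  structure(df, class = c("exposure_thresholds", "data.frame"))
}

config_hash <- function(object) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(object, tmp, version = 2L)  # stable serialization
  unname(tools::md5sum(tmp))
}

#' Run one case and write its output files
#'
#' Solves a single model/pressure case and writes the standard artifact
#' set into `outdir`: a VTK field file, the per-element sample CSV, a
#' per-layer summary CSV, and a JSON run manifest (configuration hash,
#' package version, seed, resolution, solver diagnostics) so every output
#' file is traceable to one manifest.
#'
#' @param model An [anatomy_model()].
#' @param pressure Pressure in kPa or a [load_case()].
#' @param outdir Output directory (created if missing).
#' @param resolution Mesh resolution.
#' @param settings [solver_settings()].
#' @param seed Seed recorded in the manifest (the static solve itself is
#'   deterministic).
#' @param tag Basename for the output files.
#' @return Invisible list of written paths plus the solved case.
#' @export
run_case <- function(model, pressure, outdir, resolution = "medium",
                     settings = solver_settings(), seed = NULL,
                     tag = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lc <- if (inherits(pressure, "load_case")) pressure else
    load_case(pressure)
  if (is.null(tag))
    tag <- sprintf("%s_p%g_sf%g", model$model_id, lc$pressure,
                   model$stiffness_factor)
  case <- solve_case(model, lc, resolution, settings)
  paths <- list(
    vtk = file.path(outdir, paste0(tag, ".vtk")),
    samples = file.path(outdir, paste0(tag, "_elements.csv")),
    summary = file.path(outdir, paste0(tag, "_layers.csv")),
    manifest = file.path(outdir, paste0(tag, "_manifest.json")))
  write_vtk(case$mesh, paths$vtk, case$solution)
  write_samples_csv(case$samples, paths$samples)
  utils::write.csv(layer_summary(case$samples, model$model_id,
                                 lc$pressure, model$stiffness_factor),
                   paths$summary, row.names = FALSE)
  manifest <- list(
    config_hash = config_hash(list(model = model, pressure = lc$pressure,
                                   contact = lc$contact_mode,
                                   resolution = resolution,
                                   settings = unclass(settings))),
    package_version =
      as.character(utils::packageVersion("tissueload")),
    seed = seed, resolution = resolution,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    case = case$meta)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, list(case = case)))
}

#' Write an exposure study's tables
#'
#' Emits the tidy exposure report and per-layer summaries as CSV, and the
#' threshold table plus a study manifest (with trend-check results) as
#' JSON.
#'
#' @param study An `exposure_study` from [run_study()].
#' @param outdir Output directory.
#' @param seed Seed recorded in the manifest.
#' @return Invisible list of written paths.
#' @export
write_study <- function(study, outdir, seed = NULL) {
  stopifnot(inherits(study, "exposure_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(report = file.path(outdir, "exposure_report.csv"),
                summaries = file.path(outdir, "layer_summaries.csv"),
                thresholds = file.path(outdir, "thresholds.json"),
                manifest = file.path(outdir, "study_manifest.json"))
  utils::write.csv(study$report, paths$report, row.names = FALSE)
  utils::write.csv(study$summaries, paths$summaries, row.names = FALSE)
  write_thresholds_json(study$thresholds, paths$thresholds)
  jsonlite::write_json(
    list(config_hash = config_hash(study$settings),
         package_version =
           as.character(utils::packageVersion("tissueload")),
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         settings = study$settings,
         cases = study$cases,
         trends = study$trends),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
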