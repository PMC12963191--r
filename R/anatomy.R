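SOFT_LAYERS <- c("epidermis", "dermis", "adipose", "muscle")
ALL_LAYERS <- c(SOFT_LAYERS, "bone")

#' Define one tissue layer of the stack
#'
#' @param name Layer name, one of epidermis, dermis, adipose, muscle, bone.
#' @param thickness Layer thickness in mm, `> 0`.
#' @param material A [material_params()] object for the layer.
#' @param target_element_count Optional reference element count (metadata
#'   only; meshes are resolution-controlled, not count-controlled).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(name, thickness, material, target_element_count = NA) {
  name <- match.arg(name, ALL_LAYERS)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("layer '", name, "': thickness must be > 0 (mm)")
  stopifnot(inherits(material, "material_params"))
  structure(list(name = name, thickness = thickness, material = material,
                 target_element_count = target_element_count),
            class = "layer_spec")
}

#' Assemble an anatomical model
#'
#' An ordered surface-to-depth stack of tissue layers over bone, together
#' with the domain, indenter, and region-of-interest (ROI) geometry shared
#' by all load cases. The lateral extent defaults to a 60 mm radius, the
#' axisymmetric equivalent of the half-width of a 120 x 120 mm footprint;
#' the indenter is a 10-mm-diameter circular patch and the ROI a
#' 30-mm-diameter cylinder under it.
#'
#' @param model_id Identifier string (e.g. `"model1"`).
#' @param layers List of [layer_spec()] objects ordered surface to depth;
#'   exactly one bone layer, which must be last.
#' @param domain_half_width Domain radius in mm.
#' @param indenter_radius Loaded-patch radius in mm.
#' @param roi_radius ROI radius in mm, `> indenter_radius`.
#' @param stiffness_factor Multiplicative soft-tissue stiffness scale in
#'   `(0, 1]` (1 = baseline; 0.9 and 0.8 are the softening variants).
#' @return An `anatomy_model` object.
#' @seealso [builtin_model()], [make_variants()], [load_config()]
#' @export
anatomy_model <- function(model_id, layers, domain_half_width = 60,
                          indenter_radius = 5, roi_radius = 15,
                          stiffness_factor = 1) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  if (!length(layers)) stop("at least one layer required")
  if (!all(vapply(layers, inherits, logical(1), "layer_spec")))
    stop("layers must be layer_spec objects")
  nm <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              toString(nm[duplicated(nm)]))
  if (sum(nm == "bone") != 1L || nm[length(nm)] != "bone")
    stop("exactly one bone layer is required, and it must be the deepest")
  if (!(domain_half_width > 0 && indenter_radius > 0 && roi_radius > 0))
    stop("geometry radii must be positive")
  if (roi_radius <= indenter_radius)
    stop("roi_radius must exceed indenter_radius")
  if (roi_radius > domain_half_width)
    stop("roi_radius cannot exceed the domain radius")
  if (!(stiffness_factor > 0 && stiffness_factor <= 1))
    stop("stiffness_factor must be in (0, 1]")
  names(layers) <- nm
  structure(list(model_id = model_id, layers = layers,
                 domain_half_width = domain_half_width,
                 indenter_radius = indenter_radius,
                 roi_radius = roi_radius,
                 stiffness_factor = stiffness_factor),
            class = "anatomy_model")
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("<anatomy_model> %s (stiffness factor %g)\n", x$model_id,
              x$stiffness_factor))
  cat(sprintf("  domain r = %g mm, indenter a = %g mm, ROI r = %g mm\n",
              x$domain_half_width, x$indenter_radius, x$roi_radius))
  for (ly in x$layers)
    cat(sprintf("  %-10s t = %5.2f mm, E = %g kPa, nu = %g\n",
                ly$name, ly$thickness, ly$material$E, ly$material$nu))
  invisible(x)
}

#' Built-in anatomical parameterizations
#'
#' Two documented layer stacks representing distinct adult anatomical
#' profiles of the back region. They share the loading geometry and differ
#' in skin-layer thicknesses and muscle stiffness: `model1` has thicker
#' epidermis/dermis/adipose and stiffer muscle than `model2`, so `model2`
#' transmits more load to depth. Every value can be overridden through a
#' configuration file (see [load_config()]).
#'
#' Defaults (thickness mm / E kPa, Poisson 0.48 for soft tissue):
#' epidermis 0.1 or 0.07 / 1500; dermis 1.5 or 0.8 / 35; adipose 4.4 or
#' 3 / 2; muscle 6.6 / 2 or 1; bone 5 / 6480 (linear elastic, Poisson
#' 0.33). Reference 3-D element counts are carried as metadata only.
#'
#' @param model_id `"model1"` or `"model2"`.
#' @return An [anatomy_model()] at baseline stiffness.
#' @export
#' @examples
#' builtin_model("model1")
builtin_model <- function(model_id = c("model1", "model2")) {
  model_id <- match.arg(model_id)
  p <- if (model_id == "model1") {
    list(epi_t = 0.1, derm_t = 1.5, adip_t = 4.4, musc_E = 2,
         counts = c(40318, 29802, 64423, 98980, 7890))
  } else {
    list(epi_t = 0.07, derm_t = 0.8, adip_t = 3, musc_E = 1,
         counts = c(46901, 20774, 48869, 98980, 37890))
  }
  layers <- list(
    layer_spec("epidermis", p$epi_t,
               material_params("epidermis", 1500, 0.48), p$counts[1]),
    layer_spec("dermis", p$derm_t,
               material_params("dermis", 35, 0.48), p$counts[2]),
    layer_spec("adipose", p$adip_t,
               material_params("adipose", 2, 0.48), p$counts[3]),
    layer_spec("muscle", 6.6,
               material_params("muscle", p$musc_E, 0.48), p$counts[4]),
    layer_spec("bone", 5,
               material_params("bone", 6480, 0.33, is_linear = TRUE),
               p$counts[5]))
  anatomy_model(model_id, layers)
}

#' Generate stiffness-softened model variants
#'
#' Applies [reduce_stiffness()] to every soft-tissue layer (bone untouched)
#' for each reduction fraction, emulating uniform age- or disease-related
#' softening.
#'
#' @param base An [anatomy_model()].
#' @param fractions Numeric vector of reduction fractions in `[0, 1)`,
#'   e.g. `c(0.1, 0.2)`.
#' @return List of `anatomy_model` objects, one per fraction, with
#'   `stiffness_factor` set to `base$stiffness_factor * (1 - fraction)`.
#' @export
make_variants <- function(base, fractions) {
  stopifnot(inherits(base, "anatomy_model"))
  if (!length(fractions)) return(list())
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  lapply(fractions, function(f) {
    layers <- lapply(base$layers, function(ly) {
      layer_spec(ly$name, ly$thickness,
                 reduce_stiffness(ly$material, f, skip_linear = TRUE),
                 ly$target_element_count)
    })
    anatomy_model(base$model_id, layers,
                  domain_half_width = base$domain_half_width,
                  indenter_radius = base$indenter_radius,
                  roi_radius = base$roi_radius,
                  stiffness_factor = base$stiffness_factor * (1 - f))
  })
}

#' Define a load case
#'
#' @param pressure Applied pressure in kPa, `> 0`. The study pressures are
#'   2, 6, 8 and 10 kPa but any positive value is accepted.
#' @param contact_mode Load delivery mode: `"rigid_punch"` (default) models
#'   the loading electrode as a flat rigid frictionless disc pressed with
#'   the total force of the nominal pressure over the patch, matching the
#'   rigid sensor of the study protocol; `"traction_patch"` applies the
#'   nominal pressure directly as a uniform follower traction over the
#'   patch (no indenter stiffness).
#' @return A `load_case` object.
#' @export
load_case <- function(pressure, contact_mode = c("rigid_punch",
                                                 "traction_patch")) {
  contact_mode <- match.arg(contact_mode)
  if (!is.numeric(pressure) || length(pressure) != 1L || pressure < 0)
    stop("pressure must be a nonnegative number (kPa)")
  structure(list(pressure = pressure, contact_mode = contact_mode),
            class = "load_case")
}

# ---- configuration file round trip ------------------------------------

CONFIG_TOP_KEYS <- c("model_id", "layers", "geometry", "loads", "variants",
                     "solver", "seed")
CONFIG_LAYER_KEYS <- c("thickness_mm", "E_kPa", "nu", "prony", "is_linear",
                       "target_element_count")
CONFIG_GEOM_KEYS <- c("domain_half_width_mm", "indenter_radius_mm",
                      "roi_radius_mm")

#' Write a model configuration file
#'
#' Serializes an [anatomy_model()] (plus optional load pressures, softening
#' variants, solver overrides, and a seed) to a flat YAML file that
#' [load_config()] reads back to an identical model.
#'
#' @param model An [anatomy_model()].
#' @param path Output file path.
#' @param pressures_kPa Numeric vector of load pressures.
#' @param stiffness_reductions Numeric vector of softening fractions.
#' @param solver Optional named list of [solver_settings()] overrides.
#' @param seed Optional integer seed recorded in the config.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path, pressures_kPa = c(2, 6, 8, 10),
                         stiffness_reductions = c(0.1, 0.2),
                         solver = list(), seed = NULL) {
  stopifnot(inherits(model, "anatomy_model"))
  layers <- lapply(model$layers, function(ly) {
    out <- list(thickness_mm = ly$thickness, E_kPa = ly$material$E,
                nu = ly$material$nu)
    if (length(ly$material$prony$gamma))
      out$prony <- list(gamma = ly$material$prony$gamma,
                        tau = ly$material$prony$tau)
    if (ly$material$is_linear) out$is_linear <- TRUE
    if (!is.na(ly$target_element_count))
      out$target_element_count <- ly$target_element_count
    out
  })
  cfg <- list(
    model_id = model$model_id,
    layers = layers,
    geometry = list(domain_half_width_mm = model$domain_half_width,
                    indenter_radius_mm = model$indenter_radius,
                    roi_radius_mm = model$roi_radius),
    loads = list(pressures_kPa = as.numeric(pressures_kPa)),
    variants = list(stiffness_reductions = as.numeric(stiffness_reductions)))
  if (length(solver)) cfg$solver <- solver
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_error <- function(path, ...) stop("config ", path, ": ", ...)

#' Read and validate a model configuration file
#'
#' Parses the YAML written by [write_config()] (or hand-edited), validating
#' every field against the type invariants; unknown keys are rejected with
#' the offending field path.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `model` ([anatomy_model()]), `load_cases`
#'   (list of [load_case()]), `stiffness_reductions`, `solver` (named list
#'   of overrides), and `seed` (or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_TOP_KEYS)
  if (length(unknown))
    config_error(path, "unknown top-level key(s): ", toString(unknown))
  if (is.null(cfg$model_id) || is.null(cfg$layers))
    config_error(path, "'model_id' and 'layers' are required")
  missing_layers <- setdiff(ALL_LAYERS, names(cfg$layers))
  if (length(missing_layers))
    config_error(path, "missing layer(s): ", toString(missing_layers))
  unknown <- setdiff(names(cfg$layers), ALL_LAYERS)
  if (length(unknown))
    config_error(path, "unknown layer(s): ", toString(unknown))

  layers <- lapply(ALL_LAYERS, function(nm) {
    ly <- cfg$layers[[nm]]
    unknown <- setdiff(names(ly), CONFIG_LAYER_KEYS)
    if (length(unknown))
      config_error(path, "layers/", nm, ": unknown key(s): ",
                   toString(unknown))
    for (req in c("thickness_mm", "E_kPa", "nu"))
      if (is.null(ly[[req]]) || !is.numeric(ly[[req]]))
        config_error(path, "layers/", nm, "/", req, " missing or non-numeric")
    if (ly$thickness_mm <= 0)
      config_error(path, "layers/", nm, "/thickness_mm must be > 0")
    mat <- tryCatch(
      material_params(nm, ly$E_kPa, ly$nu,
                      prony = if (is.null(ly$prony)) list() else ly$prony,
                      is_linear = isTRUE(ly$is_linear) || nm == "bone"),
      error = function(e) config_error(path, "layers/", nm, ": ",
                                       conditionMessage(e)))
    layer_spec(nm, ly$thickness_mm, mat,
               if (is.null(ly$target_element_count)) NA
               else ly$target_element_count)
  })

  geom <- cfg$geometry
  if (!is.null(geom)) {
    unknown <- setdiff(names(geom), CONFIG_GEOM_KEYS)
    if (length(unknown))
      config_error(path, "geometry: unknown key(s): ", toString(unknown))
  }
  gval <- function(key, default) {
    v <- geom[[key]]
    if (is.null(v)) default
    else if (!is.numeric(v) || v <= 0)
      config_error(path, "geometry/", key, " must be a positive number")
    else v
  }
  model <- anatomy_model(
    cfg$model_id, layers,
    domain_half_width = gval("domain_half_width_mm", 60),
    indenter_radius = gval("indenter_radius_mm", 5),
    roi_radius = gval("roi_radius_mm", 15))

  pressures <- cfg$loads$pressures_kPa
  if (is.null(pressures)) pressures <- c(2, 6, 8, 10)
  if (!is.numeric(pressures) || any(pressures <= 0))
    config_error(path, "loads/pressures_kPa must be positive numbers")
  reductions <- cfg$variants$stiffness_reductions
  if (is.null(reductions)) reductions <- numeric(0)
  if (!is.numeric(reductions) || any(reductions < 0 | reductions >= 1))
    config_error(path, "variants/stiffness_reductions must lie in [0, 1)")

  list(model = model,
       load_cases = lapply(pressures, load_case),
       stiffness_reductions = reductions,
       solver = if (is.null(cfg$solver)) list() else cfg$solver,
       seed = cfg$seed)
}
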