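#' Von Mises equivalent stress
#'
#' `sigma_vm = sqrt(3/2 s:s)` with `s` the deviator of the Cauchy stress:
#' the scalar deviatoric stress intensity used throughout the layer
#' analysis. Zero for purely hydrostatic states; equal to `|sigma|` for
#' uniaxial stress.
#'
#' @param sigma Symmetric 3x3 Cauchy stress tensor (kPa).
#' @return Scalar equivalent stress (kPa).
#' @export
#' @examples
#' von_mises(diag(c(10, 0, 0)))  # 10
von_mises <- function(sigma) {
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == c(3L, 3L)))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  s <- sigma - diag(mean(diag(sigma)), 3L)
  sqrt(3 / 2 * sum(s * s))
}

#' Effective (equivalent) strain
#'
#' `eps_eff = sqrt(2/3 e:e)` with `e` the deviator of the logarithmic
#' strain tensor. The 2/3 normalization makes an incompressible uniaxial
#' stretch `lambda` give `eps_eff = |log(lambda)|`, so the value pairs
#' directly with the strain benchmarks quoted in percent.
#'
#' @param eps Symmetric 3x3 logarithmic strain tensor.
#' @return Scalar equivalent strain (dimensionless).
#' @export
#' @examples
#' effective_strain(diag(c(0.1, -0.05, -0.05)))  # 0.1
effective_strain <- function(eps) {
  eps <- as.matrix(eps)
  stopifnot(all(dim(eps) == c(3L, 3L)))
  if (max(abs(eps - t(eps))) > 1e-8 * max(1, max(abs(eps))))
    stop("eps must be symmetric")
  e <- eps - diag(mean(diag(eps)), 3L)
  sqrt(2 / 3 * sum(e * e))
}

#' Per-element field samples from a converged solution
#'
#' Flattens a solved case into the tidy per-element table consumed by the
#' exposure pipeline (and written by [write_samples_csv()]): one row per
#' element with its layer, location, volume, von Mises stress and
#' effective strain. Synthetic fields from [generate_field()] use the same
#' schema, so the pipeline cannot distinguish solved from generated input.
#'
#' @param mesh A `tissue_mesh`.
#' @param sol A `solution_field` from [fem_solve()].
#' @return A data.frame with columns `element_id`, `layer`, `r`, `z`,
#'   `volume`, `sigma_vm`, `eps_eff`, `roi`.
#' @export
solution_to_samples <- function(mesh, sol) {
  stopifnot(inherits(sol, "solution_field"), !is.null(sol$fields))
  f <- sol$fields
  data.frame(element_id = f$element_id, layer = f$layer, r = f$r, z = f$z,
             volume = f$volume, sigma_vm = f$sigma_vm, eps_eff = f$eps_eff,
             roi = f$roi, stringsAsFactors = FALSE)
}

check_samples <- function(samples) {
  need <- c("layer", "volume", "sigma_vm", "eps_eff")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples lack column(s): ", toString(miss))
  if (any(samples$volume <= 0)) stop("sample volumes must be positive")
  invisible(samples)
}

#' Volume-weighted layer averages
#'
#' Mean von Mises stress and effective strain of one tissue layer,
#' weighted by element volume, optionally restricted to the region of
#' interest.
#'
#' @param samples Per-element samples ([solution_to_samples()] schema).
#' @param layer Tissue label to average over.
#' @param roi_only If `TRUE` (default) restrict to ROI elements.
#' @return Named numeric vector `c(sigma_vm = , eps_eff = , volume = )`.
#' @export
layer_average <- function(samples, layer, roi_only = TRUE) {
  check_samples(samples)
  sel <- samples$layer == layer
  if (roi_only) {
    if (is.null(samples$roi)) stop("samples lack an 'roi' column")
    sel <- sel & samples$roi
  }
  if (!any(sel)) stop("no samples selected for layer '", layer, "'")
  v <- samples$volume[sel]
  c(sigma_vm = sum(v * samples$sigma_vm[sel]) / sum(v),
    eps_eff = sum(v * samples$eps_eff[sel]) / sum(v),
    volume = sum(v))
}

#' Layer-ratio profile of a field quantity
#'
#' Volume-weighted ROI means per layer divided by the mean of a reference
#' layer - the form in which depth profiles are reported (stress
#' normalized to adipose, strain to epidermis). Peak-based ratios are
#' available via `statistic = "max"` since the reported basis is not
#' uniquely determined.
#'
#' @param samples Per-element samples.
#' @param quantity `"sigma_vm"` or `"eps_eff"`.
#' @param normalize_to Reference layer name.
#' @param layers Layers to report (default the four soft tissues).
#' @param statistic `"mean"` (volume-weighted, default) or `"max"`.
#' @param roi_only Restrict to ROI elements (default `TRUE`).
#' @return Named numeric vector of ratios, 1 for the reference layer.
#' @export
layer_ratio_profile <- function(samples, quantity = c("sigma_vm", "eps_eff"),
                                normalize_to, layers = SOFT_LAYERS,
                                statistic = c("mean", "max"),
                                roi_only = TRUE) {
  quantity <- match.arg(quantity)
  statistic <- match.arg(statistic)
  check_samples(samples)
  if (!normalize_to %in% layers)
    stop("normalize_to must be one of: ", toString(layers))
  vals <- vapply(layers, function(ly) {
    sel <- samples$layer == ly
    if (roi_only) sel <- sel & samples$roi
    if (!any(sel)) stop("layer '", ly, "' absent from selection")
    x <- samples[[quantity]][sel]
    if (statistic == "mean") sum(samples$volume[sel] * x) /
      sum(samples$volume[sel]) else max(x)
  }, numeric(1))
  ref <- vals[[normalize_to]]
  if (ref == 0) stop("zero-valued normalizing layer '", normalize_to, "'")
  vals / ref
}

#' Per-layer summary table of a solved case
#'
#' @param samples Per-element samples.
#' @param model,pressure,stiffness_factor Metadata columns for the output.
#' @return Data.frame with one row per layer: volume-weighted mean and max
#'   of von Mises stress and effective strain inside the ROI.
#' @export
layer_summary <- function(samples, model = NA, pressure = NA,
                          stiffness_factor = NA) {
  check_samples(samples)
  layers <- intersect(c(SOFT_LAYERS, "bone"), unique(samples$layer))
  do.call(rbind, lapply(layers, function(ly) {
    sel <- samples$layer == ly & samples$roi
    if (!any(sel)) sel <- samples$layer == ly
    v <- samples$volume[sel]
    data.frame(model = model, pressure_kPa = pressure,
               stiffness_factor = stiffness_factor, layer = ly,
               roi_volume_mm3 = sum(v),
               mean_sigma_vm = sum(v * samples$sigma_vm[sel]) / sum(v),
               max_sigma_vm = max(samples$sigma_vm[sel]),
               mean_eps_eff = sum(v * samples$eps_eff[sel]) / sum(v),
               max_eps_eff = max(samples$eps_eff[sel]),
               stringsAsFactors = FALSE)
  }))
}
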