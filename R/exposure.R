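# Volume-weighted percentile thresholds, exceedance curves, and the
# AUC / volume-fraction tissue-exposure metrics.

#' Volume-weighted percentile
#'
#' Smallest value at which the cumulative volume fraction reaches `q/100`,
#' with linear interpolation on cumulative volume between order statistics
#' (left-continuous convention, so results are reproducible bit-for-bit).
#' For equal volumes this reduces to the standard sample percentile.
#'
#' @param values Numeric vector.
#' @param volumes Positive weights (element volumes), recycled if scalar.
#' @param q Percentile in (0, 100); the reference thresholds use 75.
#' @return The weighted percentile.
#' @export
#' @examples
#' weighted_percentile(c(1, 2), c(3, 1), 75)  # 1: 75% of volume at <= 1
weighted_percentile <- function(values, volumes = 1, q = 75) {
  if (!length(values)) stop("empty input")
  if (length(volumes) == 1L) volumes <- rep(volumes, length(values))
  stopifnot(length(volumes) == length(values), all(volumes > 0),
            q > 0, q < 100)
  o <- order(values)
  x <- values[o]
  cf <- cumsum(volumes[o]) / sum(volumes)
  k <- which(cf >= q / 100)[1L]
  if (is.na(k)) k <- length(x)       # guard against rounding at the top
  if (k == 1L) return(x[1L])
  x[k - 1L] + (q / 100 - cf[k - 1L]) / (cf[k] - cf[k - 1L]) *
    (x[k] - x[k - 1L])
}

#' Volume-weighted exceedance curve
#'
#' The survival function of a field over a tissue selection:
#' `S(x)` = fraction of selected volume with value `>= x`, represented as
#' an exact step function on the volume-weighted order statistics (no
#' histogram binning), so downstream AUC integration is exact.
#'
#' @param values Numeric field values (nonnegative for AUC use).
#' @param volumes Positive weights, recycled if scalar.
#' @return An `exceedance_curve`: list with `x` (ascending unique values),
#'   `w` (volume fraction at each), `S` (fraction `>=` each x), and
#'   `total_volume`.
#' @export
exceedance_curve <- function(values, volumes = 1) {
  if (!length(values)) stop("empty selection")
  if (length(volumes) == 1L) volumes <- rep(volumes, length(values))
  stopifnot(length(volumes) == length(values), all(volumes > 0))
  agg <- rowsum(volumes, values)          # sorts by unique value
  x <- as.numeric(rownames(agg))
  w <- as.vector(agg) / sum(volumes)
  structure(list(x = x, w = w, S = rev(cumsum(rev(w))),
                 total_volume = sum(volumes)),
            class = "exceedance_curve")
}

#' Evaluate an exceedance curve
#'
#' @param curve An [exceedance_curve()].
#' @param x Magnitudes at which to evaluate `S(x)`.
#' @return Fractions of volume with value `>= x`.
#' @export
exceedance_at <- function(curve, x) {
  stopifnot(inherits(curve, "exceedance_curve"))
  vapply(x, function(xi) sum(curve$w[curve$x >= xi]), numeric(1))
}

#' Area under the exceedance curve
#'
#' Exact integral `int_{from_x}^{Inf} S(x) dx` of the step function, which
#' equals the volume-weighted mean excess `E[(X - from_x)+]`. At
#' `from_x = 0` (and nonnegative values) this is the volume-weighted mean
#' of the field - the identity `E[X] = int_0^Inf S(x) dx`.
#'
#' @param curve An [exceedance_curve()].
#' @param from_x Lower integration bound (the threshold), `>= 0`.
#' @return The area, in the units of the field values.
#' @export
auc <- function(curve, from_x = 0) {
  stopifnot(inherits(curve, "exceedance_curve"), from_x >= 0)
  sum(curve$w * pmax(curve$x - from_x, 0))
}

#' Tissue exposure above a threshold
#'
#' Both quantifications of high-exposure burden used in the study
#' protocol, computed over one tissue selection:
#' \describe{
#'   \item{`exposure_auc_pct`}{the AUC ratio
#'     `100 * AUC(threshold) / AUC(0)` - the percentage of the integrated
#'     exposure burden that lies above the threshold;}
#'   \item{`volume_fraction_above_pct`}{`100 * volume(value > threshold) /
#'     volume(selection)` - the percentage of tissue volume above the
#'     threshold.}
#' }
#' The two are not equivalent; reports carry both side by side.
#'
#' @param values,volumes Field values and element volumes of the selection.
#' @param threshold Threshold in field units, `>= 0`.
#' @return List with `exposure_auc_pct`, `volume_fraction_above_pct`,
#'   `auc_total`, `auc_from_threshold`.
#' @export
tissue_exposure <- function(values, volumes, threshold) {
  curve <- exceedance_curve(values, volumes)
  total <- auc(curve, 0)
  if (total <= 0) stop("zero total AUC: all field values are zero")
  above <- auc(curve, threshold)
  list(exposure_auc_pct = 100 * above / total,
       volume_fraction_above_pct =
         100 * sum(curve$w[curve$x > threshold]),
       auc_total = total,
       auc_from_threshold = above)
}

#' Reference thresholds from the baseline model
#'
#' The 75th-percentile (volume-weighted, ROI-restricted) von Mises stress
#' and effective strain per tissue and pressure from the reference model's
#' baseline-stiffness solutions. These thresholds are held fixed when
#' scoring other models and softened variants, so exposure changes are
#' measured against a common yardstick.
#'
#' @param samples_by_pressure Named list of per-element sample tables
#'   ([solution_to_samples()] schema) for the reference model at baseline
#'   stiffness; names are the pressures in kPa.
#' @param layers Tissues to threshold (default the four soft layers).
#' @param q Percentile (default 75).
#' @param provenance Label recorded with the table (reference model id).
#' @return An `exposure_thresholds` data.frame: one row per tissue x
#'   pressure x quantity with the threshold value.
#' @export
reference_thresholds <- function(samples_by_pressure, layers = SOFT_LAYERS,
                                 q = 75, provenance = "model1") {
  if (!length(samples_by_pressure) || is.null(names(samples_by_pressure)))
    stop("samples_by_pressure must be a named list (names = pressure kPa)")
  rows <- list()
  for (pnm in names(samples_by_pressure)) {
    s <- check_samples(samples_by_pressure[[pnm]])
    for (ly in layers) {
      sel <- s$layer == ly & s$roi
      if (!any(sel))
        stop("no ROI samples for layer '", ly, "' at pressure ", pnm)
      for (qt in c("stress", "strain")) {
        v <- if (qt == "stress") s$sigma_vm[sel] else s$eps_eff[sel]
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = ly, pressure_kPa = as.numeric(pnm), quantity = qt,
          threshold = weighted_percentile(v, s$volume[sel], q),
          percentile = q, provenance = provenance,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows),
            class = c("exposure_thresholds", "data.frame"))
}

lookup_threshold <- function(thresholds, tissue, pressure, quantity) {
  hit <- thresholds$tissue == tissue &
    abs(thresholds$pressure_kPa - pressure) < 1e-9 &
    thresholds$quantity == quantity
  if (sum(hit) != 1L)
    stop("no unique threshold for ", tissue, " at ", pressure, " kPa (",
         quantity, "); available pressures: ",
         toString(unique(thresholds$pressure_kPa)))
  thresholds$threshold[hit]
}

#' Strain fractions in the therapeutic and damage bands
#'
#' Volume fractions of a strain field within the band associated with
#' therapeutic efficacy (3-6% effective strain) and above the potential
#' cell-damage level (> 9%).
#'
#' @param samples Per-element samples, or a numeric vector of strains (then
#'   supply `volumes`).
#' @param volumes Element volumes when `samples` is a bare vector.
#' @param therapeutic Band limits (strain, default `c(0.03, 0.06)`).
#' @param damage Damage threshold (strain, default `0.09`).
#' @return Named vector `c(therapeutic_pct =, damage_pct =)`.
#' @export
strain_benchmark_flags <- function(samples, volumes = NULL,
                                   therapeutic = c(0.03, 0.06),
                                   damage = 0.09) {
  if (is.data.frame(samples)) {
    check_samples(samples)
    eps <- samples$eps_eff; volumes <- samples$volume
  } else {
    eps <- samples
    if (is.null(volumes)) volumes <- rep(1, length(eps))
  }
  v <- sum(volumes)
  c(therapeutic_pct = 100 * sum(volumes[eps >= therapeutic[1] &
                                          eps <= therapeutic[2]]) / v,
    damage_pct = 100 * sum(volumes[eps > damage]) / v)
}
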