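# Structured, graded axisymmetric meshes of the layered domain.
# Coordinates: r = 0 on the load axis, z = 0 at the skin surface with z
# increasing downward; lengths in mm. Elements are 4-node quadrilaterals
# (bilinear), node order (r-,z-), (r+,z-), (r+,z+), (r-,z+).

# Sequence from `from` to `to` with n intervals whose widths grow
# geometrically by total factor `ratio` (last/first).
graded_seq <- function(from, to, n, ratio = 1) {
  stopifnot(n >= 1, to > from, ratio > 0)
  if (n == 1L) return(c(from, to))
  g <- ratio^(1 / (n - 1))
  h <- g^(0:(n - 1))
  from + (to - from) * c(0, cumsum(h)) / sum(h)
}

mesh_resolution_table <- function(resolution) {
  switch(resolution,
    coarse = list(nr = c(4L, 5L, 6L),
                  nz = c(epidermis = 3L, dermis = 3L, adipose = 4L,
                         muscle = 4L, bone = 3L)),
    medium = list(nr = c(6L, 7L, 9L),
                  nz = c(epidermis = 3L, dermis = 5L, adipose = 7L,
                         muscle = 7L, bone = 3L)),
    fine   = list(nr = c(10L, 11L, 14L),
                  nz = c(epidermis = 5L, dermis = 8L, adipose = 11L,
                         muscle = 11L, bone = 5L)),
    stop("unknown resolution: ", resolution))
}

# Core structured-grid constructor shared by build_mesh() and slab_mesh().
# r_nodes/z_nodes are the grid lines; z_layer assigns a layer label to each
# z interval (length = length(z_nodes) - 1).
structured_mesh <- function(r_nodes, z_nodes, z_layer, materials, geometry) {
  nrn <- length(r_nodes); nzn <- length(z_nodes)
  if (any(diff(r_nodes) <= 1e-9) || any(diff(z_nodes) <= 1e-9))
    stop("degenerate grid spacing; a layer is too thin for this ",
         "resolution - use a finer setting")
  nodes <- cbind(r = rep(r_nodes, times = nzn),
                 z = rep(z_nodes, each = nrn))
  ir <- rep(seq_len(nrn - 1L), times = nzn - 1L)
  iz <- rep(seq_len(nzn - 1L), each = nrn - 1L)
  n1 <- (iz - 1L) * nrn + ir
  elems <- cbind(n1, n1 + 1L, n1 + nrn + 1L, n1 + nrn)
  layer <- z_layer[iz]
  area <- (r_nodes[ir + 1L] - r_nodes[ir]) * (z_nodes[iz + 1L] - z_nodes[iz])
  rc <- (r_nodes[ir] + r_nodes[ir + 1L]) / 2
  zc <- (z_nodes[iz] + z_nodes[iz + 1L]) / 2
  mesh <- structure(list(
    nodes = nodes, elems = elems, layer = layer,
    centroid = cbind(r = rc, z = zc), area = area,
    vol = 2 * pi * rc * area,
    materials = materials, geometry = geometry,
    r_nodes = r_nodes, z_nodes = z_nodes),
    class = "tissue_mesh")
  mesh$roi <- tryCatch(
    tag_roi(mesh, geometry$roi_radius),
    error = function(e) rep(FALSE, nrow(elems)))
  mesh
}

#' Build a graded axisymmetric mesh of an anatomical model
#'
#' Structured quadrilateral mesh of the layered cylinder, refined toward
#' the load axis and toward the surface (maximum element edge near the axis
#' is at most half the far-field edge). Grid lines are placed exactly at the
#' indenter edge and at the ROI radius, and every layer receives at least
#' three elements through its thickness - including the 0.07 mm epidermis.
#' Resolution levels increase the node budget monotonically.
#'
#' @param model An [anatomy_model()].
#' @param resolution `"coarse"`, `"medium"` (default) or `"fine"`.
#' @return A `tissue_mesh` object with fields `nodes` (n x 2, mm), `elems`
#'   (m x 4 connectivity), `layer` (per-element label), `roi` (per-element
#'   logical), `vol` (per-element volume, mm^3), `area`, `centroid`,
#'   `materials` (per-layer [material_params()]), and `geometry` metadata.
#' @export
#' @examples
#' m <- build_mesh(builtin_model("model1"), "coarse")
#' table(m$layer)
build_mesh <- function(model, resolution = c("medium", "coarse", "fine")) {
  stopifnot(inherits(model, "anatomy_model"))
  resolution <- match.arg(resolution)
  res <- mesh_resolution_table(resolution)
  a <- model$indenter_radius; roi <- model$roi_radius
  R <- model$domain_half_width
  r_nodes <- c(graded_seq(0, a, res$nr[1], 1),
               graded_seq(a, roi, res$nr[2], 2)[-1],
               graded_seq(roi, R, res$nr[3], 6)[-1])
  z_ratio <- c(epidermis = 1, dermis = 1.5, adipose = 2, muscle = 2.5,
               bone = 2)
  z_nodes <- 0; z_layer <- character(0); z0 <- 0
  for (ly in model$layers) {
    n <- res$nz[[ly$name]]
    if (is.null(n)) n <- 3L
    seg <- graded_seq(z0, z0 + ly$thickness, n, z_ratio[[ly$name]])
    z_nodes <- c(z_nodes, seg[-1])
    z_layer <- c(z_layer, rep(ly$name, n))
    z0 <- z0 + ly$thickness
  }
  materials <- lapply(model$layers, `[[`, "material")
  geometry <- list(model_id = model$model_id,
                   stiffness_factor = model$stiffness_factor,
                   domain_radius = R, indenter_radius = a, roi_radius = roi,
                   thickness = vapply(model$layers, `[[`, numeric(1),
                                      "thickness"),
                   resolution = resolution)
  structured_mesh(r_nodes, z_nodes, z_layer, materials, geometry)
}

#' Build a homogeneous single-layer benchmark mesh
#'
#' Cylindrical slab of one material, used by the analytic solver benchmarks
#' (confined compression, half-space loading). Optionally graded toward the
#' axis and the surface.
#'
#' @param radius,thickness Slab dimensions in mm.
#' @param material A [material_params()] object.
#' @param nr,nz Element counts in r and z.
#' @param grade_r,grade_z Total geometric grading ratios (1 = uniform).
#' @param indenter_radius Optional loaded-patch radius; when given, a grid
#'   line is placed exactly at it. Defaults to the full radius (pressure
#'   over the whole surface).
#' @param layer Layer label for the elements (default `"slab"`).
#' @return A `tissue_mesh`.
#' @export
slab_mesh <- function(radius, thickness, material, nr = 8, nz = 8,
                      grade_r = 1, grade_z = 1, indenter_radius = radius,
                      layer = "slab") {
  stopifnot(inherits(material, "material_params"), radius > 0,
            thickness > 0, indenter_radius <= radius)
  if (indenter_radius < radius) {
    n_in <- max(2L, ceiling(nr / 2))
    n_out <- max(2L, nr - n_in)
    r_nodes <- c(graded_seq(0, indenter_radius, n_in, 1),
                 graded_seq(indenter_radius, radius, n_out, grade_r)[-1])
  } else {
    r_nodes <- graded_seq(0, radius, nr, grade_r)
  }
  z_nodes <- graded_seq(0, thickness, nz, grade_z)
  materials <- stats::setNames(list(material), layer)
  geometry <- list(model_id = "slab", stiffness_factor = 1,
                   domain_radius = radius, indenter_radius = indenter_radius,
                   roi_radius = radius,
                   thickness = stats::setNames(thickness, layer),
                   resolution = "custom")
  structured_mesh(r_nodes, z_nodes, rep(layer, nz), materials, geometry)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %s (%s): %d nodes, %d elements, %d layers\n",
              x$geometry$model_id, x$geometry$resolution, nrow(x$nodes),
              nrow(x$elems), length(unique(x$layer))))
  invisible(x)
}

#' Tag the region of interest
#'
#' Marks elements whose centroid lies within `roi_radius` of the load axis
#' and whose layer belongs to `include_layers` (by default every soft-tissue
#' layer present: epidermis, dermis, adipose, muscle - or all layers for
#' benchmark slabs without anatomical labels).
#'
#' @param mesh A `tissue_mesh`.
#' @param roi_radius ROI radius in mm, at most the domain radius.
#' @param include_layers Character vector of layer names to include.
#' @return Logical vector over elements.
#' @export
tag_roi <- function(mesh, roi_radius = mesh$geometry$roi_radius,
                    include_layers = NULL) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (roi_radius > mesh$geometry$domain_radius)
    stop("roi_radius exceeds the domain radius")
  if (is.null(include_layers)) {
    include_layers <- intersect(SOFT_LAYERS, unique(mesh$layer))
    if (!length(include_layers)) include_layers <- unique(mesh$layer)
  }
  mask <- mesh$centroid[, "r"] <= roi_radius & mesh$layer %in% include_layers
  if (!any(mask)) stop("empty ROI: no element centroid within ", roi_radius,
                       " mm in layers ", toString(include_layers))
  mask
}

#' Per-element physical volumes
#'
#' Recomputes element volumes from the geometry: polygon area times
#' `2 pi r_centroid` (exact for the axisymmetric volume integral, since the
#' area centroid satisfies the first-moment identity).
#'
#' @param mesh A `tissue_mesh`.
#' @return Numeric vector of volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  el <- mesh$elems
  r <- matrix(mesh$nodes[el, "r"], ncol = 4L)
  z <- matrix(mesh$nodes[el, "z"], ncol = 4L)
  nxt <- c(2L, 3L, 4L, 1L)
  cross <- r * z[, nxt] - r[, nxt] * z
  area2 <- rowSums(cross)           # signed, twice the area
  if (any(abs(area2) < 1e-12)) stop("degenerate element (zero area)")
  rc <- rowSums((r + r[, nxt]) * cross) / (3 * area2)
  abs(area2) / 2 * 2 * pi * rc
}
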