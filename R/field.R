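#' Magnetic model of blood
#'
#' Parameters that set the susceptibility difference between (partly
#' deoxygenated) blood and tissue, and hence the strength of the vessel-induced
#' off-resonance field. The susceptibility of fully deoxygenated blood at unit
#' hematocrit, `dchi_do_ppm`, defaults to the standard literature value
#' 4 * pi * 0.264 ppm (SI volume susceptibility) and remains user-overridable.
#'
#' @param Y Blood oxygenation fraction in `[0, 1]`.
#' @param Hct Hematocrit fraction (0 < Hct < 1).
#' @param B0 Main field strength, Tesla.
#' @param T2_blood Blood transverse relaxation time, ms.
#' @param dchi_do_ppm Susceptibility of fully deoxygenated blood at unit
#'   hematocrit, ppm.
#' @param gamma Proton gyromagnetic ratio, rad s^-1 T^-1.
#' @return An object of class `blood_model`.
#' @seealso [fb_blood_model()], [bh_blood_model()] for the free-breathing and
#'   breath-hold defaults (Y = 0.6 / 0.75, T2_blood = 32.3 / 53.2 ms).
#' @export
blood_model <- function(Y = 0.6, Hct = 0.4, B0 = 3, T2_blood = 32.3,
                        dchi_do_ppm = DCHI_DO_PPM_DEFAULT,
                        gamma = GAMMA_PROTON) {
  if (Y < 0 || Y > 1) stop("invalid-argument: need 0 <= Y <= 1")
  if (Hct <= 0 || Hct >= 1) stop("invalid-argument: need 0 < Hct < 1")
  if (B0 <= 0) stop("invalid-argument: B0 must be > 0")
  if (T2_blood <= 0) stop("invalid-argument: T2_blood must be > 0")
  structure(list(Y = Y, Hct = Hct, B0 = B0, T2_blood = T2_blood,
                 dchi_do_ppm = dchi_do_ppm, gamma = gamma),
            class = "blood_model")
}

#' @rdname blood_model
#' @param ... Overrides passed on to [blood_model()].
#' @export
fb_blood_model <- function(...) {
  args <- list(...)
  do.call(blood_model, utils::modifyList(list(Y = 0.6, T2_blood = 32.3), args))
}

#' @rdname blood_model
#' @export
bh_blood_model <- function(...) {
  args <- list(...)
  do.call(blood_model, utils::modifyList(list(Y = 0.75, T2_blood = 53.2), args))
}

#' Blood-tissue susceptibility difference
#'
#' `delta_chi = dchi_do * Hct * (1 - Y)`, dimensionless (SI volume
#' susceptibility; the ppm constant is converted internally).
#'
#' @param model A [blood_model()].
#' @return Dimensionless susceptibility difference.
#' @examples
#' delta_chi(blood_model(Y = 0.6, Hct = 0.4)) # ~5.31e-7
#' @export
delta_chi <- function(model) {
  stopifnot(inherits(model, "blood_model"))
  model$dchi_do_ppm * 1e-6 * model$Hct * (1 - model$Y)
}

# gamma * B0 * delta_chi: the rad/s scale every field term is proportional to
field_base <- function(model) model$gamma * model$B0 * delta_chi(model)

#' Off-resonance field of a single cylinder
#'
#' Angular frequency offset (rad/s) induced by one infinite cylinder in a
#' field B0 along +z. Outside the vessel (perpendicular distance rho > R):
#' `d_omega * (R/rho)^2 * sin^2(theta) * cos(2 phi)` with
#' `d_omega = gamma B0 delta_chi / 2`, `theta` the angle between the cylinder
#' axis and B0, and `phi` the azimuth measured from the projection of B0 onto
#' the plane normal to the axis. Inside (rho <= R) the offset is uniform:
#' `gamma B0 delta_chi (3 cos^2 theta - 1) / 6`.
#'
#' @param points 3-vector or n x 3 matrix of coordinates, um.
#' @param axis_point Point on the cylinder axis, um.
#' @param direction Unit axis direction.
#' @param radius Cylinder radius, um.
#' @param model A [blood_model()].
#' @return Numeric vector of angular frequency offsets, rad/s.
#' @export
cylinder_frequency_offset <- function(points, axis_point, direction, radius,
                                      model) {
  stopifnot(inherits(model, "blood_model"))
  points <- as_points(points)
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-12) direction <- direction / nd
  as.numeric(cpp_cylinder_field_single(points, as.numeric(axis_point),
                                       as.numeric(direction), radius,
                                       field_base(model)))
}

#' Precompute the off-resonance field on a lattice
#'
#' Superposes [cylinder_frequency_offset()] over all cylinders of the network
#' and their 27 periodic images onto a cubic lattice covering the voxel
#' (nodes at `i * resolution`, periodic). A per-cylinder distance cutoff can
#' truncate the `1/rho^2` dipole tail for dense networks of thin vessels; the
#' default (`Inf`) performs the full superposition.
#'
#' @param network A `cylinder_network`.
#' @param model A [blood_model()].
#' @param resolution Lattice spacing, um.
#' @param cutoff Per-cylinder perpendicular distance beyond which the
#'   extravascular contribution is dropped, um. `Inf` disables truncation.
#' @param max_nodes Guard on the total node count; larger lattices raise a
#'   resource-limit error instead of exhausting memory.
#' @return An object of class `field_grid` with `values` (3D array, rad/s),
#'   `resolution` (um), `voxel_edge` and `n` (nodes per axis).
#' @export
build_field_grid <- function(network, model, resolution = 0.8, cutoff = Inf,
                             max_nodes = 2.2e7) {
  stopifnot(inherits(network, "cylinder_network"),
            inherits(model, "blood_model"))
  if (resolution <= 0) stop("invalid-argument: resolution must be > 0")
  n <- max(2L, as.integer(round(network$voxel_edge / resolution)))
  if (as.double(n)^3 > max_nodes)
    stop(sprintf(
      "resource-limit: lattice %d^3 exceeds max_nodes = %g; coarsen resolution",
      n, max_nodes))
  vals <- cpp_build_field_grid(network$axis, network$direction,
                               network$radius, network$voxel_edge, n,
                               field_base(model), cutoff)
  dim(vals) <- c(n, n, n)
  structure(list(values = vals, resolution = network$voxel_edge / n,
                 voxel_edge = network$voxel_edge, n = n,
                 origin = c(0, 0, 0), cutoff = cutoff),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d^3 nodes, %.3g um spacing, edge %g um\n",
              x$n, x$resolution, x$voxel_edge))
  cat(sprintf("  field range: [%.3g, %.3g] rad/s\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample the off-resonance field at arbitrary points
#'
#' Grid mode (`source` is a [build_field_grid()] result): trilinear
#' interpolation between the 8 surrounding lattice nodes, periodic across the
#' voxel boundary. Exact mode (`source` is a `cylinder_network`): direct
#' superposition over all cylinders and their 27 periodic images.
#'
#' @param source A `field_grid` or a `cylinder_network`.
#' @param points 3-vector or n x 3 matrix, um (wrapped into the voxel).
#' @param model Required in exact mode: the [blood_model()].
#' @return Numeric vector of angular frequency offsets, rad/s.
#' @export
sample_field <- function(source, points, model = NULL) {
  points <- as_points(points)
  if (inherits(source, "field_grid")) {
    as.numeric(cpp_trilinear(as.numeric(source$values), source$n,
                             source$voxel_edge, points))
  } else if (inherits(source, "cylinder_network")) {
    if (is.null(model)) stop("exact mode needs a blood_model")
    as.numeric(cpp_exact_field(source$axis, source$direction, source$radius,
                               source$voxel_edge, field_base(model), points))
  } else {
    stop("source must be a field_grid or cylinder_network")
  }
}

#' Export a field grid as NIfTI
#'
#' Writes the lattice as a 3D NIfTI volume (rad/s) with the lattice spacing
#' recorded as the voxel dimension, for visualization.
#'
#' @param grid A `field_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "field_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- rep(grid$resolution / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
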