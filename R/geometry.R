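#' Exponentially spaced vessel radii
#'
#' Radii for a calibration sweep, spaced geometrically (constant ratio between
#' consecutive values) so that capillary and macrovascular scales are covered
#' evenly on a log axis. The defaults reproduce the standard sweep of 49 radii
#' between 0.4 and 100 um.
#'
#' @param n Number of radii (>= 2).
#' @param r_min,r_max Smallest and largest radius in um (0 < r_min < r_max).
#' @return Strictly increasing numeric vector of length `n`, starting at
#'   `r_min` and ending at `r_max`.
#' @examples
#' radius_grid(5, 0.4, 100)
#' @export
radius_grid <- function(n = 49, r_min = 0.4, r_max = 100) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("invalid-argument: n must be a single integer >= 2")
  if (r_min <= 0 || r_max <= r_min)
    stop("invalid-argument: need 0 < r_min < r_max")
  r <- exp(seq(log(r_min), log(r_max), length.out = n))
  r[1] <- r_min
  r[n] <- r_max
  r
}

#' Specification of a random cylinder network
#'
#' Describes the virtual vascular voxel: a cubic periodic cell seeded with
#' randomly oriented infinite cylinders of a single radius until a target
#' intravascular (blood) volume fraction is reached.
#'
#' @param radius Vessel radius in um (> 0, < `voxel_edge`).
#' @param voxel_edge Edge of the cubic virtual voxel in um.
#' @param target_fraction Target blood volume fraction (0 <= f < 1).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @param max_cylinders Abort generation if this many cylinders do not reach
#'   the target fraction.
#' @param fraction_tolerance Absolute tolerance on the achieved fraction.
#'   Whole cylinders are added, so overshoot up to one cylinder's marginal
#'   volume is accepted.
#' @param n_test_points Size of the fixed Monte-Carlo point panel used to
#'   track the intravascular fraction during generation.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(radius, voxel_edge = 500, target_fraction = 0.04,
                         seed = 1L, max_cylinders = 200000L,
                         fraction_tolerance = 0.005,
                         n_test_points = 100000L) {
  if (!is.numeric(radius) || radius <= 0)
    stop("invalid-argument: radius must be > 0")
  if (voxel_edge <= 0) stop("invalid-argument: voxel_edge must be > 0")
  if (radius >= voxel_edge)
    stop("invalid-argument: infeasible spec (radius >= voxel_edge)")
  if (target_fraction < 0 || target_fraction >= 1)
    stop("invalid-argument: need 0 <= target_fraction < 1")
  if (fraction_tolerance <= 0)
    stop("invalid-argument: fraction_tolerance must be > 0")
  structure(list(radius = radius, voxel_edge = voxel_edge,
                 target_fraction = target_fraction, seed = as.integer(seed),
                 max_cylinders = as.integer(max_cylinders),
                 fraction_tolerance = fraction_tolerance,
                 n_test_points = as.integer(n_test_points)),
            class = "network_spec")
}

#' Generate a random cylinder network
#'
#' Adds cylinders with axis points uniform in the voxel and directions
#' uniform on the sphere (Marsaglia sampling) until the Monte-Carlo-estimated
#' intravascular fraction crosses the target. The voxel is treated as a
#' periodic unit cell: containment and field queries replicate every cylinder
#' over the 26 neighbouring images, so "infinite" cylinders never deplete the
#' vascular volume near the boundary.
#'
#' @param spec A [network_spec()].
#' @return An object of class `cylinder_network` with elements `axis`
#'   (n x 3 matrix, um), `direction` (n x 3 unit rows), `radius`,
#'   `voxel_edge`, `achieved_fraction`, `target_fraction` and `seed`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  res <- cpp_generate_network(spec$voxel_edge, spec$target_fraction,
                              spec$radius, spec$max_cylinders,
                              spec$n_test_points)
  net <- structure(list(axis = res$axis, direction = res$direction,
                        radius = spec$radius, voxel_edge = spec$voxel_edge,
                        achieved_fraction = res$achieved_fraction,
                        target_fraction = spec$target_fraction,
                        fraction_tolerance = spec$fraction_tolerance,
                        seed = spec$seed),
                   class = "cylinder_network")
  net
}

#' @export
print.cylinder_network <- function(x, ...) {
  cat(sprintf(
    "<cylinder_network> %d cylinders, R = %.3g um, edge = %g um\n",
    nrow(x$axis), x$radius, x$voxel_edge))
  cat(sprintf("  blood volume fraction: %.4f (target %.4f), seed %d\n",
              x$achieved_fraction, x$target_fraction, x$seed))
  invisible(x)
}

#' Intravascular containment test
#'
#' Is a point inside any cylinder of the network? Points are wrapped into the
#' periodic unit cell and tested against all cylinders and their 27 periodic
#' images: a point is intravascular when its perpendicular distance to some
#' cylinder axis is at most that cylinder's radius.
#'
#' @param network A [generate_network()] result.
#' @param points Numeric 3-vector or n x 3 matrix of coordinates in um.
#' @return Logical vector, one entry per point.
#' @export
is_intravascular <- function(network, points) {
  stopifnot(inherits(network, "cylinder_network"))
  points <- as_points(points)
  if (nrow(network$axis) == 0) return(rep(FALSE, nrow(points)))
  as.logical(cpp_point_in_network(network$axis, network$direction,
                                  network$radius, network$voxel_edge, points))
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3) stop("points must be a 3-vector or n x 3 matrix")
    points <- matrix(points, 1, 3)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  points
}

#' Monte-Carlo blood volume fraction of a network
#'
#' Fraction of uniformly sampled voxel points that fall inside a vessel.
#' The standard error is approximately `sqrt(f (1 - f) / n_points)`.
#'
#' @param network A `cylinder_network`.
#' @param n_points Number of uniform sample points.
#' @param seed Seed for the sampling (independent of the generation seed).
#' @return Estimated intravascular volume fraction in `[0, 1]`.
#' @export
estimate_volume_fraction <- function(network, n_points = 100000L, seed = 1L) {
  stopifnot(inherits(network, "cylinder_network"), n_points >= 1)
  if (nrow(network$axis) == 0) return(0)
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n_points, 0, network$voxel_edge),
                ncol = 3)
  mean(is_intravascular(network, pts))
}

#' Serialize a cylinder network to JSON
#'
#' @param network A `cylinder_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "cylinder_network"))
  obj <- list(
    radius_um = network$radius,
    voxel_edge_um = network$voxel_edge,
    target_fraction = network$target_fraction,
    achieved_fraction = network$achieved_fraction,
    seed = network$seed,
    axis_um = network$axis,
    direction = network$direction
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cylinder network from JSON
#'
#' @param path File written by [write_network_json()].
#' @return A `cylinder_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  axis <- matrix(as.numeric(obj$axis_um), ncol = 3)
  dir <- matrix(as.numeric(obj$direction), ncol = 3)
  structure(list(axis = axis, direction = dir, radius = obj$radius_um,
                 voxel_edge = obj$voxel_edge_um,
                 achieved_fraction = obj$achieved_fraction,
                 target_fraction = obj$target_fraction,
                 fraction_tolerance = obj$fraction_tolerance %||% 0.005,
                 seed = as.integer(obj$seed)),
            class = "cylinder_network")
}
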