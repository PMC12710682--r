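# Build a cylinder_network directly from known geometry (no RNG)
manual_network <- function(axis, direction, radius, edge, fraction = NA_real_) {
  if (!is.matrix(axis)) axis <- matrix(axis, ncol = 3, byrow = TRUE)
  if (!is.matrix(direction)) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  direction <- direction / sqrt(rowSums(direction^2))
  structure(list(axis = axis, direction = direction, radius = radius,
                 voxel_edge = edge, achieved_fraction = fraction,
                 target_fraction = fraction, fraction_tolerance = 0.005,
                 seed = 0L),
            class = "cylinder_network")
}

empty_network <- function(edge = 100) {
  manual_network(matrix(0, 0, 3), matrix(0, 0, 3), 1, edge, 0)
}

# Plain-R brute-force containment oracle: all cylinders x 27 periodic images
brute_force_inside <- function(network, point) {
  e <- network$voxel_edge
  p <- point - e * floor(point / e)
  n <- nrow(network$axis)
  if (n == 0) return(FALSE)
  for (c in seq_len(n)) {
    a <- network$axis[c, ]
    d <- network$direction[c, ]
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      v <- p - c(sx, sy, sz) * e - a
      t <- sum(v * d)
      if (sum(v^2) - t^2 <= network$radius^2) return(TRUE)
    }
  }
  FALSE
}

# Small generated network shared by simulator tests
small_test_network <- function(seed = 11) {
  generate_network(network_spec(radius = 5, voxel_edge = 120,
                                target_fraction = 0.04, seed = seed))
}

# Hand-built calibration curve with known coefficients (low order first)
make_curve <- function(coefs, q_range = c(0.5, 40)) {
  structure(list(coefficients = stats::setNames(
    c(coefs, rep(0, 7 - length(coefs))), paste0("P", 0:6)),
    order = 6L, q_range = q_range, weights = NULL,
    residuals = NULL, iterations = 0L, converged = TRUE,
    reference = FALSE),
    class = "calibration_curve")
}

poly_eval <- function(coefs, q) {
  vapply(log(q), function(l) sum(coefs * l^(seq_along(coefs) - 1)), numeric(1))
}
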