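#' Vessel size index from rate changes
#'
#' `q = dR2s / dR2` where both rate changes are positive; otherwise undefined
#' (`NA`), never an error, so maps can propagate masked voxels.
#'
#' @param dr2s Gradient-echo rate change Delta R2*, s^-1 (vectorized).
#' @param dr2 Spin-echo rate change Delta R2, s^-1.
#' @return Numeric vector of vessel size indices with `NA` where undefined.
#' @examples
#' q_from_rates(3, 1)
#' @export
q_from_rates <- function(dr2s, dr2) {
  q <- rep(NA_real_, length(dr2s))
  ok <- is.finite(dr2s) & is.finite(dr2) & dr2s > 0 & dr2 > 0
  q[ok] <- dr2s[ok] / dr2[ok]
  q
}

# Signal compartments at one echo time for one physiological state
state_signal <- function(e_ev, te, f, tissue, blood) {
  (1 - f) * e_ev * exp(-te / tissue$T2_tissue) + f * exp(-te / blood$T2_blood)
}

#' Calibration sweep over vessel radii
#'
#' For each radius one cylinder network is generated and a single random walk
#' is simulated under the free-breathing (FB) field. Because the off-resonance
#' field is linear in the susceptibility difference and the walk geometry does
#' not depend on the field, the breath-hold (BH) phase trajectories are the FB
#' trajectories scaled by `delta_chi(BH) / delta_chi(FB)` -- identical to
#' re-simulating with shared geometry and spin seeds. Per radius the sweep
#' records Delta R2* at `te_ge`, Delta R2 at `te_se` (FB as the
#' high-relaxation "active" state, so rates are positive) and `q`, with
#' batch-means Monte-Carlo standard errors.
#'
#' The per-radius voxel edge, lattice resolution and dipole cutoff scale with
#' the radius (`max(base_edge, edge_per_radius * R)`, at most
#' `max_nodes_axis` lattice nodes per axis, cutoff `cutoff_factor * R`) so
#' that thin-vessel networks stay tractable while large vessels keep a
#' near-target blood volume fraction.
#'
#' @param radii Radii to sweep, um (typically [radius_grid()]).
#' @param fb,bh [blood_model()]s for the two states; they are expected to
#'   differ in `Y` and `T2_blood` only.
#' @param tissue A [tissue_model()].
#' @param echoes An [echo_times()].
#' @param n_spins Spin packets per radius.
#' @param dt Time step, ms.
#' @param seed Master seed; all per-radius seeds derive from it.
#' @param target_fraction Blood volume fraction target.
#' @param n_batches Spin batches for Monte-Carlo standard errors.
#' @param include_blood Add the analytic blood compartment
#'   `f * exp(-t / T2_blood)` to the compared signals. The default (`FALSE`)
#'   makes the calibration a pure extravascular-contrast relation, for which
#'   `q` decreases monotonically toward 1 as radii shrink into the
#'   motional-narrowing regime; with the blood pool included its T2 contrast
#'   dominates at capillary radii and `q(R)` is no longer single-valued.
#' @param base_edge,edge_per_radius,max_nodes_axis,cutoff_factor Desk-scale
#'   geometry rules (see above).
#' @param verbose Print per-radius progress.
#' @return A `calibration_table` data frame with one row per radius: `radius`,
#'   `dr2s`, `dr2`, `q`, their `_se` batch-means errors, `valid`,
#'   `achieved_fraction`, `n_cylinders`, `voxel_edge`, `resolution`, `seed`.
#' @export
sweep_calibration <- function(radii, fb = fb_blood_model(),
                              bh = bh_blood_model(),
                              tissue = tissue_model(),
                              echoes = echo_times(),
                              n_spins = 20000, dt = 0.1, seed = 1L,
                              target_fraction = 0.04, n_batches = 10,
                              base_edge = 128, edge_per_radius = 15,
                              max_nodes_axis = 160, cutoff_factor = 20,
                              include_blood = FALSE, verbose = FALSE) {
  stopifnot(inherits(fb, "blood_model"), inherits(bh, "blood_model"),
            inherits(tissue, "tissue_model"), inherits(echoes, "echo_times"))
  radii <- sort(as.numeric(radii))
  set.seed(seed)
  seeds <- matrix(sample.int(1e8, 2 * length(radii)), ncol = 2)
  te_ge <- echoes$te_ge
  te_se <- echoes$te_se
  times <- sort(unique(c(te_ge, te_se / 2, te_se)))
  i_ge <- match(te_ge, times)
  base_fb <- field_base(fb)
  base_bh <- field_base(bh)
  batch <- rep(seq_len(n_batches), length.out = n_spins)

  rows <- lapply(seq_along(radii), function(i) {
    r <- radii[i]
    edge <- max(base_edge, edge_per_radius * r)
    nspec <- network_spec(radius = r, voxel_edge = edge,
                          target_fraction = target_fraction,
                          seed = seeds[i, 1])
    net <- generate_network(nspec)
    n_nodes <- min(max_nodes_axis, ceiling(edge / 0.8))
    grid <- build_field_grid(net, fb, resolution = edge / n_nodes,
                             cutoff = cutoff_factor * r)
    pos <- seed_spins(net, n_spins = n_spins, seed = seeds[i, 2])
    cfg <- sim_config(duration = te_se, dt = dt, n_spins = n_spins,
                      seed = seeds[i, 2], se_echo_time = te_se)
    traj <- evolve_phases(pos, net, grid, tissue, cfg, times)
    ph_se_fb <- se_phases(traj, te_se)
    ratio <- if (base_fb != 0) base_bh / base_fb else NA_real_

    rates_for <- function(idx) {
      e_ge_fb <- dephasing_factor(traj$phases, idx)[i_ge]
      e_se_fb <- dephasing_factor(ph_se_fb, idx)[length(times)]
      if (is.finite(ratio)) {
        ph <- traj$phases * ratio
        e_ge_bh <- dephasing_factor(ph, idx)[i_ge]
        e_se_bh <- dephasing_factor(ph - 2 * outer(
          ph[, match(te_se / 2, times)],
          as.numeric(times >= te_se / 2 - 1e-9)), idx)[length(times)]
      } else {
        e_ge_bh <- 1
        e_se_bh <- 1
      }
      f <- if (include_blood) net$achieved_fraction else 0
      s_ge_fb <- state_signal(e_ge_fb, te_ge, f, tissue, fb)
      s_ge_bh <- state_signal(e_ge_bh, te_ge, f, tissue, bh)
      s_se_fb <- state_signal(e_se_fb, te_se, f, tissue, fb)
      s_se_bh <- state_signal(e_se_bh, te_se, f, tissue, bh)
      if (any(c(s_ge_fb, s_ge_bh, s_se_fb, s_se_bh) <= 0))
        return(c(NA_real_, NA_real_, NA_real_))
      dr2s <- relaxation_change(s_ge_fb, s_ge_bh, te_ge)
      dr2 <- relaxation_change(s_se_fb, s_se_bh, te_se)
      c(dr2s, dr2, q_from_rates(dr2s, dr2))
    }

    full <- rates_for(NULL)
    per_batch <- vapply(seq_len(n_batches),
                        function(b) rates_for(which(batch == b)),
                        numeric(3))
    ses <- apply(per_batch, 1, stats::sd) / sqrt(n_batches)
    if (verbose)
      message(sprintf(
        "R = %7.3f um: %4d cyl, f = %.4f, dR2* = %7.3f, dR2 = %6.3f, q = %s",
        r, nrow(net$axis), net$achieved_fraction, full[1], full[2],
        format(full[3], digits = 4)))
    data.frame(radius = r, dr2s = full[1], dr2 = full[2], q = full[3],
               dr2s_se = ses[1], dr2_se = ses[2], q_se = ses[3],
               valid = all(is.finite(full)) && full[1] > 0 && full[2] > 0,
               achieved_fraction = net$achieved_fraction,
               n_cylinders = nrow(net$axis), voxel_edge = edge,
               resolution = edge / n_nodes, seed = seeds[i, 1])
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("calibration_table", "data.frame")
  attr(tab, "n_spins") <- n_spins
  attr(tab, "master_seed") <- seed
  tab
}

#' Fit the radius-vs-ln(q) calibration curve
#'
#' Least squares of radius on `{ln^n q, n = 0..order}` with iteratively
#' reweighted bisquare robust weights (Tukey tuning constant 4.685, residual
#' scale `median|r| / 0.6745`, convergence when the largest weight change
#' drops below 1e-6 or after 50 iterations). The valid q range of the fit is
#' the span of the table's q values; evaluation outside it is clipped.
#'
#' @param table A `calibration_table` (or any data frame with `radius`, `q`
#'   and optionally `valid` columns).
#' @param order Polynomial order in `ln q` (default 6).
#' @return An object of class `calibration_curve`: `coefficients` (length
#'   `order + 1`, lowest order first), `order`, `q_range`, `weights`,
#'   `residuals`, `iterations`, `converged`.
#' @export
fit_calibration <- function(table, order = 6) {
  stopifnot(is.data.frame(table))
  keep <- is.finite(table$q) & table$q > 0 & is.finite(table$radius)
  if (!is.null(table$valid)) keep <- keep & table$valid
  x <- log(table$q[keep])
  y <- table$radius[keep]
  if (length(y) < order + 2)
    stop(sprintf(
      "invalid-argument: need >= %d valid rows for order %d, have %d",
      order + 2, order, length(y)))
  V <- outer(x, 0:order, `^`)
  qrV <- qr(V)
  if (qrV$rank < ncol(V))
    stop(sprintf("fit-failure: singular design (rank %d < %d, condition %g)",
                 qrV$rank, ncol(V), kappa(V)))
  w <- rep(1, length(y))
  cc <- 4.685
  converged <- FALSE
  iter <- 0L
  beta <- NULL
  repeat {
    iter <- iter + 1L
    beta <- stats::lm.wfit(V, y, w)$coefficients
    r <- y - drop(V %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s < 1e-10 * max(1, median(abs(y)))) {
      converged <- TRUE # (near-)interpolating fit: residual scale ~ 0
      break
    }
    u <- r / (cc * s)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (max(abs(w_new - w)) < 1e-6) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
    if (iter >= 50L) break
  }
  structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                paste0("P", 0:order)),
                 order = order, q_range = range(table$q[keep]),
                 weights = w, residuals = y - drop(V %*% beta),
                 iterations = iter, converged = converged,
                 reference = FALSE),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> order %d in ln q, q in [%.3g, %.3g]%s\n",
              x$order, x$q_range[1], x$q_range[2],
              if (isTRUE(x$reference)) " (reference fixture)" else ""))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Mean vessel radius from the vessel size index
#'
#' Evaluates `R(q) = sum_n P_n ln^n q` with `q` clipped into the curve's
#' valid range (high-order polynomials are not extrapolated); the result is
#' floored at 0. `q <= 0` or `NA` yields `NA` (masked), never an error.
#'
#' @param curve A [fit_calibration()] result (or [reference_curve()]).
#' @param q Vessel size indices (vectorized).
#' @return Radii in um, with attribute `"clipped"`: logical vector marking
#'   inputs outside the valid range.
#' @export
radius_from_q <- function(curve, q) {
  stopifnot(inherits(curve, "calibration_curve"))
  q <- as.numeric(q)
  ok <- is.finite(q) & q > 0
  clipped <- ok & (q < curve$q_range[1] | q > curve$q_range[2])
  qc <- pmin(pmax(q, curve$q_range[1]), curve$q_range[2])
  out <- rep(NA_real_, length(q))
  lx <- log(qc[ok])
  acc <- rep(0, length(lx)) # Horner, highest order first
  for (p in rev(curve$coefficients)) acc <- acc * lx + p
  out[ok] <- pmax(acc, 0)
  attr(out, "clipped") <- clipped
  out
}

#' @export
predict.calibration_curve <- function(object, q, ...) radius_from_q(object, q)

#' Printed reference calibration coefficients
#'
#' A read-only fixture holding the published sixth-order coefficient list
#' `[-2.70, 24.82, -27.26, 20.49, -5.89, 0.64]` for comparison plots. The
#' sixth-order polynomial has seven coefficients but only six values were
#' printed, so the mapping is ambiguous; both interpretations are exposed
#' (`"p0_p5"`: the values are P0..P5 with P6 = 0; `"p1_p6"`: P1..P6 with
#' P0 = 0) and neither is ever used as a silent default anywhere in the
#' package.
#'
#' @param interpretation Which coefficient assignment to return.
#' @param q_range Nominal validity range attached to the fixture (the source
#'   did not print one); defaults to `[1.1, 60]`.
#' @return A `calibration_curve` flagged as a reference fixture.
#' @examples
#' radius_from_q(reference_curve(), 2) # ~7 um
#' @export
reference_curve <- function(interpretation = c("p0_p5", "p1_p6"),
                            q_range = c(1.1, 60)) {
  interpretation <- match.arg(interpretation)
  pn <- c(-2.70, 24.82, -27.26, 20.49, -5.89, 0.64)
  coefs <- if (interpretation == "p0_p5") c(pn, 0) else c(0, pn)
  structure(list(coefficients = stats::setNames(coefs, paste0("P", 0:6)),
                 order = 6L, q_range = q_range, weights = NULL,
                 residuals = NULL, iterations = 0L, converged = NA,
                 reference = TRUE, interpretation = interpretation),
            class = "calibration_curve")
}

#' Calibration curve JSON I/O
#'
#' The JSON records `order`, `coefficients_low_to_high`, `q_min`, `q_max` and
#' a free-form `provenance` string, with the coefficient ordering explicit in
#' the key name.
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @param provenance Free-form description stored alongside the fit.
#' @return `path` (write) or a `calibration_curve` (read).
#' @export
write_curve_json <- function(curve, path, provenance = "bhvsi fit") {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(
    list(order = curve$order,
         coefficients_low_to_high = as.numeric(curve$coefficients),
         q_min = curve$q_range[1], q_max = curve$q_range[2],
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.numeric(obj$coefficients_low_to_high)
  structure(list(coefficients = stats::setNames(coefs,
                                                paste0("P", seq_along(coefs) - 1)),
                 order = as.integer(obj$order),
                 q_range = c(obj$q_min, obj$q_max), weights = NULL,
                 residuals = NULL, iterations = NA_integer_, converged = NA,
                 reference = FALSE, provenance = obj$provenance),
            class = "calibration_curve")
}

#' Calibration table TSV I/O
#'
#' @param table A `calibration_table`.
#' @param path File path.
#' @return `path` (write) or a `calibration_table` (read).
#' @export
write_calibration_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_tsv
#' @export
read_calibration_tsv <- function(path) {
  tab <- utils::read.delim(path)
  class(tab) <- c("calibration_table", "data.frame")
  tab
}
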