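#' Tissue model for the random walk
#'
#' @param D Water diffusion coefficient, um^2/ms (>= 0; 0 gives the static
#'   dephasing limit).
#' @param T2_tissue Tissue transverse relaxation time, ms.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(D = 1, T2_tissue = 83.5) {
  if (D < 0) stop("invalid-argument: D must be >= 0")
  if (T2_tissue <= 0) stop("invalid-argument: T2_tissue must be > 0")
  structure(list(D = D, T2_tissue = T2_tissue), class = "tissue_model")
}

#' Simulation configuration
#'
#' @param duration Total simulated time, ms.
#' @param dt Diffusion time step, ms.
#' @param n_spins Explicit number of spin packets; if `NULL`, the count is
#'   `round(spin_density * (1 - f) * voxel_edge^3)`.
#' @param spin_density Mean extravascular spin packet density, um^-3. The
#'   nominal 5 um^-3 over a 500 um voxel implies ~6e8 packets; desk-scale runs
#'   pass an explicit `n_spins` instead.
#' @param seed Integer seed for seeding and the random walk.
#' @param field_mode `"grid"` (trilinear interpolation on a precomputed
#'   lattice) or `"exact"` (direct superposition at every step).
#' @param se_echo_time Spin-echo time, ms (must be <= duration when used).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, dt = 0.1, n_spins = NULL, spin_density = 5,
                       seed = 1L, field_mode = c("grid", "exact"),
                       se_echo_time = NULL) {
  if (dt <= 0) stop("invalid-argument: dt must be > 0")
  if (duration <= 0) stop("invalid-argument: duration must be > 0")
  if (!is.null(se_echo_time) && se_echo_time > duration)
    stop("invalid-argument: duration must cover se_echo_time")
  structure(list(duration = duration, dt = dt, n_spins = n_spins,
                 spin_density = spin_density, seed = as.integer(seed),
                 field_mode = match.arg(field_mode),
                 se_echo_time = se_echo_time),
            class = "sim_config")
}

#' Echo and repetition times of the dual-echo acquisition
#'
#' Defaults follow a SAGE EPI protocol: TE_GE/TE_SE/TR = 27.08/90/1700 ms.
#'
#' @param te_ge Gradient-echo time, ms.
#' @param te_se Spin-echo time, ms.
#' @param tr Repetition time, ms.
#' @return An object of class `echo_times`.
#' @export
echo_times <- function(te_ge = 27.08, te_se = 90, tr = 1700) {
  if (te_ge <= 0 || te_se <= te_ge)
    stop("invalid-argument: need 0 < te_ge < te_se")
  structure(list(te_ge = te_ge, te_se = te_se, tr = tr), class = "echo_times")
}

#' Seed extravascular spin packets
#'
#' Positions uniform in the extravascular space, obtained by rejection
#' sampling against [is_intravascular()]. Deterministic given the seed.
#'
#' @param network A `cylinder_network`.
#' @param n_spins Number of packets. If `NULL`, derived from `spin_density`
#'   (refused above `max_auto_spins` to avoid accidental cluster-scale runs).
#' @param spin_density Packets per um^3 used when `n_spins` is `NULL`.
#' @param seed Integer seed.
#' @param max_auto_spins Guard for density-derived counts.
#' @return n x 3 matrix of positions, um.
#' @export
seed_spins <- function(network, n_spins = NULL, spin_density = 5, seed = 1L,
                       max_auto_spins = 1e7) {
  stopifnot(inherits(network, "cylinder_network"))
  if (network$achieved_fraction >= 1)
    stop("invalid-argument: no extravascular volume")
  if (is.null(n_spins)) {
    n_spins <- round(spin_density * (1 - network$achieved_fraction) *
                       network$voxel_edge^3)
    if (n_spins > max_auto_spins)
      stop(sprintf(paste0(
        "invalid-argument: density-derived spin count %g exceeds %g; ",
        "pass an explicit n_spins"), n_spins, max_auto_spins))
  }
  set.seed(seed)
  cpp_seed_spins(network$axis, network$direction, network$radius,
                 network$voxel_edge, as.integer(n_spins))
}

#' Random-walk phase evolution
#'
#' Discrete-time, continuous-space random walk of extravascular spin packets.
#' Each step proposes an isotropic Gaussian displacement (per-axis standard
#' deviation `sqrt(2 D dt)`); proposals landing inside a vessel are rejected
#' and the packet keeps its position for that step (vessels are impermeable
#' barriers). The accrued phase uses the field at the pre-step position
#' (first-order Euler of the Bloch-Torrey phase integral, error O(dt)).
#' Positions wrap periodically. Longitudinal relaxation is omitted.
#'
#' In the static limit `D = 0` the phase is evaluated in closed form,
#' `phi(t) = omega(r0) * t`, on the same field source.
#'
#' @param positions n x 3 matrix from [seed_spins()].
#' @param network A `cylinder_network` (barriers).
#' @param field A `field_grid` (grid mode) or the same `cylinder_network`
#'   with `model` supplied (exact mode).
#' @param tissue A [tissue_model()].
#' @param config A [sim_config()]; `config$seed` drives the walk.
#' @param times Record times, ms (strictly increasing, > 0). Step boundaries
#'   are the union of the `dt` lattice and the requested times, so arbitrary
#'   echo times are hit exactly.
#' @param model A [blood_model()], required in exact mode.
#' @return An object of class `phase_trajectories`: list with `phases`
#'   (n_spins x n_times matrix, rad), `times`, `displacement` (n_spins x 3,
#'   the unwrapped sum of accepted steps, um; `NULL` in the static limit),
#'   and bookkeeping fields.
#' @export
evolve_phases <- function(positions, network, field, tissue, config, times,
                          model = NULL) {
  stopifnot(inherits(network, "cylinder_network"),
            inherits(tissue, "tissue_model"), inherits(config, "sim_config"))
  positions <- as_points(positions)
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("invalid-argument: times must be positive and strictly increasing")
  exact <- inherits(field, "cylinder_network")
  if (exact && is.null(model)) stop("exact field mode needs a blood_model")

  displacement <- NULL
  if (tissue$D == 0) {
    w0 <- if (exact) sample_field(field, positions, model)
          else sample_field(field, positions)
    phases <- outer(w0, times * 1e-3)
  } else {
    tmax <- max(times)
    bounds <- sort(unique(round(c(seq(config$dt, tmax, by = config$dt),
                                  times, tmax), 9)))
    dts <- diff(c(0, bounds))
    rec <- !is.na(match(round(bounds, 9), round(times, 9)))
    set.seed(config$seed)
    res <- if (exact) {
      cpp_evolve_phases(positions, network$axis, network$direction,
                        network$radius, network$voxel_edge,
                        1L, numeric(0), 0L, field_base(model),
                        dts, rec, tissue$D)
    } else {
      stopifnot(inherits(field, "field_grid"))
      cpp_evolve_phases(positions, network$axis, network$direction,
                        network$radius, network$voxel_edge,
                        0L, as.numeric(field$values), field$n,
                        0, dts, rec, tissue$D)
    }
    phases <- res$phases
    displacement <- res$displacement
  }
  structure(list(phases = phases, times = times, n_spins = nrow(positions),
                 field_mode = if (exact) "exact" else "grid",
                 displacement = displacement, seed = config$seed),
            class = "phase_trajectories")
}

# |mean of unit phasors| per recorded time, optionally on a spin subset
dephasing_factor <- function(phases, idx = NULL) {
  if (!is.null(idx)) phases <- phases[idx, , drop = FALSE]
  sqrt(colMeans(cos(phases))^2 + colMeans(sin(phases))^2)
}

# SE phases: ideal instantaneous refocusing at te/2 negates the accrued phase
se_phases <- function(traj, te_se) {
  k <- which(abs(traj$times - te_se / 2) < 1e-6)
  if (length(k) != 1)
    stop("invalid-argument: te_se/2 must be among the recorded times")
  ph <- traj$phases
  half <- ph[, k]
  after <- traj$times >= te_se / 2 - 1e-9
  ph[, after] <- ph[, after] - 2 * half
  ph
}

make_signal_trace <- function(times, e_ev, f, tissue, blood, include_blood,
                              echo) {
  tissue_factor <- exp(-times / tissue$T2_tissue)
  if (include_blood && !is.null(blood)) {
    blood_factor <- exp(-times / blood$T2_blood)
    magnitude <- (1 - f) * e_ev * tissue_factor + f * blood_factor
  } else {
    blood_factor <- rep(0, length(times))
    magnitude <- e_ev * tissue_factor
    f <- 0
  }
  structure(data.frame(time_ms = times, e_ev = e_ev,
                       tissue_factor = tissue_factor,
                       blood_factor = blood_factor,
                       magnitude = magnitude),
            class = c("signal_trace", "data.frame"),
            echo = echo, includes_t2 = TRUE, blood_fraction = f)
}

#' Gradient-echo (FID) signal from phase trajectories
#'
#' The extravascular dephasing factor is the magnitude of the mean unit
#' phasor, `E_ev(t) = |mean exp(i phi(t))|`. The total magnitude combines the
#' simulated extravascular compartment with an analytic blood pool:
#' `S(t) = (1 - f) E_ev(t) exp(-t / T2_tissue) + f exp(-t / T2_blood)`,
#' `f` the achieved blood volume fraction. Intravascular packets are not
#' walked; the blood pool enters only through its T2 (set
#' `include_blood = FALSE` to drop it).
#'
#' @param traj An [evolve_phases()] result.
#' @param network The `cylinder_network` (supplies `f`).
#' @param tissue A [tissue_model()].
#' @param blood A [blood_model()] (supplies `T2_blood`); may be `NULL` when
#'   `include_blood = FALSE`.
#' @param include_blood Include the analytic blood compartment?
#' @return A `signal_trace` data frame: `time_ms`, `e_ev`, `tissue_factor`,
#'   `blood_factor`, `magnitude`.
#' @export
ge_signal <- function(traj, network, tissue, blood = NULL,
                      include_blood = TRUE) {
  stopifnot(inherits(traj, "phase_trajectories"))
  if (traj$n_spins == 0) stop("invalid-state: no spins")
  e_ev <- dephasing_factor(traj$phases)
  make_signal_trace(traj$times, e_ev, network$achieved_fraction, tissue,
                    blood, include_blood, "GE")
}

#' Spin-echo signal from phase trajectories
#'
#' As [ge_signal()], with all phases negated at `te_se / 2` (ideal
#' instantaneous refocusing). Requires `te_se / 2` among the recorded times.
#'
#' @inheritParams ge_signal
#' @param te_se Spin-echo time, ms.
#' @return A `signal_trace` data frame.
#' @export
se_signal <- function(traj, network, tissue, blood = NULL, te_se,
                      include_blood = TRUE) {
  stopifnot(inherits(traj, "phase_trajectories"))
  if (traj$n_spins == 0) stop("invalid-state: no spins")
  e_ev <- dephasing_factor(se_phases(traj, te_se))
  make_signal_trace(traj$times, e_ev, network$achieved_fraction, tissue,
                    blood, include_blood, "SE")
}

#' Transverse relaxation-rate change from a signal ratio
#'
#' `Delta R2(*) = -ln(s_active / s_baseline) / TE` with TE converted to
#' seconds; positive when the active state has the lower signal (stronger
#' relaxation).
#'
#' @param s_active,s_baseline Signal magnitudes (> 0); vectorized.
#' @param te_ms Echo time, ms.
#' @return Rate change in s^-1.
#' @examples
#' relaxation_change(0.9, 1, 27.08) # ~3.891 s^-1
#' @export
relaxation_change <- function(s_active, s_baseline, te_ms) {
  if (any(s_active <= 0) || any(s_baseline <= 0))
    stop("invalid-argument: signals must be > 0")
  -log(s_active / s_baseline) / (te_ms / 1000)
}

#' Write a GE/SE signal trace pair as TSV
#'
#' Columns: `time_ms`, `ge`, `se`, `e_ev_ge`, `e_ev_se`.
#'
#' @param ge,se `signal_trace` objects on the same time base.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(ge, se, path) {
  stopifnot(identical(ge$time_ms, se$time_ms))
  df <- data.frame(time_ms = ge$time_ms, ge = ge$magnitude,
                   se = se$magnitude, e_ev_ge = ge$e_ev, e_ev_se = se$e_ev)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
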