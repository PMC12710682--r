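#' Default phantom region layout
#'
#' Partitions the grid into background (0), non-responding tissue (1), a
#' responding "GM" shell (2) and a responding "WM" core (3): nested centered
#' boxes with a tissue gap between shell and core so region medians survive
#' spatial smoothing.
#'
#' @param dims Length-3 grid dimensions.
#' @return Integer 3D array of region labels.
#' @export
phantom_regions <- function(dims = c(64, 64, 8)) {
  lab <- array(0L, dims)
  ctr <- (dims + 1) / 2
  box <- function(fx, fz) {
    half <- c(fx, fx, fz) * dims
    lo <- pmax(1, ceiling(ctr - half))
    hi <- pmin(dims, floor(ctr + half))
    list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  }
  brain <- box(0.313, 0.375) # 20/14/8/6-voxel halves on the 64 x 64 x 8 grid
  lab[brain$x, brain$y, brain$z] <- 1L
  gm_out <- box(0.22, 0.375)
  lab[gm_out$x, gm_out$y, gm_out$z] <- 2L
  gm_in <- box(0.125, 0.375)
  lab[gm_in$x, gm_in$y, gm_in$z] <- 1L
  wm <- box(0.094, 0.25)
  lab[wm$x, wm$y, wm$z] <- 3L
  lab
}

#' Specification of a synthetic dual-echo phantom
#'
#' Defines a 4D dual-echo breath-hold run with known per-region ground
#' truth. Default true rates (Delta R2* = 1.2, Delta R2 = 0.35 s^-1 in the
#' GM shell) are plausible breath-hold magnitudes chosen for testing, not
#' published values.
#'
#' @param dims Grid dimensions (default 64 x 64 x 8).
#' @param regions Integer label array from [phantom_regions()] (0 background,
#'   1 tissue, 2 GM, 3 WM); must partition the grid.
#' @param dr2s_by_region,dr2_by_region True rate changes per region label
#'   0..3, s^-1.
#' @param baseline_ge,baseline_se Baseline intensities per region label 0..3.
#' @param noise_sd Additive Gaussian noise SD on magnitude, per echo
#'   (named `ge`, `se`). The defaults give temporal SNR ~ 100 in tissue.
#' @param lag Hemodynamic lag, volumes (circular delay of the response).
#' @param drift Fractional linear drift per volume.
#' @param seed Integer seed.
#' @param design A [build_block_design()].
#' @param echoes An [echo_times()].
#' @param response `"hrf"` for the canonical HRF-convolved response,
#'   `"boxcar"` for an ideal square response (exact inverse-model identity).
#' @param voxel_dim Voxel dimensions, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 8), regions = phantom_regions(dims),
                         dr2s_by_region = c(0, 0, 1.2, 0.85),
                         dr2_by_region = c(0, 0, 0.35, 0.30),
                         baseline_ge = c(20, 1000, 1000, 1000),
                         baseline_se = c(16, 800, 800, 800),
                         noise_sd = c(ge = 10, se = 8),
                         lag = 3L, drift = 0, seed = 1L,
                         design = build_block_design(),
                         echoes = echo_times(),
                         response = c("hrf", "boxcar"),
                         voxel_dim = c(3.4, 3.4, 3.5)) {
  stopifnot(inherits(design, "block_design"), inherits(echoes, "echo_times"))
  if (!identical(dim(regions), as.integer(dims)))
    stop("invalid-argument: regions must match dims")
  if (!all(regions %in% 0:3))
    stop("invalid-argument: region labels must partition the grid into 0..3")
  if (any(noise_sd < 0)) stop("invalid-argument: noise_sd must be >= 0")
  structure(list(dims = as.integer(dims), regions = regions,
                 dr2s_by_region = dr2s_by_region,
                 dr2_by_region = dr2_by_region,
                 baseline_ge = baseline_ge, baseline_se = baseline_se,
                 noise_sd = noise_sd, lag = as.integer(lag), drift = drift,
                 seed = as.integer(seed), design = design, echoes = echoes,
                 response = match.arg(response),
                 voxel_dim = voxel_dim),
            class = "phantom_spec")
}

#' Unit-amplitude hemodynamic response timecourse
#'
#' The BH boxcar convolved with the canonical HRF, peak-normalized to 1 and
#' circularly delayed by `lag` volumes. With `response = "boxcar"` the raw
#' (shifted) boxcar is returned instead.
#'
#' @param design A [build_block_design()].
#' @param lag Circular delay in volumes.
#' @param response `"hrf"` or `"boxcar"`.
#' @return Numeric vector of length `n_volumes`, maximum 1 (or all zero for
#'   an all-FB design).
#' @export
response_timecourse <- function(design, lag = 0L, response = c("hrf", "boxcar")) {
  response <- match.arg(response)
  n <- design$n_volumes
  box <- as.numeric(design$states == "BH")
  h <- if (response == "boxcar") {
    box
  } else {
    if (all(box == 0)) box
    else {
      tt <- seq(0, 32, by = design$tr / 1000)
      v <- convolve(box, rev(canonical_hrf(tt)), type = "open")[seq_len(n)]
      v / max(v)
    }
  }
  h[((seq_len(n) - 1 - lag) %% n) + 1]
}

#' Generate a synthetic dual-echo phantom
#'
#' Signal model per voxel and volume:
#' `S_e(v, t) = S0_e(v) * exp(TE_e * dR2_e(v) * h(t)) * (1 + drift * (t - 1))
#' + noise`, with the sign chosen so BH raises the signal (relaxation is
#' reduced during the hold). The plateau ratio BH/FB of a noise-free boxcar
#' phantom is therefore `exp(TE_e * dR2_e)`, and the mapping pipeline's
#' log-ratio recovers the true rates exactly. Noise is additive Gaussian on
#' the magnitude (adequate at SNR >> 3; negative values are clipped at 0).
#'
#' @param spec A [phantom_spec()].
#' @return List: `ge` and `se` [echo_series()], `truth` (per-voxel `dr2s`,
#'   `dr2`, `q`, `responding` mask, `lag`, `h`), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  n <- spec$design$n_volumes
  h <- response_timecourse(spec$design, spec$lag, spec$response)
  reg <- spec$regions + 1L # 1-based lookup
  dr2s <- array(spec$dr2s_by_region[reg], d)
  dr2 <- array(spec$dr2_by_region[reg], d)
  set.seed(spec$seed)
  mk <- function(baseline_by_region, te_ms, rates, sd, label) {
    s0 <- array(baseline_by_region[reg], d)
    te <- te_ms / 1000
    drift_fac <- 1 + spec$drift * (seq_len(n) - 1)
    arr <- array(0, c(d, n))
    for (t in seq_len(n))
      arr[, , , t] <- s0 * exp(te * rates * h[t]) * drift_fac[t]
    if (sd > 0) arr <- arr + array(rnorm(length(arr), 0, sd), dim(arr))
    arr[arr < 0] <- 0
    echo_series(arr, tr = spec$design$tr, voxel_dim = spec$voxel_dim,
                te = te_ms, label = label)
  }
  ge <- mk(spec$baseline_ge, spec$echoes$te_ge, dr2s, spec$noise_sd[["ge"]],
           "GE")
  se <- mk(spec$baseline_se, spec$echoes$te_se, dr2, spec$noise_sd[["se"]],
           "SE")
  truth <- list(dr2s = dr2s, dr2 = dr2,
                q = array(q_from_rates(dr2s, dr2), d),
                responding = dr2s > 0 & dr2 > 0, lag = spec$lag, h = h)
  list(ge = ge, se = se, truth = truth, spec = spec)
}

#' Null phantom (no response)
#'
#' [make_phantom()] with all rate changes forced to zero; used for
#' false-positive-rate testing.
#'
#' @param spec A [phantom_spec()].
#' @return As [make_phantom()].
#' @export
make_null_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec$dr2s_by_region <- rep(0, 4)
  spec$dr2_by_region <- rep(0, 4)
  make_phantom(spec)
}

#' Write a phantom to disk
#'
#' GE/SE NIfTI series, ground-truth NIfTI volumes, and a JSON sidecar with
#' the spec scalars and seed.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_echo_series(phantom$ge, file.path(dir, "ge.nii.gz"))
  write_echo_series(phantom$se, file.path(dir, "se.nii.gz"))
  vd <- phantom$spec$voxel_dim
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- vd
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(phantom$truth$dr2s, "truth_dr2s")
  wr(phantom$truth$dr2, "truth_dr2")
  wr(phantom$truth$responding, "truth_responding")
  s <- phantom$spec
  jsonlite::write_json(
    list(dims = s$dims, lag = s$lag, drift = s$drift, seed = s$seed,
         noise_sd = as.list(s$noise_sd), response = s$response,
         dr2s_by_region = s$dr2s_by_region, dr2_by_region = s$dr2_by_region,
         tr_ms = s$design$tr, te_ge_ms = s$echoes$te_ge,
         te_se_ms = s$echoes$te_se, n_volumes = s$design$n_volumes),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
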