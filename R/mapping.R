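#' Breath-hold block design
#'
#' Alternating free-breathing / breath-hold half-cycles, FB first and BH
#' second in each cycle (the hold follows inspiration at the end of free
#' breathing). The defaults give the standard paradigm: 110 volumes, five and
#' a half 20-volume (34 s) cycles of 10 + 10 volumes (17 s halves) at
#' TR 1.7 s.
#'
#' @param n_volumes Total number of volumes.
#' @param volumes_per_cycle Volumes per full FB+BH cycle.
#' @param volumes_per_half Volumes per half cycle.
#' @param tr Repetition time, ms.
#' @return An object of class `block_design` with a per-volume `states`
#'   vector (`"FB"`/`"BH"`).
#' @export
build_block_design <- function(n_volumes = 110, volumes_per_cycle = 20,
                               volumes_per_half = 10, tr = 1700) {
  if (volumes_per_half < 1)
    stop("invalid-argument: volumes_per_half must be >= 1")
  if (volumes_per_cycle != 2 * volumes_per_half)
    stop("invalid-argument: volumes_per_cycle must be 2 * volumes_per_half")
  rem <- n_volumes %% volumes_per_cycle
  if (!(rem == 0 || rem == volumes_per_half))
    stop("invalid-argument: n_volumes must be whole or half cycles")
  if (tr <= 0) stop("invalid-argument: tr must be > 0")
  states <- rep(rep(c("FB", "BH"), each = volumes_per_half),
                length.out = n_volumes)
  structure(list(n_volumes = as.integer(n_volumes),
                 volumes_per_cycle = as.integer(volumes_per_cycle),
                 volumes_per_half = as.integer(volumes_per_half),
                 tr = tr, states = states),
            class = "block_design")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Standard parameterization: response peak at 6 s, undershoot peak at 16 s,
#' both with 1 s dispersion, peak:undershoot amplitude ratio 6:1, support
#' 0-32 s.
#'
#' @param t Time in seconds (vectorized; negative times give 0).
#' @return HRF values (arbitrary units).
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, scale = 1) - dgamma(t, shape = 16, scale = 1) / 6
  h[t < 0] <- 0
  h
}

#' HRF task regressor and temporal derivative
#'
#' The BH boxcar sampled at TR is convolved with the canonical HRF
#' ([canonical_hrf()]); the temporal-derivative regressor uses the finite
#' difference of a 1-s-shifted HRF. The derivative column is orthogonalized
#' against the HRF column, and both are unit-peak normalized.
#'
#' @param design A [build_block_design()].
#' @return Matrix with columns `hrf` and `deriv`, one row per volume.
#' @export
hrf_regressor <- function(design) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_volumes
  tr_s <- design$tr / 1000
  tt <- seq(0, 32, by = tr_s)
  box <- as.numeric(design$states == "BH")
  conv_with <- function(kernel) {
    if (all(box == 0)) return(numeric(n))
    v <- convolve(box, rev(kernel), type = "open")[seq_len(n)]
    m <- max(abs(v))
    if (m > 0) v / m else v
  }
  hrf <- conv_with(canonical_hrf(tt))
  deriv <- conv_with(canonical_hrf(tt) - canonical_hrf(tt - 1))
  if (any(hrf != 0))
    deriv <- deriv - hrf * sum(deriv * hrf) / sum(hrf * hrf)
  m <- max(abs(deriv))
  if (m > 0) deriv <- deriv / m
  cbind(hrf = hrf, deriv = deriv)
}

#' 4D echo series container
#'
#' @param data 4D numeric array (x, y, z, t) of magnitude intensities.
#' @param tr Repetition time, ms.
#' @param voxel_dim Length-3 voxel dimensions, mm.
#' @param te Echo time, ms.
#' @param label `"GE"` or `"SE"`.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, tr, voxel_dim, te, label = c("GE", "SE")) {
  label <- match.arg(label)
  data <- as.array(data)
  if (length(dim(data)) != 4) stop("invalid-argument: data must be 4D")
  if (length(voxel_dim) != 3) stop("invalid-argument: voxel_dim must be length 3")
  if (min(data) < 0)
    warning("negative intensities present; magnitude data expected")
  structure(list(data = data, tr = tr, voxel_dim = as.numeric(voxel_dim),
                 te = te, label = label),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series %s> %dx%dx%d x %d volumes, TE %g ms, TR %g ms\n",
              x$label, d[1], d[2], d[3], d[4], x$te, x$tr))
  invisible(x)
}

#' Read / write echo series as NIfTI
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param te Echo time, ms.
#' @param label `"GE"` or `"SE"`.
#' @param tr Repetition time, ms; if `NULL`, taken from the NIfTI time step
#'   (assumed seconds).
#' @return An `echo_series` (read); `path` invisibly (write).
#' @export
read_echo_series <- function(path, te, label = c("GE", "SE"), tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pd) >= 4) pd[4] * 1000 else 1700
  echo_series(unclass(img)[, , , , drop = FALSE], tr = tr,
              voxel_dim = pd[1:3] * ifelse(max(pd[1:3]) < 0.1, 1000, 1),
              te = te, label = match.arg(label))
}

#' @rdname read_echo_series
#' @param series An `echo_series`.
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_dim, series$tr / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1D truncated-Gaussian convolution matrix with renormalized rows
# (constants are preserved exactly, including at the boundary)
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  rad <- max(1L, ceiling(3 * sigma_vox))
  offs <- -rad:rad
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

smooth3d <- function(v, K1, K2, K3) {
  d <- dim(v)
  v <- array(K1 %*% matrix(v, d[1]), d)
  v <- aperm(array(K2 %*% matrix(aperm(v, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(K3 %*% matrix(aperm(v, c(3, 1, 2)), d[3]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Isotropic Gaussian spatial smoothing
#'
#' Per-volume separable 3D Gaussian smoothing with
#' `sigma(voxels) = fwhm / (2.3548 * voxel_dim)` per axis. The kernel is
#' truncated at 3 sigma and renormalized, so spatially constant volumes are
#' unchanged everywhere including the boundary. `fwhm = 0` is the identity.
#'
#' @param series An [echo_series()].
#' @param fwhm Full width at half maximum, mm.
#' @return A smoothed `echo_series`.
#' @export
smooth_series <- function(series, fwhm = 5) {
  stopifnot(inherits(series, "echo_series"))
  if (fwhm < 0) stop("invalid-argument: fwhm must be >= 0")
  if (fwhm == 0) return(series)
  d <- dim(series$data)
  sig <- fwhm / (2.3548 * series$voxel_dim)
  K1 <- gauss_kernel_matrix(d[1], sig[1])
  K2 <- gauss_kernel_matrix(d[2], sig[2])
  K3 <- gauss_kernel_matrix(d[3], sig[3])
  out <- series$data
  for (t in seq_len(d[4]))
    out[, , , t] <- smooth3d(series$data[, , , t], K1, K2, K3)
  series$data <- out
  series
}

#' Build a first-level design matrix
#'
#' Columns: intercept, HRF-convolved task regressor, its temporal derivative,
#' then any nuisance regressors (e.g. the six motion parameters), each
#' demeaned.
#'
#' @param design A [build_block_design()].
#' @param nuisance Optional matrix of nuisance regressors (rows = volumes).
#' @return Design matrix with column names; first-level contracts use the
#'   `"hrf"` column.
#' @export
build_design_matrix <- function(design, nuisance = NULL) {
  X <- cbind(intercept = rep(1, design$n_volumes), hrf_regressor(design))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != design$n_volumes)
      stop("invalid-argument: nuisance rows must match n_volumes")
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, sweep(nuisance, 2, colMeans(nuisance)))
  }
  X
}

#' Voxelwise GLM fit
#'
#' Ordinary least squares per voxel; the t-statistic tests the HRF column
#' (`t = beta_hrf / se(beta_hrf)`, two-sided p from the t distribution with
#' `n - rank(X)` degrees of freedom). Voxels with zero residual variance and
#' zero effect (e.g. constant series) get `t = 0`, `p = 1`.
#'
#' @param series An [echo_series()].
#' @param X Design matrix from [build_design_matrix()] (full column rank).
#' @return An object of class `glm_result`: per-column beta maps, `tstat`,
#'   `pval` and `sigma2` 3D arrays, `predicted` task response (volumes x
#'   voxels matrix, `beta_hrf * hrf + beta_deriv * deriv`), `dof`, `dims`.
#' @export
fit_glm <- function(series, X) {
  stopifnot(inherits(series, "echo_series"))
  X <- as.matrix(X)
  d <- dim(series$data)
  if (d[4] != nrow(X))
    stop("invalid-argument: series length does not match design matrix")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fit-failure: collinear design columns: ",
         paste(bad, collapse = ", "))
  }
  nv <- prod(d[1:3])
  Y <- t(matrix(series$data, nv, d[4]))
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  dof <- d[4] - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  h <- match("hrf", colnames(X))
  se <- sqrt(sigma2 * XtXinv[h, h])
  # a residual sd below ~1e-8 of the signal scale is numerically zero
  # (noise-free series), not evidence: guard the 0/0 as non-significant
  degenerate <- sqrt(sigma2) <= 1e-8 * sqrt(colMeans(Y^2))
  tstat <- ifelse(se > 0 & !degenerate, B[h, ] / se, 0)
  pval <- ifelse(se > 0 & !degenerate, 2 * pt(-abs(tstat), dof), 1)
  task_cols <- intersect(c("hrf", "deriv"), colnames(X))
  predicted <- X[, task_cols, drop = FALSE] %*%
    B[match(task_cols, colnames(X)), , drop = FALSE]
  rownames(B) <- colnames(X)
  structure(list(beta = B, tstat = array(tstat, d[1:3]),
                 pval = array(pval, d[1:3]),
                 sigma2 = array(sigma2, d[1:3]), predicted = predicted,
                 dof = dof, dims = d[1:3], columns = colnames(X)),
            class = "glm_result")
}

#' Joint GE+SE significance mask
#'
#' A voxel is included when it shows a significant signal increase during BH
#' (two-sided p below `alpha` with a positive HRF beta) in both the GE and
#' the SE fit.
#'
#' @param ge_result,se_result [fit_glm()] results on the same grid.
#' @param alpha Uncorrected significance level (default 0.001).
#' @return 3D logical array.
#' @export
joint_significance_mask <- function(ge_result, se_result, alpha = 0.001) {
  if (!identical(ge_result$dims, se_result$dims))
    stop("invalid-argument: GE and SE grids differ")
  bh_ge <- array(ge_result$beta["hrf", ], ge_result$dims)
  bh_se <- array(se_result$beta["hrf", ], se_result$dims)
  ge_result$pval < alpha & bh_ge > 0 & se_result$pval < alpha & bh_se > 0
}

#' Hemodynamic lag as a circular shift
#'
#' Integer circular shift `s*` maximizing the circular cross-correlation
#' between a (demeaned) timecourse and the BH boxcar; ties resolve to the
#' smallest nonnegative shift. A flat timecourse gives shift 0 with a
#' warning.
#'
#' @param timecourse Numeric vector, one value per volume.
#' @param design The [build_block_design()].
#' @return Integer shift in `[0, n_volumes)`.
#' @export
lag_shift <- function(timecourse, design) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_volumes
  if (length(timecourse) != n)
    stop("invalid-argument: timecourse length must equal n_volumes")
  if (stats::sd(timecourse) == 0) {
    warning("flat timecourse; returning shift 0")
    return(0L)
  }
  x <- timecourse - mean(timecourse)
  b <- as.numeric(design$states == "BH")
  b <- b - mean(b)
  cc <- vapply(0:(n - 1), function(s) {
    sum(x * b[((seq_len(n) - 1 - s) %% n) + 1])
  }, numeric(1))
  as.integer(which.max(cc) - 1L)
}

#' Circularly shift the state labels
#'
#' @param design A [build_block_design()].
#' @param shift Integer shift from [lag_shift()]; labels are delayed by
#'   `shift` volumes (circularly).
#' @return Character vector of shifted `"FB"`/`"BH"` labels.
#' @export
shift_labels <- function(design, shift) {
  n <- design$n_volumes
  design$states[((seq_len(n) - 1 - shift) %% n) + 1]
}

#' Block averaging of BH and FB volumes
#'
#' Voxelwise means over volumes labeled BH and FB. By default the first
#' `transition_drop` volumes after each (circular) state change are excluded,
#' since the hemodynamic response is still in transit there and would dilute
#' the plateau contrast.
#'
#' @param series An [echo_series()].
#' @param labels Per-volume `"FB"`/`"BH"` labels (typically
#'   [shift_labels()]).
#' @param transition_drop Number of volumes dropped after each state change.
#' @return List with `bh` and `fb` mean 3D arrays and `used`, the logical
#'   vector of retained volumes.
#' @export
block_average <- function(series, labels, transition_drop = 2) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  n <- d[4]
  if (length(labels) != n)
    stop("invalid-argument: labels must cover all volumes")
  used <- rep(TRUE, n)
  if (transition_drop > 0) {
    flips <- which(labels != labels[c(n, seq_len(n - 1))])
    for (f in flips)
      used[((f - 1) + seq_len(transition_drop) - 1) %% n + 1] <- FALSE
  }
  bh_idx <- which(labels == "BH" & used)
  fb_idx <- which(labels == "FB" & used)
  if (length(bh_idx) == 0 || length(fb_idx) == 0)
    stop("invalid-argument: a label class is empty after transition dropping")
  flat <- matrix(series$data, prod(d[1:3]), n)
  list(bh = array(rowMeans(flat[, bh_idx, drop = FALSE]), d[1:3]),
       fb = array(rowMeans(flat[, fb_idx, drop = FALSE]), d[1:3]),
       used = used)
}

#' Voxelwise VSI maps from block means
#'
#' Per masked voxel: Delta R2* and Delta R2 from the FB/BH mean-signal ratio
#' at the respective echo times (FB, the high-relaxation state, is the
#' "active" argument of [relaxation_change()], so both rates are positive
#' for a BOLD signal increase during BH), then `q` and the mean vessel
#' radius through the calibration curve. Voxels with nonpositive mean
#' signals are masked out and counted in the QC report; out-of-range `q`
#' values are clipped and flagged.
#'
#' @param ge_means,se_means Lists with `bh` and `fb` 3D arrays
#'   ([block_average()] output) for each echo.
#' @param echoes An [echo_times()].
#' @param curve A [fit_calibration()] curve.
#' @param mask 3D logical array of voxels to map.
#' @return An object of class `vsi_maps`: `dr2s`, `dr2`, `q`, `radius` 3D
#'   arrays (`NA` outside the final mask), `mask`, `out_of_range` flag plane
#'   and a `qc` list.
#' @export
compute_vsi <- function(ge_means, se_means, echoes, curve, mask) {
  stopifnot(inherits(echoes, "echo_times"),
            inherits(curve, "calibration_curve"))
  d <- dim(mask)
  ok <- mask & ge_means$bh > 0 & ge_means$fb > 0 &
    se_means$bh > 0 & se_means$fb > 0
  n_nonpos <- sum(mask & !ok)
  tmpl <- array(NA_real_, d)
  dr2s <- dr2 <- q <- radius <- tmpl
  dr2s[ok] <- relaxation_change(ge_means$fb[ok], ge_means$bh[ok],
                                echoes$te_ge)
  dr2[ok] <- relaxation_change(se_means$fb[ok], se_means$bh[ok],
                               echoes$te_se)
  q[ok] <- q_from_rates(dr2s[ok], dr2[ok])
  r_ok <- radius_from_q(curve, q[ok])
  radius[ok] <- r_ok
  oor <- array(FALSE, d)
  oor[ok] <- attr(r_ok, "clipped")
  structure(list(dr2s = dr2s, dr2 = dr2, q = q, radius = radius,
                 mask = ok, out_of_range = oor,
                 qc = list(n_mask_in = sum(mask),
                           n_nonpositive_signal = n_nonpos,
                           n_q_undefined = sum(ok & !is.finite(q)),
                           n_clipped = sum(oor))),
            class = "vsi_maps")
}

#' @export
print.vsi_maps <- function(x, ...) {
  cat(sprintf("<vsi_maps> %s voxels mapped (%d clipped, %d undefined q)\n",
              sum(x$mask), x$qc$n_clipped, x$qc$n_q_undefined))
  if (any(x$mask))
    cat(sprintf(
      "  median dR2* %.3g s^-1, dR2 %.3g s^-1, q %.3g, radius %.3g um\n",
      median(x$dr2s[x$mask]), median(x$dr2[x$mask]),
      median(x$q[x$mask], na.rm = TRUE),
      median(x$radius[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' Full dual-echo VSI mapping pipeline
#'
#' Smoothing, voxelwise GLM with the canonical HRF and temporal derivative
#' (plus optional motion nuisance regressors), joint GE+SE significance
#' masking, hemodynamic-lag compensation by a single global circular shift,
#' block averaging of BH and FB volumes, and conversion to Delta R2*,
#' Delta R2, `q` and radius maps.
#'
#' The circular shift is estimated from the mask-mean demeaned GE timecourse
#' by default (`lag_source = "signal"`); `"predicted"` uses the mask-mean
#' GLM-predicted task response instead, which tracks the regressor's own
#' shape and therefore compresses lags larger than the derivative can model.
#' The reported `lag_volumes` is the estimated shift minus the intrinsic lag
#' of the HRF-convolved regressor itself.
#'
#' @param ge,se GE and SE [echo_series()] on one grid.
#' @param design A [build_block_design()].
#' @param curve A calibration curve.
#' @param motion Optional nuisance regressor matrix (e.g. 6 motion columns).
#' @param fwhm Smoothing FWHM, mm (0 disables).
#' @param alpha Significance level for the joint mask.
#' @param transition_drop Volumes dropped after each state change in block
#'   averaging.
#' @param lag_source `"signal"` or `"predicted"` (see above).
#' @return List: `maps` ([compute_vsi()] result), `glm_ge`, `glm_se`,
#'   `mask`, `shift` (applied circular shift), `lag_volumes` (hemodynamic
#'   lag relative to the regressor), `labels` (shifted state labels).
#' @export
map_vsi <- function(ge, se, design, curve, motion = NULL, fwhm = 5,
                    alpha = 0.001, transition_drop = 2,
                    lag_source = c("signal", "predicted")) {
  lag_source <- match.arg(lag_source)
  stopifnot(inherits(ge, "echo_series"), inherits(se, "echo_series"))
  if (!identical(dim(ge$data), dim(se$data)))
    stop("invalid-argument: GE and SE grids differ")
  ge_s <- smooth_series(ge, fwhm)
  se_s <- smooth_series(se, fwhm)
  X <- build_design_matrix(design, nuisance = motion)
  glm_ge <- fit_glm(ge_s, X)
  glm_se <- fit_glm(se_s, X)
  mask <- joint_significance_mask(glm_ge, glm_se, alpha)
  d <- dim(ge$data)
  if (any(mask)) {
    vmask <- as.vector(mask)
    tc <- if (lag_source == "signal") {
      colMeans(matrix(ge_s$data, prod(d[1:3]), d[4])[vmask, , drop = FALSE])
    } else {
      rowMeans(glm_ge$predicted[, vmask, drop = FALSE])
    }
    shift <- lag_shift(tc, design)
  } else {
    warning("empty joint mask; no lag compensation applied")
    shift <- 0L
  }
  s0 <- lag_shift(hrf_regressor(design)[, "hrf"], design)
  labels <- shift_labels(design, shift)
  ge_m <- block_average(ge_s, labels, transition_drop)
  se_m <- block_average(se_s, labels, transition_drop)
  maps <- compute_vsi(ge_m, se_m, echo_times(te_ge = ge$te, te_se = se$te,
                                             tr = design$tr),
                      curve, mask)
  list(maps = maps, glm_ge = glm_ge, glm_se = glm_se, mask = mask,
       shift = shift, lag_volumes = (shift - s0) %% design$n_volumes,
       labels = labels)
}

#' Gray/white matter region summary and comparison
#'
#' Per-subject mean and standard deviation of the mapped vessel radius in
#' two regions, and (for more than one subject) a paired Wilcoxon
#' signed-rank test of the region means across subjects. All-zero paired
#' differences are degenerate and reported as such (`p = NA`).
#'
#' @param maps A `vsi_maps` or a list of them (one per subject).
#' @param gm_mask,wm_mask 3D logical region masks.
#' @return List: `per_subject` data frame (gm/wm mean, sd, n), `p_value`,
#'   `note`.
#' @export
region_summary <- function(maps, gm_mask, wm_mask) {
  if (inherits(maps, "vsi_maps")) maps <- list(maps)
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    gm <- m$radius[gm_mask & m$mask & is.finite(m$radius)]
    wm <- m$radius[wm_mask & m$mask & is.finite(m$radius)]
    if (length(gm) == 0 || length(wm) == 0)
      stop("invalid-argument: empty region-mask intersection for subject ", i)
    data.frame(subject = i, gm_mean = mean(gm), gm_sd = stats::sd(gm),
               gm_n = length(gm), wm_mean = mean(wm),
               wm_sd = stats::sd(wm), wm_n = length(wm))
  })
  per <- do.call(rbind, rows)
  p <- NA_real_
  note <- NULL
  if (nrow(per) > 1) {
    diffs <- per$gm_mean - per$wm_mean
    if (all(diffs == 0)) {
      note <- "all paired differences are zero; signed-rank test degenerate"
    } else {
      p <- wilcox.test(per$gm_mean, per$wm_mean, paired = TRUE)$p.value
    }
  }
  list(per_subject = per, p_value = p, note = note)
}

#' Write VSI maps as NIfTI plus a QC report
#'
#' Writes `dr2s`, `dr2`, `q`, `radius`, `mask` and `out_of_range` volumes
#' (NA encoded as 0 in the flag/rate maps is avoided by writing NaN) and a
#' `qc.json`.
#'
#' @param maps A `vsi_maps`.
#' @param dir Output directory (created if needed).
#' @param voxel_dim Voxel dimensions, mm.
#' @return `dir`, invisibly.
#' @export
write_vsi_maps <- function(maps, dir, voxel_dim = c(3.4, 3.4, 3.5)) {
  stopifnot(inherits(maps, "vsi_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- voxel_dim
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(maps$dr2s, "dr2s")
  wr(maps$dr2, "dr2")
  wr(maps$q, "q")
  wr(maps$radius, "radius")
  wr(maps$mask, "mask")
  wr(maps$out_of_range, "out_of_range")
  jsonlite::write_json(maps$qc, file.path(dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a block design and echo times from YAML
#'
#' Keys: `n_volumes`, `volumes_per_cycle`, `volumes_per_half`, `tr_ms`,
#' `te_ge_ms`, `te_se_ms`.
#'
#' @param path YAML file.
#' @return List with `design` ([build_block_design()]) and `echoes`
#'   ([echo_times()]).
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  list(design = build_block_design(
         n_volumes = y$n_volumes %||% 110,
         volumes_per_cycle = y$volumes_per_cycle %||% 20,
         volumes_per_half = y$volumes_per_half %||% 10,
         tr = y$tr_ms %||% 1700),
       echoes = echo_times(te_ge = y$te_ge_ms %||% 27.08,
                           te_se = y$te_se_ms %||% 90,
                           tr = y$tr_ms %||% 1700))
}

#' Read a motion-parameter table
#'
#' Tab-separated table of nuisance regressors (six rigid-body columns by
#' convention), one row per volume.
#'
#' @param path TSV file.
#' @param header Does the file have a header line?
#' @return Numeric matrix.
#' @export
read_motion_tsv <- function(path, header = FALSE) {
  as.matrix(read.delim(path, header = header))
}
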