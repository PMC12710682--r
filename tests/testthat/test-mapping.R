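tiny_design <- function(n = 40, half = 5, tr = 1700) {
  build_block_design(n_volumes = n, volumes_per_cycle = 2 * half,
                     volumes_per_half = half, tr = tr)
}

test_that("the default paradigm matches the breath-hold protocol", {
  d <- build_block_design()
  expect_equal(d$n_volumes, 110L)
  expect_equal(d$volumes_per_cycle * d$tr, 34000) # 34 s per cycle
  expect_equal(d$volumes_per_half * d$tr, 17000)  # 17 s per half
  expect_equal(d$states[1:20], rep(c("FB", "BH"), each = 10)) # BH second
  expect_equal(sum(d$states == "BH"), 50) # five full cycles + FB half
  expect_error(build_block_design(volumes_per_half = 0), "invalid-argument")
  expect_error(build_block_design(n_volumes = 105), "invalid-argument")
  expect_error(build_block_design(volumes_per_cycle = 30,
                                  volumes_per_half = 10), "invalid-argument")
})

test_that("HRF regressor peaks after onset and is orthogonal to its derivative", {
  d <- tiny_design(n = 60, half = 15, tr = 1000)
  X <- hrf_regressor(d)
  expect_equal(max(abs(X[, "hrf"])), 1)
  expect_lt(abs(sum(X[, "hrf"] * X[, "deriv"])), 1e-10)
  # short single-block design: peak 4-8 s after BH onset
  d1 <- d
  d1$states <- rep("FB", 60)
  d1$states[16:17] <- "BH"
  h1 <- hrf_regressor(d1)[, "hrf"]
  peak_s <- (which.max(h1) - 16) * 1 # tr = 1 s
  expect_gte(peak_s, 4)
  expect_lte(peak_s, 8)
  # all-FB design: zero regressor
  d0 <- d
  d0$states <- rep("FB", 60)
  expect_true(all(hrf_regressor(d0) == 0))
})

test_that("Gaussian smoothing preserves constants and has the right width", {
  arr <- array(7, c(16, 16, 8, 2))
  s <- echo_series(arr, tr = 1700, voxel_dim = c(3.4, 3.4, 3.5), te = 27.08,
                   label = "GE")
  sm <- smooth_series(s, fwhm = 5)
  expect_equal(sm$data, arr, tolerance = 1e-12)
  expect_identical(smooth_series(s, fwhm = 0)$data, arr)
  expect_error(smooth_series(s, fwhm = -1), "invalid-argument")

  # impulse response FWHM ~ 5 mm on a 1 mm grid
  imp <- array(0, c(41, 41, 41, 1))
  imp[21, 21, 21, 1] <- 1
  si <- echo_series(imp, tr = 1000, voxel_dim = c(1, 1, 1), te = 27.08,
                    label = "GE")
  prof <- smooth_series(si, fwhm = 5)$data[, 21, 21, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above)
  hi <- max(above)
  right <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  left <- lo - (prof[lo] - half) / (prof[lo] - prof[lo - 1])
  width <- right - left
  expect_equal(width, 5, tolerance = 0.1)
})

test_that("the GLM recovers noiseless effects and controls type-I error", {
  d <- tiny_design(n = 40, half = 5)
  X <- build_design_matrix(d)
  beta <- c(100, 4, -1)
  y <- drop(X %*% beta)
  arr <- array(rep(y, each = 8), c(2, 2, 2, 40))
  s <- echo_series(arr, 1700, c(3, 3, 3), 27.08, "GE")
  fit <- fit_glm(s, X)
  expect_equal(unname(fit$beta[, 1]), beta, tolerance = 1e-9)
  expect_equal(max(fit$sigma2), 0, tolerance = 1e-12)
  expect_equal(drop(fit$predicted[, 1]), drop(X[, 2:3] %*% beta[2:3]),
               tolerance = 1e-9)

  # constant series: guarded t = 0, p = 1
  cs <- echo_series(array(5, c(2, 2, 1, 40)), 1700, c(3, 3, 3), 27.08, "GE")
  cfit <- fit_glm(cs, X)
  expect_true(all(cfit$tstat == 0))
  expect_true(all(cfit$pval == 1))

  # collinear design is refused with the culprit named
  Xbad <- cbind(X, dup = X[, "hrf"])
  expect_error(fit_glm(s, Xbad), "collinear")

  # pure noise: two-sided p < 0.001 in ~0.1% of voxels
  set.seed(31)
  noise <- array(rnorm(24 * 24 * 12 * 40, 100, 5), c(24, 24, 12, 40))
  nfit <- fit_glm(echo_series(noise, 1700, c(3, 3, 3), 27.08, "GE"), X)
  rate <- mean(nfit$pval < 0.001)
  expect_lt(rate, 0.003)
  pos_rate <- mean(nfit$pval < 0.001 & nfit$beta["hrf", ] > 0)
  expect_lt(pos_rate, 0.002)
})

test_that("joint mask requires a positive response in both echoes", {
  d <- tiny_design(n = 40, half = 5)
  X <- build_design_matrix(d)
  set.seed(32)
  mkfit <- function(amp) {
    y <- 100 + amp * X[, "hrf"]
    arr <- array(rep(y, each = 64), c(4, 4, 4, 40)) +
      array(rnorm(64 * 40, 0, 1), c(4, 4, 4, 40))
    fit_glm(echo_series(arr, 1700, c(3, 3, 3), 27.08, "GE"), X)
  }
  strong <- mkfit(20)
  null <- mkfit(0)
  negat <- mkfit(-20)
  expect_true(all(joint_significance_mask(strong, strong)))
  expect_false(any(joint_significance_mask(strong, null)))   # SE missing
  expect_false(any(joint_significance_mask(null, strong)))   # GE missing
  expect_false(any(joint_significance_mask(strong, negat)))  # wrong sign
  expect_error(joint_significance_mask(strong, fit_glm(
    echo_series(array(1, c(2, 2, 2, 40)), 1700, c(3, 3, 3), 27.08, "GE"), X)),
    "invalid-argument")
})

test_that("circular lag estimation finds synthetic delays exactly", {
  d <- build_block_design()
  box <- as.numeric(d$states == "BH")
  expect_identical(lag_shift(box, d), 0L)
  delayed <- box[((seq_len(110) - 1 - 3) %% 110) + 1]
  expect_identical(lag_shift(delayed, d), 3L)
  set.seed(33)
  s <- lag_shift(rnorm(110), d)
  expect_gte(s, 0)
  expect_lt(s, 110)
  expect_warning(s0 <- lag_shift(rep(1, 110), d), "flat")
  expect_identical(s0, 0L)
  expect_identical(shift_labels(d, 3)[4:13], rep("FB", 10))
})

test_that("block averaging recovers plateaus and drops transitions", {
  d <- tiny_design(n = 40, half = 5)
  lab <- d$states
  y <- ifelse(lab == "BH", 110, 90)
  arr <- array(rep(y, each = 4), c(2, 2, 1, 40))
  s <- echo_series(arr, 1700, c(3, 3, 3), 27.08, "GE")
  m0 <- block_average(s, lab, transition_drop = 0)
  expect_equal(as.numeric(m0$bh), rep(110, 4))
  expect_equal(as.numeric(m0$fb), rep(90, 4))
  m2 <- block_average(s, lab, transition_drop = 2)
  expect_equal(as.numeric(m2$bh), rep(110, 4))
  expect_equal(sum(m2$used), 40 - 2 * 8)
  cs <- echo_series(array(5, c(2, 2, 1, 40)), 1700, c(3, 3, 3), 27.08, "GE")
  mc <- block_average(cs, lab)
  expect_equal(mc$bh, mc$fb)
  expect_error(block_average(s, rep("BH", 40)), "invalid-argument")
  expect_error(block_average(s, lab[1:10]), "invalid-argument")

  # unbiasedness under iid noise
  set.seed(34)
  diffs <- replicate(20, {
    sn <- s
    sn$data <- s$data + array(rnorm(length(s$data), 0, 5), dim(s$data))
    m <- block_average(sn, lab)
    mean(m$bh) - 110
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(20))
})

test_that("rate maps compose the log-ratio and calibration lookup", {
  d3 <- c(2, 2, 1)
  mask <- array(TRUE, d3)
  ge <- list(bh = array(1, d3), fb = array(0.9, d3))
  se <- list(bh = array(1, d3), fb = array(0.9, d3))
  cv <- make_curve(c(5, 2), q_range = c(0.5, 10))
  maps <- compute_vsi(ge, se, echo_times(), cv, mask)
  expect_equal(as.numeric(maps$dr2s), rep(3.890713, 4), tolerance = 1e-6)
  expect_equal(as.numeric(maps$dr2), rep(1.170672, 4), tolerance = 1e-6)
  expect_equal(as.numeric(maps$q), rep(90 / 27.08, 4), tolerance = 1e-12)
  expect_equal(as.numeric(maps$radius), rep(5 + 2 * log(90 / 27.08), 4),
               tolerance = 1e-9)

  # voxels outside the mask stay undefined
  mask2 <- mask
  mask2[1, 1, 1] <- FALSE
  maps2 <- compute_vsi(ge, se, echo_times(), cv, mask2)
  expect_true(is.na(maps2$q[1, 1, 1]))
  expect_false(maps2$mask[1, 1, 1])

  # nonpositive means are masked out and counted
  ge_bad <- ge
  ge_bad$fb[2, 1, 1] <- 0
  maps3 <- compute_vsi(ge_bad, se, echo_times(), cv, mask)
  expect_false(maps3$mask[2, 1, 1])
  expect_equal(maps3$qc$n_nonpositive_signal, 1)
})

test_that("noise-free block series invert the signal equation exactly", {
  spec <- phantom_spec(dims = c(10, 10, 4),
                       regions = phantom_regions(c(10, 10, 4)),
                       noise_sd = c(ge = 0, se = 0), lag = 2,
                       response = "boxcar", seed = 9)
  ph <- make_phantom(spec)
  shift <- lag_shift(colMeans(matrix(ph$ge$data, 400, 110)), spec$design)
  expect_identical(shift, 2L)
  lab <- shift_labels(spec$design, shift)
  gm <- block_average(ph$ge, lab)
  sm <- block_average(ph$se, lab)
  cv <- make_curve(c(5, 2), q_range = c(0.1, 100))
  maps <- compute_vsi(gm, sm, spec$echoes, cv, ph$truth$responding)
  idx <- ph$truth$responding
  expect_equal(maps$dr2s[idx], ph$truth$dr2s[idx], tolerance = 1e-12)
  expect_equal(maps$dr2[idx], ph$truth$dr2[idx], tolerance = 1e-12)
})

test_that("doubling the true contrast doubles the recovered contrast", {
  base <- phantom_spec(dims = c(20, 20, 4),
                       regions = phantom_regions(c(20, 20, 4)), seed = 10)
  dbl <- base
  dbl$dr2s_by_region <- base$dr2s_by_region * 2
  dbl$dr2_by_region <- base$dr2_by_region * 2
  cv <- make_curve(c(5, 2), q_range = c(0.1, 100))
  med <- function(spec) {
    ph <- make_phantom(spec)
    res <- map_vsi(ph$ge, ph$se, spec$design, cv, fwhm = 0)
    gm <- spec$regions == 2 & res$mask
    median(res$maps$dr2s[gm])
  }
  expect_equal(med(dbl) / med(base), 2, tolerance = 0.05)
})

test_that("region summaries separate a simulated cohort", {
  d3 <- c(6, 6, 2)
  gm_mask <- array(rep(c(TRUE, FALSE), each = 36), d3)
  wm_mask <- !gm_mask
  set.seed(35)
  mk <- function(gm_mu, wm_mu) {
    r <- array(NA_real_, d3)
    r[gm_mask] <- rnorm(36, gm_mu, 0.3)
    r[wm_mask] <- rnorm(36, wm_mu, 0.3)
    structure(list(radius = r, mask = array(TRUE, d3)), class = "vsi_maps")
  }
  cohort <- lapply(1:14, function(i) mk(7.2, 6.1))
  rs <- region_summary(cohort, gm_mask, wm_mask)
  expect_equal(nrow(rs$per_subject), 14)
  expect_lt(rs$p_value, 0.01)
  expect_gt(mean(rs$per_subject$gm_mean), mean(rs$per_subject$wm_mean))

  single <- mk(7, 6)
  one <- array(FALSE, d3)
  one[1, 1, 1] <- TRUE
  rs1 <- region_summary(single, one, wm_mask)
  expect_equal(rs1$per_subject$gm_mean, single$radius[1, 1, 1])

  degen <- region_summary(cohort, gm_mask, gm_mask)
  expect_true(is.na(degen$p_value))
  expect_match(degen$note, "degenerate")
  expect_error(region_summary(single, array(FALSE, d3), wm_mask),
               "invalid-argument")
})

test_that("series, design and motion files round-trip through disk", {
  arr <- array(runif(4 * 4 * 2 * 6, 50, 150), c(4, 4, 2, 6))
  s <- echo_series(arr, tr = 1700, voxel_dim = c(3.4, 3.4, 3.5), te = 27.08,
                   label = "GE")
  p <- tempfile(fileext = ".nii.gz")
  write_echo_series(s, p)
  back <- read_echo_series(p, te = 27.08, label = "GE", tr = 1700)
  expect_equal(back$data, arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_dim, s$voxel_dim, tolerance = 1e-5)
  unlink(p)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_volumes: 110", "volumes_per_cycle: 20",
               "volumes_per_half: 10", "tr_ms: 1700",
               "te_ge_ms: 27.08", "te_se_ms: 90"), yml)
  dy <- read_design_yaml(yml)
  expect_equal(dy$design$n_volumes, 110L)
  expect_equal(dy$echoes$te_ge, 27.08)
  unlink(yml)

  mot <- matrix(rnorm(110 * 6), 110, 6)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(mot, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  m <- read_motion_tsv(tsv)
  expect_equal(dim(m), c(110L, 6L))
  X <- build_design_matrix(build_block_design(), nuisance = m)
  expect_equal(ncol(X), 9)
  expect_lt(max(abs(colMeans(X[, 4:9]))), 1e-12)
  unlink(tsv)
})

test_that("VSI maps are written as NIfTI volumes with a QC report", {
  d3 <- c(4, 4, 2)
  mask <- array(TRUE, d3)
  ge <- list(bh = array(1, d3), fb = array(0.9, d3))
  cv <- make_curve(c(5, 2), q_range = c(0.5, 10))
  maps <- compute_vsi(ge, ge, echo_times(), cv, mask)
  dir <- tempfile()
  write_vsi_maps(maps, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "dr2s.nii.gz", "dr2.nii.gz", "q.nii.gz", "radius.nii.gz",
    "mask.nii.gz", "out_of_range.nii.gz", "qc.json")))))
  q_back <- RNifti::readNifti(file.path(dir, "q.nii.gz"))
  expect_equal(as.array(q_back), unclass(maps$q), tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
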