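test_that("vessel size index guards division and is scale invariant", {
  expect_equal(q_from_rates(3, 1), 3)
  expect_equal(q_from_rates(3.891, 0.5), 7.782)
  expect_true(is.na(q_from_rates(1, 0)))
  expect_true(is.na(q_from_rates(-1, 2)))
  expect_true(is.na(q_from_rates(NA, 2)))
  set.seed(1)
  a <- runif(50, 0.1, 5)
  b <- runif(50, 0.1, 5)
  k <- runif(50, 0.01, 100)
  expect_equal(q_from_rates(k * a, k * b), q_from_rates(a, b),
               tolerance = 1e-12)
})

test_that("noiseless degree-6 rows are recovered exactly", {
  truth <- c(-2.70, 24.82, -27.26, 20.49, -5.89, 0.64, 0)
  q <- exp(seq(log(1.2), log(30), length.out = 20))
  tab <- data.frame(radius = poly_eval(truth, q), q = q)
  cv <- fit_calibration(tab, order = 6)
  expect_equal(as.numeric(cv$coefficients), truth,
               tolerance = 1e-6 * max(abs(truth)))
  expect_equal(as.numeric(radius_from_q(cv, q)), tab$radius,
               tolerance = 1e-8)
  expect_true(cv$converged)
})

test_that("bisquare weighting suppresses a gross outlier", {
  truth <- c(-2.70, 24.82, -27.26, 20.49, -5.89, 0.64, 0)
  q <- exp(seq(log(1.2), log(30), length.out = 14))
  clean <- data.frame(radius = poly_eval(truth, q), q = q)
  dirty <- clean
  dirty$radius[7] <- dirty$radius[7] * 10
  cv_clean <- fit_calibration(clean)
  cv_dirty <- fit_calibration(dirty)
  rel <- abs(radius_from_q(cv_dirty, q) - radius_from_q(cv_clean, q)) /
    abs(radius_from_q(cv_clean, q))
  expect_lt(max(rel), 0.05)
  expect_lt(cv_dirty$weights[7], 0.01) # the outlier is effectively removed
})

test_that("too few rows and singular designs are refused", {
  expect_error(fit_calibration(data.frame(radius = 1:5,
                                          q = seq(2, 3, length.out = 5))),
               "invalid-argument")
  expect_error(fit_calibration(data.frame(radius = 1:10, q = rep(2, 10))),
               "fit-failure")
})

test_that("robust fit agrees with an independent bisquare implementation", {
  library(MASS)
  truth <- c(-2.70, 24.82, -27.26, 20.49, -5.89, 0.64, 0)
  q <- exp(seq(log(1.2), log(30), length.out = 25))
  set.seed(42)
  y <- poly_eval(truth, q) + rnorm(25, 0, 0.3)
  y[5] <- y[5] * 8
  tab <- data.frame(radius = y, q = q)
  cv <- fit_calibration(tab)
  V <- outer(log(q), 0:6, `^`)
  ref <- MASS::rlm(V, y, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  mine <- radius_from_q(cv, q)
  theirs <- pmax(drop(V %*% coef(ref)), 0)
  expect_lt(max(abs(mine - theirs) / pmax(abs(theirs), 1)), 0.05)
})

test_that("curve evaluation clips, floors and masks", {
  cv <- make_curve(c(5, 2), q_range = c(0.5, 10))
  expect_equal(as.numeric(radius_from_q(cv, exp(1))), 7)
  expect_equal(as.numeric(radius_from_q(cv, 1)), 5) # ln 1 = 0 -> P0
  r <- radius_from_q(cv, c(-1, 0, NA, 20, 2))
  expect_true(all(is.na(r[1:3])))
  expect_equal(r[4], as.numeric(radius_from_q(cv, 10)),
               ignore_attr = TRUE) # clipped to q_max
  expect_identical(attr(r, "clipped"), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  neg <- make_curve(c(-5), q_range = c(0.5, 10))
  expect_equal(as.numeric(radius_from_q(neg, 2)), 0) # floored
})

test_that("reference coefficients expose both printed interpretations", {
  lo <- reference_curve("p0_p5")
  hi <- reference_curve("p1_p6")
  expect_equal(as.numeric(radius_from_q(lo, 1)), 0)   # P0 = -2.70, floored
  expect_equal(lo$coefficients[["P0"]], -2.70)
  expect_equal(lo$coefficients[["P6"]], 0)
  expect_equal(hi$coefficients[["P0"]], 0)
  expect_equal(hi$coefficients[["P6"]], 0.64)
  expect_true(lo$reference)
  # plausible microvascular radius at a typical gray-matter q
  expect_equal(as.numeric(radius_from_q(lo, 2)), 6.9732, tolerance = 1e-4)
})

test_that("curve and table serialization round-trip", {
  cv <- make_curve(c(1, 2, 3, 4, 5, 6, 7), q_range = c(1.5, 25))
  path <- tempfile(fileext = ".json")
  write_curve_json(cv, path, provenance = "test")
  back <- read_curve_json(path)
  expect_equal(as.numeric(back$coefficients), as.numeric(cv$coefficients))
  expect_equal(back$q_range, cv$q_range)
  expect_equal(back$order, 6L)
  unlink(path)

  tab <- data.frame(radius = c(1, 2), dr2s = c(0.5, 1), dr2 = c(0.4, 0.6),
                    q = c(1.25, 5 / 3), valid = c(TRUE, TRUE))
  class(tab) <- c("calibration_table", "data.frame")
  p2 <- tempfile(fileext = ".tsv")
  write_calibration_tsv(tab, p2)
  back2 <- read_calibration_tsv(p2)
  expect_equal(back2$q, tab$q, tolerance = 1e-12)
  unlink(p2)
})

test_that("a scaled sweep produces positive, reproducible physiology", {
  tab <- sweep_calibration(c(3, 30), n_spins = 1500, seed = 5)
  expect_s3_class(tab, "calibration_table")
  expect_true(all(tab$valid))
  expect_true(all(tab$dr2s > 0 & tab$dr2 > 0 & tab$q > 0))
  expect_true(all(tab$dr2s > tab$dr2)) # GE change exceeds SE change
  expect_gt(tab$q[2], tab$q[1])        # larger vessels, larger q
  tab2 <- sweep_calibration(c(3, 30), n_spins = 1500, seed = 5)
  expect_equal(tab, tab2, tolerance = 0)
})

test_that("identical FB and BH states yield flagged, undefined rows", {
  same <- fb_blood_model()
  tab <- sweep_calibration(3, fb = same, bh = same, n_spins = 400, seed = 6)
  expect_false(any(tab$valid))
  expect_true(all(is.na(tab$q)))
  expect_equal(tab$dr2s, 0)
  expect_equal(tab$dr2, 0)
})
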