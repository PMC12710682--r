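test_that("spin seeding is extravascular, uniform, and density-derived", {
  net <- small_test_network(seed = 41)
  pos <- seed_spins(net, n_spins = 3000, seed = 2)
  expect_equal(nrow(pos), 3000)
  expect_false(any(is_intravascular(net, pos)))

  # empty network: uniform over the whole voxel (octant chi-square)
  emp <- empty_network(edge = 20)
  pos0 <- seed_spins(emp, n_spins = 8000, seed = 3)
  oct <- table(1 + (pos0[, 1] > 10) + 2 * (pos0[, 2] > 10) +
                 4 * (pos0[, 3] > 10))
  expect_length(oct, 8)
  expect_gt(stats::chisq.test(as.numeric(oct))$p.value, 1e-4)

  # density-derived count
  pos_d <- seed_spins(emp, spin_density = 0.05, seed = 4)
  expect_equal(nrow(pos_d), round(0.05 * 20^3))
  expect_error(seed_spins(emp, spin_density = 5, max_auto_spins = 1000),
               "invalid-argument")
})

test_that("static spins accrue phase linearly and refocus perfectly", {
  net <- small_test_network(seed = 41)
  fb <- fb_blood_model()
  tis0 <- tissue_model(D = 0)
  cfg <- sim_config(duration = 90, seed = 5, se_echo_time = 90)
  pos <- seed_spins(net, n_spins = 500, seed = 5)
  times <- c(10, 45, 90)
  tr <- evolve_phases(pos, net, net, tis0, cfg, times, model = fb)
  w0 <- sample_field(net, pos, fb)
  expect_equal(tr$phases, outer(w0, times * 1e-3), tolerance = 1e-15)
  se <- se_signal(tr, net, tis0, fb, te_se = 90)
  expect_lt(abs(se$e_ev[3] - 1), 1e-12)
  ge <- ge_signal(tr, net, tis0, fb)
  expect_lt(ge$e_ev[3], 1) # static GE dephasing is irreversible
})

test_that("zero field leaves phases at zero and the compartment model intact", {
  net <- manual_network(c(60, 60, 0), c(0, 0, 1), 5, 120, fraction = 0.04)
  zero_grid <- build_field_grid(empty_network(120), fb_blood_model(),
                                resolution = 4)
  tis <- tissue_model(D = 1)
  cfg <- sim_config(duration = 90, seed = 6, se_echo_time = 90)
  pos <- seed_spins(net, n_spins = 400, seed = 6)
  tr <- evolve_phases(pos, net, zero_grid, tis, cfg, c(27.08, 45, 90))
  expect_true(all(tr$phases == 0))
  fb <- fb_blood_model()
  ge <- ge_signal(tr, net, tis, fb)
  se <- se_signal(tr, net, tis, fb, te_se = 90)
  t <- ge$time_ms
  expect_equal(ge$magnitude,
               0.96 * exp(-t / 83.5) + 0.04 * exp(-t / 32.3),
               tolerance = 1e-12)
  expect_equal(se$magnitude, ge$magnitude, tolerance = 1e-12)
  # dropping the blood pool leaves pure tissue decay
  ge0 <- ge_signal(tr, net, tis, include_blood = FALSE)
  expect_equal(ge0$magnitude, exp(-t / 83.5), tolerance = 1e-12)
})

test_that("free diffusion follows the 2 D t displacement law", {
  emp <- empty_network(edge = 200)
  tis <- tissue_model(D = 1)
  cfg <- sim_config(duration = 20, seed = 7)
  pos <- seed_spins(emp, n_spins = 4000, seed = 7)
  tr <- evolve_phases(pos, emp, build_field_grid(emp, fb_blood_model(), 20),
                      tis, cfg, times = 20)
  v <- apply(tr$displacement, 2, stats::var)
  expect_equal(as.numeric(v), rep(2 * 1 * 20, 3), tolerance = 0.12)
})

test_that("diffusion breaks spin-echo refocusing but SE stays above GE", {
  net <- small_test_network(seed = 41)
  fb <- fb_blood_model()
  tis <- tissue_model(D = 1)
  cfg <- sim_config(duration = 90, seed = 8, se_echo_time = 90)
  pos <- seed_spins(net, n_spins = 4000, seed = 8)
  g <- build_field_grid(net, fb, resolution = 0.8)
  tr <- evolve_phases(pos, net, g, tis, cfg, c(27.08, 45, 90))
  ge <- ge_signal(tr, net, tis, fb)
  se <- se_signal(tr, net, tis, fb, te_se = 90)
  expect_true(all(ge$e_ev <= 1 + 1e-12))
  expect_true(all(se$e_ev <= 1 + 1e-12))
  # batch-means MC error on the SE factor at TE
  batches <- split(seq_len(4000), rep(1:10, length.out = 4000))
  eb <- vapply(batches, function(i)
    bhvsi:::dephasing_factor(bhvsi:::se_phases(tr, 90), i)[3], numeric(1))
  mc_se <- sd(eb) / sqrt(10)
  expect_lt(se$e_ev[3], 1 - 3 * mc_se) # refocusing genuinely incomplete
  expect_gt(se$e_ev[3], ge$e_ev[3])    # but still better than GE
})

test_that("fixed seeds give bit-identical trajectories and MC error shrinks", {
  net <- small_test_network(seed = 41)
  fb <- fb_blood_model()
  tis <- tissue_model(D = 1)
  g <- build_field_grid(net, fb, resolution = 1.6)
  cfg <- sim_config(duration = 30, seed = 9)
  pos <- seed_spins(net, n_spins = 300, seed = 9)
  t1 <- evolve_phases(pos, net, g, tis, cfg, c(15, 30))
  t2 <- evolve_phases(pos, net, g, tis, cfg, c(15, 30))
  expect_identical(t1$phases, t2$phases)

  e_at <- function(n, seed) {
    p <- seed_spins(net, n_spins = n, seed = seed)
    tr <- evolve_phases(p, net, g, tis,
                        sim_config(duration = 30, seed = seed), 30)
    bhvsi:::dephasing_factor(tr$phases)[1]
  }
  seeds <- 1:16
  r <- sd(vapply(seeds + 100, function(s) e_at(800, s), numeric(1))) /
    sd(vapply(seeds, function(s) e_at(400, s), numeric(1)))
  expect_gt(r, 0.35) # ~1/sqrt(2) with wide stochastic margin
  expect_lt(r, 1.1)
})

test_that("relaxation change matches hand-computed log ratios", {
  expect_equal(relaxation_change(0.9, 1, 27.08), 3.890713, tolerance = 1e-6)
  expect_equal(relaxation_change(0.9, 1, 90), 1.170672, tolerance = 1e-6)
  expect_equal(relaxation_change(0.7, 0.7, 50), 0)
  expect_error(relaxation_change(0, 1, 50), "invalid-argument")
  expect_error(relaxation_change(1, -2, 50), "invalid-argument")
})

test_that("trace TSV export writes the expected columns", {
  net <- manual_network(c(60, 60, 0), c(0, 0, 1), 5, 120, fraction = 0.04)
  fb <- fb_blood_model()
  tis0 <- tissue_model(D = 0)
  pos <- seed_spins(net, n_spins = 200, seed = 10)
  tr <- evolve_phases(pos, net, net, tis0,
                      sim_config(duration = 90, seed = 10), c(45, 90),
                      model = fb)
  ge <- ge_signal(tr, net, tis0, fb)
  se <- se_signal(tr, net, tis0, fb, te_se = 90)
  path <- tempfile(fileext = ".tsv")
  write_trace_tsv(ge, se, path)
  back <- read.delim(path)
  expect_named(back, c("time_ms", "ge", "se", "e_ev_ge", "e_ev_se"))
  expect_equal(back$ge, ge$magnitude, tolerance = 1e-6)
  unlink(path)
})

test_that("invalid time grids and missing half-echo times are rejected", {
  net <- small_test_network(seed = 41)
  pos <- seed_spins(net, n_spins = 10, seed = 1)
  cfg <- sim_config(duration = 90, seed = 1)
  expect_error(evolve_phases(pos, net, net, tissue_model(0), cfg,
                             c(30, 20), model = fb_blood_model()),
               "invalid-argument")
  tr <- evolve_phases(pos, net, net, tissue_model(0), cfg, c(30, 90),
                      model = fb_blood_model())
  expect_error(se_signal(tr, net, tissue_model(0), fb_blood_model(),
                         te_se = 90), "invalid-argument")
  expect_error(sim_config(duration = 50, se_echo_time = 90),
               "invalid-argument")
})
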