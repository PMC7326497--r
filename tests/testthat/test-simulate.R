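# Forward model: kinetics, rendering, noise, determinism, fixtures.

test_that("membrane signal follows the lag/linear/plateau form", {
  p <- kinetic_params(lag_min = 5, rate_au_per_min = 10, plateau_au = 1000)
  expect_equal(membrane_signal(0, p), 0)
  expect_equal(membrane_signal(6, p), 10)  # unit time on the linear segment
  # curvature coupling: r_eff = rate + b / R
  pc <- kinetic_params(lag_min = 5, rate_au_per_min = 1, plateau_au = 1000,
                       curvature_coupling_b = 5)
  expect_equal(membrane_signal(7, pc, radius_um = 10), 3.0)
  # inactive enzyme is valid, not an error
  p0 <- kinetic_params(rate_au_per_min = 0, curvature_coupling_b = 0)
  expect_equal(membrane_signal(c(0, 50, 500), p0), c(0, 0, 0))
})

test_that("membrane signal is continuous, non-decreasing and bounded (property)", {
  set.seed(42)
  tgrid <- seq(0, 200, by = 0.05)
  for (i in 1:25) {
    p <- kinetic_params(lag_min = runif(1, 0, 30),
                        rate_au_per_min = runif(1, 0, 20),
                        plateau_au = runif(1, 1, 500),
                        curvature_coupling_b = runif(1, 0, 30))
    r <- runif(1, 1, 30)
    s <- membrane_signal(tgrid, p, r)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s <= p$plateau_au + 1e-12))
    expect_lt(max(abs(diff(s))), (p$rate_au_per_min + p$curvature_coupling_b) * 0.05 + 1e-9)
  }
})

test_that("baseline haze saturates exponentially", {
  p <- kinetic_params(baseline_max_au = 100, baseline_tau_min = 7)
  expect_equal(baseline_signal(0, p), 0)
  expect_equal(baseline_signal(7, p), 100 * (1 - exp(-1)))
  expect_lt(abs(baseline_signal(1e6, p) - 100), 1e-6)
  expect_error(kinetic_params(baseline_tau_min = 0), "baseline_tau_min")
})

test_that("rendered frames match the analytic forward model", {
  # no vesicles, no haze, no noise -> all-zero reporter
  p0 <- kinetic_params(baseline_max_au = 0)
  sc0 <- simulation_scene(image_shape = c(32, 32), pixel_size_um = 0.25,
                          guvs = data.frame(guv_id = character(0),
                                            center_row_um = numeric(0),
                                            center_col_um = numeric(0),
                                            radius_um = numeric(0)),
                          psf_sigma_um = 0, photon_gain = Inf,
                          read_noise_sd = 0, kinetics = p0, seed = 1)
  fr0 <- render_frame(sc0, 0)
  expect_true(all(fr0$noisy == 0))

  # one vesicle, crisp optics, pre-lag: membrane nonzero only on the annulus,
  # reporter zero
  sc1 <- simulation_scene(image_shape = c(120, 120), pixel_size_um = 0.25,
                          guvs = data.frame(guv_id = "g1", center_row_um = 15,
                                            center_col_um = 15, radius_um = 10),
                          psf_sigma_um = 0, photon_gain = Inf,
                          read_noise_sd = 0,
                          kinetics = kinetic_params(baseline_max_au = 0),
                          seed = 1)
  fr1 <- render_frame(sc1, 0)
  ann <- raster_annulus(c(120, 120), (15 / 0.25) + 0.5 * c(1, 1), 40, 1)
  expect_true(all(fr1$noisy[2, , ] == 0))
  expect_true(all((fr1$noisy[1, , ] > 0) == ann))

  # mean over the true annulus equals signal + haze to 1e-6
  kin <- tiny_kinetics()
  sc2 <- simulation_scene(image_shape = c(120, 120), pixel_size_um = 0.25,
                          guvs = data.frame(guv_id = "g1", center_row_um = 15,
                                            center_col_um = 15, radius_um = 10),
                          psf_sigma_um = 0, photon_gain = Inf,
                          read_noise_sd = 0, kinetics = kin, seed = 1)
  for (t in c(0, 12, 30, 61)) {
    fr <- render_frame(sc2, t)
    got <- mean(fr$noisy[2, , ][ann])
    want <- membrane_signal(t, kin, 10) + baseline_signal(t, kin)
    expect_lt(abs(got - want) / max(want, 1), 1e-6)
  }
})

test_that("simulation is deterministic under a seed and truth is exact", {
  sc <- noisy_scene(n_guvs = 3, seed = 77)
  a <- simulate_timelapse(sc)
  b <- simulate_timelapse(sc)
  expect_identical(a$stack$pixels, b$stack$pixels)

  # noiseless scene: true-mask traces equal the analytic curve at every frame
  scn <- noiseless_scene(n_guvs = 3, seed = 8)
  sim <- simulate_timelapse(scn)
  for (i in seq_len(3)) {
    m <- sim$truth$masks[[i]]
    tr <- vapply(seq_along(scn$time_grid_min),
                 function(t) mean(sim$stack$pixels[t, 2, , ][m]), 0)
    want <- membrane_signal(scn$time_grid_min, scn$kinetics,
                            scn$guvs$radius_um[i]) +
      baseline_signal(scn$time_grid_min, scn$kinetics)
    expect_lt(max(abs(tr - want) / pmax(want, 1)), 1e-6)
  }

  # curvature coupling makes true rates strictly decrease with radius
  scb <- simulation_scene(image_shape = c(256, 256), n_guvs = 6,
                          psf_sigma_um = 0,
                          kinetics = kinetic_params(curvature_coupling_b = 10),
                          seed = 3)
  simb <- simulate_timelapse(scb)
  o <- order(simb$truth$guvs$radius_um)
  expect_true(all(diff(simb$truth$guvs$true_rate_au_per_min[o]) < 0))
})

test_that("noisy pixels are unbiased estimates of the noiseless image", {
  # Monte-Carlo: >= 1e4 draws of one bright pixel, 3 sigma band on the mean
  x <- 50
  gain <- 50
  read_sd <- 1
  set.seed(9)
  draws <- rpois(2e4, gain * x) / gain + rnorm(2e4, 0, read_sd)
  se <- sqrt(x / gain + read_sd^2) / sqrt(2e4)
  expect_lt(abs(mean(draws) - x), 3 * se)
})

test_that("the fixture registry encodes the reported fold ratios", {
  f1 <- guv_fixture("FIG1C", seed = 2)
  r1 <- vapply(f1, function(s) s$kinetics$rate_au_per_min, 0)
  expect_equal(unname(r1["CI"] / r1["CII"]), 7)
  f7 <- guv_fixture("FIG7D", seed = 2)
  r7 <- vapply(f7, function(s) s$kinetics$rate_au_per_min, 0)
  expect_equal(unname(r7["U_BATS"] / r7["CII_WT"]), 7)
  expect_equal(unname(r7["UdC_BATS"] / r7["CII_WT"]), 11)
  f9 <- guv_fixture("FIG9_CI", seed = 2)
  r9 <- vapply(f9, function(s) s$kinetics$rate_au_per_min, 0)
  expect_equal(unname(r9["PI4P"] / r9["base"]), 1.8)
  expect_equal(unname(r9["PI45P2"] / r9["base"]), 1.2)
  f9b <- guv_fixture("FIG9_CII", seed = 2)
  r9b <- vapply(f9b, function(s) s$kinetics$rate_au_per_min, 0)
  expect_equal(unname(r9b["PI4P"] / r9b["base"]), 1.7)
  expect_equal(unname(r9b["PI45P2"] / r9b["base"]), 1.0)
  # curvature fixture: sign pattern of the coupling
  f2 <- guv_fixture("FIG2GH", seed = 2)
  expect_gt(f2$SO55_DO27$kinetics$curvature_coupling_b, 0)
  expect_equal(f2$SO82$kinetics$curvature_coupling_b, 0)
  expect_equal(f2$SO82$kinetics$rate_au_per_min, 0)
  expect_gt(f2$DO82$kinetics$rate_au_per_min, 0)
  expect_error(guv_fixture("nope"), "FIG1C")
})
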