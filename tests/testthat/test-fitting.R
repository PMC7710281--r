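# per-curve and per-pixel two-component fitting

test_that("noiseless curves are recovered essentially exactly", {
  truth <- biexp_params(2500, 0.4, 2500, 2.0)
  mu <- model_curve(truth, irf_delta(), acq_default)
  fit <- fit_decay(mu, irf_delta(), acq_default,
                   fit_options(fit_background = FALSE))
  cf <- coef(fit)
  expect_equal(cf[["tau1_ns"]], 0.4, tolerance = 1e-3)
  expect_equal(cf[["tau2_ns"]], 2.0, tolerance = 1e-3)
  expect_equal(cf[["alpha1"]], 2500, tolerance = 1e-3)
  expect_equal(cf[["alpha2"]], 2500, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
})

test_that("optimizer beats the exhaustive grid-search oracle", {
  # 20 random truths on 64-bin curves; the fitted Poisson objective must
  # not exceed the brute-force minimum over the bounded box
  tau1_grid <- seq(0.05, 1.0, by = 0.05)
  tau2_grid <- seq(1.0, 6.0, by = 0.05)
  f_grid <- seq(0, 1, by = 0.05)
  set.seed(314)
  opts <- fit_options(fit_background = FALSE)
  for (i in 1:20) {
    truth <- params_canonical(f = runif(1, 0.2, 0.8),
                              tau1 = runif(1, 0.2, 0.8),
                              tau2 = runif(1, 1.5, 4.5))
    y <- simulate_pixel(truth, irf_delta(), acq_small, 1e4,
                        seed = 1000 + i)
    fit <- fit_decay(y, irf_delta(), acq_small, opts)
    oracle_min <- grid_search_min(y, acq_small, tau1_grid, tau2_grid,
                                  f_grid)
    expect_lte(fit$objective_value, oracle_min + 1e-6)
  }
})

test_that("monoexponential input is flagged degenerate with the right tau", {
  truth <- biexp_params(1, 1.5, 0, 6)
  y <- simulate_pixel(truth, irf_delta(), acq_default, 1e4, seed = 77)
  fit <- fit_decay(y, irf_delta(), acq_default)
  expect_true(fit$degenerate)
  expect_equal(tau_avg(fit$params), 1.5, tolerance = 0.02 * 1.5)
})

test_that("insufficient photons raise an error, weak fits only flag", {
  y <- rep(0L, acq_default$n_bins); y[1] <- 10L
  expect_error(fit_decay(y, irf_delta(), acq_default), "insufficient")
  expect_error(fit_decay(rep(1, 10), irf_delta(), acq_default),
               "length")
})

test_that("parameter recovery is unbiased at 1e4 photons", {
  n_rep <- 200
  truth <- params_canonical(0.5)
  taus <- vapply(seq_len(n_rep), function(i) {
    y <- simulate_pixel(truth, irf_delta(), acq_default, 1e4,
                        seed = 2000 + i)
    cf <- coef(fit_decay(y, irf_delta(), acq_default))
    c(cf[["tau1_ns"]], cf[["tau2_ns"]])
  }, numeric(2))
  expect_lt(abs(mean(taus[1, ]) - 0.4), 0.05)
  expect_lt(abs(mean(taus[2, ]) - 2.0), 0.15)
})

test_that("reduced chi-square of correctly specified WLS fits is ~1", {
  n_rep <- 200
  truth <- params_canonical(0.5)
  opts <- fit_options(objective = "wls")
  chis <- vapply(seq_len(n_rep), function(i) {
    y <- simulate_pixel(truth, irf_delta(), acq_default, 1e4,
                        seed = 3000 + i)
    fit_decay(y, irf_delta(), acq_default, opts)$chisq_red
  }, numeric(1))
  expect_gte(mean(chis), 0.8)
  expect_lte(mean(chis), 1.2)
})

test_that("fitted model phasor matches the data phasor", {
  truth <- params_canonical(0.6)
  for (i in 1:5) {
    y <- simulate_pixel(truth, irf_delta(), acq_default, 1e4,
                        seed = 4000 + i)
    fit <- fit_decay(y, irf_delta(), acq_default)
    if (!fit$converged || fit$degenerate) next
    ph_fit <- phasor_transform(fitted(fit), acq_default)
    ph_dat <- phasor_transform(y, acq_default)
    expect_lt(abs(ph_fit$g - ph_dat$g), 0.02)
    expect_lt(abs(ph_fit$s - ph_dat$s), 0.02)
  }
})

test_that("decay_fit methods are coherent", {
  truth <- params_canonical(0.5)
  y <- simulate_pixel(truth, irf_gaussian(), acq_default, 5e3, seed = 8)
  fit <- fit_decay(y, irf_gaussian(), acq_default)
  expect_named(coef(fit), c("alpha1", "tau1_ns", "alpha2", "tau2_ns",
                            "background"))
  expect_equal(fitted(fit), predict(fit))
  expect_equal(residuals(fit, type = "response"), y - fitted(fit))
  expect_equal(residuals(fit),
               (y - fitted(fit)) / sqrt(pmax(fitted(fit), 1e-12)))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(acq_default$n_bins, 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1))
  expect_output(print(fit), "decay fit")
  expect_output(print(summary(fit)), "tau_avg")
})

test_that("fit_image maps a uniform scene within 3% of ground truth", {
  scene <- flim_scene(n_cells = 1, dim = c(24, 24), radius_range = c(6, 7),
                      params = params_canonical(0.5),
                      photons_per_pixel = 2000, seed = 5)
  cube <- simulate_scene(scene, irf_delta(), acq_default, seed = 6)
  map <- fit_image(cube, irf_delta())
  in_cell <- scene$labels == 1
  expect_true(all(map$valid[in_cell]))
  truth_tau <- scene$truth$tau_avg_ns[1]
  expect_equal(mean(map$tau_avg_ns[in_cell & map$valid]), truth_tau,
               tolerance = 0.03)
  # valid pixels satisfy the lifetime-band invariant
  expect_true(all(map$tau_avg_ns[map$valid] >= 0.05 - 1e-9))
  expect_true(all(map$tau_avg_ns[map$valid] <= 6 + 1e-9))
  expect_true(all(is.na(map$tau_avg_ns[!map$valid])))
})

test_that("an all-zero cube yields a fully invalid map", {
  cube <- flim_cube(array(0L, c(8, 8, 64)), flim_acquisition(n_bins = 64))
  map <- fit_image(cube, irf_delta())
  expect_false(any(map$valid))
  expect_true(all(is.na(map$tau_avg_ns)))
})

test_that("dim pixels are rescued by one step of spatial pooling", {
  # per-pixel budget below threshold, 3x3 pool above it
  scene <- flim_scene(n_cells = 1, dim = c(16, 16), radius_range = c(5, 6),
                      params = params_canonical(0.5),
                      photons_per_pixel = 60, seed = 9)
  cube <- simulate_scene(scene, irf_delta(), acq_default, seed = 10)
  opts <- fit_options(photon_threshold = 300, bin_radius = 1L)
  map <- fit_image(cube, irf_delta(), opts)
  expect_gt(sum(map$valid), 0)
  expect_gt(map$provenance$n_pooled, 0)
  # with pooling disabled those pixels are invalid
  map_np <- fit_image(cube, irf_delta(),
                      fit_options(photon_threshold = 300, bin_radius = 0L))
  expect_false(any(map_np$valid))
})

test_that("two-population scenes preserve the tau_avg ordering", {
  n_ordered <- 0L
  for (i in 1:20) {
    scene <- flim_scene(n_cells = 2, dim = c(32, 32),
                        radius_range = c(4, 5),
                        params = list(params_canonical(0.3),
                                      params_canonical(0.8)),
                        photons_per_pixel = 1000, seed = 100 + i)
    cube <- simulate_scene(scene, irf_delta(), acq_default,
                           seed = 200 + i)
    map <- fit_image(cube, irf_delta())
    m1 <- mean(map$tau_avg_ns[scene$labels == 1 & map$valid])
    m2 <- mean(map$tau_avg_ns[scene$labels == 2 & map$valid])
    # cell 1 (free fraction 0.3) must show the longer mean lifetime
    if (m1 > m2) n_ordered <- n_ordered + 1L
  }
  expect_equal(n_ordered, 20L)
})
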