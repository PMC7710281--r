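# forward model and derived lifetime quantities

test_that("tau_avg follows the amplitude-weighted formula", {
  expect_equal(tau_avg(biexp_params(1, 0.4, 0, 2.0)), 0.4)
  expect_equal(tau_avg(biexp_params(1, 0.4, 1, 2.0)), 1.2)
  expect_equal(tau_avg(biexp_params(3, 0.4, 1, 2.0)), 0.8)
  expect_error(tau_avg(biexp_params(0, 0.4, 0, 2.0)), "undefined")
})

test_that("free_fraction is the amplitude share of the fast component", {
  expect_equal(free_fraction(biexp_params(1, 0.4, 1, 2.0)), 0.5)
  expect_equal(free_fraction(biexp_params(0, 0.4, 5, 2.0)), 0)
  # consistency of the (free fraction, tau_avg) pair: 0.7*0.4 + 0.3*2.0
  p <- biexp_params(0.7, 0.4, 0.3, 2.0)
  expect_equal(free_fraction(p), 0.7)
  expect_equal(tau_avg(p), 0.88)
  expect_error(free_fraction(biexp_params(0, 1, 0, 2)), "undefined")
})

test_that("constructor enforces canonical tau1 <= tau2 ordering", {
  p <- biexp_params(alpha1 = 2, tau1_ns = 3.0, alpha2 = 5, tau2_ns = 0.5)
  expect_lte(p$tau1_ns, p$tau2_ns)
  expect_equal(p$alpha1, 5)   # amplitude follows its lifetime in the swap
  expect_equal(p$alpha2, 2)
  expect_error(biexp_params(1, -0.4, 1, 2), "positive")
  expect_error(biexp_params(-1, 0.4, 1, 2), "non-negative")
})

test_that("tau_avg lies in [tau1, tau2] and decreases with alpha1", {
  set.seed(42)
  for (i in 1:50) {
    p <- biexp_params(runif(1, 0, 10), runif(1, 0.1, 1),
                      runif(1, 1e-3, 10), runif(1, 1, 6))
    ta <- tau_avg(p)
    expect_gte(ta, p$tau1_ns)
    expect_lte(ta, p$tau2_ns)
  }
  # strictly decreasing in alpha1 at fixed total amplitude
  f_grid <- seq(0.05, 0.95, by = 0.05)
  ta <- vapply(f_grid, function(f) tau_avg(params_canonical(f)), numeric(1))
  expect_true(all(diff(ta) < 0))
})

test_that("model_curve matches the analytic monoexponential (delta IRF)", {
  mu <- model_curve(biexp_params(100, 0.4, 0, 2.0), irf_delta(),
                    acq_default)
  t_grid <- bin_centers(acq_default)
  expected <- exp(-t_grid / 0.4)
  expected <- 100 * expected / sum(expected)
  expect_equal(mu, expected, tolerance = 1e-12)
  expect_equal(sum(mu), 100, tolerance = 1e-6)
})

test_that("model_curve conserves total expected photons", {
  cases <- list(
    list(p = biexp_params(120, 0.4, 80, 2.0, background = 0.5),
         irf = irf_delta()),
    list(p = biexp_params(3000, 0.3, 7000, 3.1, background = 2),
         irf = irf_gaussian()),
    list(p = biexp_params(10, 0.9, 10, 1.1),
         irf = irf_gaussian(fwhm_ns = 0.6, center_ns = 2)))
  for (cs in cases) {
    mu <- model_curve(cs$p, cs$irf, acq_default)
    expect_equal(sum(mu),
                 cs$p$alpha1 + cs$p$alpha2 +
                   cs$p$background * acq_default$n_bins,
                 tolerance = 1e-6)
    expect_true(all(mu >= 0))
  }
})

test_that("period wrap-around matches the brute-force series oracle", {
  # slow decay (3 ns in a 12.5 ns window) folds a visible tail across the
  # period boundary; the discrete model must equal the truncated infinite
  # series of wraps
  mu <- model_curve(biexp_params(0, 1, 500, 3.0), irf_delta(), acq_default)
  oracle <- wrap_series_oracle(500, 3.0, acq_default, n_wraps = 60L)
  expect_equal(mu, oracle, tolerance = 1e-12)
})

test_that("gaussian IRF converges to the delta IRF as fwhm -> 0", {
  p <- biexp_params(800, 0.4, 200, 2.0)
  first_center <- acq_default$bin_width_ns / 2
  mu_delta <- model_curve(p, irf_delta(), acq_default)
  mu_narrow <- model_curve(p, irf_gaussian(fwhm_ns = 1e-4,
                                           center_ns = first_center),
                           acq_default)
  expect_lt(max(abs(mu_narrow - mu_delta)), 1e-6 * max(mu_delta))
})

test_that("model_curve rejects ill-conditioned lifetimes", {
  expect_error(model_curve(biexp_params(1, 1e-8, 1, 2), irf_delta(),
                           acq_default), "ill-conditioned")
})

test_that("monoexponential phasors sit on the universal semicircle", {
  for (tau in c(0.2, 0.5, 1, 2, 3.5, 5)) {
    mu <- model_curve(biexp_params(100, tau, 0, 6), irf_delta(),
                      acq_default)
    ph <- phasor_transform(mu, acq_default)
    # closed form for an ideal decay at the fundamental harmonic
    wt <- ph$omega_ns_inv * tau
    expect_equal(ph$g, 1 / (1 + wt^2), tolerance = 0.01)
    expect_equal(ph$s, wt / (1 + wt^2), tolerance = 0.01)
    expect_lt(abs(ph$g^2 + ph$s^2 - ph$g), 0.01)
    expect_true(ph$g >= 0 && ph$g <= 1)
    # bin-center sampling lets s creep ~3e-5 over the continuous 0.5 cap
    expect_true(ph$s >= 0 && ph$s <= 0.5 + 1e-3)
  }
})

test_that("mixture phasor lies on the chord between component phasors", {
  acq <- acq_default
  ph1 <- phasor_transform(model_curve(biexp_params(100, 0.4, 0, 2),
                                      irf_delta(), acq), acq)
  ph2 <- phasor_transform(model_curve(biexp_params(0, 0.4, 100, 2),
                                      irf_delta(), acq), acq)
  for (f in c(0.25, 0.5, 0.8)) {
    mix <- phasor_transform(model_curve(params_canonical(f, total = 100),
                                        irf_delta(), acq), acq)
    # photon-weighted linearity of the transform
    expect_equal(mix$g, f * ph1$g + (1 - f) * ph2$g, tolerance = 1e-9)
    expect_equal(mix$s, f * ph1$s + (1 - f) * ph2$s, tolerance = 1e-9)
  }
})

test_that("data and model phasors agree at 1e4 photons", {
  p <- params_canonical(0.5, total = 1)
  mu <- model_curve(params_canonical(0.5, total = 1e4), irf_delta(),
                    acq_default)
  y <- simulate_pixel(p, irf_delta(), acq_default, 1e4, seed = 11)
  ph_mu <- phasor_transform(mu, acq_default)
  ph_y <- phasor_transform(y, acq_default)
  expect_lt(abs(ph_mu$g - ph_y$g), 0.02)
  expect_lt(abs(ph_mu$s - ph_y$s), 0.02)
})

test_that("phasor errors and IRF referencing behave", {
  expect_error(phasor_transform(numeric(256), acq_default), "no photons")
  # an IRF-blurred monoexponential referenced back to impulse excitation
  # returns to the semicircle
  mu <- model_curve(biexp_params(1000, 1.5, 0, 6), irf_gaussian(),
                    acq_default)
  ph <- phasor_transform(mu, acq_default, irf = irf_gaussian())
  expect_lt(abs(ph$g^2 + ph$s^2 - ph$g), 0.01)
})

test_that("acquisition and IRF constructors validate their invariants", {
  expect_error(flim_acquisition(n_bins = 4), "n_bins")
  expect_error(flim_acquisition(period_ns = -1), "period_ns")
  acq <- flim_acquisition(n_bins = 100, period_ns = 10)
  expect_equal(acq$bin_width_ns * acq$n_bins, acq$period_ns,
               tolerance = 1e-9)
  expect_error(irf_gaussian(fwhm_ns = 0), "fwhm")
  expect_error(irf_measured(1:3, c(-1, 1, 1)), "non-negative")
  expect_equal(sum(irf_profile(irf_gaussian(), acq_default)), 1,
               tolerance = 1e-9)
  m <- irf_measured(bin_centers(acq_default),
                    irf_profile(irf_gaussian(), acq_default))
  expect_equal(sum(m$weight), 1, tolerance = 1e-9)
})
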