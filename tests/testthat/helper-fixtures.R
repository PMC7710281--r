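# shared fixtures and independent oracles for the suite

acq_default <- flim_acquisition()                 # 256 bins, 12.5 ns
acq_small <- flim_acquisition(n_bins = 64L, period_ns = 12.5)

params_canonical <- function(f = 0.5, total = 1, tau1 = 0.4, tau2 = 2.0,
                             bg = 0) {
  biexp_params(alpha1 = f * total, tau1_ns = tau1,
               alpha2 = (1 - f) * total, tau2_ns = tau2, background = bg)
}

# brute-force wrap-around series oracle for a delta-IRF monoexponential:
# per-bin expected counts from the truncated infinite series of period
# wraps, normalized to the amplitude
wrap_series_oracle <- function(alpha, tau, acq, n_wraps = 60L) {
  t_grid <- (seq_len(acq$n_bins) - 0.5) * acq$bin_width_ns
  s <- Reduce(`+`, lapply(0:(n_wraps - 1L), function(k)
    exp(-(t_grid + k * acq$period_ns) / tau)))
  alpha * s / sum(s)
}

# exhaustive grid-search oracle for the Poisson MLE objective on a
# delta-IRF curve with zero background: amplitude at its per-shape optimum
# (A = total counts); returns the minimum objective over the box
grid_search_min <- function(counts, acq, tau1_grid, tau2_grid, f_grid) {
  t_grid <- (seq_len(acq$n_bins) - 0.5) * acq$bin_width_ns
  shape <- function(tau) { s <- exp(-t_grid / tau); s / sum(s) }
  s1 <- vapply(tau1_grid, shape, numeric(acq$n_bins))
  s2 <- vapply(tau2_grid, shape, numeric(acq$n_bins))
  A <- sum(counts)
  best <- Inf
  for (i in seq_along(tau1_grid)) {
    for (j in seq_along(tau2_grid)) {
      # all f values at once: mu is n_bins x n_f
      mix <- outer(s1[, i], f_grid) + outer(s2[, j], 1 - f_grid)
      mu <- pmax(A * mix, 1e-12)
      obj <- colSums(mu - counts * log(mu))
      best <- min(best, min(obj))
    }
  }
  best
}

# closed-form paired t test on per-donor differences (textbook formula)
paired_t_oracle <- function(diffs) {
  n <- length(diffs)
  m <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  t_stat <- m / se
  list(t = t_stat, df = n - 1,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}
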