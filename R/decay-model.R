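#' Two-component NAD(P)H decay parameters
#'
#' The kinetic state of one decay: amplitudes and lifetimes of the free
#' (short-lived, ~0.4 ns) and protein-bound (long-lived, 2-4 ns) NAD(P)H
#' components, plus a constant background. Components are stored in canonical
#' order `tau1_ns <= tau2_ns` (free first); inputs supplied in the opposite
#' order are swapped together with their amplitudes.
#'
#' Amplitudes are in expected-photon units: `alpha1 + alpha2` is the expected
#' total number of signal photons in the histogram.
#'
#' @param alpha1,alpha2 Non-negative component amplitudes (expected photons).
#' @param tau1_ns,tau2_ns Component lifetimes in ns (> 0).
#' @param background Non-negative expected background photons per bin.
#' @return An object of class `biexp_params`.
#' @examples
#' p <- biexp_params(alpha1 = 1, tau1_ns = 0.4, alpha2 = 1, tau2_ns = 2)
#' tau_avg(p)        # 1.2 ns
#' free_fraction(p)  # 0.5
#' @export
biexp_params <- function(alpha1, tau1_ns, alpha2, tau2_ns, background = 0) {
  vals <- c(alpha1, tau1_ns, alpha2, tau2_ns, background)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (tau1_ns <= 0 || tau2_ns <= 0) stop("lifetimes must be positive")
  if (alpha1 < 0 || alpha2 < 0) stop("amplitudes must be non-negative")
  if (background < 0) stop("background must be non-negative")
  if (tau1_ns > tau2_ns) {  # canonical order: free (short) component first
    tmp <- tau1_ns; tau1_ns <- tau2_ns; tau2_ns <- tmp
    tmp <- alpha1; alpha1 <- alpha2; alpha2 <- tmp
  }
  structure(list(alpha1 = alpha1, tau1_ns = tau1_ns,
                 alpha2 = alpha2, tau2_ns = tau2_ns,
                 background = background),
            class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  cat(sprintf(
    "Two-component decay: alpha1 = %.4g, tau1 = %.4g ns (free); alpha2 = %.4g, tau2 = %.4g ns (bound); bg = %.4g/bin\n",
    x$alpha1, x$tau1_ns, x$alpha2, x$tau2_ns, x$background))
  if (x$alpha1 + x$alpha2 > 0)
    cat(sprintf("  tau_avg = %.4g ns, free fraction = %.4g\n",
                tau_avg(x), free_fraction(x)))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' The mean lifetime used for metabolic readout,
#' `tau_avg = (alpha1 * tau1 + alpha2 * tau2) / (alpha1 + alpha2)`.
#' Amplitude weighting (not intensity `alpha * tau` weighting) is used: a
#' larger free-NAD(P)H amplitude share lowers `tau_avg`, indicating a
#' glycolytic shift.
#'
#' @param params A [biexp_params()] object with `alpha1 + alpha2 > 0`.
#' @return Mean lifetime in ns; always within `[tau1_ns, tau2_ns]`.
#' @export
tau_avg <- function(params) {
  stopifnot(inherits(params, "biexp_params"))
  tot <- params$alpha1 + params$alpha2
  if (tot <= 0) stop("undefined lifetime: alpha1 + alpha2 must be > 0")
  (params$alpha1 * params$tau1_ns + params$alpha2 * params$tau2_ns) / tot
}

#' Free NAD(P)H amplitude fraction
#'
#' `alpha1 / (alpha1 + alpha2)`, the amplitude share of the unbound (free)
#' component. A higher free fraction indicates relatively more glycolytic
#' metabolism; it is monotonically decreasing in `tau_avg` for fixed
#' lifetimes.
#'
#' @inheritParams tau_avg
#' @return Fraction in \[0, 1\].
#' @export
free_fraction <- function(params) {
  stopifnot(inherits(params, "biexp_params"))
  tot <- params$alpha1 + params$alpha2
  if (tot <= 0) stop("undefined fraction: alpha1 + alpha2 must be > 0")
  params$alpha1 / tot
}

# circular convolution of two equal-length vectors via FFT;
# y_fft may be precomputed with fft(y) for repeated calls
circ_convolve <- function(x, y_fft) {
  Re(stats::fft(stats::fft(x) * y_fft, inverse = TRUE)) / length(x)
}

# normalized periodic monoexponential shape sampled at bin centers.
# The infinite wrap-around series sum_k exp(-(t + k*T)/tau) is proportional
# to exp(-t/tau), so normalizing the sampled single exponential to unit sum
# includes wrap-around exactly.
exp_shape <- function(tau, t_grid) {
  s <- exp(-t_grid / tau)
  s / sum(s)
}

#' Expected photon counts of a two-component decay
#'
#' Forward model used by the fitter: the per-bin expected counts are the
#' background plus the circular convolution (over the repetition period) of
#' the IRF with `alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2)`. Each
#' component's discrete shape is normalized over one period so that the total
#' expected signal photons equal `alpha1 + alpha2`; wrap-around of incomplete
#' decay across the period boundary is included.
#'
#' @param params A [biexp_params()] object.
#' @param irf An IRF model (default ideal impulse). See [irf].
#' @param acq A [flim_acquisition()] object.
#' @return Numeric vector of expected counts, length `acq$n_bins`, summing to
#'   `alpha1 + alpha2 + background * n_bins`.
#' @examples
#' mu <- model_curve(biexp_params(100, 0.4, 0, 2), irf_delta())
#' sum(mu)  # 100
#' @export
model_curve <- function(params, irf = irf_delta(), acq = flim_acquisition()) {
  stopifnot(inherits(params, "biexp_params"), inherits(acq, "flim_acquisition"))
  if (min(params$tau1_ns, params$tau2_ns) < 1e-3 * acq$bin_width_ns)
    stop("ill-conditioned model: lifetime shorter than 1e-3 x bin width")
  t_grid <- bin_centers(acq)
  sig <- params$alpha1 * exp_shape(params$tau1_ns, t_grid) +
         params$alpha2 * exp_shape(params$tau2_ns, t_grid)
  if (!identical(irf$kind, "delta")) {
    prof <- irf_profile(irf, acq)
    sig <- circ_convolve(sig, stats::fft(prof))
    sig[sig < 0] <- 0  # clip FFT round-off
  }
  sig + params$background
}

#' Phasor transform of a decay histogram
#'
#' First (or higher) harmonic Fourier coefficients of the normalized decay:
#' `g = sum(c * cos(w t)) / sum(c)`, `s = sum(c * sin(w t)) / sum(c)` at the
#' bin centers, with `w = 2 * pi * harmonic / period`. Monoexponential decays
#' lie on the universal semicircle `g^2 + s^2 = g`; mixtures lie on the chord
#' between their component phasors. Used as a fit-independent cross-check of
#' the decay model.
#'
#' @param counts Non-negative per-bin photon counts (or a model curve).
#' @param acq A [flim_acquisition()] object.
#' @param harmonic Positive integer harmonic of the repetition frequency.
#' @param irf Optional IRF model; when supplied, the phasor is divided (in
#'   the complex plane) by the IRF's phasor, referencing it to an ideal
#'   impulse excitation.
#' @return An object of class `phasor_point` with fields `g`, `s`,
#'   `harmonic`, `omega_ns_inv`.
#' @export
phasor_transform <- function(counts, acq = flim_acquisition(), harmonic = 1L,
                             irf = NULL) {
  stopifnot(inherits(acq, "flim_acquisition"))
  counts <- as.numeric(counts)
  if (length(counts) != acq$n_bins)
    stop("counts length does not match acquisition n_bins")
  if (sum(counts) <= 0) stop("undefined phasor: curve has no photons")
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L) stop("harmonic must be a positive integer")
  omega <- 2 * pi * harmonic / acq$period_ns
  t_grid <- bin_centers(acq)
  z <- sum(counts * exp(1i * omega * t_grid)) / sum(counts)
  if (!is.null(irf)) {
    prof <- irf_profile(irf, acq)
    z_irf <- sum(prof * exp(1i * omega * t_grid))
    z <- z / z_irf
  }
  structure(list(g = Re(z), s = Im(z), harmonic = harmonic,
                 omega_ns_inv = omega),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("Phasor (harmonic %d): g = %.4f, s = %.4f\n",
              x$harmonic, x$g, x$s))
  invisible(x)
}
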