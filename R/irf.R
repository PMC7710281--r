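#' Instrument response function models
#'
#' The instrument response function (IRF) is the temporal blur of the
#' excitation/detection chain; the measured decay is the convolution of the
#' true fluorescence decay with the IRF over the laser repetition period.
#' Three kinds are supported: an ideal impulse (`irf_delta()`), a Gaussian of
#' given full width at half maximum (`irf_gaussian()`), and a measured
#' histogram (`irf_measured()`). The Gaussian default (FWHM 0.25 ns centered
#' 1.0 ns into the window) is typical of multiphoton TCSPC detection.
#'
#' @param fwhm_ns Full width at half maximum in ns (> 0).
#' @param center_ns Center of the Gaussian within the repetition window (ns).
#' @param bin_center_ns Bin-center times of a measured IRF histogram (ns).
#' @param weight Non-negative per-bin weights of a measured IRF histogram;
#'   normalized internally to sum to 1.
#'
#' @return An object of class `flim_irf` with a `kind` field, one of
#'   `"delta"`, `"gaussian"`, `"measured"`.
#' @examples
#' irf_gaussian(fwhm_ns = 0.25, center_ns = 1)
#' @name irf
NULL

#' @rdname irf
#' @export
irf_delta <- function() {
  structure(list(kind = "delta"), class = "flim_irf")
}

#' @rdname irf
#' @export
irf_gaussian <- function(fwhm_ns = 0.25, center_ns = 1.0) {
  if (!is.finite(fwhm_ns) || fwhm_ns <= 0) stop("fwhm_ns must be > 0")
  structure(list(kind = "gaussian", fwhm_ns = fwhm_ns, center_ns = center_ns),
            class = "flim_irf")
}

#' @rdname irf
#' @export
irf_measured <- function(bin_center_ns, weight) {
  if (length(bin_center_ns) != length(weight) || length(weight) < 2L)
    stop("bin_center_ns and weight must be equal-length vectors (>= 2)")
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("measured IRF weights must be finite and non-negative")
  if (sum(weight) <= 0) stop("measured IRF must have positive total weight")
  structure(list(kind = "measured",
                 bin_center_ns = as.numeric(bin_center_ns),
                 weight = as.numeric(weight) / sum(weight)),
            class = "flim_irf")
}

#' @export
print.flim_irf <- function(x, ...) {
  switch(x$kind,
    delta = cat("IRF: ideal impulse (delta)\n"),
    gaussian = cat(sprintf("IRF: gaussian, FWHM %.4g ns, center %.4g ns\n",
                           x$fwhm_ns, x$center_ns)),
    measured = cat(sprintf("IRF: measured histogram, %d points\n",
                           length(x$weight))))
  invisible(x)
}

#' Discretized IRF histogram on an acquisition grid
#'
#' Returns the per-bin IRF weights on the acquisition's time grid, wrapped
#' circularly over the repetition period and normalized to sum to 1. The
#' Gaussian kind is integrated exactly over bin edges (with period wrapping);
#' the measured kind is linearly interpolated onto the grid.
#'
#' @param irf A [irf_delta()], [irf_gaussian()] or [irf_measured()] object.
#' @param acq A [flim_acquisition()] object.
#' @return Numeric vector of length `acq$n_bins` summing to 1.
#' @export
irf_profile <- function(irf, acq) {
  stopifnot(inherits(irf, "flim_irf"), inherits(acq, "flim_acquisition"))
  n <- acq$n_bins
  period <- acq$period_ns
  switch(irf$kind,
    delta = {
      p <- numeric(n); p[1] <- 1; p
    },
    gaussian = {
      sigma <- irf$fwhm_ns / (2 * sqrt(2 * log(2)))
      edges <- seq(0, period, length.out = n + 1L)
      # wrap mass from neighboring periods back into the window
      k <- ceiling(6 * sigma / period) + 1L
      p <- numeric(n)
      for (shift in (-k):k) {
        mu <- irf$center_ns + shift * period
        p <- p + diff(stats::pnorm(edges, mean = mu, sd = sigma))
      }
      p / sum(p)
    },
    measured = {
      t_grid <- bin_centers(acq)
      w <- stats::approx(irf$bin_center_ns, irf$weight, xout = t_grid,
                         rule = 2)$y
      w[w < 0] <- 0
      if (sum(w) <= 0)
        stop("measured IRF has no weight on the acquisition window")
      w / sum(w)
    })
}
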