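#' TCSPC acquisition settings
#'
#' Describes the time axis of a time-correlated single-photon counting (TCSPC)
#' acquisition: the number of histogram time bins per pixel and the laser
#' repetition window they span. The defaults correspond to a standard
#' multiphoton NAD(P)H FLIM setup: 256 time bins over a 12.5 ns window
#' (80 MHz Ti:Sapphire repetition rate).
#'
#' @param n_bins Number of time bins per pixel (integer, >= 8).
#' @param period_ns Laser repetition window in nanoseconds (> 0).
#' @param excitation_nm Excitation wavelength in nm (metadata only).
#' @param emission_band_nm Length-2 emission bandpass in nm (metadata only).
#'
#' @return An object of class `flim_acquisition` with fields `n_bins`,
#'   `period_ns`, `bin_width_ns`, `excitation_nm`, `emission_band_nm`.
#' @examples
#' acq <- flim_acquisition()
#' acq$bin_width_ns * acq$n_bins  # = period_ns
#' @export
flim_acquisition <- function(n_bins = 256L, period_ns = 12.5,
                             excitation_nm = 760,
                             emission_band_nm = c(410, 500)) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 8L)
    stop("n_bins must be a single integer >= 8")
  if (length(period_ns) != 1L || !is.finite(period_ns) || period_ns <= 0)
    stop("period_ns must be a single positive number")
  structure(list(
    n_bins = n_bins,
    period_ns = period_ns,
    bin_width_ns = period_ns / n_bins,
    excitation_nm = excitation_nm,
    emission_band_nm = emission_band_nm
  ), class = "flim_acquisition")
}

#' Bin-center time coordinates
#'
#' Time coordinate convention: 0-based bin index `i`, bin centers at
#' `t_i = (i + 0.5) * bin_width_ns`.
#'
#' @param acq A [flim_acquisition()] object.
#' @return Numeric vector of length `n_bins` (ns).
#' @export
bin_centers <- function(acq) {
  stopifnot(inherits(acq, "flim_acquisition"))
  (seq_len(acq$n_bins) - 0.5) * acq$bin_width_ns
}

#' @export
print.flim_acquisition <- function(x, ...) {
  cat(sprintf("TCSPC acquisition: %d bins over %.4g ns (bin width %.4g ns)\n",
              x$n_bins, x$period_ns, x$bin_width_ns))
  cat(sprintf("  excitation %g nm, emission band %g-%g nm\n",
              x$excitation_nm, x$emission_band_nm[1], x$emission_band_nm[2]))
  invisible(x)
}

as_acquisition_list <- function(acq) {
  list(n_bins = acq$n_bins, period_ns = acq$period_ns,
       bin_width_ns = acq$bin_width_ns,
       excitation_nm = acq$excitation_nm,
       emission_band_nm = acq$emission_band_nm)
}

acquisition_from_list <- function(x) {
  acq <- flim_acquisition(
    n_bins = x$n_bins,
    period_ns = x$period_ns,
    excitation_nm = if (!is.null(x$excitation_nm)) x$excitation_nm else 760,
    emission_band_nm = if (!is.null(x$emission_band_nm))
      as.numeric(unlist(x$emission_band_nm)) else c(410, 500)
  )
  if (!is.null(x$bin_width_ns) &&
      abs(x$bin_width_ns * x$n_bins - x$period_ns) > 1e-9)
    stop("inconsistent acquisition metadata: bin_width_ns * n_bins != period_ns")
  acq
}
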