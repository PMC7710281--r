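#' Per-pixel lifetime map of a FLIM cube
#'
#' Fits the two-component decay model independently in every pixel whose
#' histogram carries at least `options$photon_threshold` photons. Pixels
#' below the threshold get one escalation: their counts are pooled with the
#' spatial neighborhood of radius `options$bin_radius` (3x3 for radius 1)
#' and refitted; pixels still below threshold are masked invalid. The
#' result is deterministic given the cube and options, and independent of
#' pixel processing order.
#'
#' @param cube A [flim_cube()] object.
#' @param irf IRF model assumed by the forward model.
#' @param options A [fit_options()] object.
#' @return An object of class `lifetime_map` with matrices `tau_avg_ns`,
#'   `free_fraction`, `chisq_red`, `n_photons` (NA outside the valid mask),
#'   logical matrix `valid`, and `acq`/`provenance` metadata.
#' @export
fit_image <- function(cube, irf = irf_gaussian(), options = fit_options()) {
  stopifnot(inherits(cube, "flim_cube"))
  acq <- cube$acq
  counts <- cube$counts
  d <- dim(counts)
  nr <- d[1]; nc <- d[2]
  intensity <- rowSums(counts, dims = 2L)

  tau_map <- matrix(NA_real_, nr, nc)
  ff_map <- matrix(NA_real_, nr, nc)
  chisq_map <- matrix(NA_real_, nr, nc)
  nph_map <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  n_pooled <- 0L
  n_failed <- 0L

  r <- options$bin_radius
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      y <- NULL
      if (intensity[i, j] >= options$photon_threshold) {
        y <- counts[i, j, ]
        nph <- intensity[i, j]
      } else if (r > 0L) {
        ii <- max(1L, i - r):min(nr, i + r)
        jj <- max(1L, j - r):min(nc, j + r)
        pooled_int <- sum(intensity[ii, jj])
        if (pooled_int >= options$photon_threshold) {
          block <- counts[ii, jj, , drop = FALSE]
          y <- colSums(matrix(block, ncol = acq$n_bins))
          nph <- pooled_int
          n_pooled <- n_pooled + 1L
        }
      }
      if (is.null(y)) next
      fit <- fit_decay(y, irf, acq, options)
      if (!fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      tau_map[i, j] <- tau_avg(fit$params)
      ff_map[i, j] <- free_fraction(fit$params)
      chisq_map[i, j] <- fit$chisq_red
      nph_map[i, j] <- nph
      valid[i, j] <- TRUE
    }
  }
  if (n_failed > 0L)
    message(n_failed, " pixel fit(s) did not converge; masked invalid")

  structure(list(tau_avg_ns = tau_map, free_fraction = ff_map,
                 chisq_red = chisq_map, n_photons = nph_map, valid = valid,
                 acq = acq,
                 provenance = c(cube$provenance,
                                list(objective = options$objective,
                                     photon_threshold = options$photon_threshold,
                                     bin_radius = options$bin_radius,
                                     n_pooled = n_pooled,
                                     n_failed = n_failed,
                                     cube_seed = cube$seed))),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("Lifetime map: %d x %d pixels, %d valid (%.1f%%)\n",
              nrow(x$valid), ncol(x$valid), nv,
              100 * nv / length(x$valid)))
  if (nv > 0)
    cat(sprintf("  tau_avg %.3f-%.3f ns (median %.3f), free fraction median %.3f\n",
                min(x$tau_avg_ns, na.rm = TRUE),
                max(x$tau_avg_ns, na.rm = TRUE),
                stats::median(x$tau_avg_ns, na.rm = TRUE),
                stats::median(x$free_fraction, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.lifetime_map <- function(x, what = c("tau_avg_ns", "free_fraction",
                                          "chisq_red"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
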