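# Seeded synthetic TCSPC data: single decays, labeled scenes (disc "cells"
# on a background), and paired two-population cohorts with known ground
# truth. Every generator is a pure function of its arguments and seed;
# randomness never leaks through global RNG state.

# run code under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. seed = NULL uses (and advances) the
# current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.finite(seed)) stop("seed must be a finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# derive a stream of child seeds from one parent seed (kept < 2^31)
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Simulate one pixel's photon-count decay histogram
#'
#' Draws per-bin counts as independent Poisson variables whose means follow
#' the two-component forward model ([model_curve()]), with the amplitudes
#' rescaled so the expected total signal photons equal `n_photons` (the free
#' fraction of `params` is preserved). The background of `params` is kept in
#' expected-photons-per-bin units. Per-bin Poisson sampling is statistically
#' identical to photon-by-photon arrival simulation at the histogram level.
#'
#' @param params A [biexp_params()] object giving the decay composition.
#' @param irf IRF model (see [irf]).
#' @param acq A [flim_acquisition()] object.
#' @param n_photons Expected total signal photons (>= 0).
#' @param seed Integer seed; identical seeds give identical histograms.
#' @return Integer vector of per-bin counts, length `acq$n_bins`.
#' @examples
#' p <- biexp_params(1, 0.4, 1, 2)
#' y <- simulate_pixel(p, irf_delta(), flim_acquisition(), 1000, seed = 1)
#' sum(y)
#' @export
simulate_pixel <- function(params, irf = irf_delta(),
                           acq = flim_acquisition(), n_photons, seed = NULL) {
  stopifnot(inherits(params, "biexp_params"))
  if (!is.finite(n_photons) || n_photons < 0)
    stop("n_photons must be non-negative")
  mu <- pixel_mean_curve(params, irf, acq, n_photons)
  with_seed(seed, stats::rpois(acq$n_bins, mu))
}

# expected per-bin counts for a pixel with a given photon budget
pixel_mean_curve <- function(params, irf, acq, n_photons) {
  tot <- params$alpha1 + params$alpha2
  f <- if (tot > 0) params$alpha1 / tot else 0
  scaled <- biexp_params(alpha1 = f * n_photons, tau1_ns = params$tau1_ns,
                         alpha2 = (1 - f) * n_photons,
                         tau2_ns = params$tau2_ns,
                         background = params$background)
  if (n_photons == 0 && params$background == 0) return(numeric(acq$n_bins))
  model_curve(scaled, irf, acq)
}

#' Ground-truth scene of disc-shaped cells
#'
#' Builds a labeled scene: `n_cells` non-overlapping discs placed on a
#' `dim[1] x dim[2]` grid, each carrying its own decay parameters and
#' photon-per-pixel budget, over an optional uniform background photon rate.
#' This is the ground truth a simulated image cube is generated from, and
#' the truth table recovery tests compare against.
#'
#' @param n_cells Number of discs to place.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param radius_range Disc radius range in pixels, sampled uniformly.
#' @param params A single [biexp_params()] (recycled) or a list of one per
#'   cell.
#' @param photons_per_pixel Expected signal photons per in-cell pixel; a
#'   scalar (recycled) or one value per cell.
#' @param background_rate Expected background photons per bin for every
#'   pixel (in-cell pixels included).
#' @param seed Integer seed controlling placement and radii.
#' @return An object of class `flim_scene`: `labels` (integer matrix, 0 =
#'   background), `params` (list per cell), `photons_per_pixel`,
#'   `background_rate`, and a `truth` data frame (cell_id, true free
#'   fraction, true tau_avg).
#' @export
flim_scene <- function(n_cells = 5L, dim = c(64L, 64L),
                       radius_range = c(4, 8),
                       params = biexp_params(1, 0.4, 1, 2),
                       photons_per_pixel = 5000,
                       background_rate = 0, seed = NULL) {
  n_cells <- as.integer(n_cells)
  if (inherits(params, "biexp_params")) params <- rep(list(params), n_cells)
  if (length(params) != n_cells)
    stop("params must be one biexp_params or a list of length n_cells")
  photons_per_pixel <- rep_len(photons_per_pixel, n_cells)
  if (any(photons_per_pixel < 0)) stop("photon budgets must be >= 0")
  labels <- matrix(0L, dim[1], dim[2])
  with_seed(seed, {
    centers <- matrix(NA_real_, n_cells, 2)
    radii <- numeric(n_cells)
    placed <- 0L
    tries <- 0L
    while (placed < n_cells && tries < 2000L) {
      tries <- tries + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cy <- stats::runif(1, r + 1, dim[1] - r)
      cx <- stats::runif(1, r + 1, dim[2] - r)
      if (placed > 0L) {
        d <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                  (centers[seq_len(placed), 2] - cx)^2)
        if (any(d < radii[seq_len(placed)] + r + 2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cy, cx)
      radii[placed] <- r
    }
    if (placed < n_cells)
      stop("could not place ", n_cells, " non-overlapping cells; ",
           "reduce n_cells or radius_range")
    rows <- row(labels); cols <- col(labels)
    for (i in seq_len(n_cells)) {
      inside <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
        radii[i]^2
      labels[inside] <- i
    }
  })
  truth <- data.frame(
    cell_id = seq_len(n_cells),
    free_fraction = vapply(params, free_fraction, numeric(1)),
    tau_avg_ns = vapply(params, tau_avg, numeric(1)),
    photons_per_pixel = photons_per_pixel
  )
  structure(list(labels = labels, params = params,
                 photons_per_pixel = photons_per_pixel,
                 background_rate = background_rate, truth = truth,
                 seed = seed),
            class = "flim_scene")
}

#' Simulate a FLIM image cube from a ground-truth scene
#'
#' Every labeled pixel is simulated from its cell's decay parameters at that
#' cell's photon budget; background pixels receive only the background rate.
#' The result carries the scene (ground truth) and seed as provenance.
#'
#' @param scene A [flim_scene()] object.
#' @param irf IRF model.
#' @param acq A [flim_acquisition()] object.
#' @param seed Integer seed; fixed seed gives a bit-identical cube.
#' @return An object of class `flim_cube`: `counts` (integer array rows x
#'   cols x n_bins), `acq`, `seed`, `scene`.
#' @export
simulate_scene <- function(scene, irf = irf_gaussian(),
                           acq = flim_acquisition(), seed = NULL) {
  stopifnot(inherits(scene, "flim_scene"))
  labels <- scene$labels
  n_cells <- length(scene$params)
  if (n_cells > 0 && max(labels) > n_cells)
    stop("scene labels reference cells with no parameters")
  dims <- dim(labels)
  counts <- array(0L, c(dims[1], dims[2], acq$n_bins))
  with_seed(seed, {
    for (i in seq_len(n_cells)) {
      idx <- which(labels == i)
      if (!length(idx)) next
      mu <- pixel_mean_curve(scene$params[[i]], irf, acq,
                             scene$photons_per_pixel[i])
      # one Poisson draw per (pixel, bin), addressed by flat array index
      draws <- stats::rpois(length(idx) * acq$n_bins,
                            lambda = rep(mu, each = length(idx)))
      flat <- rep(idx, times = acq$n_bins) +
        rep((seq_len(acq$n_bins) - 1L) * prod(dims), each = length(idx))
      counts[flat] <- draws
    }
    if (scene$background_rate > 0) {
      bg_idx <- which(labels == 0L)
      if (length(bg_idx)) {
        draws <- stats::rpois(length(bg_idx) * acq$n_bins,
                              scene$background_rate)
        flat <- rep(bg_idx, times = acq$n_bins) +
          rep((seq_len(acq$n_bins) - 1L) * prod(dims),
              each = length(bg_idx))
        counts[flat] <- draws
      }
    }
  })
  flim_cube(counts, acq, seed = seed, scene = scene)
}

#' FLIM image cube container
#'
#' @param counts Non-negative integer array `rows x cols x n_bins`.
#' @param acq A [flim_acquisition()] object; its `n_bins` must match the
#'   third dimension of `counts`.
#' @param seed,scene,provenance Optional provenance carried with the cube.
#' @return An object of class `flim_cube`.
#' @export
flim_cube <- function(counts, acq, seed = NULL, scene = NULL,
                      provenance = list()) {
  if (length(dim(counts)) != 3L)
    stop("counts must be a rows x cols x n_bins array")
  if (dim(counts)[3] != acq$n_bins)
    stop("time dimension (", dim(counts)[3], ") does not match acquisition n_bins (",
         acq$n_bins, ")")
  if (any(counts < 0)) stop("photon counts must be non-negative")
  structure(list(counts = counts, acq = acq, seed = seed, scene = scene,
                 provenance = provenance),
            class = "flim_cube")
}

#' @export
print.flim_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM cube: %d x %d pixels, %d time bins, %g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Time-summed intensity image of a cube
#' @param cube A [flim_cube()] object.
#' @return Numeric matrix of per-pixel total photons.
#' @export
intensity_image <- function(cube) {
  stopifnot(inherits(cube, "flim_cube"))
  rowSums(cube$counts, dims = 2L)
}

#' Paired two-population cohort specification
#'
#' Describes the design being emulated: `n_donors` donors each contribute a
#' matched pair of cell populations (a reference population and a shifted
#' population) that differ by `delta` in free-NAD(P)H fraction. Donor-level
#' reference free fractions are drawn around `free_fraction_ref` with
#' standard deviation `donor_sd`; individual cells scatter around their
#' donor/condition mean with standard deviation `cell_sd`. All free
#' fractions are clamped to \[0, 1\].
#'
#' @param n_donors Number of donors (>= 2; paired design).
#' @param delta Free-fraction shift of the shifted population relative to
#'   the reference (positive = more free NAD(P)H = more glycolytic = lower
#'   tau_avg).
#' @param free_fraction_ref Mean reference free fraction across donors.
#' @param donor_sd Inter-donor SD of the reference free fraction.
#' @param cell_sd Cell-to-cell SD of free fraction within a population.
#' @param cells_per_condition Cells imaged per donor and condition.
#' @param photons_per_pixel Expected signal photons per in-cell pixel.
#' @param tau1_ns,tau2_ns Free and bound lifetimes shared by all cells (ns).
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_donors = 4L, delta = 0.2, free_fraction_ref = 0.5,
                        donor_sd = 0.05, cell_sd = 0.05,
                        cells_per_condition = 8L, photons_per_pixel = 5000,
                        tau1_ns = 0.4, tau2_ns = 2.0, seed = 1L) {
  n_donors <- as.integer(n_donors)
  if (n_donors < 2L) stop("paired design requires n_donors >= 2")
  if (cells_per_condition < 1L) stop("cells_per_condition must be >= 1")
  structure(list(n_donors = n_donors, delta = delta,
                 free_fraction_ref = free_fraction_ref,
                 donor_sd = donor_sd, cell_sd = cell_sd,
                 cells_per_condition = as.integer(cells_per_condition),
                 photons_per_pixel = photons_per_pixel,
                 tau1_ns = tau1_ns, tau2_ns = tau2_ns,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a paired cohort with known ground truth
#'
#' Generates the per-cell ground-truth table of a paired two-population
#' cohort and, depending on `output`, the measured per-cell lifetimes:
#'
#' * `output = "truth"`: measured columns equal the ground truth (cell-level
#'   scatter only; no photon noise). Fast path for statistical calibration
#'   studies of the downstream paired test.
#' * `output = "fit"`: each cell's decay is simulated as one pooled
#'   histogram carrying `photons_per_pixel` expected photons per pixel times
#'   `pixels_per_cell`, then refitted with [fit_decay()]; measured columns
#'   come from the fit.
#' * `output = "cubes"`: one image cube per donor and condition is simulated
#'   ([flim_scene()] + [simulate_scene()]); measured columns are left `NA`
#'   for the image pipeline ([fit_image()], [segment_cells()],
#'   [aggregate_cells()]) to fill.
#'
#' @param spec A [cohort_spec()] object.
#' @param irf IRF model.
#' @param acq A [flim_acquisition()] object.
#' @param output One of `"truth"`, `"fit"`, `"cubes"`.
#' @param pixels_per_cell Pixels pooled per cell for `output = "fit"`.
#' @param options [fit_options()] used when `output = "fit"`.
#' @return A list of class `flim_cohort`: `cell_table` (data frame with
#'   donor, condition, cell_id, true_free_fraction, true_tau_avg_ns,
#'   mean_tau_avg_ns, mean_free_fraction), `cubes` (named list of
#'   [flim_cube()]s, or NULL), and `spec`.
#' @export
simulate_cohort <- function(spec, irf = irf_gaussian(),
                            acq = flim_acquisition(),
                            output = c("truth", "fit", "cubes"),
                            pixels_per_cell = 1L,
                            options = fit_options()) {
  stopifnot(inherits(spec, "cohort_spec"))
  output <- match.arg(output)
  conditions <- c("reference", "shifted")
  rows <- list()
  cubes <- list()
  with_seed(spec$seed, {
    for (d in seq_len(spec$n_donors)) {
      f_ref <- clamp01(spec$free_fraction_ref +
                         stats::rnorm(1, 0, spec$donor_sd))
      f_cond <- c(reference = f_ref, shifted = clamp01(f_ref + spec$delta))
      for (cond in conditions) {
        f_cells <- clamp01(stats::rnorm(spec$cells_per_condition,
                                        f_cond[[cond]], spec$cell_sd))
        cell_params <- lapply(f_cells, function(f)
          biexp_params(alpha1 = f, tau1_ns = spec$tau1_ns,
                       alpha2 = 1 - f, tau2_ns = spec$tau2_ns))
        tab <- data.frame(
          donor = sprintf("donor%02d", d),
          condition = cond,
          cell_id = seq_along(f_cells),
          true_free_fraction = f_cells,
          true_tau_avg_ns = vapply(cell_params, tau_avg, numeric(1)),
          mean_tau_avg_ns = NA_real_,
          mean_free_fraction = NA_real_
        )
        if (output == "truth") {
          tab$mean_tau_avg_ns <- tab$true_tau_avg_ns
          tab$mean_free_fraction <- tab$true_free_fraction
        } else if (output == "fit") {
          for (i in seq_along(cell_params)) {
            y <- simulate_pixel(cell_params[[i]], irf, acq,
                                n_photons = spec$photons_per_pixel *
                                  pixels_per_cell)
            fit <- fit_decay(y, irf, acq, options)
            tab$mean_tau_avg_ns[i] <- tau_avg(fit$params)
            tab$mean_free_fraction[i] <- free_fraction(fit$params)
          }
        } else { # cubes
          scene <- flim_scene(
            n_cells = spec$cells_per_condition,
            params = cell_params,
            photons_per_pixel = spec$photons_per_pixel,
            seed = NULL)  # inside cohort RNG stream
          cube <- simulate_scene(scene, irf, acq, seed = NULL)
          cube$provenance <- list(donor = tab$donor[1], condition = cond,
                                  cohort_seed = spec$seed)
          cubes[[sprintf("donor%02d_%s", d, cond)]] <- cube
        }
        rows[[length(rows) + 1L]] <- tab
      }
    }
  })
  structure(list(cell_table = do.call(rbind, rows),
                 cubes = if (output == "cubes") cubes else NULL,
                 spec = spec),
            class = "flim_cohort")
}

#' @export
print.flim_cohort <- function(x, ...) {
  cat(sprintf(
    "Paired FLIM cohort: %d donors x 2 conditions x %d cells (delta = %+.2f free fraction)\n",
    x$spec$n_donors, x$spec$cells_per_condition, x$spec$delta))
  if (!is.null(x$cubes)) cat(sprintf("  with %d image cubes\n", length(x$cubes)))
  invisible(x)
}
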