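#' Segment cells from an integrated-intensity image
#'
#' Global thresholding of the time-summed photon image (Otsu's method by
#' default, or a fixed threshold), followed by 8-connected component
#' labeling; components smaller than `min_area` pixels are discarded and
#' the surviving labels renumbered 1..k in raster (row-major) order of
#' first occurrence. A blank image yields an empty mask, not an error.
#'
#' @param intensity Numeric matrix of per-pixel total photons (see
#'   [intensity_image()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (photons) when `method = "fixed"`;
#'   pixels strictly above it are foreground.
#' @param min_area Minimum component area in pixels.
#' @return Integer label matrix of class `cell_mask` (0 = background);
#'   attribute `threshold` records the threshold used.
#' @export
segment_cells <- function(intensity, method = c("otsu", "fixed"),
                          threshold = NULL, min_area = 20L) {
  method <- match.arg(method)
  if (!is.matrix(intensity) || any(intensity < 0))
    stop("intensity must be a non-negative matrix")
  mx <- max(intensity)
  if (mx <= 0) {
    mask <- matrix(0L, nrow(intensity), ncol(intensity))
    attr(mask, "threshold") <- NA_real_
    class(mask) <- c("cell_mask", class(mask))
    return(mask)
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(intensity / mx), range = c(0, 1)) * mx
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
    threshold
  }
  fg <- intensity > thr
  labels <- label_components_8(fg)
  # area filter + renumber by raster order of first pixel
  if (max(labels) > 0L) {
    areas <- tabulate(labels)
    keep <- which(areas >= min_area)
    remap <- integer(max(labels))
    first_px <- vapply(keep, function(k) which(labels == k)[1], integer(1))
    keep <- keep[order(first_px)]
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  attr(labels, "threshold") <- thr
  class(labels) <- c("cell_mask", class(labels))
  labels
}

# 8-connected component labeling of a logical matrix by breadth-first
# search (EBImage::bwlabel is 4-connected, which splits diagonally touching
# regions; the contract here is 8-connectivity)
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  todo <- which(fg)
  next_label <- 0L
  offsets_i <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  offsets_j <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  for (start in todo) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((px - 1L) %% nr) + 1L
      j <- ((px - 1L) %/% nr) + 1L
      ni <- i + offsets_i
      nj <- j + offsets_j
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      nb <- (nj[ok] - 1L) * nr + ni[ok]
      nb <- nb[fg[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- next_label
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("Cell mask: %d x %d pixels, %d cells (threshold %.4g)\n",
              nrow(x), ncol(x), max(x), attr(x, "threshold")))
  invisible(x)
}

#' Aggregate lifetime statistics per segmented cell
#'
#' Computes per-cell summaries of a [fit_image()] lifetime map over a
#' [segment_cells()] mask: area, total photons, and the mean
#' amplitude-weighted lifetime and free fraction over the cell's *valid*
#' pixels. Cells with no valid pixel are dropped with a warning. Means are
#' unweighted over valid pixels by default; `weight = "photon"` weights
#' each pixel by its photon count.
#'
#' @param map A `lifetime_map` from [fit_image()].
#' @param mask A `cell_mask` from [segment_cells()] (same shape).
#' @param intensity Optional per-pixel total-photon matrix; when supplied,
#'   the `photons` column is the exact in-cell photon sum (conserved across
#'   cells in integer arithmetic). Otherwise photons are summed over valid
#'   pixels of the map, which double-counts spatially pooled fits.
#' @param donor,condition Metadata labels attached to every cell row.
#' @param weight `"pixel"` (unweighted over valid pixels) or `"photon"`.
#' @return A data frame (one row per cell) with columns `cell_id`, `donor`,
#'   `condition`, `area_px`, `photons`, `mean_tau_avg_ns`,
#'   `mean_free_fraction`.
#' @export
aggregate_cells <- function(map, mask, intensity = NULL,
                            donor = NA_character_,
                            condition = NA_character_,
                            weight = c("pixel", "photon")) {
  stopifnot(inherits(map, "lifetime_map"))
  weight <- match.arg(weight)
  if (!all(dim(mask) == dim(map$valid)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match lifetime map ",
         paste(dim(map$valid), collapse = "x"))
  n_cells <- max(mask)
  rows <- vector("list", n_cells)
  dropped <- integer(0)
  for (k in seq_len(n_cells)) {
    in_cell <- mask == k
    idx <- which(in_cell & map$valid)
    if (!length(idx)) {
      dropped <- c(dropped, k)
      next
    }
    w <- if (weight == "photon") map$n_photons[idx] else
      rep(1, length(idx))
    rows[[k]] <- data.frame(
      cell_id = k, donor = donor, condition = condition,
      area_px = sum(in_cell),
      photons = if (!is.null(intensity)) sum(intensity[in_cell]) else
        sum(map$n_photons[idx]),
      mean_tau_avg_ns = sum(w * map$tau_avg_ns[idx]) / sum(w),
      mean_free_fraction = sum(w * map$free_fraction[idx]) / sum(w))
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " cell(s) with no valid pixels: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), donor = character(0),
                      condition = character(0), area_px = integer(0),
                      photons = numeric(0), mean_tau_avg_ns = numeric(0),
                      mean_free_fraction = numeric(0))
  rownames(out) <- NULL
  out
}
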