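# File formats: image cubes and masks as multi-page TIFF with a JSON
# metadata sidecar (same path with .json extension), lifetime maps as
# 32-bit float multi-page TIFF (pages stored scaled into [0,1]; per-page
# scale factors live in the sidecar, since TIFF float storage is only
# defined on [0,1] by the writer), tables and measured IRFs as plain CSV.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for ", path, " (expected ", sp, ")")
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a FLIM cube as multi-page TIFF + JSON sidecar
#'
#' One 16-bit unsigned TIFF page per time bin (page order = 0-based time-bin
#' order); acquisition settings, seed and provenance go to a JSON sidecar
#' next to the TIFF. The round trip is lossless for counts up to 65535.
#'
#' @param cube A [flim_cube()] object.
#' @param path TIFF output path (sidecar written to the same path with a
#'   `.json` extension).
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   [flim_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "flim_cube"))
  if (max(cube$counts) > 65535L)
    stop("counts exceed 16-bit TIFF range (65535)")
  pages <- lapply(seq_len(cube$acq$n_bins),
                  function(b) cube$counts[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(format = "nadflim-cube", version = 1L,
               acquisition = as_acquisition_list(cube$acq),
               seed = cube$seed, provenance = cube$provenance)
  if (!is.null(cube$scene))
    meta$truth <- cube$scene$truth
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  acq <- if (!is.null(meta$acquisition))
    acquisition_from_list(meta$acquisition) else flim_acquisition()
  if (length(pages) != acq$n_bins)
    stop("format error: sidecar n_bins = ", acq$n_bins,
         " but TIFF has ", length(pages), " pages")
  counts <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) counts[, , b] <- pages[[b]]
  cube <- flim_cube(counts, acq,
                    seed = meta$seed,
                    provenance = if (is.null(meta$provenance)) list() else
                      as.list(meta$provenance))
  if (!is.null(meta$truth)) cube$truth <- as.data.frame(meta$truth)
  cube
}

#' Write / read a lifetime map as 32-bit float TIFF + JSON sidecar
#'
#' Pages (in order): tau_avg (ns), free fraction, reduced chi-square,
#' validity mask. Invalid pixels are stored as 0 and restored to NA on
#' read using the mask page.
#'
#' @param map A `lifetime_map` from [fit_image()].
#' @param path TIFF output path.
#' @return `write_lifetime_map` returns `path` invisibly;
#'   `read_lifetime_map` returns a `lifetime_map`.
#' @export
write_lifetime_map <- function(map, path) {
  stopifnot(inherits(map, "lifetime_map"))
  fill0 <- function(m) { m[!is.finite(m)] <- 0; m }
  pages_raw <- list(tau_avg_ns = fill0(map$tau_avg_ns),
                    free_fraction = fill0(map$free_fraction),
                    chisq_red = fill0(map$chisq_red),
                    valid = map$valid * 1)
  scales <- vapply(pages_raw, function(m) max(max(m), 1), numeric(1))
  pages <- Map(function(m, s) m / s, pages_raw, scales)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L,
                  compression = "none")
  write_sidecar(path, list(format = "nadflim-map", version = 1L,
                           pages = names(pages_raw),
                           page_scales = as.list(scales),
                           acquisition = as_acquisition_list(map$acq),
                           provenance = map$provenance))
  invisible(path)
}

#' @rdname write_lifetime_map
#' @export
read_lifetime_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 4L)
    stop("format error: lifetime map must have 4 pages, found ",
         length(pages))
  scales <- unlist(meta$page_scales)
  valid <- pages[[4]] * scales[4] > 0.5
  restore <- function(m, s) { m <- m * s; m[!valid] <- NA_real_; m }
  structure(list(tau_avg_ns = restore(pages[[1]], scales[1]),
                 free_fraction = restore(pages[[2]], scales[2]),
                 chisq_red = restore(pages[[3]], scales[3]),
                 n_photons = NULL, valid = valid,
                 acq = acquisition_from_list(meta$acquisition),
                 provenance = as.list(meta$provenance)),
            class = "lifetime_map")
}

#' Write / read a cell mask as 16-bit TIFF
#' @param mask A `cell_mask` from [segment_cells()].
#' @param path TIFF output path.
#' @return `write_cell_mask` returns `path` invisibly; `read_cell_mask`
#'   returns an integer label matrix.
#' @export
write_cell_mask <- function(mask, path) {
  tiff::writeTIFF(unclass(mask) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_cell_mask
#' @export
read_cell_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  class(m) <- c("cell_mask", class(m))
  m
}

#' Write / read per-cell tables as CSV
#' @param table A cell-table data frame.
#' @param path CSV path.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   a data frame.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a measured IRF as two-column CSV
#'
#' Columns: `bin_center_ns`, `normalized_weight`.
#'
#' @param irf An [irf_measured()] object.
#' @param path CSV path.
#' @return `write_irf_csv` returns `path` invisibly; `read_irf_csv` an
#'   [irf_measured()] object.
#' @export
write_irf_csv <- function(irf, path) {
  stopifnot(inherits(irf, "flim_irf"), identical(irf$kind, "measured"))
  utils::write.csv(data.frame(bin_center_ns = irf$bin_center_ns,
                              normalized_weight = irf$weight),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_irf_csv
#' @export
read_irf_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("bin_center_ns", "normalized_weight") %in% names(df)))
    stop("IRF CSV needs columns bin_center_ns, normalized_weight")
  irf_measured(df$bin_center_ns, df$normalized_weight)
}

# IRF <-> JSON-friendly list
as_irf_list <- function(irf) {
  unclass(irf)
}

irf_from_list <- function(x) {
  switch(x$kind,
    delta = irf_delta(),
    gaussian = irf_gaussian(fwhm_ns = x$fwhm_ns, center_ns = x$center_ns),
    measured = irf_measured(as.numeric(unlist(x$bin_center_ns)),
                            as.numeric(unlist(x$weight))),
    stop("unknown IRF kind: ", x$kind))
}
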