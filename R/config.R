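#' Pipeline configuration
#'
#' Bundles every stage's settings: acquisition, IRF, cohort design, fit and
#' segmentation options, output seed and verbosity. Round-trips losslessly
#' through its JSON form; unknown keys in a config file are rejected.
#'
#' @param acquisition A [flim_acquisition()] object.
#' @param irf An IRF model (see [irf]).
#' @param cohort A [cohort_spec()] object.
#' @param fit A [fit_options()] object.
#' @param min_area Segmentation minimum component area (px).
#' @param alpha Significance level of the paired comparison.
#' @param seed Master seed; each stage derives its own stream from it.
#' @param verbose Emit progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = flim_acquisition(),
                            irf = irf_gaussian(),
                            cohort = cohort_spec(),
                            fit = fit_options(),
                            min_area = 20L, alpha = 0.05,
                            seed = 1L, verbose = TRUE) {
  structure(list(acquisition = acquisition, irf = irf, cohort = cohort,
                 fit = fit, min_area = as.integer(min_area), alpha = alpha,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

config_keys <- c("acquisition", "irf", "cohort", "fit", "min_area",
                 "alpha", "seed", "verbose")

#' Write / read a pipeline configuration as JSON
#' @param config A [pipeline_config()] object.
#' @param path JSON path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fit_list <- unclass(config$fit)
  fit_list$init <- as.list(fit_list$init)  # keep names in JSON
  out <- list(acquisition = as_acquisition_list(config$acquisition),
              irf = as_irf_list(config$irf),
              cohort = unclass(config$cohort),
              fit = fit_list,
              min_area = config$min_area, alpha = config$alpha,
              seed = config$seed, verbose = config$verbose)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(config_keys, collapse = ", "), ")")
  defaults <- pipeline_config()
  acq <- if (!is.null(x$acquisition)) acquisition_from_list(x$acquisition)
    else defaults$acquisition
  irf <- if (!is.null(x$irf)) irf_from_list(x$irf) else defaults$irf
  cohort <- if (!is.null(x$cohort)) do.call(cohort_spec, x$cohort)
    else defaults$cohort
  fit <- if (!is.null(x$fit)) {
    fx <- x$fit
    fit_options(objective = fx$objective,
                init = unlist(fx$init),
                tau1_bounds = as.numeric(unlist(fx$tau1_bounds)),
                tau2_bounds = as.numeric(unlist(fx$tau2_bounds)),
                photon_threshold = fx$photon_threshold,
                bin_radius = fx$bin_radius,
                fit_background = fx$fit_background,
                background_value = fx$background_value,
                maxit = fx$maxit, factr = fx$factr)
  } else defaults$fit
  pipeline_config(acquisition = acq, irf = irf, cohort = cohort, fit = fit,
                  min_area = if (!is.null(x$min_area)) x$min_area else
                    defaults$min_area,
                  alpha = if (!is.null(x$alpha)) x$alpha else defaults$alpha,
                  seed = if (!is.null(x$seed)) x$seed else defaults$seed,
                  verbose = if (!is.null(x$verbose)) x$verbose else
                    defaults$verbose)
}
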