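# Lightweight containers for volumetric data: observed intensities with a
# validity mask, integer label allocations, per-class component models and
# the EM-HMRF configuration.

#' Intensity volume
#'
#' A 3D grid of observed intensities with a logical validity mask. Voxels
#' outside the mask take part in neither the likelihood nor the spatial
#' prior (e.g. non-brain voxels, or everything outside the gray/white-matter
#' mask in MRI use).
#'
#' @param values 3D numeric array.
#' @param mask Optional 3D logical array of the same shape; defaults to all
#'   `TRUE`. Values must be finite wherever `mask` is `TRUE`.
#' @return An object of class `intensity_volume` with fields `values`, `mask`.
#' @export
intensity_volume <- function(values, mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(values))
  }
  if (!is.array(mask) || !identical(dim(mask), dim(values)) ||
      !is.logical(mask)) {
    stop("'mask' must be a logical array with the same shape as 'values'",
         call. = FALSE)
  }
  if (!any(mask)) stop("'mask' must contain at least one voxel", call. = FALSE)
  if (any(!is.finite(values[mask]))) {
    stop("'values' must be finite on the mask", call. = FALSE)
  }
  structure(list(values = values, mask = mask), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity volume %s, %d/%d voxels masked in\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Label volume
#'
#' A 3D grid of integer class allocations: 0 marks voxels outside the mask,
#' positive integers are tissue classes (1 = class 1 / GM, 2 = class 2 / WM
#' in the two-class MRI setting).
#'
#' @param labels 3D array of non-negative integers.
#' @param n_classes Number of classes the labeling may use (default: the
#'   largest label present). Values above `n_classes` are rejected.
#' @return An object of class `label_volume` with fields `labels`, `n_classes`.
#' @export
label_volume <- function(labels, n_classes = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("'labels' must be a 3D array", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("'labels' must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (is.null(n_classes)) n_classes <- max(labels, 1L)
  bad <- unique(labels[labels > n_classes])
  if (length(bad)) {
    stop(sprintf("labels exceed n_classes = %d: %s", n_classes,
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(labels = labels, n_classes = as.integer(n_classes)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:x$n_classes))
  cat(sprintf("label volume %s (%d classes): %s\n",
              paste(dim(x$labels), collapse = "x"), x$n_classes,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Mixture component model
#'
#' One tissue class's distribution family, parameters and mixture weight.
#'
#' @param family `"stable"` or `"gaussian"`.
#' @param params A [stable_params] or [gaussian_params] object, matching
#'   `family`.
#' @param weight Mixture proportion in \[0, 1\].
#' @return An object of class `component_model`.
#' @export
component_model <- function(family = c("stable", "gaussian"), params, weight) {
  family <- match.arg(family)
  ok <- switch(family,
               stable = inherits(params, "stable_params"),
               gaussian = inherits(params, "gaussian_params"))
  if (!ok) stop("'params' does not match 'family'", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1) {
    stop("'weight' must be a proportion in [0, 1]", call. = FALSE)
  }
  structure(list(family = family, params = params, weight = as.numeric(weight)),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("component [%s], weight %.4f: %s\n", x$family, x$weight,
              if (x$family == "stable") format(x$params)
              else sprintf("N(mu=%.4g, sigma=%.4g)", x$params$mu,
                           x$params$sigma)))
  invisible(x)
}

# log-density of one component at intensities x, floored for log-safety
.model_logpdf <- function(x, model) {
  if (model$family == "stable") {
    stable_logpdf(x, model$params)
  } else {
    log(pmax(stats::dnorm(x, model$params$mu, model$params$sigma),
             .STABLE_FLOOR))
  }
}

#' EM-HMRF configuration
#'
#' Tuning parameters of the segmentation engine. `beta_c` weighs the Potts
#' spatial prior against the data likelihood: 0 reduces the model to a
#' spatial-free finite mixture, larger values smooth more. The default 0.5
#' gives a good likelihood/prior balance for tissue segmentation.
#'
#' @param beta_c Clique coefficient, >= 0 (default 0.5).
#' @param max_iter Maximum EM iterations (default 20).
#' @param icm_sweeps_per_iter ICM label-update sweeps per EM iteration
#'   (default 1).
#' @param tol Relative posterior-energy change declaring convergence
#'   (default 1e-4).
#' @param family Component family, `"stable"` or `"gaussian"`.
#' @param seed Integer seed controlling optimizer restarts (default 0).
#' @param min_class_size Minimum voxels per class for the per-class fits
#'   (default 50).
#' @return An object of class `hmrf_config`.
#' @export
hmrf_config <- function(beta_c = 0.5, max_iter = 20L, icm_sweeps_per_iter = 1L,
                        tol = 1e-4, family = c("stable", "gaussian"),
                        seed = 0L, min_class_size = 50L) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta_c), length(beta_c) == 1L, beta_c >= 0,
            is.numeric(max_iter), max_iter >= 1,
            is.numeric(icm_sweeps_per_iter), icm_sweeps_per_iter >= 1,
            is.numeric(tol), tol > 0,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(min_class_size), min_class_size >= 1)
  structure(list(beta_c = as.numeric(beta_c), max_iter = as.integer(max_iter),
                 icm_sweeps_per_iter = as.integer(icm_sweeps_per_iter),
                 tol = as.numeric(tol), family = family,
                 seed = as.integer(seed),
                 min_class_size = as.integer(min_class_size)),
            class = "hmrf_config")
}

#' Serialize an EM-HMRF configuration to / from JSON
#'
#' @param config An [hmrf_config] object.
#' @param json A JSON string as produced by `hmrf_config_to_json()`.
#' @return A JSON string, or an [hmrf_config] object.
#' @export
hmrf_config_to_json <- function(config) {
  stopifnot(inherits(config, "hmrf_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname hmrf_config_to_json
#' @export
hmrf_config_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  do.call(hmrf_config, obj)
}
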