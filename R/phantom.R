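# Synthetic hollow-sphere ("empty sphere") phantom: a two-class ground
# truth on a small 3D grid, rendered with per-class alpha-stable or
# Gaussian noise. The default spec is the canonical benchmark used
# throughout the package's tests: a 20x20x20 box, shell between radii 5 and
# 8 around the grid center, component 1 (background + inner core) vs
# component 2 (shell).

#' Phantom specification
#'
#' Describes a hollow-sphere phantom: grid dimensions, sphere center and
#' radii, noise family and per-class generating parameters. The defaults are
#' the canonical two-class benchmark: a 20x20x20 grid with the shell between
#' radii 5 and 8 voxels around the grid center; for the stable family,
#' component 1 is `S0(alpha=1.4, beta=1, gamma=10, delta=0)` and component 2
#' `S0(alpha=1.8, beta=0, gamma=10, delta=20)`; for the Gaussian family,
#' `N(0, 14.14^2)` and `N(20, 14.14^2)` (the `sigma = sqrt(2)*gamma`
#' counterparts of `gamma = 10`).
#'
#' @param dims Integer triple of voxel counts (default `c(20, 20, 20)`).
#' @param center Real triple, sphere center in 0-based voxel coordinates
#'   (default the grid center, `(dims - 1) / 2`).
#' @param r_inner,r_outer Shell radii in voxels; `0 < r_inner < r_outer <
#'   min(dims)/2`. A voxel belongs to the shell (class 2) when its center's
#'   Euclidean distance `d` from `center` satisfies `r_inner <= d < r_outer`.
#' @param family `"stable"` or `"gaussian"`.
#' @param comp1,comp2 Generating parameters for class 1 (background + core)
#'   and class 2 (shell): [stable_params] or [gaussian_params] matching
#'   `family`. Defaults as described above.
#' @param seed Integer seed for the noise rendering.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(20L, 20L, 20L), center = (dims - 1) / 2,
                         r_inner = 5, r_outer = 8,
                         family = c("stable", "gaussian"),
                         comp1 = NULL, comp2 = NULL, seed = 0L) {
  family <- match.arg(family)
  stopifnot(length(dims) == 3L, all(dims >= 1), all(dims == round(dims)),
            length(center) == 3L, all(is.finite(center)))
  if (!(r_inner > 0 && r_inner < r_outer && r_outer < min(dims) / 2)) {
    stop("radii must satisfy 0 < r_inner < r_outer < min(dims)/2",
         call. = FALSE)
  }
  if (is.null(comp1)) {
    comp1 <- if (family == "stable") stable_params(1.4, 1, 10, 0)
    else gaussian_params(0, 14.14)
  }
  if (is.null(comp2)) {
    comp2 <- if (family == "stable") stable_params(1.8, 0, 10, 20)
    else gaussian_params(20, 14.14)
  }
  want <- if (family == "stable") "stable_params" else "gaussian_params"
  if (!inherits(comp1, want) || !inherits(comp2, want)) {
    stop(sprintf("component parameters must be <%s> for family '%s'",
                 want, family), call. = FALSE)
  }
  structure(list(dims = as.integer(dims), center = as.numeric(center),
                 r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer),
                 family = family, comp1 = comp1, comp2 = comp2,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "hollow-sphere phantom: %s grid, shell %g <= d < %g around (%s), %s noise, seed %d\n",
    paste(x$dims, collapse = "x"), x$r_inner, x$r_outer,
    paste(format(x$center), collapse = ", "), x$family, x$seed))
  invisible(x)
}

#' Ground-truth labels of the hollow-sphere phantom
#'
#' Labels every voxel of the grid: class 2 (shell) where the voxel center's
#' Euclidean distance from the sphere center lies in `[r_inner, r_outer)`,
#' class 1 elsewhere (background and inner core). The mask covers the whole
#' grid, so class counts always partition `prod(dims)`.
#'
#' @param spec A [phantom_spec].
#' @return A [label_volume].
#' @export
hollow_sphere_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  gx <- (seq_len(d[1]) - 1) - spec$center[1]
  gy <- (seq_len(d[2]) - 1) - spec$center[2]
  gz <- (seq_len(d[3]) - 1) - spec$center[3]
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  lab <- array(1L, dim = d)
  lab[r2 >= spec$r_inner^2 & r2 < spec$r_outer^2] <- 2L
  label_volume(lab, n_classes = 2L)
}

#' Render the phantom's noisy intensity volume
#'
#' Draws every voxel's intensity independently from its class's generating
#' distribution (Chambers-Mallows-Stuck draws for the stable family,
#' Gaussian draws otherwise), seeded by `spec$seed`: the same spec and seed
#' always reproduce the volume bit-exactly, and the caller's RNG stream is
#' left untouched.
#'
#' @param labels A [label_volume] with the phantom's ground truth (shape
#'   must match `spec$dims`).
#' @param spec A [phantom_spec].
#' @return An [intensity_volume] (full mask).
#' @export
render_phantom <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  if (!identical(dim(labels$labels), spec$dims)) {
    stop("label shape does not match the phantom spec dims", call. = FALSE)
  }
  i1 <- labels$labels == 1L
  i2 <- labels$labels == 2L
  v <- array(0, dim = spec$dims)
  draw <- function(n, p) {
    if (spec$family == "stable") .stable_rng(n, p)
    else stats::rnorm(n, p$mu, p$sigma)
  }
  .with_seed(spec$seed, {
    v[i1] <- draw(sum(i1), spec$comp1)
    v[i2] <- draw(sum(i2), spec$comp2)
  })
  intensity_volume(v)
}

#' Generate a complete hollow-sphere phantom
#'
#' Convenience wrapper returning the ground truth and the rendered noisy
#' volume together.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `truth` ([label_volume]), `image`
#'   ([intensity_volume]) and `spec`.
#' @export
hollow_sphere_phantom <- function(spec = phantom_spec()) {
  truth <- hollow_sphere_labels(spec)
  list(truth = truth, image = render_phantom(truth, spec), spec = spec)
}

#' Serialize a phantom spec to / from JSON
#'
#' @param spec A [phantom_spec].
#' @param json A JSON string produced by `phantom_spec_to_json()`.
#' @return A JSON string, or a [phantom_spec].
#' @export
phantom_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- unclass(spec)
  obj$comp1 <- unclass(obj$comp1)
  obj$comp2 <- unclass(obj$comp2)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' @rdname phantom_spec_to_json
#' @export
phantom_spec_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  mk <- function(p) {
    if (o$family == "stable") {
      stable_params(p$alpha, p$beta, p$gamma, p$delta,
                    beta_undefined = isTRUE(p$beta_undefined))
    } else gaussian_params(p$mu, p$sigma)
  }
  phantom_spec(dims = o$dims, center = o$center, r_inner = o$r_inner,
               r_outer = o$r_outer, family = o$family,
               comp1 = mk(o$comp1), comp2 = mk(o$comp2), seed = o$seed)
}
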