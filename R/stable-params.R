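#' Alpha-stable parameter set
#'
#' Container for the four parameters of a univariate alpha-stable law in
#' Nolan's S0 (continuous-in-alpha) parameterization: characteristic exponent
#' `alpha` in (0, 2], asymmetry `beta` in \[-1, 1\], dispersion `gamma` > 0 and
#' location `delta`. The Gaussian law is the `alpha = 2` limiting case with
#' standard deviation `sigma = sqrt(2) * gamma`; `alpha = 1, beta = 0` is the
#' Cauchy law with scale `gamma` and median `delta`.
#'
#' At the Gaussian boundary `alpha = 2` the characteristic function no longer
#' depends on `beta`, so the asymmetry parameter carries no distributional
#' meaning; it is stored as 0 and flagged via `beta_undefined`.
#'
#' @param alpha Characteristic exponent, in (0, 2]. Smaller values give
#'   heavier tails.
#' @param beta Asymmetry, in \[-1, 1\].
#' @param gamma Dispersion (scale, same units as the data), > 0.
#' @param delta Location (same units as the data).
#' @param beta_undefined Logical flag set when `alpha = 2` makes `beta`
#'   meaningless. Defaults to `alpha == 2`.
#' @return An object of class `stable_params`.
#' @examples
#' stable_params(1.4, 1, 10, 0)
#' stable_params(2, 0, 10, 20) # Gaussian with sigma = sqrt(2)*10
#' @export
stable_params <- function(alpha, beta, gamma, delta,
                          beta_undefined = (alpha == 2)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 2) {
    stop("'alpha' must be a single finite value in (0, 2]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < -1 || beta > 1) {
    stop("'beta' must be a single finite value in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    stop("'gamma' must be a single finite positive value", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("'delta' must be a single finite value", call. = FALSE)
  }
  if (alpha == 2) beta <- 0
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         beta_undefined = isTRUE(beta_undefined)),
    class = "stable_params"
  )
}

#' @export
print.stable_params <- function(x, ...) {
  beta_txt <- if (x$beta_undefined) "undefined (alpha = 2)" else
    format(x$beta, digits = 4)
  cat("alpha-stable parameters (S0):\n",
      "  alpha = ", format(x$alpha, digits = 4),
      "  beta = ", beta_txt,
      "  gamma = ", format(x$gamma, digits = 4),
      "  delta = ", format(x$delta, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
format.stable_params <- function(x, ...) {
  sprintf("S0(alpha=%.4g, beta=%.4g%s, gamma=%.4g, delta=%.4g)",
          x$alpha, x$beta, if (x$beta_undefined) " [undef]" else "",
          x$gamma, x$delta)
}

#' Gaussian parameter set
#'
#' Mean/standard-deviation parameters for the Gaussian component family, the
#' `alpha = 2` limiting case of the stable family (`sigma = sqrt(2) * gamma`).
#'
#' @param mu Location (mean), intensity units.
#' @param sigma Standard deviation, > 0.
#' @return An object of class `gaussian_params`.
#' @export
gaussian_params <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("'mu' must be a single finite value", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single finite positive value", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Gaussian parameters: mu = %.4g, sigma = %.4g\n", x$mu, x$sigma))
  invisible(x)
}

#' Convert stable parameters between the S0 and S1 parameterizations
#'
#' The package works internally in Nolan's S0 parameterization, which is
#' continuous in `alpha`. The classical S1 parameterization shares
#' `alpha`, `beta`, `gamma` and differs only in location:
#' `delta0 = delta1 + beta * gamma * tan(pi * alpha / 2)` for `alpha != 1`, and
#' `delta0 = delta1 + beta * (2/pi) * gamma * log(gamma)` for `alpha = 1`.
#'
#' @param params A [stable_params] object, interpreted in the `from`
#'   parameterization.
#' @param from,to Either `"S0"` or `"S1"`.
#' @return A [stable_params] object in the `to` parameterization.
#' @export
stable_convert <- function(params, from = c("S0", "S1"), to = c("S1", "S0")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(inherits(params, "stable_params"))
  if (from == to) return(params)
  shift <- if (params$alpha == 1) {
    params$beta * (2 / pi) * params$gamma * log(params$gamma)
  } else {
    params$beta * params$gamma * tan(pi * params$alpha / 2)
  }
  delta <- if (from == "S1") params$delta + shift else params$delta - shift
  stable_params(params$alpha, params$beta, params$gamma, delta,
                beta_undefined = params$beta_undefined)
}

#' Serialize stable parameters to / from JSON
#'
#' Round-trips a parameter set through a flat JSON object
#' `{"alpha":..., "beta":..., "gamma":..., "delta":..., "beta_undefined":...}`.
#'
#' @param params A [stable_params] object.
#' @param json A JSON string as produced by `stable_params_to_json()`.
#' @return `stable_params_to_json()` returns a JSON string;
#'   `stable_params_from_json()` returns a [stable_params] object.
#' @export
stable_params_to_json <- function(params) {
  stopifnot(inherits(params, "stable_params"))
  jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
}

#' @rdname stable_params_to_json
#' @export
stable_params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  stable_params(obj$alpha, obj$beta, obj$gamma, obj$delta,
                beta_undefined = isTRUE(obj$beta_undefined))
}
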