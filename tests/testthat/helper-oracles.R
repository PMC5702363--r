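# Independent oracles used across the suite.

# Slow per-point quadrature inversion of the stable characteristic function
# (S0): f(x) = (1/pi) Int_0^inf Re(exp(-i t z) psi(t)) dt / gamma.
# Independent of the package's FFT-grid evaluation path.
quad_stable_pdf <- function(x, alpha, beta, gamma, delta) {
  cf <- function(t) {
    if (alpha == 1) {
      w <- ifelse(t == 0, 0, beta * (2 / pi) * log(abs(t)))
      exp(-abs(t) * (1 + 1i * w))
    } else {
      w <- ifelse(t == 0, 0,
                  beta * tan(pi * alpha / 2) * (abs(t)^(1 - alpha) - 1))
      exp(-abs(t)^alpha * (1 + 1i * w))
    }
  }
  vapply(x, function(xi) {
    z <- (xi - delta) / gamma
    ig <- function(t) Re(exp(-1i * t * z) * cf(t))
    stats::integrate(ig, 0, Inf, rel.tol = 1e-12,
                     subdivisions = 2000L)$value / (pi * gamma)
  }, numeric(1))
}

# Brute-force Potts prior energy by triple loop over voxels and the 6-neighborhood
brute_prior_energy <- function(lab, beta_c) {
  d <- dim(lab)
  e <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (lab[i, j, k] == 0L) next
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii > d[1] || jj > d[2] || kk > d[3]) next
      if (lab[ii, jj, kk] == 0L) next
      if (lab[ii, jj, kk] != lab[i, j, k]) e <- e + beta_c
    }
  }
  e
}

# random small label array with both classes present
random_labels <- function(dims, seed, p_zero = 0) {
  set.seed(seed)
  repeat {
    l <- array(sample(0:2, prod(dims), replace = TRUE,
                      prob = c(p_zero, (1 - p_zero) / 2, (1 - p_zero) / 2)),
               dim = dims)
    if (sum(l == 1L) > 0 && sum(l == 2L) > 0) return(l)
  }
}

# small gaussian two-class test fixture: volume + labels + fitted-form models
gaussian_fixture <- function(dims = c(6L, 6L, 6L), seed = 1,
                             mu = c(0, 6), sigma = c(2, 2)) {
  lab <- random_labels(dims, seed)
  lab[lab == 0L] <- 1L
  set.seed(seed + 1000)
  v <- array(0, dim = dims)
  v[lab == 1L] <- rnorm(sum(lab == 1L), mu[1], sigma[1])
  v[lab == 2L] <- rnorm(sum(lab == 2L), mu[2], sigma[2])
  models <- list(
    component_model("gaussian", gaussian_params(mu[1], sigma[1]), 0.5),
    component_model("gaussian", gaussian_params(mu[2], sigma[2]), 0.5))
  list(y = intensity_volume(v), labels = label_volume(lab, 2L),
       models = models)
}
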