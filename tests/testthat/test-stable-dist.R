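# Numerical stable-distribution machinery: density, log-density, CDF,
# sampling, quantile initialization, maximum likelihood.

test_that("closed-form special cases: Gaussian and Cauchy limits", {
  # alpha = 2 is N(delta, 2*gamma^2): sigma = sqrt(2)*gamma
  expect_equal(stable_pdf(0, stable_params(2, 0, 1, 0)), 1 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_equal(stable_logpdf(0, stable_params(2, 0, 1, 0)),
               -log(2 * sqrt(pi)), tolerance = 1e-12)
  xg <- seq(-60, 60, length.out = 2001)
  expect_lt(max(abs(stable_pdf(xg, stable_params(2, 0, 3, -1)) -
                      dnorm(xg, -1, sqrt(2) * 3))), 1e-6)
  # alpha = 1, beta = 0 is Cauchy(delta, gamma)
  expect_equal(stable_pdf(0, stable_params(1, 0, 1, 0)), 1 / pi,
               tolerance = 1e-12)
  expect_lt(max(abs(stable_pdf(xg, stable_params(1, 0, 2, 5)) -
                      dcauchy(xg, 5, 2))), 1e-6)
})

test_that("pdf and logpdf agree with the direct quadrature oracle", {
  xg <- seq(-20, 20, length.out = 41)
  ours <- stable_pdf(xg, stable_params(1.5, 0.5, 2, 1))
  oracle <- quad_stable_pdf(xg, 1.5, 0.5, 2, 1)
  expect_lt(max(abs(ours - oracle)), 1e-6)

  lo <- stable_logpdf(xg, stable_params(1.7, -0.3, 3, 5))
  oracle2 <- quad_stable_pdf(xg, 1.7, -0.3, 3, 5)
  expect_lt(max(abs(lo - log(oracle2))), 1e-5)
})

test_that("log-density is floored: finite deep in the tails", {
  for (p in list(stable_params(1.7, 0, 1, 0), stable_params(0.9, 1, 2, 3),
                 stable_params(2, 0, 1, 0))) {
    lp <- stable_logpdf(p$delta + c(-1000, 1000) * p$gamma, p)
    expect_true(all(is.finite(lp)))
    expect_true(all(lp < 0))
  }
})

test_that("parameter and input validation errors", {
  expect_error(stable_params(2.5, 0, 1, 0), "alpha")
  expect_error(stable_params(1.5, 2, 1, 0), "beta")
  expect_error(stable_params(1.5, 0, -1, 0), "gamma")
  expect_error(stable_pdf(c(1, NaN), stable_params(1.5, 0, 1, 0)),
               "non-finite")
  expect_error(stable_pdf(Inf, stable_params(1.5, 0, 1, 0)), "non-finite")
})

test_that("density integrates to ~1 over [delta - 200 gamma, delta + 200 gamma]", {
  for (a in c(1, 1.3, 1.6, 2)) {
    for (b in c(-0.7, 0, 0.5)) {
      p <- stable_params(a, if (a == 2) 0 else b, 2, 1)
      xg <- seq(p$delta - 200 * p$gamma, p$delta + 200 * p$gamma,
                length.out = 40001)
      f <- stable_pdf(xg, p)
      mass <- sum((f[-1] + f[-length(f)]) / 2 * diff(xg))
      expect_gte(mass, 0.98)
      expect_lte(mass, 1.0 + 1e-6)
    }
  }
})

test_that("sampling: moments, symmetry, determinism", {
  x <- stable_sample(1e5, stable_params(2, 0, 10, 0), seed = 11)
  expect_equal(sd(x), sqrt(2) * 10, tolerance = 0.02)
  x <- stable_sample(1e5, stable_params(1, 0, 1, 7), seed = 12)
  expect_lt(abs(median(x) - 7), 0.05)
  a <- stable_sample(1000, stable_params(1.4, 1, 10, 0), seed = 13)
  b <- stable_sample(1000, stable_params(1.4, 1, 10, 0), seed = 13)
  expect_identical(a, b)
  # seeding is local: the caller's RNG stream is not disturbed
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(stable_sample(10, stable_params(1.5, 0, 1, 0), 5))
  expect_identical(runif(1), r1)
})

test_that("samples match the numerically integrated CDF (KS distance)", {
  p <- stable_params(1.5, 0.5, 2, 1)
  x <- sort(stable_sample(1e5, p, seed = 21))
  ks <- max(abs(stats::ecdf(x)(x) - stable_cdf(x, p)))
  expect_lt(ks, 0.01)
})

test_that("quantile initialization recovers Gaussian-limit parameters", {
  x <- stable_sample(1e5, stable_params(2, 0, 10, 20), seed = 31)
  est <- mcculloch_init(x)
  expect_gte(est$alpha, 1.9)
  expect_lt(abs(est$delta - 20), 1)
})

test_that("quantile initialization is location- and scale-equivariant", {
  x <- stable_sample(5000, stable_params(1.4, 0.5, 3, -2), seed = 32)
  e0 <- mcculloch_init(x)
  es <- mcculloch_init(x + 17)
  expect_equal(es$alpha, e0$alpha)
  expect_equal(es$beta, e0$beta)
  expect_equal(es$gamma, e0$gamma, tolerance = 1e-10)
  expect_equal(es$delta, e0$delta + 17, tolerance = 1e-10)
  ek <- mcculloch_init(3 * x)
  expect_equal(ek$alpha, e0$alpha)
  expect_equal(ek$gamma, 3 * e0$gamma, tolerance = 1e-10)
})

test_that("quantile initialization rejects degenerate samples", {
  expect_error(mcculloch_init(rep(1, 100)), "degenerate")
  expect_error(mcculloch_init(c(1, 2, 3)), "at least 10")
})

test_that("MLE satisfies the ascent contract and recovers parameters", {
  p <- stable_params(1.8, 0, 10, 20)
  x <- stable_sample(8000, p, seed = 41)
  fit <- stable_fit_mle(x)
  expect_gte(attr(fit, "loglik"), attr(fit, "init_loglik"))
  expect_lt(abs(fit$alpha - 1.8), 0.1)
  expect_lt(abs(fit$delta - 20), 1)
  # heavier-tailed, fully skewed component
  p2 <- stable_params(1.4, 1, 10, 0)
  x2 <- stable_sample(8000, p2, seed = 42)
  fit2 <- stable_fit_mle(x2)
  expect_gte(attr(fit2, "loglik"), attr(fit2, "init_loglik"))
  expect_lt(abs(fit2$alpha - 1.4), 0.1)
})

test_that("MLE flags beta undefined at the Gaussian boundary", {
  x <- stable_sample(8000, stable_params(2, 0, 10, 20), seed = 43)
  fit <- stable_fit_mle(x)
  expect_equal(fit$alpha, 2)
  expect_true(fit$beta_undefined)
  expect_equal(fit$beta, 0)
  expect_equal(fit$gamma, 10, tolerance = 0.1)
  expect_equal(fit$delta, 20, tolerance = 0.1)
})

test_that("MLE input contracts", {
  expect_error(stable_fit_mle(rnorm(10)), "at least 50")
  expect_error(stable_fit_mle(rep(c(1, 2), 50)), "degenerate")
})

test_that("S0/S1 conversion round-trips and shifts only the location", {
  p <- stable_params(1.4, 1, 10, 0)
  q <- stable_convert(p, "S0", "S1")
  expect_equal(q$alpha, p$alpha)
  expect_equal(q$gamma, p$gamma)
  back <- stable_convert(q, "S1", "S0")
  expect_equal(back$delta, p$delta, tolerance = 1e-12)
})

test_that("parameters serialize to JSON and back", {
  p <- stable_params(1.7, -0.3, 3, 5)
  expect_equal(stable_params_from_json(stable_params_to_json(p)), p)
  p2 <- stable_params(2, 0, 1, 0)
  expect_true(stable_params_from_json(stable_params_to_json(p2))$beta_undefined)
})
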