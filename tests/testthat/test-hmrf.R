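# EM-HMRF engine: energies, ICM updates, component fits, EM loop.

test_that("prior energy: hand-enumerated clique cases", {
  expect_equal(prior_energy(label_volume(array(1L, c(3, 3, 3))), 0.5), 0)
  expect_equal(prior_energy(label_volume(array(c(1L, 2L), c(1, 1, 2))), 0.5),
               0.5)
  chk <- label_volume(array(c(1L, 2L, 2L, 1L), c(2, 2, 1)))
  expect_equal(prior_energy(chk, 0.5), 2.0)
})

test_that("prior energy matches brute-force enumeration on random labelings", {
  for (s in 1:5) {
    lab <- random_labels(c(5, 4, 3), seed = s, p_zero = 0.2)
    expect_equal(prior_energy(label_volume(lab), 0.7),
                 brute_prior_energy(lab, 0.7))
  }
})

test_that("likelihood energy: single-voxel value and additivity", {
  m <- list(component_model("stable", stable_params(2, 0, 1, 0), 1))
  y1 <- intensity_volume(array(0, c(1, 1, 1)))
  l1 <- label_volume(array(1L, c(1, 1, 1)))
  expect_equal(likelihood_energy(y1, l1, m), log(2 * sqrt(pi)),
               tolerance = 1e-12)
  y2 <- intensity_volume(array(0, c(1, 1, 2)))
  l2 <- label_volume(array(1L, c(1, 1, 2)))
  expect_equal(likelihood_energy(y2, l2, m),
               2 * likelihood_energy(y1, l1, m), tolerance = 1e-12)
})

test_that("likelihood energy matches a per-voxel quadrature-oracle loop", {
  set.seed(7)
  dims <- c(5, 5, 4)
  lab <- random_labels(dims, seed = 7)
  lab[lab == 0L] <- 1L
  y <- array(runif(prod(dims), -15, 25), dim = dims)
  models <- list(
    component_model("stable", stable_params(1.5, 0.5, 2, 1), 0.5),
    component_model("stable", stable_params(1.7, -0.3, 3, 5), 0.5))
  got <- likelihood_energy(intensity_volume(y), label_volume(lab), models)
  want <- 0
  for (i in seq_along(y)) {
    p <- models[[lab[i]]]$params
    want <- want - log(quad_stable_pdf(y[i], p$alpha, p$beta, p$gamma,
                                       p$delta))
  }
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("likelihood energy requires a model for every observed label", {
  fx <- gaussian_fixture(seed = 3)
  expect_error(likelihood_energy(fx$y, fx$labels, fx$models[1]),
               "no component model")
})

test_that("ICM with beta_c = 0 equals the per-voxel density argmax", {
  fx <- gaussian_fixture(seed = 11)
  cfg <- hmrf_config(beta_c = 0, family = "gaussian")
  out <- icm_sweep(fx$y, fx$labels, fx$models, cfg)
  d1 <- dnorm(fx$y$values, fx$models[[1]]$params$mu,
              fx$models[[1]]$params$sigma)
  d2 <- dnorm(fx$y$values, fx$models[[2]]$params$mu,
              fx$models[[2]]$params$sigma)
  want <- ifelse(d2 > d1, 2L, 1L)
  expect_identical(as.vector(out$labels), as.vector(want))
})

test_that("ICM flips an isolated discordant voxel when densities tie", {
  # center voxel observes y = 0 where both class densities are equal;
  # its 6 concordant-to-1 neighbors decide via the prior term 6*beta_c
  lab <- array(1L, c(3, 3, 3))
  lab[2, 2, 2] <- 2L
  v <- array(-5, c(3, 3, 3))
  v[2, 2, 2] <- 0
  models <- list(
    component_model("gaussian", gaussian_params(-5, 3), 0.5),
    component_model("gaussian", gaussian_params(5, 3), 0.5))
  out <- icm_sweep(intensity_volume(v), label_volume(lab), models,
                   hmrf_config(beta_c = 0.5, family = "gaussian"))
  expect_equal(out$labels[2, 2, 2], 1L)
})

test_that("ICM never increases the posterior energy", {
  for (s in 1:5) {
    fx <- gaussian_fixture(dims = c(7L, 6L, 5L), seed = s)
    cfg <- hmrf_config(beta_c = 0.75, family = "gaussian")
    before <- posterior_energy(fx$y, fx$labels, fx$models, cfg$beta_c)
    lab <- fx$labels
    for (k in 1:3) {
      lab <- icm_sweep(fx$y, lab, fx$models, cfg)
      after <- posterior_energy(fx$y, lab, fx$models, cfg$beta_c)
      expect_lte(after, before + 1e-9)
      before <- after
    }
  }
})

test_that("component fits recover Gaussian truth and proper weights", {
  fx <- gaussian_fixture(dims = c(12L, 12L, 12L), seed = 21,
                         mu = c(0, 10), sigma = c(2, 3))
  models <- fit_components(fx$y, fx$labels, family = "gaussian")
  n1 <- sum(fx$labels$labels == 1L)
  n2 <- sum(fx$labels$labels == 2L)
  expect_equal(models[[1]]$weight + models[[2]]$weight, 1, tolerance = 1e-12)
  expect_lt(abs(models[[1]]$params$mu - 0), 3 * 2 / sqrt(n1))
  expect_lt(abs(models[[2]]$params$mu - 10), 3 * 3 / sqrt(n2))
  expect_equal(models[[1]]$params$sigma, 2, tolerance = 0.15)
})

test_that("component fits raise an empty-class error naming the class", {
  fx <- gaussian_fixture(seed = 22)
  all1 <- fx$labels
  all1$labels[] <- 1L
  err <- tryCatch(fit_components(fx$y, all1, family = "gaussian"),
                  error = function(e) e)
  expect_s3_class(err, "stableHMRF_empty_class")
  expect_match(conditionMessage(err), "class 2")
})

test_that("one EM iteration at beta_c = 0 equals naive-Bayes classification", {
  fx <- gaussian_fixture(dims = c(8L, 8L, 8L), seed = 31, mu = c(0, 5))
  cfg <- hmrf_config(beta_c = 0, max_iter = 1, family = "gaussian")
  res <- em_hmrf(fx$y, fx$labels, cfg)
  models <- fit_components(fx$y, fx$labels, family = "gaussian")
  ll1 <- dnorm(fx$y$values, models[[1]]$params$mu, models[[1]]$params$sigma,
               log = TRUE)
  ll2 <- dnorm(fx$y$values, models[[2]]$params$mu, models[[2]]$params$sigma,
               log = TRUE)
  nb <- ifelse(ll2 > ll1, 2L, 1L)
  expect_identical(as.vector(res$labels$labels), as.vector(nb))
})

test_that("segmentation is equivariant under class relabeling", {
  fx <- gaussian_fixture(dims = c(8L, 8L, 8L), seed = 41, mu = c(0, 6))
  cfg <- hmrf_config(family = "gaussian", max_iter = 5)
  res <- em_hmrf(fx$y, fx$labels, cfg)
  swapped_init <- fx$labels
  swapped_init$labels <- array(c(2L, 1L)[fx$labels$labels],
                               dim = dim(fx$labels$labels))
  res_sw <- em_hmrf(fx$y, swapped_init, cfg)
  expect_identical(as.vector(res_sw$labels$labels),
                   as.vector(c(2L, 1L)[res$labels$labels]))
})

test_that("stable and Gaussian families agree on unambiguous Gaussian data", {
  ph <- hollow_sphere_phantom(phantom_spec(family = "gaussian", seed = 5))
  cfg_s <- hmrf_config(family = "stable", seed = 5)
  cfg_g <- hmrf_config(family = "gaussian", seed = 5)
  rs <- em_hmrf(ph$image, ph$truth, cfg_s)
  rg <- em_hmrf(ph$image, ph$truth, cfg_g)
  mods <- rg$models_per_iter[[rg$n_iter]]
  lr <- abs(dnorm(ph$image$values, mods[[1]]$params$mu,
                  mods[[1]]$params$sigma, log = TRUE) -
              dnorm(ph$image$values, mods[[2]]$params$mu,
                    mods[[2]]$params$sigma, log = TRUE))
  unamb <- lr > 0.1
  agree <- mean(rs$labels$labels[unamb] == rg$labels$labels[unamb])
  expect_gte(agree, 0.99)
})

test_that("stronger spatial coupling never increases discordant pairs", {
  ph <- hollow_sphere_phantom(phantom_spec(family = "gaussian", seed = 9))
  disc <- vapply(c(0, 0.25, 0.5, 1, 2), function(bc) {
    res <- em_hmrf(ph$image, ph$truth,
                   hmrf_config(beta_c = bc, family = "gaussian", seed = 9))
    prior_energy(res$labels, 1)
  }, numeric(1))
  expect_true(all(diff(disc) <= 0))
})

test_that("EM records coherent traces and converges on easy data", {
  fx <- gaussian_fixture(dims = c(10L, 10L, 10L), seed = 51, mu = c(0, 8))
  res <- em_hmrf(fx$y, fx$labels, hmrf_config(family = "gaussian"))
  expect_true(res$converged)
  expect_length(res$energy_trace, res$n_iter)
  expect_length(res$loglik_trace, res$n_iter)
  expect_length(res$models_per_iter, res$n_iter)
  tr <- trace_as_data_frame(res)
  expect_equal(nrow(tr), res$n_iter)
  expect_true(all(c("posterior_energy", "loglik", "mu_1", "sigma_2") %in%
                    names(tr)))
})

test_that("EM propagates the empty-class error with the iteration index", {
  # a single-class truth forces the empty-class contract at iteration 1
  fx <- gaussian_fixture(seed = 61)
  one <- fx$labels
  one$labels[] <- 1L
  one$labels[1, 1, 1] <- 2L  # class present but far below the minimum
  expect_error(em_hmrf(fx$y, one, hmrf_config(family = "gaussian")),
               "EM iteration 1")
})

test_that("config serializes to JSON and back", {
  cfg <- hmrf_config(beta_c = 0.25, max_iter = 7, family = "gaussian",
                     seed = 3)
  expect_equal(hmrf_config_from_json(hmrf_config_to_json(cfg)), cfg)
})
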