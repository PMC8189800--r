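test_that("prior_spec validates and prior odds are computed both ways", {
  p <- prior_spec()
  expect_equal(p$kmax, 5)
  expect_equal(prior_odds_multimodal(p), 4)
  expect_equal(prior_odds_multimodal(p, method = "simulation", n_sim = 2e5,
                                     seed = 3), 4, tolerance = 0.05)
  expect_error(prior_spec(kmax = 3, k_prior = c(0.5, 0.5)))
  expect_error(prior_spec(delta = 0))
  p2 <- prior_spec(kmax = 4, k_prior = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(prior_odds_multimodal(p2), 0.6 / 0.4)
})

test_that("bayes_factor matches the posterior/prior odds ratio and sentinels", {
  p <- prior_spec()
  # P(k=1) = 0.2 -> posterior odds 4, prior odds 4 -> log BF = 0
  expect_equal(bayes_factor(c(0.2, 0.5, 0.2, 0.05, 0.05), p), 0)
  expect_equal(bayes_factor(c(0.5, 0.5, 0, 0, 0), 4), log((0.5 / 0.5) / 4))
  # sentinel: no multimodal mass
  expect_equal(bayes_factor(c(1, 0, 0, 0, 0), p), log(0.003))
  # sentinel: no unimodal mass
  expect_identical(bayes_factor(c(0, 1, 0, 0, 0), p), Inf)
  expect_error(bayes_factor(c(0.5, 0.4), p), "probability vector")
})

test_that("evidence classes follow the log-BF boundaries", {
  got <- classify_evidence(c(-2, 1, 1.001, 3, 3.2, 5, 5.2, Inf, log(0.003)))
  expect_equal(as.character(got),
               c("unimodal", "unimodal", "positive", "positive", "strong",
                 "strong", "very_strong", "very_strong", "unimodal"))
})

test_that("max_weight_component breaks ties toward the smaller mean", {
  fit <- list(means = c(2, 0.5, 1), sds = c(0.1, 0.2, 0.3),
              weights = c(0.4, 0.2, 0.4))
  got <- max_weight_component(fit)
  expect_equal(got$mean, 1)   # tie between means 2 and 1 -> smaller mean
  expect_equal(got$weight, 0.4)
  fit2 <- list(means = c(1, 3), sds = c(0.1, 0.1), weights = c(0.3, 0.7))
  expect_equal(max_weight_component(fit2)$mean, 3)
})

test_that("rjMCMC finds one component in unimodal data", {
  x <- generate_offset_sample(list(means = 0.7, sds = 0.15, weights = 1),
                              500, seed = 51)
  fit <- fit_rjmcmc(x, seed = 51)
  expect_equal(fit$k_modal, 1L)
  expect_lte(fit$log_bf, 1)
  expect_equal(fit$point_fit$means, 0.7, tolerance = 0.05)
  expect_equal(fit$point_fit$sds, 0.15, tolerance = 0.05)
  expect_equal(as.character(fit$evidence), "unimodal")
})

test_that("rjMCMC recovers a separated two-component mixture", {
  comp <- list(means = c(0.5, 1.5), sds = c(0.05, 0.05), weights = c(0.6, 0.4))
  x <- generate_offset_sample(comp, 500, seed = 52)
  fit <- fit_rjmcmc(x, seed = 52)
  expect_gte(fit$k_modal, 2L)
  expect_gt(fit$log_bf, 5)
  expect_equal(as.character(fit$evidence), "very_strong")
  if (fit$k_modal == 2) {
    expect_equal(fit$point_fit$means, c(0.5, 1.5), tolerance = 0.05)
    expect_equal(fit$point_fit$weights, c(0.6, 0.4), tolerance = 0.07)
  }
  # density-mode sensitivity check: draws are overwhelmingly bimodal
  expect_gt(mean(count_density_modes(fit) >= 2), 0.9)
})

test_that("rjMCMC is reproducible and validates its input", {
  x <- generate_offset_sample(list(means = 1, sds = 0.2, weights = 1),
                              200, seed = 53)
  f1 <- fit_rjmcmc(x, n_iter = 300, burn_in = 100, seed = 7)
  f2 <- fit_rjmcmc(x, n_iter = 300, burn_in = 100, seed = 7)
  expect_identical(f1$k_draws, f2$k_draws)
  expect_identical(f1$log_bf, f2$log_bf)
  expect_error(fit_rjmcmc(rnorm(10)), "at least 50")
  expect_error(fit_rjmcmc(rep(1, 100)), "zero variance")
})

test_that("mixture fits agree with mclust model selection on bimodal data", {
  comp <- list(means = c(0.6, 2), sds = c(0.08, 0.08), weights = c(0.5, 0.5))
  x <- generate_offset_sample(comp, 500, seed = 54)
  fit <- fit_rjmcmc(x, seed = 54)
  bic <- mclust::mclustBIC(x, G = 1:5, modelNames = "V", verbose = FALSE)
  g_bic <- as.integer(names(which.max(bic[, "V"])))
  expect_equal(fit$k_modal, g_bic)
  if (fit$k_modal == 2) {
    km <- fixmodal:::with_seed(54, kmeans(x, 2))
    expect_equal(sort(fit$point_fit$means), sort(as.numeric(km$centers)),
                 tolerance = 0.05)
  }
})
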