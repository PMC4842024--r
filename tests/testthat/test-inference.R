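## Gibbs sampler and DIC

test_that("intercept-only posterior matches the conjugate closed form", {
  ## flat-intercept Gaussian model: marginalizing beta0 gives
  ## sigma2_e | y ~ InvGamma(0.5 + (n-1)/2, 0.5 + SS/2), SS = sum((y-ybar)^2)
  ped <- founders_ped(20)
  set.seed(31)
  yfix <- rnorm(20, 3, 1.3)
  d <- simulate_dataset(ped, trait_truth("M1", sigma2_a = 0, sigma2_e = 1),
                        seed = 1)
  d$y <- yfix # fixed 20-point dataset
  fit <- fit_animal_model(d, model_spec("M0"),
                          mcmc_settings(22000, 2000, 4, chains = 2, seed = 5))
  SS <- sum((yfix - mean(yfix))^2)
  shape <- 0.5 + 19 / 2
  rate <- 0.5 + SS / 2
  closed_mean <- rate / (shape - 1)
  got <- fit$summary$mean[fit$summary$parameter == "sigma2_e"]
  expect_equal(got, closed_mean, tolerance = 0.02 * closed_mean)
  expect_equal(fit$summary$mean[fit$summary$parameter == "beta0"],
               mean(yfix), tolerance = 0.03)
})

test_that("M1 posterior means match the grid-integration oracle on 10 individuals", {
  ped <- random_ped(10, seed = 21, phen_prob = 1)
  tr <- trait_truth("M1", sigma2_a = 0.6, sigma2_e = 0.4)
  d <- simulate_dataset(ped, tr, seed = 8)
  oracle <- oracle_grid_posterior(ped, d$y, model_spec("M1"))
  fit <- fit_animal_model(d, model_spec("M1"),
                          mcmc_settings(30000, 2000, 4, chains = 3, seed = 17))
  got <- setNames(fit$summary$mean, fit$summary$parameter)
  expect_equal(got[["sigma2_a"]], oracle[["sigma2_a"]], tolerance = 0.02)
  expect_equal(got[["sigma2_e"]], oracle[["sigma2_e"]], tolerance = 0.02)
})

test_that("variance full-conditional draws follow the analytic inverse-gamma", {
  ## conjugacy: with the latent block frozen, sigma2 | w is
  ## InvGamma(0.5 + (np-1)/2, 0.5 + ||w||^2 / 2); the sampler's draws are
  ## reciprocal gammas, so a KS test against the analytic gamma applies
  np <- 60
  set.seed(77)
  w <- rnorm(np, 0, 0.7)
  shape <- 0.5 + (np - 1) / 2
  rate <- 0.5 + sum(w^2) / 2
  draws <- pedpower:::rinvgamma(5000, shape, rate)
  ks <- suppressWarnings(ks.test(1 / draws, pgamma, shape = shape, rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("sum-to-zero constraints hold at every retained draw", {
  ped <- tiny_system(6)
  tr <- trait_truth("M2", sigma2_a = 0.3, sigma2_m = 0.3, sigma2_e = 0.4)
  d <- simulate_dataset(ped, tr, seed = 2)
  fit <- fit_animal_model(d, model_spec("M2"),
                          mcmc_settings(600, 100, 2, chains = 2, seed = 3))
  expect_lt(fit$max_abs_constraint, 1e-8)
  ## and the posterior-mean latent vectors inherit it
  expect_lt(abs(sum(fit$latent$a)), 1e-8)
  expect_lt(abs(sum(fit$latent$m)), 1e-8)
})

test_that("DIC components satisfy their identities and degenerate cases", {
  ped <- tiny_system(7)
  d <- simulate_dataset(ped, trait_truth("M1"), seed = 4)
  fit <- fit_animal_model(d, model_spec("M1"),
                          mcmc_settings(2000, 500, 3, chains = 2, seed = 5))
  expect_equal(fit$dic$DIC, fit$dic$Dbar + fit$dic$pD)
  expect_equal(fit$dic$pD, fit$dic$Dbar - fit$dic$Dhat)
  expect_true(is.finite(fit$dic$pD))

  ## degenerate chain: all draws identical => pD = 0, DIC = Dhat
  yv <- d$y[d$observed]
  mu <- rep(mean(yv), length(yv))
  dev0 <- -2 * sum(dnorm(yv, mu, sqrt(0.5), log = TRUE))
  fake <- structure(list(
    draws = matrix(dev0, 50, 1, dimnames = list(NULL, "deviance")),
    y = yv, mu_bar = mu, sig_e_bar = 0.5), class = "fit_result")
  dic <- compute_dic(fake)
  expect_equal(dic$pD, 0, tolerance = 1e-10)
  expect_equal(dic$DIC, dic$Dhat)
})

test_that("two independent fits agree on DIC within Monte-Carlo error", {
  ped <- tiny_system(8)
  d <- simulate_dataset(ped, trait_truth("M1"), seed = 6)
  f1 <- fit_animal_model(d, model_spec("M1"),
                         mcmc_settings(6000, 1000, 5, chains = 2, seed = 11))
  f2 <- fit_animal_model(d, model_spec("M1"),
                         mcmc_settings(6000, 1000, 5, chains = 2, seed = 12))
  expect_lt(abs(f1$dic$DIC - f2$dic$DIC), 4)
})

test_that("a fixed-variance normal-mean model has pD of about one", {
  ## one effective parameter (the mean): recompute per-draw deviance from
  ## the chain's beta0 draws with the variance held at its posterior mean
  ped <- founders_ped(50)
  d <- simulate_dataset(ped, trait_truth("M1", beta0 = 2, sigma2_a = 0,
                                         sigma2_e = 1), seed = 9)
  fit <- fit_animal_model(d, model_spec("M0"),
                          mcmc_settings(12000, 2000, 2, chains = 2, seed = 13))
  yv <- d$y[d$observed]
  s2 <- fit$sig_e_bar
  devs <- vapply(fit$draws[, "beta0"], function(b)
    -2 * sum(dnorm(yv, b, sqrt(s2), log = TRUE)), numeric(1))
  Dbar <- mean(devs)
  Dhat <- -2 * sum(dnorm(yv, mean(fit$draws[, "beta0"]), sqrt(s2), log = TRUE))
  expect_equal(Dbar - Dhat, 1, tolerance = 0.2)
})

test_that("convergence failures are flagged, never silent", {
  ped <- tiny_system(9)
  tr <- trait_truth("M2", sigma2_a = 0.3, sigma2_m = 0.3, sigma2_e = 0.4)
  d <- simulate_dataset(ped, tr, seed = 7)
  st <- mcmc_settings(300, 100, 1, chains = 2, seed = 1, rhat_limit = 1.000001)
  expect_message(fit <- fit_animal_model(d, model_spec("M2"), st),
                 "convergence gate")
  expect_false(fit$converged)
})

test_that("vacuous maternal structure and empty data are rejected", {
  f <- founders_ped(8)
  d <- simulate_dataset(f, trait_truth("M1"), seed = 1)
  expect_error(fit_animal_model(d, model_spec("M2")), "known mother")
  d$y[] <- NA
  d$observed[] <- FALSE
  expect_error(fit_animal_model(d, model_spec("M1")), "observed phenotypes")
})

test_that("credible intervals bracket the posterior mean for variances", {
  ped <- tiny_system(10)
  d <- simulate_dataset(ped, trait_truth("M1"), seed = 3)
  fit <- fit_animal_model(d, model_spec("M1"),
                          mcmc_settings(2000, 500, 2, chains = 2, seed = 2))
  v <- fit$summary[grepl("sigma2", fit$summary$parameter), ]
  expect_true(all(v$q2.5 <= v$mean & v$mean <= v$q97.5))
  expect_true(all(v$q2.5 > 0))
})
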