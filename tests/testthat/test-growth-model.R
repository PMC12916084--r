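test_that("the log-likelihood collapses to the closed form at the median", {
  tiny <- make_tiny_growth(n_fish = 10)
  params <- tiny$surveys
  k <- match(paste(tiny$records$species, tiny$records$lake_id,
                   tiny$records$year),
             paste(params$species, params$lake_id, params$year))
  exact <- tiny$records
  exact$length_cm <- biphasic_mean(params[k, ], exact$age_yr)
  sigma <- c(bluegill = 0.2, walleye = 0.15)
  ll <- growth_loglik(exact, params, sigma)
  closed <- sum(-log(exact$length_cm) - log(sigma[exact$species]) -
                  0.5 * log(2 * pi))
  expect_equal(ll, closed, tolerance = 1e-10)
})

test_that("the log-likelihood matches the per-record scalar oracle", {
  tiny <- make_tiny_growth(n_fish = 10)
  sigma <- c(bluegill = 0.12, walleye = 0.18)
  expect_equal(growth_loglik(tiny$records, tiny$surveys, sigma),
               oracle_loglik(tiny$records, tiny$surveys, sigma),
               tolerance = 1e-8)
})

test_that("widening sigma trades tail mass against precision at the mode", {
  rec <- data.frame(species = "walleye", lake_id = "L001", year = 2010,
                    length_cm = 20, age_yr = 2)
  par <- data.frame(species = "walleye", lake_id = "L001", year = 2010,
                    alpha = 2, beta1 = 9, amat = 3, beta2 = 1)
  # at the median (mu = 20): larger sigma only flattens the density
  expect_gt(growth_loglik(rec, par, c(walleye = 0.1)),
            growth_loglik(rec, par, c(walleye = 0.2)))
  far <- rec
  far$length_cm <- 60   # far in the tail: larger sigma helps
  expect_lt(growth_loglik(far, par, c(walleye = 0.1)),
            growth_loglik(far, par, c(walleye = 0.2)))
  bad <- rec
  bad$length_cm <- -1
  expect_error(growth_loglik(bad, par, c(walleye = 0.1)), "non-positive length")
})

test_that("the hyperprior matches its oracle and enforces supports", {
  tiny <- make_tiny_growth()
  expect_equal(growth_logprior(tiny$hyper), oracle_logprior(tiny$hyper),
               tolerance = 1e-10)
  expect_equal(growth_logprior(tiny$hyper, var_prior = "sd"),
               oracle_logprior(tiny$hyper, var_prior = "sd"),
               tolerance = 1e-10)
  out <- tiny$hyper
  out$gamma0[1, 1] <- 31
  expect_identical(growth_logprior(out), -Inf)
  neg <- tiny$hyper
  neg$sd_phi[2] <- -0.1
  expect_identical(growth_logprior(neg), -Inf)
  # standard normal at zero contributes -log(2 pi)/2 per slope
  flat <- tiny$hyper
  base_val <- growth_logprior(flat)
  flat$gamma1["beta1"] <- 0
  delta <- growth_logprior(flat) - base_val
  expect_equal(delta, -0.5 * log(2 * pi) -
                 dnorm(tiny$hyper$gamma1[["beta1"]], 0, 1, log = TRUE),
               tolerance = 1e-10)
})

test_that("the joint posterior density matches the brute-force oracle", {
  tiny <- make_tiny_growth(n_fish = 20)
  data <- growth_model_data(tiny$records, tiny$thermal)
  latent <- as.matrix(tiny$surveys[match(
    paste(data$surveys$species, data$surveys$lake_id, data$surveys$year),
    paste(tiny$surveys$species, tiny$surveys$lake_id, tiny$surveys$year)),
    c("alpha", "beta1", "amat", "beta2")])
  expect_equal(growth_logposterior(tiny$hyper, latent, data),
               oracle_logposterior(tiny$hyper, latent, data),
               tolerance = 1e-8)
})

test_that("a tight hierarchy pins survey parameters to their predictors", {
  tiny <- make_tiny_growth(n_fish = 10)
  data <- growth_model_data(tiny$records, tiny$thermal)
  hyper <- tiny$hyper
  hyper$tau[] <- 0
  hyper$omega[] <- 0
  hyper$sd_phi[] <- 1e-4
  at_phi <- growth_linpred(hyper, data)
  at_phi[, "amat"] <- clamp(at_phi[, "amat"], 0.25, 30)
  at_phi[, "alpha"] <- pmax(at_phi[, "alpha"], 0)
  at_phi[, "beta1"] <- pmax(at_phi[, "beta1"], 1e-3)
  off <- at_phi
  off[, "beta1"] <- off[, "beta1"] + 0.05
  expect_gt(growth_logposterior(hyper, at_phi, data),
            growth_logposterior(hyper, off, data) + 1e4)
})

test_that("an empty lake enters the posterior only through its omega priors", {
  tiny <- make_tiny_growth(n_fish = 15)
  data <- growth_model_data(tiny$records, tiny$thermal)
  latent <- as.matrix(tiny$surveys[match(
    paste(data$surveys$species, data$surveys$lake_id, data$surveys$year),
    paste(tiny$surveys$species, tiny$surveys$lake_id, tiny$surveys$year)),
    c("alpha", "beta1", "amat", "beta2")])
  lp1 <- growth_logposterior(tiny$hyper, latent, data)
  with_lake <- tiny$hyper
  with_lake$omega <- rbind(tiny$hyper$omega, L999 = c(0.3, -0.1, 0.2, 0.05))
  lp2 <- growth_logposterior(with_lake, latent, data)
  expected_delta <- sum(dnorm(c(0.3, -0.1, 0.2, 0.05), 0,
                              tiny$hyper$sd_omega, log = TRUE))
  expect_equal(lp2 - lp1, expected_delta, tolerance = 1e-10)
})

test_that("the sampler is deterministic under a fixed seed", {
  tiny <- make_tiny_growth(n_fish = 60, seed = 7)
  quick <- mcmc_config(n_iter = 400, n_burnin = 200, thin = 2, n_adapt = 100)
  f1 <- fit_growth_model(tiny$records, tiny$thermal, mcmc = quick, seed = 31)
  f2 <- fit_growth_model(tiny$records, tiny$thermal, mcmc = quick, seed = 31)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_growth_model(tiny$records, tiny$thermal, mcmc = quick, seed = 32)
  expect_false(identical(f1$draws, f3$draws))
  # retained draw count honours (n_iter - n_burnin) / thin
  expect_equal(dim(f1$draws)[1], (400 - 200) / 2)
  expect_equal(dim(f1$draws)[2], 3)
})

test_that("prior-only sampling recovers the Normal(0,1) slope prior", {
  tiny <- make_tiny_growth(n_fish = 10)
  prior_cfg <- mcmc_config(n_iter = 6000, n_burnin = 1000, thin = 1,
                           n_adapt = 500)
  fit <- fit_growth_model(tiny$records, tiny$thermal, mcmc = prior_cfg,
                          seed = 77, sample_prior = TRUE)
  for (p in c("gamma1_beta1", "gamma1_amat", "gamma1_beta2")) {
    g <- pooled_draws(fit, p)
    expect_equal(mean(g), 0, tolerance = 3 / sqrt(length(g) / 20))
    expect_equal(sd(g), 1, tolerance = 0.1)
  }
})
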