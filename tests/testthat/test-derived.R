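# builds a degenerate growth_fit whose pooled draws are fully controlled
fake_growth_fit <- function(draws_list, species = "walleye",
                            t_range = c(-1.5, 1.5)) {
  n <- length(draws_list[[1]])
  arr <- array(NA_real_, c(n, 1, length(draws_list)),
               dimnames = list(NULL, NULL, names(draws_list)))
  for (p in names(draws_list)) arr[, 1, p] <- draws_list[[p]]
  structure(list(draws = arr,
                 data = list(species = species,
                             surveys = data.frame(t_scaled = t_range))),
            class = "growth_fit")
}

fake_fit_for <- function(species, alpha, beta1, amat, beta2,
                         g1 = c(0, 0, 0), tau = c(0, 0, 0), n = 400) {
  nm <- function(stem) sprintf("%s[%s]", stem, species)
  draws <- list(rep(alpha, n), rep(beta1, n), rep(amat, n), rep(beta2, n),
                rep(g1[1], n), rep(g1[2], n), rep(g1[3], n),
                rep(tau[1], n), rep(tau[2], n), rep(tau[3], n))
  names(draws) <- c(nm("gamma0_alpha"), nm("gamma0_beta1"), nm("gamma0_amat"),
                    nm("gamma0_beta2"), "gamma1_beta1", "gamma1_amat",
                    "gamma1_beta2", nm("tau_beta1"), nm("tau_amat"),
                    nm("tau_beta2"))
  fake_growth_fit(draws, species)
}

fake_longevity_fit <- function(intercept, slope, n = 400, species = "walleye") {
  arr <- array(NA_real_, c(n, 1, 2),
               dimnames = list(NULL, NULL, c("intercept", "temp_slope")))
  arr[, 1, "intercept"] <- intercept
  arr[, 1, "temp_slope"] <- slope
  structure(list(draws = arr, species = species), class = "longevity_fit")
}

test_that("size at maturity is the exact per-draw arithmetic identity", {
  fit <- fake_fit_for("walleye", alpha = 2, beta1 = 3, amat = 4, beta2 = 1)
  expect_equal(size_at_maturity_draws(fit, "walleye", 0), rep(14, 400))
  # with zero temperature effects the answer is temperature-invariant
  expect_equal(size_at_maturity_draws(fit, "walleye", 1.2),
               size_at_maturity_draws(fit, "walleye", -1.2))
  expect_warning(size_at_maturity_draws(fit, "walleye", 5), "extrapolating")
})

test_that("maximum size combines growth and longevity draws correctly", {
  gfit <- fake_fit_for("walleye", alpha = 2, beta1 = 3, amat = 4, beta2 = 1)
  lfit <- fake_longevity_fit(intercept = 10, slope = 0)
  d <- growth_curve_draws(gfit, lfit, "walleye", 0, seed = 1)
  # Lmax = alpha + beta1 amat + beta2 (amax - amat) = 14 + 6 = 20
  expect_equal(unique(round(d$lmax, 10)), 20)
  expect_equal(unique(d$amax), 10)
  expect_equal(d$frac_amax_floored, 0)
  # curves are nondecreasing for positive slopes
  expect_true(all(diff(d$curve$q50) >= -1e-12))
  # amax below amat is floored to amat, and the fraction reported
  lfit2 <- fake_longevity_fit(intercept = 2, slope = 0)
  d2 <- growth_curve_draws(gfit, lfit2, "walleye", 0, seed = 1)
  expect_equal(d2$frac_amax_floored, 1)
  expect_equal(unique(d2$amax), 4)
  expect_equal(unique(round(d2$lmax, 10)), 14)  # curve ends at maturity
})

test_that("amax draws follow the longevity linear predictor per species", {
  n <- 200
  arr <- array(NA_real_, c(n, 1, 4),
               dimnames = list(NULL, NULL,
                               c("intercept", "temp_slope",
                                 "species_offset[walleye]",
                                 "temp_interaction[walleye]")))
  arr[, 1, "intercept"] <- 10
  arr[, 1, "temp_slope"] <- -0.5
  arr[, 1, "species_offset[walleye]"] <- 3
  arr[, 1, "temp_interaction[walleye]"] <- 0.2
  lfit <- structure(list(draws = arr, species = c("bluegill", "walleye")),
                    class = "longevity_fit")
  expect_equal(amax_draws(lfit, "bluegill", 2), rep(10 - 1, n))
  expect_equal(amax_draws(lfit, "walleye", 2), rep(10 + 3 + (-0.3) * 2, n))
  # zero interaction: a common slope across species
  arr[, 1, "temp_interaction[walleye]"] <- 0
  lfit0 <- structure(list(draws = arr, species = c("bluegill", "walleye")),
                     class = "longevity_fit")
  d1 <- amax_draws(lfit0, "bluegill", 1) - amax_draws(lfit0, "bluegill", 0)
  d2 <- amax_draws(lfit0, "walleye", 1) - amax_draws(lfit0, "walleye", 0)
  expect_equal(d1, d2)
})

test_that("maturity-size uncertainty grows when amat uncertainty enters", {
  set.seed(71)
  n <- 4000
  fit <- fake_growth_fit(list(
    "gamma0_alpha[walleye]" = rnorm(n, 2, 0.2),
    "gamma0_beta1[walleye]" = rnorm(n, 3, 0.2),
    "gamma0_amat[walleye]" = rnorm(n, 4, 0.5),
    "gamma0_beta2[walleye]" = rnorm(n, 1, 0.1),
    "gamma1_beta1" = rnorm(n, 0, 0.1), "gamma1_amat" = rnorm(n, 0, 0.1),
    "gamma1_beta2" = rnorm(n, 0, 0.1),
    "tau_beta1[walleye]" = rep(0, n), "tau_amat[walleye]" = rep(0, n),
    "tau_beta2[walleye]" = rep(0, n)))
  full_sd <- sd(size_at_maturity_draws(fit, "walleye", 0))
  fixed <- fit
  fixed$draws[, 1, "gamma0_amat[walleye]"] <-
    mean(fit$draws[, 1, "gamma0_amat[walleye]"])
  fixed_sd <- sd(size_at_maturity_draws(fixed, "walleye", 0))
  expect_gte(full_sd, fixed_sd)
})

test_that("temperature regimes coincide when no effect exists anywhere", {
  set.seed(72)
  n <- 3000
  mk <- function() fake_growth_fit(list(
    "gamma0_alpha[walleye]" = rnorm(n, 2, 0.1),
    "gamma0_beta1[walleye]" = rnorm(n, 3, 0.1),
    "gamma0_amat[walleye]" = rnorm(n, 4, 0.1),
    "gamma0_beta2[walleye]" = rnorm(n, 1, 0.05),
    "gamma1_beta1" = rep(0, n), "gamma1_amat" = rep(0, n),
    "gamma1_beta2" = rep(0, n),
    "tau_beta1[walleye]" = rep(0, n), "tau_amat[walleye]" = rep(0, n),
    "tau_beta2[walleye]" = rep(0, n)))
  gfit <- mk()
  lfit <- fake_longevity_fit(intercept = 10, slope = 0, n = n)
  cool <- growth_curve_draws(gfit, lfit, "walleye", -1.4, seed = 4)
  warm <- growth_curve_draws(gfit, lfit, "walleye", 1.4, seed = 4)
  common <- seq_len(min(nrow(cool$curve), nrow(warm$curve)))
  expect_equal(cool$curve$q50[common], warm$curve$q50[common],
               tolerance = 0.02)
  expect_equal(median(cool$lmax), median(warm$lmax), tolerance = 0.02)
})

test_that("credible bands order correctly at every age", {
  cfg <- simulation_config(n_lakes = 4, n_species = 1, years_per_lake = 1,
                           fish_per_survey = 50, seed = 37)
  sim <- simulate_dataset(cfg)
  quick <- mcmc_config(n_iter = 800, n_burnin = 400, thin = 2, n_adapt = 200)
  gfit <- fit_growth_model(sim$fish_all, sim$thermal, mcmc = quick, seed = 3)
  lrec <- longevity_records(sim$fish_all, sim$thermal)
  lfit <- fit_longevity_model(lrec, mcmc = quick, seed = 4)
  der <- derive_size_curves(gfit, lfit, seed = 8)
  expect_true(all(der$curves$q2.5 <= der$curves$q50 + 1e-12))
  expect_true(all(der$curves$q50 <= der$curves$q97.5 + 1e-12))
  expect_true(all(c("lmat", "lmax", "amax") %in% names(der$summary)))
})
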