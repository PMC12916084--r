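small_config <- function(...) {
  simulation_config(n_lakes = 6, n_species = 2, years_per_lake = 1,
                    fish_per_survey = 40, n_history_years = 10, seed = 5, ...)
}

test_that("a fixed seed reproduces the generator byte for byte", {
  a <- simulate_dataset(small_config())
  b <- simulate_dataset(small_config())
  expect_identical(a$temps, b$temps)
  expect_identical(a$truth$params, b$truth$params)
  expect_identical(a$fish, b$fish)
})

test_that("zero day-noise and zero gradient collapse all lakes onto one seasonal curve", {
  cfg <- small_config(day_noise_sd = 0, climate_gdd_range = c(2000, 2000))
  temps <- simulate_daily_temps(cfg)
  by_lake <- split(temps$temp_c, temps$lake_id)
  for (l in by_lake) expect_equal(l, by_lake[[1]], tolerance = 1e-12)
})

test_that("annual GDD5 increases strictly along the climate gradient", {
  cfg <- small_config(day_noise_sd = 0)
  temps <- simulate_daily_temps(cfg)
  gdd <- gdd5_table(temps)
  one_year <- gdd[gdd$year == 2005, ]
  one_year <- one_year[order(one_year$lake_id), ]
  expect_true(all(diff(one_year$gdd5) > 0))
  # expected GDD5 hits the configured gradient closely
  expect_equal(range(one_year$gdd5), cfg$climate_gdd_range, tolerance = 0.01)
})

test_that("population truths equal the linear predictor in the noise-free limit", {
  cfg <- small_config(sd_tau = rep(0, 3), sd_omega = rep(0, 4),
                      sd_phi = rep(0, 4), longevity_lake_sd = 0)
  thermal <- data.frame(lake_id = sprintf("L%03d", 1:6), year = 2010,
                        t_scaled = seq(-1, 1, length.out = 6))
  truth <- simulate_populations(cfg, thermal)
  p <- truth$params
  j <- match(p$species, cfg$species)
  expect_equal(p$beta1,
               unname(cfg$gamma0[j, "beta1"] + cfg$gamma1["beta1"] * p$t_scaled),
               tolerance = 1e-12)
  expect_equal(p$amat,
               unname(cfg$gamma0[j, "amat"] + cfg$gamma1["amat"] * p$t_scaled),
               tolerance = 1e-12)
  # centred covariate: T = 0 returns the species baseline exactly
  at0 <- p[abs(p$t_scaled) < 1e-9, ]
  expect_equal(at0$beta1, unname(cfg$gamma0[match(at0$species, cfg$species),
                                            "beta1"]), tolerance = 1e-12)
})

test_that("simulated slopes of beta1 on temperature recover gamma1_beta1", {
  cfg <- simulation_config(n_lakes = 60, n_species = 1, years_per_lake = 2,
                           fish_per_survey = 10, seed = 17,
                           sd_omega = rep(0.05, 4), sd_phi = rep(0.05, 4))
  thermal <- data.frame(lake_id = rep(sprintf("L%03d", 1:60), 2),
                        year = rep(2010:2011, each = 60),
                        t_scaled = rep(seq(-1.6, 1.6, length.out = 60), 2))
  truth <- simulate_populations(cfg, thermal)
  slope <- coef(lm(beta1 ~ t_scaled, truth$params))[2]
  expect_equal(unname(slope), unname(cfg$gamma1["beta1"]), tolerance = 0.1)
})

test_that("lengths collapse to the biphasic mean as observation noise vanishes", {
  cfg <- small_config(obs_sigma = rep(1e-9, 2))
  sim <- simulate_dataset(cfg)
  p <- sim$truth$params
  key <- paste(p$species, p$lake_id, p$year)
  k <- match(paste(sim$fish_all$species, sim$fish_all$lake_id,
                   sim$fish_all$year), key)
  mu <- biphasic_mean(p[k, ], sim$fish_all$age_yr)
  expect_equal(sim$fish_all$length_cm, mu, tolerance = 1e-6)
  expect_error(simulate_fish(sim$truth, small_config(obs_sigma = c(0, 0.1))),
               "positive")
})

test_that("sampled ages respect truncation at the true maximum age", {
  sim <- simulate_dataset(small_config())
  p <- sim$truth$params
  for (k in sample(nrow(p), 5)) {
    sel <- sim$fish_all$species == p$species[k] &
      sim$fish_all$lake_id == p$lake_id[k] & sim$fish_all$year == p$year[k]
    ages <- sim$fish_all$age_yr[sel]
    expect_lte(compute_a95(ages), p$amax[k])
    expect_lte(max(ages), p$amax[k])
  }
})

test_that("log-length residuals about the biphasic mean are normal", {
  cfg <- simulation_config(n_lakes = 2, n_species = 1, years_per_lake = 1,
                           fish_per_survey = 2000, seed = 29)
  sim <- simulate_dataset(cfg)
  p <- sim$truth$params
  key <- paste(p$species, p$lake_id, p$year)
  k <- match(paste(sim$fish_all$species, sim$fish_all$lake_id,
                   sim$fish_all$year), key)
  resid <- log(sim$fish_all$length_cm) -
    log(biphasic_mean(p[k, ], sim$fish_all$age_yr))
  expect_gt(shapiro.test(resid)$p.value, 0.01)
  expect_equal(sd(resid), cfg$obs_sigma[[1]], tolerance = 0.05)
})

test_that("age masking conserves every record and honours the quota", {
  cfg <- small_config(aged_quota = 3)
  sim <- simulate_dataset(cfg)
  expect_identical(nrow(sim$fish), nrow(sim$fish_all))
  expect_identical(sim$fish$fish_id, sim$fish_all$fish_id)
  expect_identical(sim$fish$length_cm, sim$fish_all$length_cm)
  expect_true(all(is.na(sim$fish$age_yr[!sim$fish$aged_flag])))
  expect_identical(sim$fish$age_yr[sim$fish$aged_flag],
                   sim$fish_all$age_yr[sim$fish$aged_flag])
  # per survey x bin at most the quota keeps an age
  bin <- floor(sim$fish$length_cm / cfg$bin_width)
  tab <- tapply(sim$fish$aged_flag,
                paste(sim$fish$species, sim$fish$lake_id, sim$fish$year, bin),
                sum)
  expect_true(all(tab <= 3))
  # a generous quota masks nothing
  all_aged <- mask_ages(sim$fish_all, small_config(aged_quota = 10000))
  expect_true(all(all_aged$aged_flag))
  expect_error(mask_ages(sim$fish_all, small_config(aged_quota = 0)))
})
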