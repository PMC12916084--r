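# Synthetic survey generator: lakes along a thermal gradient, species with
# distinct baseline growth, lake-year surveys with biphasic lognormal
# length-at-age, and length-stratified age subsampling.  Every downstream
# stage of the analysis can therefore be exercised against a known truth.

# Baseline life-history pool the generator draws species from.  Values are
# plausible for upper-Midwest lake fishes: small-bodied panfish grow slowly
# and die young, esocids grow fast and live long.  Units: alpha cm, beta1 and
# beta2 cm/yr, amat yr, obs_sigma lognormal scale, longevity_intercept yr,
# longevity_slope yr per SD of the thermal covariate.
species_pool <- function() {
  data.frame(
    species = c("bluegill", "black_crappie", "yellow_perch",
                "smallmouth_bass", "largemouth_bass", "walleye",
                "northern_pike"),
    alpha  = c(0.5, 1.0, 1.5, 2.5, 3.0, 4.0, 10.0),
    beta1  = c(2.8, 4.0, 3.5, 6.0, 6.5, 7.5, 11.0),
    amat   = c(2.0, 2.2, 2.5, 3.0, 3.0, 4.5, 3.5),
    beta2  = c(1.2, 1.5, 1.3, 2.0, 2.2, 2.5, 5.0),
    obs_sigma = c(0.14, 0.14, 0.13, 0.13, 0.13, 0.12, 0.12),
    longevity_intercept = c(9, 10, 11, 12, 13, 15, 17),
    longevity_slope = c(-0.4, -0.4, -0.4, -0.4, -0.4, -0.4, -0.4),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic survey generator
#'
#' Assembles and validates all knobs of the generator: the survey design
#' (lakes, species, years, fish per survey), the true hierarchical growth
#' parameters (species baselines `gamma0`, temperature slopes `gamma1`,
#' random-effect and process SDs), the longevity coefficients, the climate
#' gradient spanned by the lakes, and the length-stratified aging quota.
#'
#' Species baselines default to a pool of seven upper-Midwest lake fishes;
#' `n_species` picks maximally contrasted members of that pool.  The default
#' temperature slopes (`gamma1 = c(beta1 = 0.5, amat = -0.5, beta2 = 0)`, on
#' the z-scored covariate scale) encode a temperature-size-rule world in
#' which juveniles grow faster and mature earlier in warm lakes while adult
#' growth is unaffected.
#'
#' @param n_lakes,n_species,years_per_lake,fish_per_survey survey design
#'   (all positive integers).
#' @param aged_quota per-length-bin aging quota: a count (>= 1) or a
#'   fraction in (0, 1).
#' @param gamma0 species-by-parameter matrix of baselines (columns `alpha`,
#'   `beta1`, `amat`, `beta2`); rows must match `n_species`.
#' @param gamma1 temperature slopes for `beta1`, `amat`, `beta2` (the age-0
#'   intercept `alpha` is not temperature-dependent).
#' @param sd_tau SDs of species random slopes (`beta1`, `amat`, `beta2`).
#' @param sd_omega SDs of lake random intercepts (all four parameters).
#' @param sd_phi process SDs of survey-level parameters about their linear
#'   predictors.
#' @param obs_sigma per-species lognormal observation scale (> 0).
#' @param longevity_intercept,longevity_slope per-species coefficients of
#'   true maximum age on the scaled thermal covariate.
#' @param longevity_lake_sd SD of the lake effect on true maximum age.
#' @param climate_gdd_range range (degree-days) of mean annual GDD5 across
#'   the lake gradient.
#' @param seasonal_amplitude amplitude (deg C) of the annual temperature
#'   cycle.
#' @param day_noise_sd SD (deg C) of day-to-day temperature noise.
#' @param survival_rate geometric survival rate shaping the sampled age
#'   distribution (young fish dominate).
#' @param n_history_years years of daily temperature simulated before the
#'   first survey year (feeds the trailing-window covariate).
#' @param first_year first simulated calendar year.
#' @param window trailing window (years) of the thermal covariate.
#' @param bin_width length-bin width (cm) for age subsampling and keys.
#' @param species optional character vector of species names (overrides the
#'   pool selection; length `n_species`).
#' @param seed master seed; every generator stage derives its own stream
#'   from it, so a fixed seed gives byte-identical output.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_lakes = 40, n_species = 2, years_per_lake = 2,
                              fish_per_survey = 60, aged_quota = 5,
                              gamma0 = NULL,
                              gamma1 = c(beta1 = 0.5, amat = -0.5, beta2 = 0),
                              sd_tau = c(beta1 = 0.1, amat = 0.1, beta2 = 0.1),
                              sd_omega = c(alpha = 0.3, beta1 = 0.2,
                                           amat = 0.2, beta2 = 0.1),
                              sd_phi = c(alpha = 0.2, beta1 = 0.2,
                                         amat = 0.2, beta2 = 0.15),
                              obs_sigma = NULL,
                              longevity_intercept = NULL,
                              longevity_slope = NULL,
                              longevity_lake_sd = 1,
                              climate_gdd_range = c(1500, 3000),
                              seasonal_amplitude = 14,
                              day_noise_sd = 1.5,
                              survival_rate = 0.75,
                              n_history_years = 10,
                              first_year = 2000,
                              window = 10,
                              bin_width = 1,
                              species = NULL,
                              seed = 1) {
  stopifnot(n_lakes >= 1, n_species >= 1, years_per_lake >= 1,
            fish_per_survey >= 1, n_history_years >= 0, window >= 1,
            bin_width > 0, survival_rate > 0, survival_rate < 1,
            seasonal_amplitude > 0, day_noise_sd >= 0,
            length(climate_gdd_range) == 2,
            climate_gdd_range[1] <= climate_gdd_range[2],
            climate_gdd_range[1] > 0)
  if (aged_quota <= 0 || (aged_quota > 1 && aged_quota != round(aged_quota)))
    stop("aged_quota must be a fraction in (0, 1] or a positive integer count")

  pool <- species_pool()
  if (is.null(species)) {
    if (n_species > nrow(pool))
      stop("n_species exceeds the built-in species pool; supply `species` and `gamma0`")
    # maximally spread subset of the pool (contrasting life histories)
    idx <- unique(round(seq(1, nrow(pool), length.out = n_species)))
    species <- pool$species[idx]
  }
  stopifnot(length(species) == n_species)
  pick <- match(species, pool$species)

  if (is.null(gamma0)) {
    gamma0 <- as.matrix(pool[pick, c("alpha", "beta1", "amat", "beta2")])
    rownames(gamma0) <- species
  }
  gamma0 <- as.matrix(gamma0)
  stopifnot(nrow(gamma0) == n_species, ncol(gamma0) == 4)
  colnames(gamma0) <- c("alpha", "beta1", "amat", "beta2")
  rownames(gamma0) <- species
  if (any(gamma0 < 0) || any(gamma0[, "amat"] <= 0))
    stop("gamma0 baselines must be non-negative with positive amat")

  obs_sigma <- obs_sigma %||% stats::setNames(pool$obs_sigma[pick], species)
  if (any(obs_sigma <= 0)) stop("obs_sigma must be positive")
  longevity_intercept <- longevity_intercept %||%
    stats::setNames(pool$longevity_intercept[pick], species)
  longevity_slope <- longevity_slope %||%
    stats::setNames(pool$longevity_slope[pick], species)
  stopifnot(length(obs_sigma) == n_species,
            length(longevity_intercept) == n_species,
            length(longevity_slope) == n_species,
            length(gamma1) == 3, length(sd_tau) == 3, length(sd_omega) == 4,
            length(sd_phi) == 4, all(sd_tau >= 0), all(sd_omega >= 0),
            all(sd_phi >= 0), longevity_lake_sd >= 0)

  structure(list(
    n_lakes = as.integer(n_lakes), n_species = as.integer(n_species),
    years_per_lake = as.integer(years_per_lake),
    fish_per_survey = as.integer(fish_per_survey),
    aged_quota = aged_quota, species = species,
    gamma0 = gamma0,
    gamma1 = stats::setNames(as.numeric(gamma1), c("beta1", "amat", "beta2")),
    sd_tau = stats::setNames(as.numeric(sd_tau), c("beta1", "amat", "beta2")),
    sd_omega = stats::setNames(as.numeric(sd_omega),
                               c("alpha", "beta1", "amat", "beta2")),
    sd_phi = stats::setNames(as.numeric(sd_phi),
                             c("alpha", "beta1", "amat", "beta2")),
    obs_sigma = stats::setNames(as.numeric(obs_sigma), species),
    longevity_intercept = stats::setNames(as.numeric(longevity_intercept), species),
    longevity_slope = stats::setNames(as.numeric(longevity_slope), species),
    longevity_lake_sd = longevity_lake_sd,
    climate_gdd_range = as.numeric(climate_gdd_range),
    seasonal_amplitude = seasonal_amplitude, day_noise_sd = day_noise_sd,
    survival_rate = survival_rate,
    n_history_years = as.integer(n_history_years),
    first_year = as.integer(first_year), window = as.integer(window),
    bin_width = bin_width, seed = as.integer(seed)
  ), class = "sim_config")
}

# mean annual air-of-lake temperature giving a target annual GDD5 for the
# deterministic sinusoid temp(d) = m + A sin(2 pi (d - 114)/365)
invert_gdd_target <- function(target, amplitude, base = 5) {
  doy <- 1:365
  curve <- sin(2 * pi * (doy - 114) / 365)
  f <- function(m) sum(pmax(m + amplitude * curve - base, 0)) - target
  stats::uniroot(f, c(-30, 60), tol = 1e-10)$root
}

#' Simulate daily lake surface temperatures
#'
#' One temperature per lake per calendar day over the simulated span
#' (`n_history_years` history years plus `years_per_lake` survey years).
#' Each lake follows the same sinusoidal annual cycle shifted by a
#' lake-specific offset chosen so that expected annual GDD5 spans
#' `climate_gdd_range` linearly across lakes, plus independent Gaussian
#' day-to-day noise.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `lake_id`, `date` (Date), `temp_c`.
#' @export
simulate_daily_temps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_years <- config$n_history_years + config$years_per_lake
  if (n_years <= 0) stop("simulated span must cover at least one year")
  years <- seq(config$first_year, length.out = n_years)
  dates <- seq(as.Date(paste0(years[1], "-01-01")),
               as.Date(paste0(years[length(years)], "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$seasonal_amplitude * sin(2 * pi * (doy - 114) / 365)

  targets <- if (config$n_lakes == 1) mean(config$climate_gdd_range) else
    seq(config$climate_gdd_range[1], config$climate_gdd_range[2],
        length.out = config$n_lakes)
  offsets <- vapply(targets, invert_gdd_target,
                    numeric(1), amplitude = config$seasonal_amplitude)

  lake_ids <- sprintf("L%03d", seq_len(config$n_lakes))
  set.seed(derive_seed(config$seed, 1))
  out <- do.call(rbind, lapply(seq_len(config$n_lakes), function(l) {
    noise <- if (config$day_noise_sd > 0)
      stats::rnorm(length(dates), 0, config$day_noise_sd) else 0
    data.frame(lake_id = lake_ids[l], date = dates,
               temp_c = offsets[l] + seasonal + noise,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate true population-level growth and longevity parameters
#'
#' Runs the hierarchical model generatively.  For each parameter
#' p in \{beta1, amat, beta2\} the survey-level linear predictor is
#' `gamma0[species, p] + (gamma1[p] + tau[species, p]) * T + omega[lake, p]`
#' with `T` the scaled thermal covariate; for `alpha` it is
#' `gamma0[species, alpha] + omega[lake, alpha]`.  Survey-level parameters
#' are then drawn from normals with SD `sd_phi[p]`, truncated to their
#' biological supports (`alpha >= 0`, `beta1 > 0`, `amat` in [0.25, 30],
#' `beta2` unconstrained).  True maximum age is the species longevity line
#' plus a lake effect, floored at `amat + 1`.
#'
#' @param config a [simulation_config()].
#' @param thermal data frame with one row per survey lake-year and columns
#'   `lake_id`, `year`, `t_scaled` (see [thermal_covariates()] and
#'   [scale_covariate()]).
#' @return object of class `sim_truth`: list with survey-level `params`
#'   (one row per species x lake x year holding the generating parameters,
#'   recoverable by id join), species random slopes `tau`, lake random
#'   intercepts `omega`, and lake longevity effects.
#' @export
simulate_populations <- function(config, thermal) {
  stopifnot(inherits(config, "sim_config"),
            all(c("lake_id", "year", "t_scaled") %in% names(thermal)))
  lake_ids <- sort(unique(thermal$lake_id))
  years <- sort(unique(thermal$year))
  surveys <- expand.grid(species = config$species, lake_id = lake_ids,
                         year = years, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  key <- paste(surveys$lake_id, surveys$year)
  tkey <- paste(thermal$lake_id, thermal$year)
  if (!all(key %in% tkey))
    stop("every survey lake-year needs a scaled temperature value")
  surveys$t_scaled <- thermal$t_scaled[match(key, tkey)]

  set.seed(derive_seed(config$seed, 2))
  J <- config$n_species; L <- length(lake_ids)
  rn0 <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else rep(0, n)
  tau <- cbind(beta1 = rn0(J, config$sd_tau["beta1"]),
               amat  = rn0(J, config$sd_tau["amat"]),
               beta2 = rn0(J, config$sd_tau["beta2"]))
  rownames(tau) <- config$species
  omega <- cbind(alpha = rn0(L, config$sd_omega["alpha"]),
                 beta1 = rn0(L, config$sd_omega["beta1"]),
                 amat  = rn0(L, config$sd_omega["amat"]),
                 beta2 = rn0(L, config$sd_omega["beta2"]))
  rownames(omega) <- lake_ids
  lake_lon <- stats::setNames(rn0(L, config$longevity_lake_sd), lake_ids)

  j <- match(surveys$species, config$species)
  l <- match(surveys$lake_id, lake_ids)
  Tk <- surveys$t_scaled
  draw <- function(mu, sd, lower = -Inf, upper = Inf) {
    if (sd > 0) rtnorm(length(mu), mu, sd, lower, upper) else clamp(mu, lower, upper)
  }
  phi_alpha <- config$gamma0[j, "alpha"] + omega[l, "alpha"]
  phi_b1 <- config$gamma0[j, "beta1"] +
    (config$gamma1["beta1"] + tau[j, "beta1"]) * Tk + omega[l, "beta1"]
  phi_am <- config$gamma0[j, "amat"] +
    (config$gamma1["amat"] + tau[j, "amat"]) * Tk + omega[l, "amat"]
  phi_b2 <- config$gamma0[j, "beta2"] +
    (config$gamma1["beta2"] + tau[j, "beta2"]) * Tk + omega[l, "beta2"]
  surveys$alpha <- draw(phi_alpha, config$sd_phi["alpha"], lower = 0)
  surveys$beta1 <- draw(phi_b1, config$sd_phi["beta1"], lower = 1e-3)
  surveys$amat  <- draw(phi_am, config$sd_phi["amat"], lower = 0.25, upper = 30)
  surveys$beta2 <- draw(phi_b2, config$sd_phi["beta2"])
  surveys$amax <- pmax(
    config$longevity_intercept[j] + config$longevity_slope[j] * Tk + lake_lon[l],
    surveys$amat + 1)

  structure(list(params = surveys, tau = tau, omega = omega,
                 lake_longevity = lake_lon, species = config$species,
                 lake_ids = lake_ids),
            class = "sim_truth")
}

#' Simulate individual fish records (fully aged)
#'
#' Ages are drawn from a decreasing geometric-like distribution over
#' 0..floor(Amax) (young fish dominate; age 0 are young-of-year caught in
#' fall surveys).  Observed length is a lognormal draw whose median equals
#' the biphasic mean at the fish's age, with per-species scale `obs_sigma`.
#'
#' @param truth a [simulate_populations()] result.
#' @param config the matching [simulation_config()].
#' @return data frame with columns `fish_id`, `species`, `lake_id`, `year`,
#'   `length_cm`, `age_yr`, `structure`, `aged_flag` (all `TRUE` here; see
#'   [mask_ages()]).
#' @export
simulate_fish <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (any(config$obs_sigma <= 0)) stop("obs_sigma must be positive")
  set.seed(derive_seed(config$seed, 3))
  p <- truth$params
  n <- config$fish_per_survey
  structures <- c("otolith", "scale", "cleithrum", "fin_ray", "spine")
  out <- vector("list", nrow(p))
  for (k in seq_len(nrow(p))) {
    ages <- sample_ages(n, p$amax[k], config$survival_rate)
    mu <- biphasic_mean(p[k, ], ages)
    sig <- config$obs_sigma[[p$species[k]]]
    len <- stats::rlnorm(n, meanlog = log(pmax(mu, 1e-6)), sdlog = sig)
    out[[k]] <- data.frame(
      species = p$species[k], lake_id = p$lake_id[k], year = p$year[k],
      length_cm = len, age_yr = as.numeric(ages),
      structure = sample(structures, n, replace = TRUE,
                         prob = c(0.45, 0.35, 0.10, 0.05, 0.05)),
      aged_flag = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- cbind(fish_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Mask ages outside a length-stratified subsample
#'
#' Emulates standard agency practice: within each survey and each length
#' bin, only a quota of fish keep their laboratory age; the rest are
#' length-only records.  No fish are added, dropped or relabelled.
#'
#' @param records fully aged fish records from [simulate_fish()].
#' @param config a [simulation_config()]; its `aged_quota` is a per-bin
#'   count (>= 1) or a fraction in (0, 1), and `bin_width` sets the bins.
#' @return `records` with `age_yr` set to `NA` and `aged_flag` to `FALSE`
#'   outside the retained subsample; row count and order unchanged.
#' @export
mask_ages <- function(records, config) {
  stopifnot(inherits(config, "sim_config"))
  quota <- config$aged_quota
  if (quota <= 0) stop("aged quota must be positive")
  if (!all(records$aged_flag)) stop("mask_ages expects fully aged records")
  set.seed(derive_seed(config$seed, 4))
  bin <- floor(records$length_cm / config$bin_width)
  grp <- interaction(records$species, records$lake_id, records$year, bin,
                     drop = TRUE)
  keep <- logical(nrow(records))
  for (g in split(seq_len(nrow(records)), grp)) {
    k <- if (quota < 1) ceiling(quota * length(g)) else min(quota, length(g))
    keep[if (length(g) == 1) g else sample(g, k)] <- TRUE
  }
  records$age_yr[!keep] <- NA_real_
  records$aged_flag <- keep
  records
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining daily temperatures, thermal covariates,
#' population truths, fish records and age masking.
#'
#' @param config a [simulation_config()].
#' @return list with elements `config`, `temps` (daily temperatures),
#'   `thermal` (survey lake-year covariate table incl. `t_scaled`),
#'   `scaling` (the [scale_covariate()] record), `truth`, `fish_all`
#'   (fully aged records) and `fish` (after [mask_ages()]).
#' @export
simulate_dataset <- function(config) {
  temps <- simulate_daily_temps(config)
  gdd <- gdd5_table(temps)
  survey_years <- seq(config$first_year + config$n_history_years,
                      length.out = config$years_per_lake)
  thermal <- thermal_covariates(gdd, survey_years, window = config$window)
  scaling <- scale_covariate(thermal$t_window_mean)
  thermal$t_scaled <- scaling$scaled
  truth <- simulate_populations(config, thermal)
  fish_all <- simulate_fish(truth, config)
  fish <- mask_ages(fish_all, config)
  list(config = config, temps = temps, thermal = thermal, scaling = scaling,
       truth = truth, fish_all = fish_all, fish = fish)
}

#' Simulate population longevity (a95) records directly
#'
#' Generates 95th-percentile-age records straight from the Gaussian
#' regression the longevity module fits: per-species intercepts and
#' temperature slopes, a lake random intercept, and residual noise.  Used
#' for focused parameter-recovery and calibration checks of
#' [fit_longevity_model()] without running the full survey generator.
#'
#' @param n_lakes number of lakes (spread evenly over `t_range`).
#' @param species character vector of species labels.
#' @param intercepts,slopes per-species intercept (yr) and slope (yr per SD
#'   of scaled temperature); recycled to `length(species)`.
#' @param years_per_lake records per lake and species.
#' @param sd_lake,sd_resid lake random-intercept and residual SDs (yr).
#' @param t_range range of the scaled covariate across lakes.
#' @param n_fish nominal fish count attached to each record.
#' @param seed RNG seed.
#' @return data frame with `species`, `lake_id`, `year`, `a95`, `n_fish`,
#'   `t_scaled`.
#' @export
simulate_a95_records <- function(n_lakes = 40, species = c("sp1", "sp2", "sp3"),
                                 intercepts = 12, slopes = -0.4,
                                 years_per_lake = 2, sd_lake = 1,
                                 sd_resid = 1, t_range = c(-1.7, 1.7),
                                 n_fish = 50, seed = 1) {
  stopifnot(n_lakes >= 2, years_per_lake >= 1, sd_lake >= 0, sd_resid > 0)
  J <- length(species)
  intercepts <- rep_len(intercepts, J)
  slopes <- rep_len(slopes, J)
  set.seed(seed)
  lake_ids <- sprintf("L%03d", seq_len(n_lakes))
  t_lake <- stats::setNames(seq(t_range[1], t_range[2], length.out = n_lakes),
                            lake_ids)
  u_lake <- stats::setNames(
    if (sd_lake > 0) stats::rnorm(n_lakes, 0, sd_lake) else rep(0, n_lakes),
    lake_ids)
  out <- expand.grid(species = species, lake_id = lake_ids,
                     year = seq_len(years_per_lake), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  j <- match(out$species, species)
  out$t_scaled <- t_lake[out$lake_id]
  out$a95 <- intercepts[j] + slopes[j] * out$t_scaled +
    u_lake[out$lake_id] + stats::rnorm(nrow(out), 0, sd_resid)
  out$n_fish <- n_fish
  out[c("species", "lake_id", "year", "a95", "n_fish", "t_scaled")]
}
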