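# Hierarchical Bayesian biphasic growth model.
#
# Observation model: length y_i ~ Lognormal(log mu_i, sigma_j) with mu_i the
# biphasic mean at the fish's age.  Survey-level parameters (alpha, beta1,
# amat, beta2) are drawn from normals, truncated to their supports, around
# linear predictors in the scaled thermal covariate with species baselines
# (gamma0, Uniform(0,30) priors), a global temperature slope per parameter
# (gamma1, Normal(0,1) priors), species random slopes (tau) and lake random
# intercepts (omega).  Gamma(1,1) priors sit on the variance-scale
# hyperparameters (precision placement by default, SD switchable).
#
# The exact log-density is implemented natively (growth_logprior,
# growth_loglik, growth_logposterior); sampling is delegated to JAGS with a
# model specification generated from the same structure.

PAR4 <- c("alpha", "beta1", "amat", "beta2")
PAR3 <- c("beta1", "amat", "beta2")

# truncation supports of survey-level parameters, shared by the native
# density and the JAGS specification
PAR_LOWER <- c(alpha = 0, beta1 = 1e-3, amat = 0.25, beta2 = -Inf)
PAR_UPPER <- c(alpha = Inf, beta1 = Inf, amat = 30, beta2 = Inf)

#' Bundle fish records and thermal covariates for the growth model
#'
#' Index-encodes species, lakes and surveys (species x lake x year) and
#' attaches the scaled thermal covariate to each survey.
#'
#' @param records fully aged fish records (`species`, `lake_id`, `year`,
#'   `length_cm`, `age_yr`; no missing ages, positive lengths).
#' @param thermal data frame with `lake_id`, `year`, `t_scaled`.
#' @return object of class `growth_data`: list with fish-level vectors
#'   (`y`, `age`, `survey`, `species_idx`), the survey table, and dimension
#'   constants `N`, `S`, `J`, `L`.
#' @export
growth_model_data <- function(records, thermal) {
  stopifnot(all(c("species", "lake_id", "year", "length_cm", "age_yr")
                %in% names(records)))
  if (any(is.na(records$age_yr))) stop("all records must be aged")
  if (any(records$length_cm <= 0)) stop("lengths must be positive")
  species <- sort(unique(records$species))
  lakes <- sort(unique(records$lake_id))
  surveys <- unique(records[c("species", "lake_id", "year")])
  surveys <- surveys[order(surveys$species, surveys$lake_id, surveys$year), ]
  rownames(surveys) <- NULL
  skey <- paste(surveys$species, surveys$lake_id, surveys$year)
  tkey <- paste(thermal$lake_id, thermal$year)
  surveys$t_scaled <- thermal$t_scaled[match(paste(surveys$lake_id, surveys$year),
                                             tkey)]
  if (any(is.na(surveys$t_scaled)))
    stop("every survey lake-year needs a scaled temperature")
  surveys$species_idx <- match(surveys$species, species)
  surveys$lake_idx <- match(surveys$lake_id, lakes)
  structure(list(
    y = records$length_cm, age = records$age_yr,
    survey = match(paste(records$species, records$lake_id, records$year), skey),
    species_idx = match(records$species, species),
    surveys = surveys, species = species, lakes = lakes,
    N = nrow(records), S = nrow(surveys), J = length(species),
    L = length(lakes)), class = "growth_data")
}

#' Lognormal observation log-likelihood of the biphasic model
#'
#' Sum over fish of the lognormal log-density of observed length with
#' log-scale location `log(biphasic_mean(age))` and per-species scale.
#'
#' @param records fish records (`species`, `lake_id`, `year`, `length_cm`,
#'   `age_yr`).
#' @param params survey-level parameters: data frame with `species`,
#'   `lake_id`, `year`, `alpha`, `beta1`, `amat`, `beta2` (one row per
#'   survey; every record must map to a row).
#' @param sigma named per-species lognormal scale vector.
#' @return scalar log-likelihood.
#' @export
growth_loglik <- function(records, params, sigma) {
  k <- match(paste(records$species, records$lake_id, records$year),
             paste(params$species, params$lake_id, params$year))
  if (any(is.na(k)))
    stop("record without survey parameters: ",
         paste(records$species, records$lake_id, records$year)[which(is.na(k))[1]])
  if (any(records$length_cm <= 0))
    stop("non-positive length for fish record ", which(records$length_cm <= 0)[1])
  mu <- biphasic_mean(params[k, ], records$age_yr)
  if (any(mu <= 0))
    stop("non-positive predicted mean for fish record ", which(mu <= 0)[1])
  s <- sigma[records$species]
  if (any(is.na(s) | s <= 0)) stop("missing or non-positive sigma for a species")
  sum(stats::dlnorm(records$length_cm, meanlog = log(mu), sdlog = s, log = TRUE))
}

#' Log-prior of the growth model hyperparameters
#'
#' Uniform(0, 30) on every species baseline `gamma0`, Normal(0, 1) on the
#' temperature slopes `gamma1`, Normal(0, sd_tau) on species random slopes,
#' Normal(0, sd_omega) on lake random intercepts, and Gamma(1, 1) on every
#' variance-scale hyperparameter (process, random-effect and observation
#' scales).  The Gamma(1, 1) prior is placed on the *precisions*
#' (`var_prior = "precision"`, the conventional Gibbs-sampler reading of a
#' "sigma^2 prior", conjugate and default) or on the *standard deviations*
#' (`var_prior = "sd"`); either way the density is reported in SD
#' coordinates (with the change-of-variables Jacobian for the precision
#' placement), matching the state stored in `hyper`.  Support violations
#' return `-Inf`.
#'
#' @param hyper list with `gamma0` (J x 4 matrix, columns alpha/beta1/amat/
#'   beta2), `gamma1` (length 3), `tau` (J x 3), `omega` (L x 4), `sd_phi`
#'   (4), `sd_tau` (3), `sd_omega` (4), `sd_obs` (J).
#' @param var_prior placement of the Gamma(1, 1) prior, `"precision"`
#'   (default) or `"sd"`.
#' @return scalar log-prior density.
#' @export
growth_logprior <- function(hyper, var_prior = c("precision", "sd")) {
  var_prior <- match.arg(var_prior)
  sds <- c(hyper$sd_phi, hyper$sd_tau, hyper$sd_omega, hyper$sd_obs)
  if (any(sds <= 0) || any(hyper$gamma0 < 0) || any(hyper$gamma0 > 30))
    return(-Inf)
  lp_scale <- if (var_prior == "sd") {
    sum(stats::dgamma(sds, 1, 1, log = TRUE))
  } else {
    # Gamma(1,1) density on prec = sd^-2, times Jacobian |d prec / d sd|
    sum(stats::dgamma(sds^-2, 1, 1, log = TRUE) + log(2) - 3 * log(sds))
  }
  sum(stats::dunif(hyper$gamma0, 0, 30, log = TRUE)) +
    sum(stats::dnorm(hyper$gamma1, 0, 1, log = TRUE)) +
    sum(stats::dnorm(hyper$tau, 0, rep(hyper$sd_tau, each = nrow(hyper$tau)),
                     log = TRUE)) +
    sum(stats::dnorm(hyper$omega, 0,
                     rep(hyper$sd_omega, each = nrow(hyper$omega)),
                     log = TRUE)) +
    lp_scale
}

# linear predictors phi for every survey and parameter, J x 4 hyper layout
growth_linpred <- function(hyper, data) {
  s <- data$surveys
  j <- s$species_idx; l <- s$lake_idx; Tk <- s$t_scaled
  cbind(
    alpha = hyper$gamma0[j, "alpha"] + hyper$omega[l, "alpha"],
    beta1 = hyper$gamma0[j, "beta1"] +
      (hyper$gamma1[["beta1"]] + hyper$tau[j, "beta1"]) * Tk +
      hyper$omega[l, "beta1"],
    amat = hyper$gamma0[j, "amat"] +
      (hyper$gamma1[["amat"]] + hyper$tau[j, "amat"]) * Tk +
      hyper$omega[l, "amat"],
    beta2 = hyper$gamma0[j, "beta2"] +
      (hyper$gamma1[["beta2"]] + hyper$tau[j, "beta2"]) * Tk +
      hyper$omega[l, "beta2"])
}

#' Joint log-posterior of the growth model
#'
#' `growth_logprior()` plus the truncated-normal log-densities of the
#' survey-level parameters around their linear predictors plus
#' `growth_loglik()`.  This is the exact target density the MCMC sampler
#' draws from.
#'
#' @param hyper hyperparameter list (see [growth_logprior()]).
#' @param latent survey-level parameters: matrix or data frame with columns
#'   `alpha`, `beta1`, `amat`, `beta2`, rows aligned with `data$surveys`.
#' @param data a [growth_model_data()] bundle.
#' @inheritParams growth_logprior
#' @return scalar log-posterior (un-normalised); `-Inf` on support
#'   violations.
#' @export
growth_logposterior <- function(hyper, latent, data,
                                var_prior = c("precision", "sd")) {
  stopifnot(inherits(data, "growth_data"))
  latent <- as.data.frame(latent)
  stopifnot(nrow(latent) == data$S)
  lp <- growth_logprior(hyper, var_prior)
  if (!is.finite(lp)) return(-Inf)
  phi <- growth_linpred(hyper, data)
  for (p in PAR4) {
    lp <- lp + sum(dtnorm_log(latent[[p]], phi[, p], hyper$sd_phi[[p]],
                              PAR_LOWER[[p]], PAR_UPPER[[p]]))
  }
  if (!is.finite(lp)) return(-Inf)
  mu <- biphasic_mean(latent[data$survey, ], data$age)
  if (any(mu <= 0)) return(-Inf)
  lp + sum(stats::dlnorm(data$y, log(mu), hyper$sd_obs[data$species_idx],
                         log = TRUE))
}

#' MCMC settings
#'
#' Desk-scale default: 3 chains of 10,000 iterations, burn-in 2,000,
#' thinning 4 (2,000 retained draws per chain).  [full_mcmc_config()]
#' reproduces the full-scale run of 3 chains of 125,000 iterations,
#' burn-in 30,000, thinning 10.
#'
#' @param n_chains,n_iter,n_burnin,thin chain count, total iterations per
#'   chain, burn-in iterations, thinning interval.  Retained draws per
#'   chain = `(n_iter - n_burnin) / thin`.
#' @param n_adapt JAGS adaptation iterations (counted inside the burn-in).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 10000, n_burnin = 2000,
                        thin = 4, n_adapt = 1000) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= n_adapt, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_adapt = as.integer(n_adapt)), class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
full_mcmc_config <- function() {
  mcmc_config(n_chains = 3, n_iter = 125000, n_burnin = 30000, thin = 10,
              n_adapt = 5000)
}

# JAGS specification mirroring growth_logposterior().  The species-slope
# hierarchy is written in centred form (eta = gamma1 + tau) which mixes far
# better under Gibbs; tau is recovered deterministically.  Gamma(1,1)
# scale priors sit on precisions (conjugate) or SDs per var_prior.
growth_jags_model <- function(include_likelihood = TRUE,
                              var_prior = "precision") {
  lik <- "
  for (i in 1:N) {
    mu0[i] <- alpha[k[i]] + b1[k[i]] * age[i] -
              step(age[i] - amat[k[i]]) * (b1[k[i]] - b2[k[i]]) * (age[i] - amat[k[i]])
    mu[i] <- ifelse(mu0[i] > 1.0E-6, mu0[i], 1.0E-6)
    y[i] ~ dlnorm(log(mu[i]), prec_obs[sp[i]])
  }"
  scale_prior <- function(par, idx) {
    if (var_prior == "precision")
      sprintf("prec_%s[%s] ~ dgamma(1, 1)\n    sd_%s[%s] <- pow(prec_%s[%s], -0.5)",
              par, idx, par, idx, par, idx)
    else
      sprintf("sd_%s[%s] ~ dgamma(1, 1)\n    prec_%s[%s] <- pow(sd_%s[%s], -2)",
              par, idx, par, idx, par, idx)
  }
  paste0("model {", if (include_likelihood) lik else "", "
  for (s in 1:S) {
    alpha[s] ~ dnorm(ph_a[s],  prec_phi[1]) T(0,)
    b1[s]    ~ dnorm(ph_b1[s], prec_phi[2]) T(1.0E-3,)
    amat[s]  ~ dnorm(ph_am[s], prec_phi[3]) T(0.25, 30)
    b2[s]    ~ dnorm(ph_b2[s], prec_phi[4])
    ph_a[s]  <- g0[spk[s], 1] + om[lake[s], 1]
    ph_b1[s] <- g0[spk[s], 2] + eta[spk[s], 1] * Tk[s] + om[lake[s], 2]
    ph_am[s] <- g0[spk[s], 3] + eta[spk[s], 2] * Tk[s] + om[lake[s], 3]
    ph_b2[s] <- g0[spk[s], 4] + eta[spk[s], 3] * Tk[s] + om[lake[s], 4]
  }
  for (j in 1:J) {
    for (p in 1:4) { g0[j, p] ~ dunif(0, 30) }
    for (p in 1:3) {
      eta[j, p] ~ dnorm(g1[p], prec_tau[p])
      tau[j, p] <- eta[j, p] - g1[p]
    }
    ", scale_prior("obs", "j"), "
  }
  for (l in 1:L) { for (p in 1:4) { om[l, p] ~ dnorm(0, prec_om[p]) } }
  for (p in 1:3) {
    g1[p] ~ dnorm(0, 1)
    ", scale_prior("tau", "p"), "
  }
  for (p in 1:4) {
    ", scale_prior("phi", "p"), "
    ", scale_prior("om", "p"), "
  }
}")
}

# data-informed starting values: least-squares biphasic fit per species
growth_inits <- function(data, config, seed, var_prior = "precision") {
  g0 <- matrix(NA_real_, data$J, 4)
  for (j in seq_len(data$J)) {
    sel <- data$species_idx == j
    if (sum(sel) >= 4 && length(unique(data$age[sel])) >= 3) {
      ls <- fit_biphasic_ls(data$age[sel], data$y[sel])
      g0[j, ] <- c(clamp(ls$alpha, 0.05, 29), clamp(ls$beta1, 0.05, 29),
                   clamp(ls$amat, 0.3, 25), clamp(ls$beta2, 0.05, 29))
    } else {
      g0[j, ] <- c(2, 5, 3, 1.5)   # generic mid-range start
    }
  }
  sidx <- data$surveys$species_idx
  lapply(seq_len(config$n_chains), function(ch) {
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = derive_seed(seed, 100 + ch),
      g0 = g0, g1 = rep(0, 3), eta = matrix(0, data$J, 3),
      om = matrix(0, data$L, 4),
      alpha = g0[sidx, 1], b1 = g0[sidx, 2], amat = g0[sidx, 3],
      b2 = g0[sidx, 4])
    if (var_prior == "precision") {
      ini$prec_phi <- rep(4, 4); ini$prec_tau <- rep(10, 3)
      ini$prec_om <- rep(10, 4); ini$prec_obs <- rep(25, data$J)
    } else {
      ini$sd_phi <- rep(0.5, 4); ini$sd_tau <- rep(0.3, 3)
      ini$sd_om <- rep(0.3, 4); ini$sd_obs <- rep(0.2, data$J)
    }
    ini
  })
}

# mcmc.list -> iterations x chains x parameters array
mcmc_list_to_array <- function(ml) {
  vars <- colnames(ml[[1]])
  arr <- array(NA_real_, c(nrow(ml[[1]]), length(ml), length(vars)),
               dimnames = list(NULL, NULL, vars))
  for (c in seq_along(ml)) arr[, c, ] <- as.matrix(ml[[c]])
  arr
}

# translate JAGS variable names to scientific labels
rename_growth_params <- function(vars, species) {
  out <- vars
  m <- regmatches(vars, regexec("^g0\\[(\\d+),(\\d+)\\]$", vars))
  for (i in seq_along(vars)) {
    if (length(m[[i]]) == 3) {
      out[i] <- sprintf("gamma0_%s[%s]", PAR4[as.integer(m[[i]][3])],
                        species[as.integer(m[[i]][2])])
    } else if (grepl("^g1\\[", vars[i])) {
      out[i] <- sprintf("gamma1_%s", PAR3[as.integer(sub("^g1\\[(\\d+)\\]$", "\\1",
                                                         vars[i]))])
    } else if (grepl("^tau\\[", vars[i])) {
      ij <- as.integer(strsplit(gsub("tau\\[|\\]", "", vars[i]), ",")[[1]])
      out[i] <- sprintf("tau_%s[%s]", PAR3[ij[2]], species[ij[1]])
    } else if (grepl("^sd_phi\\[", vars[i])) {
      out[i] <- sprintf("sd_phi_%s", PAR4[as.integer(gsub("\\D", "", vars[i]))])
    } else if (grepl("^sd_tau\\[", vars[i])) {
      out[i] <- sprintf("sd_tau_%s", PAR3[as.integer(gsub("\\D", "", vars[i]))])
    } else if (grepl("^sd_om\\[", vars[i])) {
      out[i] <- sprintf("sd_omega_%s", PAR4[as.integer(gsub("\\D", "", vars[i]))])
    } else if (grepl("^sd_obs\\[", vars[i])) {
      out[i] <- sprintf("sigma_obs[%s]", species[as.integer(gsub("\\D", "", vars[i]))])
    }
  }
  out
}

#' Fit the hierarchical biphasic growth model by MCMC
#'
#' Samples the posterior defined by [growth_logposterior()] with JAGS
#' (Gibbs/slice sampling), seeded and reproducible: the same seed yields
#' identical draws.  Monitored parameters are the species baselines
#' (`gamma0_*`), temperature slopes (`gamma1_*`), species random slopes
#' (`tau_*`), all SD hyperparameters and the per-species observation scales.
#'
#' @param records fully aged fish records (typically the age-length-key
#'   expanded sample of surveys passing [filter_surveys()]).
#' @param thermal survey lake-year covariate table with `t_scaled`.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed driving all chain RNGs.
#' @param sample_prior if `TRUE` the likelihood is omitted and the chains
#'   sample the prior (prior-recovery checks).
#' @inheritParams growth_logprior
#' @param quiet suppress JAGS progress output.
#' @return object of class `growth_fit`: list with `draws` (retained
#'   iterations x chains x parameters, scientific names), `data` (the
#'   [growth_model_data()] bundle), `mcmc`, `seed`.
#' @export
fit_growth_model <- function(records, thermal, mcmc = mcmc_config(),
                             seed = 1, sample_prior = FALSE,
                             var_prior = c("precision", "sd"), quiet = TRUE) {
  var_prior <- match.arg(var_prior)
  data <- if (inherits(records, "growth_data")) records else
    growth_model_data(records, thermal)
  jd <- list(S = data$S, spk = data$surveys$species_idx,
             lake = data$surveys$lake_idx, Tk = data$surveys$t_scaled,
             J = data$J, L = data$L)
  if (!sample_prior)
    jd <- c(jd, list(N = data$N, y = data$y, age = data$age,
                     k = data$survey, sp = data$species_idx))
  inits <- growth_inits(data, mcmc, seed, var_prior)
  model <- rjags::jags.model(
    textConnection(growth_jags_model(!sample_prior, var_prior)), data = jd,
    inits = inits, n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
    quiet = quiet)
  post_adapt_burn <- mcmc$n_burnin - mcmc$n_adapt
  if (post_adapt_burn > 0) stats::update(model, post_adapt_burn,
                                  progress.bar = "none")
  monitors <- c("g0", "g1", "tau", "sd_phi", "sd_tau", "sd_om", "sd_obs")
  samples <- rjags::coda.samples(model, monitors,
                                 n.iter = mcmc$n_iter - mcmc$n_burnin,
                                 thin = mcmc$thin, progress.bar = "none")
  draws <- mcmc_list_to_array(samples)
  dimnames(draws)[[3]] <- rename_growth_params(dimnames(draws)[[3]],
                                               data$species)
  structure(list(draws = draws, data = data, mcmc = mcmc, seed = seed,
                 sample_prior = sample_prior, var_prior = var_prior),
            class = "growth_fit")
}

#' Pooled posterior draws of one parameter
#'
#' @param fit a `growth_fit` or `longevity_fit`.
#' @param param parameter name (third dimension of `fit$draws`).
#' @return for [draws_matrix()] the retained iterations x chains matrix;
#'   for [pooled_draws()] all chains concatenated into one vector.
#' @export
draws_matrix <- function(fit, param) {
  if (!param %in% dimnames(fit$draws)[[3]])
    stop("unknown parameter: ", param)
  fit$draws[, , param, drop = TRUE]
}

#' @rdname draws_matrix
#' @export
pooled_draws <- function(fit, param) as.vector(draws_matrix(fit, param))

#' Posterior summary table of a fit
#'
#' Mean, SD, median and 95% highest-posterior-density bounds per parameter,
#' with the HPD-excludes-zero significance flag.
#'
#' @param fit a `growth_fit` or `longevity_fit`.
#' @param prob mass of the HPD interval.
#' @return data frame, one row per monitored parameter.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  pars <- dimnames(fit$draws)[[3]]
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- pooled_draws(fit, p)
    h <- hpd_interval(x, prob)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), hpd_lower = h[["lower"]],
               hpd_upper = h[["upper"]],
               significant = h[["lower"]] > 0 | h[["upper"]] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
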