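# Subsidiary longevity analysis: 95th-percentile age per population
# regressed on temperature with species interactions and lake random
# intercepts (Gaussian errors, Normal(0,10) coefficient priors,
# half-Normal(0,10) SD priors).

#' 95th-percentile age of a population
#'
#' Longevity proxy: the 95th percentile of observed ages, by linear
#' interpolation of order statistics (the standard sample-quantile
#' definition).
#'
#' @param ages observed ages of one population (non-empty numeric).
#' @return age in years.
#' @examples
#' compute_a95(1:100)  # 95.05
#' @export
compute_a95 <- function(ages) {
  if (length(ages) == 0 || all(is.na(ages))) stop("no ages supplied")
  unname(stats::quantile(ages, 0.95, type = 7, na.rm = TRUE))
}

#' Longevity records per population
#'
#' Aggregates (typically age-length-key expanded) fish records to one
#' 95th-percentile-age record per species x lake x year population.
#'
#' @param records aged fish records.
#' @param thermal optional covariate table with `lake_id`, `year`,
#'   `t_scaled` to join.
#' @param min_fish minimum fish per population to emit a record.
#' @return data frame with `species`, `lake_id`, `year`, `a95`, `n_fish`
#'   (and `t_scaled` when `thermal` is given).
#' @export
longevity_records <- function(records, thermal = NULL, min_fish = 1) {
  sp <- split(records, interaction(records$species, records$lake_id,
                                   records$year, drop = TRUE))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(species = d$species[1], lake_id = d$lake_id[1],
               year = d$year[1], a95 = compute_a95(d$age_yr),
               n_fish = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_fish >= min_fish, ]
  out <- out[order(out$species, out$lake_id, out$year), ]
  rownames(out) <- NULL
  if (!is.null(thermal)) {
    out$t_scaled <- thermal$t_scaled[match(paste(out$lake_id, out$year),
                                           paste(thermal$lake_id, thermal$year))]
    if (any(is.na(out$t_scaled)))
      stop("every longevity record needs a scaled temperature")
  }
  out
}

longevity_jags_model <- function(J) {
  offsets <- if (J > 1) "
  for (j in 2:J) {
    sp_off[j] ~ dnorm(0, 0.01)
    sp_int[j] ~ dnorm(0, 0.01)
  }" else ""
  paste0("model {
  for (i in 1:N) {
    mu[i] <- b0 + sp_off[sp[i]] + (slope + sp_int[sp[i]]) * T[i] + u[lake[i]]
    a95[i] ~ dnorm(mu[i], prec_res)
  }
  sp_off[1] <- 0
  sp_int[1] <- 0", offsets, "
  b0 ~ dnorm(0, 0.01)
  slope ~ dnorm(0, 0.01)
  for (l in 1:L) { u[l] ~ dnorm(0, prec_lake) }
  sd_lake ~ dnorm(0, 0.01) T(0,)
  sd_res ~ dnorm(0, 0.01) T(0,)
  prec_lake <- pow(sd_lake, -2)
  prec_res <- pow(sd_res, -2)
}")
}

#' Fit the Bayesian longevity regression
#'
#' Gaussian regression of population 95th-percentile age on the scaled
#' thermal covariate with species offsets, species-by-temperature
#' interactions (treatment coding against the first species) and lake
#' random intercepts.  Coefficients carry vague Normal(0, 10) priors and
#' both SDs half-Normal(0, 10) priors.  Sampling is by JAGS, seeded and
#' reproducible.
#'
#' @param records longevity records with `species`, `lake_id`, `a95` and
#'   `t_scaled` (see [longevity_records()]).
#' @param mcmc an [mcmc_config()]; the desk default retains 2,000 draws per
#'   chain.
#' @param seed integer seed for the chain RNGs.
#' @param quiet suppress JAGS output.
#' @return object of class `longevity_fit`: list with `draws` (iterations x
#'   chains x parameters; `intercept`, `temp_slope`, `species_offset[...]`,
#'   `temp_interaction[...]`, `sd_lake`, `sd_resid`), `species` (levels,
#'   first is the reference), `lakes`, `records`, `mcmc`, `seed`.
#' @export
fit_longevity_model <- function(records, mcmc = mcmc_config(), seed = 1,
                                quiet = TRUE) {
  stopifnot(all(c("species", "lake_id", "a95", "t_scaled") %in% names(records)))
  species <- sort(unique(records$species))
  lakes <- sort(unique(records$lake_id))
  if (length(lakes) < 2)
    stop("longevity regression needs at least 2 lakes for the random effect")
  J <- length(species)
  jd <- list(N = nrow(records), a95 = records$a95,
             sp = match(records$species, species),
             lake = match(records$lake_id, lakes),
             T = records$t_scaled, L = length(lakes))
  if (J > 1) jd$J <- J
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(seed, 200 + ch),
                b0 = mean(records$a95), slope = 0, u = rep(0, length(lakes)),
                sd_lake = 1, sd_res = stats::sd(records$a95))
    if (J > 1) {
      ini$sp_off <- c(NA, rep(0, J - 1))
      ini$sp_int <- c(NA, rep(0, J - 1))
    }
    ini
  })
  model <- rjags::jags.model(textConnection(longevity_jags_model(J)),
                             data = jd, inits = inits,
                             n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                             quiet = quiet)
  post_adapt_burn <- mcmc$n_burnin - mcmc$n_adapt
  if (post_adapt_burn > 0) stats::update(model, post_adapt_burn, progress.bar = "none")
  monitors <- c("b0", "slope", "sd_lake", "sd_res",
                if (J > 1) c("sp_off", "sp_int"))
  samples <- rjags::coda.samples(model, monitors,
                                 n.iter = mcmc$n_iter - mcmc$n_burnin,
                                 thin = mcmc$thin, progress.bar = "none")
  draws <- mcmc_list_to_array(samples)
  vars <- dimnames(draws)[[3]]
  vars[vars == "b0"] <- "intercept"
  vars[vars == "slope"] <- "temp_slope"
  vars[vars == "sd_res"] <- "sd_resid"
  for (j in seq_len(J)) {
    vars[vars == sprintf("sp_off[%d]", j)] <- sprintf("species_offset[%s]",
                                                      species[j])
    vars[vars == sprintf("sp_int[%d]", j)] <- sprintf("temp_interaction[%s]",
                                                      species[j])
  }
  dimnames(draws)[[3]] <- vars
  # drop the reference species' structural zeros (constant chains)
  keep <- !vars %in% sprintf(c("species_offset[%s]", "temp_interaction[%s]"),
                             species[1])
  draws <- draws[, , keep, drop = FALSE]
  structure(list(draws = draws, species = species, lakes = lakes,
                 records = records, mcmc = mcmc, seed = seed),
            class = "longevity_fit")
}
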