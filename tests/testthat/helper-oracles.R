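# Independent brute-force oracles, coded with explicit scalar loops and
# closed-form densities so they share no code path with the package
# implementations they check.

LOG2PI <- log(2 * pi)

norm_logpdf <- function(x, m, s) -0.5 * LOG2PI - log(s) - 0.5 * ((x - m) / s)^2

# lognormal log-likelihood, one fish at a time
oracle_loglik <- function(records, params, sigma) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    p <- params[params$species == r$species & params$lake_id == r$lake_id &
                  params$year == r$year, ]
    mu <- if (r$age_yr < p$amat) p$alpha + p$beta1 * r$age_yr else
      p$alpha + p$beta1 * p$amat + p$beta2 * (r$age_yr - p$amat)
    s <- sigma[[r$species]]
    total <- total + norm_logpdf(log(r$length_cm), log(mu), s) - log(r$length_cm)
  }
  total
}

# hyperprior density sum: Uniform(0,30), Normal(0,1), centred normals,
# Gamma(1,1) = exp(-x) on precisions (default, with the sd-space Jacobian
# 2/sd^3) or directly on SD scales
oracle_logprior <- function(hyper, var_prior = "precision") {
  total <- 0
  for (g in as.vector(hyper$gamma0)) {
    if (g < 0 || g > 30) return(-Inf)
    total <- total - log(30)
  }
  for (g in hyper$gamma1) total <- total + norm_logpdf(g, 0, 1)
  for (p in 1:3) for (j in seq_len(nrow(hyper$tau)))
    total <- total + norm_logpdf(hyper$tau[j, p], 0, hyper$sd_tau[p])
  for (p in 1:4) for (l in seq_len(nrow(hyper$omega)))
    total <- total + norm_logpdf(hyper$omega[l, p], 0, hyper$sd_omega[p])
  for (s in c(hyper$sd_phi, hyper$sd_tau, hyper$sd_omega, hyper$sd_obs)) {
    if (s <= 0) return(-Inf)
    total <- total + if (var_prior == "sd") -s else
      -1 / s^2 + log(2) - 3 * log(s)
  }
  unname(total)
}

oracle_logposterior <- function(hyper, latent, data,
                                var_prior = "precision") {
  lp <- oracle_logprior(hyper, var_prior)
  if (!is.finite(lp)) return(-Inf)
  lower <- c(alpha = 0, beta1 = 1e-3, amat = 0.25, beta2 = -Inf)
  upper <- c(alpha = Inf, beta1 = Inf, amat = 30, beta2 = Inf)
  sv <- data$surveys
  for (k in seq_len(nrow(sv))) {
    j <- sv$species_idx[k]; l <- sv$lake_idx[k]; Tk <- sv$t_scaled[k]
    phi <- c(alpha = hyper$gamma0[j, "alpha"] + hyper$omega[l, "alpha"],
             beta1 = hyper$gamma0[j, "beta1"] +
               (hyper$gamma1[["beta1"]] + hyper$tau[j, "beta1"]) * Tk +
               hyper$omega[l, "beta1"],
             amat = hyper$gamma0[j, "amat"] +
               (hyper$gamma1[["amat"]] + hyper$tau[j, "amat"]) * Tk +
               hyper$omega[l, "amat"],
             beta2 = hyper$gamma0[j, "beta2"] +
               (hyper$gamma1[["beta2"]] + hyper$tau[j, "beta2"]) * Tk +
               hyper$omega[l, "beta2"])
    for (p in c("alpha", "beta1", "amat", "beta2")) {
      x <- latent[k, p]
      if (x < lower[[p]] || x > upper[[p]]) return(-Inf)
      z <- stats::pnorm(upper[[p]], phi[[p]], hyper$sd_phi[[p]]) -
        stats::pnorm(lower[[p]], phi[[p]], hyper$sd_phi[[p]])
      lp <- lp + norm_logpdf(x, phi[[p]], hyper$sd_phi[[p]]) - log(z)
    }
  }
  for (i in seq_len(data$N)) {
    k <- data$survey[i]
    a <- data$age[i]
    mu <- if (a < latent[k, "amat"])
      latent[k, "alpha"] + latent[k, "beta1"] * a
    else latent[k, "alpha"] + latent[k, "beta1"] * latent[k, "amat"] +
      latent[k, "beta2"] * (a - latent[k, "amat"])
    s <- hyper$sd_obs[data$species_idx[i]]
    lp <- lp + norm_logpdf(log(data$y[i]), log(mu), s) - log(data$y[i])
  }
  unname(lp)
}

# rank-normalised split R-hat via explicit between/within formulas
oracle_split_rhat <- function(x) {
  n <- nrow(x) - nrow(x) %% 2
  half <- n / 2
  splits <- list()
  for (c in seq_len(ncol(x))) {
    splits[[length(splits) + 1]] <- x[1:half, c]
    splits[[length(splits) + 1]] <- x[(half + 1):n, c]
  }
  flat <- unlist(splits)
  r <- rank(flat, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(flat) + 1 / 4))
  zs <- split(z, rep(seq_along(splits), each = half))
  m <- length(zs)
  means <- vapply(zs, mean, numeric(1))
  vars <- vapply(zs, stats::var, numeric(1))
  w <- sum(vars) / m
  b <- half * sum((means - mean(means))^2) / (m - 1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# autocorrelation ESS with hand-rolled autocovariances and Geyer pairing
oracle_ess <- function(x) {
  n <- nrow(x); m <- ncol(x)
  s2 <- apply(x, 2, stats::var)
  w <- mean(s2)
  bn <- stats::var(colMeans(x))
  var_plus <- (n - 1) / n * w + bn
  rho <- numeric(n)
  rho[1] <- 1
  for (t in 1:(n - 1)) {
    acsum <- 0
    for (c in seq_len(m)) {
      xb <- mean(x[, c])
      ac <- 0
      for (i in 1:(n - t)) ac <- ac + (x[i, c] - xb) * (x[i + t, c] - xb)
      acsum <- acsum + (ac / n) * (s2[c] / ((n - 1) / n * s2[c]))
    }
    rho[t + 1] <- 1 - (w - acsum / m) / var_plus
  }
  npair <- floor(n / 2)
  p <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  pos <- which(p <= 0)
  if (length(pos)) p <- p[seq_len(pos[1] - 1)]
  if (length(p) > 1) p <- cummin(p)
  tau <- max(-1 + 2 * sum(p), 1 / (m * n))
  min(m * n / tau, m * n)
}

# narrowest interval holding ceiling(prob n) draws, all windows checked
oracle_hpd <- function(x, prob = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- max(2, ceiling(prob * n))
  best <- c(s[1], s[n])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + m - 1])
  }
  best
}

# small deterministic growth-model instance: 2 lakes, 1-2 species, n fish
make_tiny_growth <- function(n_fish = 20, n_species = 2, seed = 123) {
  set.seed(seed)
  species <- c("bluegill", "walleye")[seq_len(n_species)]
  surveys <- expand.grid(species = species, lake_id = c("L001", "L002"),
                         year = 2010, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  surveys$alpha <- stats::runif(nrow(surveys), 1, 4)
  surveys$beta1 <- stats::runif(nrow(surveys), 3, 7)
  surveys$amat <- stats::runif(nrow(surveys), 2, 4)
  surveys$beta2 <- stats::runif(nrow(surveys), 0.5, 2)
  k <- sample(nrow(surveys), n_fish, replace = TRUE)
  age <- sample(0:8, n_fish, replace = TRUE)
  mu <- surveys$alpha[k] + surveys$beta1[k] * pmin(age, surveys$amat[k]) +
    surveys$beta2[k] * pmax(age - surveys$amat[k], 0)
  records <- data.frame(
    fish_id = seq_len(n_fish), species = surveys$species[k],
    lake_id = surveys$lake_id[k], year = surveys$year[k],
    length_cm = stats::rlnorm(n_fish, log(mu), 0.1), age_yr = age,
    structure = "otolith", aged_flag = TRUE, stringsAsFactors = FALSE)
  thermal <- data.frame(lake_id = c("L001", "L002"), year = 2010,
                        t_scaled = c(-1, 1))
  hyper <- list(
    gamma0 = matrix(stats::runif(n_species * 4, 1, 6), n_species, 4,
                    dimnames = list(species,
                                    c("alpha", "beta1", "amat", "beta2"))),
    gamma1 = c(beta1 = 0.4, amat = -0.3, beta2 = 0.1),
    tau = matrix(stats::rnorm(n_species * 3, 0, 0.1), n_species, 3,
                 dimnames = list(species, c("beta1", "amat", "beta2"))),
    omega = matrix(stats::rnorm(2 * 4, 0, 0.2), 2, 4,
                   dimnames = list(c("L001", "L002"),
                                   c("alpha", "beta1", "amat", "beta2"))),
    sd_phi = c(alpha = 0.3, beta1 = 0.25, amat = 0.35, beta2 = 0.2),
    sd_tau = c(beta1 = 0.15, amat = 0.2, beta2 = 0.1),
    sd_omega = c(alpha = 0.3, beta1 = 0.2, amat = 0.25, beta2 = 0.15),
    sd_obs = stats::setNames(rep(0.12, n_species), species))
  list(records = records, surveys = surveys, thermal = thermal, hyper = hyper)
}
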