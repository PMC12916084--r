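# Derived temperature-dependent size posteriors: size at maturity,
# temperature-dependent maximum age, lifetime growth curves and maximum
# size, all propagating the full posterior uncertainty of their
# constituent parameters.

# per-draw species parameters of the growth model evaluated at a scaled
# temperature (lake effects at their population mean of zero); survey-level
# supports are enforced on the linear predictors
growth_params_at <- function(fit, species, t_scaled) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!species %in% fit$data$species)
    stop("species not in fit: ", species)
  tr <- range(fit$data$surveys$t_scaled)
  if (t_scaled < tr[1] || t_scaled > tr[2])
    warning(sprintf("t_scaled = %.2f outside the observed range [%.2f, %.2f]: extrapolating",
                    t_scaled, tr[1], tr[2]))
  g <- function(p) pooled_draws(fit, p)
  sp <- sprintf("[%s]", species)
  data.frame(
    alpha = pmax(g(paste0("gamma0_alpha", sp)), 0),
    beta1 = pmax(g(paste0("gamma0_beta1", sp)) +
                   (g("gamma1_beta1") + g(paste0("tau_beta1", sp))) * t_scaled,
                 1e-3),
    amat = clamp(g(paste0("gamma0_amat", sp)) +
                   (g("gamma1_amat") + g(paste0("tau_amat", sp))) * t_scaled,
                 0.25, 30),
    beta2 = g(paste0("gamma0_beta2", sp)) +
      (g("gamma1_beta2") + g(paste0("tau_beta2", sp))) * t_scaled)
}

#' Posterior draws of length at maturity
#'
#' Per posterior draw, `Lmat = alpha + beta1(T) * amat(T)` with the
#' juvenile slope and maturation age evaluated from that draw's
#' hyperparameters at the requested temperature, so the result inherits
#' every source of uncertainty in its constituent parts.
#'
#' @param fit a [fit_growth_model()] result.
#' @param species species name.
#' @param t_scaled temperature on the scaled covariate axis (a value
#'   outside the fitted range warns about extrapolation).
#' @return numeric vector of Lmat draws (cm).
#' @export
size_at_maturity_draws <- function(fit, species, t_scaled) {
  p <- growth_params_at(fit, species, t_scaled)
  p$alpha + p$beta1 * p$amat
}

#' Posterior draws of temperature-dependent maximum age
#'
#' Per longevity-regression draw, the linear predictor
#' `intercept + species offset + (slope + species interaction) * T`.
#'
#' @param fit a [fit_longevity_model()] result.
#' @param species species name (the reference species has zero offset and
#'   interaction).
#' @param t_scaled temperature on the scaled covariate axis.
#' @return numeric vector of Amax draws (years).
#' @export
amax_draws <- function(fit, species, t_scaled) {
  stopifnot(inherits(fit, "longevity_fit"))
  if (!species %in% fit$species) stop("species not in fit: ", species)
  out <- pooled_draws(fit, "intercept") + pooled_draws(fit, "temp_slope") * t_scaled
  if (species != fit$species[1]) {
    out <- out + pooled_draws(fit, sprintf("species_offset[%s]", species)) +
      pooled_draws(fit, sprintf("temp_interaction[%s]", species)) * t_scaled
  }
  out
}

#' Posterior lifetime growth curve and maximum size at a temperature
#'
#' Combines the growth and longevity posteriors: draws from the two
#' independent fits are paired by seeded random subsampling to a common
#' draw count; per paired draw the biphasic mean is evaluated on an age
#' grid up to that draw's maximum age, and maximum size `Lmax` is the
#' length at maximum age.  Draws whose `Amax` falls below `amat` are
#' floored to `amat` (curve ends at maturity); their fraction is reported.
#'
#' @param growth_fit a [fit_growth_model()] result.
#' @param longevity_fit a [fit_longevity_model()] result.
#' @param species species name present in both fits.
#' @param t_scaled temperature on the scaled covariate axis.
#' @param age_step age grid resolution in years.
#' @param seed seed for the draw pairing.
#' @param regime optional label (e.g. "5th percentile") carried through.
#' @return object of class `derived_size_curve`: list with `species`,
#'   `regime`, `t_scaled`, `curve` (data frame `age`, `q2.5`, `q50`,
#'   `q97.5`, `n_draws`, rows up to the 97.5% posterior quantile of Amax),
#'   draw vectors `lmat`, `lmax`, `amax`, and `frac_amax_floored`.
#' @export
growth_curve_draws <- function(growth_fit, longevity_fit, species, t_scaled,
                               age_step = 0.1, seed = 1, regime = NA_character_) {
  pars <- growth_params_at(growth_fit, species, t_scaled)
  amax <- amax_draws(longevity_fit, species, t_scaled)
  n <- min(nrow(pars), length(amax))
  set.seed(seed)
  pars <- pars[sample(nrow(pars), n), ]
  amax <- amax[sample(length(amax), n)]
  floored <- amax < pars$amat
  amax <- pmax(amax, pars$amat)
  ages <- seq(0, ceiling(stats::quantile(amax, 0.975)), by = age_step)
  len <- vapply(seq_len(n), function(d) {
    out <- biphasic_mean(pars[d, ], ages)
    out[ages > amax[d]] <- NA_real_
    out
  }, numeric(length(ages)))
  qs <- apply(len, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  curve <- data.frame(age = ages, q2.5 = qs[1, ], q50 = qs[2, ],
                      q97.5 = qs[3, ], n_draws = rowSums(!is.na(len)))
  curve <- curve[curve$n_draws > 0, ]
  rownames(curve) <- NULL
  structure(list(species = species, regime = regime, t_scaled = t_scaled,
                 curve = curve,
                 lmat = pars$alpha + pars$beta1 * pars$amat,
                 lmax = biphasic_mean(pars, amax),
                 amax = amax, frac_amax_floored = mean(floored)),
            class = "derived_size_curve")
}

#' Derived size posteriors across standard temperature regimes
#'
#' Evaluates [growth_curve_draws()] for every species at the 5th, 50th and
#' 95th percentiles of the thermal covariate observed in the growth fit
#' (cool, median and warm regimes).
#'
#' @param growth_fit a [fit_growth_model()] result.
#' @param longevity_fit a [fit_longevity_model()] result.
#' @param regimes covariate quantiles defining the temperature regimes.
#' @param age_step age grid resolution in years.
#' @param seed pairing seed.
#' @return list with `curves` (tidy data frame: `species`, `regime`,
#'   `age`, `q2.5`, `q50`, `q97.5`) and `summary` (per species x regime
#'   posterior median and 95% HPD of `Lmat`, `Lmax`, `Amax`, plus the
#'   floored-draw fraction).
#' @export
derive_size_curves <- function(growth_fit, longevity_fit,
                               regimes = c(0.05, 0.5, 0.95), age_step = 0.1,
                               seed = 1) {
  tq <- stats::quantile(growth_fit$data$surveys$t_scaled, regimes)
  labels <- sprintf("p%02d", round(100 * regimes))
  species <- intersect(growth_fit$data$species, longevity_fit$species)
  curves <- list(); summaries <- list()
  for (sp in species) {
    for (r in seq_along(regimes)) {
      d <- growth_curve_draws(growth_fit, longevity_fit, sp, tq[r],
                              age_step = age_step,
                              seed = derive_seed(seed, r), regime = labels[r])
      curves[[paste(sp, r)]] <- cbind(species = sp, regime = labels[r],
                                      d$curve)
      sm <- function(x) {
        h <- hpd_interval(x)
        c(median = stats::median(x), lower = h[["lower"]], upper = h[["upper"]])
      }
      summaries[[paste(sp, r)]] <- data.frame(
        species = sp, regime = labels[r], t_scaled = unname(tq[r]),
        lmat = sm(d$lmat)[1], lmat_lo = sm(d$lmat)[2], lmat_hi = sm(d$lmat)[3],
        lmax = sm(d$lmax)[1], lmax_lo = sm(d$lmax)[2], lmax_hi = sm(d$lmax)[3],
        amax = sm(d$amax)[1], amax_lo = sm(d$amax)[2], amax_hi = sm(d$amax)[3],
        frac_amax_floored = d$frac_amax_floored, stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))))
}
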