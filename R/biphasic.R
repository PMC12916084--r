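#' Biphasic (hockey-stick) mean length at age
#'
#' Piecewise-linear growth model used throughout the package: length
#' increases at the juvenile rate `beta1` up to the change point `amat`
#' (a proxy for age at maturity) and at the adult rate `beta2` afterwards.
#' The mean function is continuous at `amat` by construction:
#' \deqn{\mu(a) = \alpha + \beta_1 \min(a, A_{mat}) + \beta_2 \max(a - A_{mat}, 0).}
#'
#' @param params list or data frame with elements/columns `alpha` (cm, length
#'   at age 0), `beta1` (cm/yr, juvenile slope), `amat` (yr, change point) and
#'   `beta2` (cm/yr, adult slope).  A data frame is recycled against `age`.
#' @param age numeric vector of ages in years; must be non-negative.
#' @return numeric vector of expected lengths (cm).
#' @examples
#' biphasic_mean(list(alpha = 2, beta1 = 3, amat = 4, beta2 = 1), age = 0:8)
#' @export
biphasic_mean <- function(params, age) {
  if (any(age < 0)) stop("age must be non-negative")
  params$alpha + params$beta1 * pmin(age, params$amat) +
    params$beta2 * pmax(age - params$amat, 0)
}

#' Least-squares biphasic fit (single population)
#'
#' Profile fit over a grid of candidate change points: for each candidate
#' `amat` the remaining parameters enter linearly and are estimated by
#' ordinary least squares on the two basis functions `min(age, amat)` and
#' `max(age - amat, 0)`.  Used to initialise the MCMC sampler and as a quick
#' deterministic summary; it is not the inferential model.
#'
#' @param age,length paired observations for one population.
#' @param amat_grid candidate change points; defaults to a grid spanning the
#'   interior of the observed age range.
#' @return list with `alpha`, `beta1`, `amat`, `beta2` and the residual sum of
#'   squares `rss` of the winning candidate.
#' @export
fit_biphasic_ls <- function(age, length, amat_grid = NULL) {
  stopifnot(length(age) == length(length), length(age) >= 4)
  if (is.null(amat_grid)) {
    r <- range(age)
    amat_grid <- seq(max(r[1] + 0.5, 0.5), max(r[2] - 0.5, 1), by = 0.25)
  }
  best <- NULL
  for (am in amat_grid) {
    x1 <- pmin(age, am)
    x2 <- pmax(age - am, 0)
    fit <- stats::lm.fit(cbind(1, x1, x2), length)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      best <- list(alpha = unname(cf[1]), beta1 = unname(cf[2]),
                   amat = am, beta2 = unname(cf[3]), rss = rss)
    }
  }
  best
}
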