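# Internal helpers shared across modules.

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler used by the synthetic generator to keep survey-level
#' growth parameters inside their biological supports.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds (may be `-Inf`/`Inf`).
#' @return numeric vector of length `n`.
#' @keywords internal
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  # both bounds far in one tail: mass numerically zero, pin to nearest bound
  if (any(phi - plo < 1e-12)) {
    out <- numeric(n)
    deg <- (phi - plo < 1e-12)
    out[] <- stats::qnorm(pmin(pmax(stats::runif(n, plo, phi), 1e-16), 1 - 1e-16),
                          mean, sd)
    out[deg & mean < lower] <- lower
    out[deg & mean > upper] <- upper
    return(pmin(pmax(out, lower), upper))
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# log-density of the same truncated normal (scalar-safe, vectorised)
dtnorm_log <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  out <- stats::dnorm(x, mean, sd, log = TRUE) - log(z)
  out[x < lower | x > upper] <- -Inf
  out
}

# sample ages from a geometric-like decreasing distribution truncated at amax:
# P(a) proportional to survival^a for a = 0, 1, ..., floor(amax)
sample_ages <- function(n, amax, survival) {
  stopifnot(amax >= 0, survival > 0, survival < 1)
  ages <- 0:max(0L, floor(amax))
  sample(ages, n, replace = TRUE, prob = survival^ages)
}

# stable per-stage seeds derived from one master seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483399L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an R object via its serialised JSON (used in run manifests)
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
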