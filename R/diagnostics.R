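# MCMC convergence diagnostics: rank-normalised split R-hat,
# autocorrelation effective sample size, and highest-posterior-density
# intervals.  Implemented from first principles; thresholds follow the
# conventional R-hat < 1.1 and ESS > 300 bounds.

as_chain_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

# split every chain into halves (dropping the last draw of odd chains)
split_chains <- function(x) {
  n <- nrow(x) - nrow(x) %% 2
  half <- n / 2
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

# classic potential scale reduction factor on a chain matrix
basic_rhat <- function(x) {
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b <- n * stats::var(colMeans(x))
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalised split R-hat
#'
#' Chains are split in half, all draws are rank-normalised through the
#' inverse normal CDF, and the classic between/within-chain variance ratio
#' is computed on the transformed splits.  Values near 1 indicate
#' convergence; > 1.1 is the conventional alarm threshold.
#'
#' @param x matrix of retained draws, iterations x chains (>= 2 chains and
#'   >= 4 draws per chain).
#' @return scalar R-hat (>= 1 up to numerical tolerance); `NA` for a
#'   constant quantity.
#' @export
split_rhat <- function(x) {
  x <- as_chain_matrix(x)
  if (ncol(x) < 2) stop("split R-hat needs at least 2 chains")
  if (nrow(x) < 4) stop("split R-hat needs at least 4 draws per chain")
  x <- split_chains(x)
  s <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3/8) / (s + 1/4))
  basic_rhat(matrix(z, nrow = nrow(x)))
}

#' Autocorrelation effective sample size
#'
#' Multi-chain effective sample size from the combined autocorrelation
#' function: per-chain autocovariances are pooled against the cross-chain
#' variance, summed over lags with Geyer's initial monotone positive
#' sequence truncation, and the total draw count is deflated by the
#' resulting integrated autocorrelation time.  Capped at the total number
#' of draws; a constant quantity reports 0.
#'
#' @param x matrix of retained draws, iterations x chains (>= 2 chains and
#'   >= 4 draws per chain).
#' @return scalar effective sample size in (0, chains x iterations], or 0
#'   for a constant quantity.
#' @export
ess_draws <- function(x) {
  x <- as_chain_matrix(x)
  if (ncol(x) < 2) stop("effective sample size needs at least 2 chains")
  n <- nrow(x); m <- ncol(x)
  if (n < 4) stop("effective sample size needs at least 4 draws per chain")
  s2 <- apply(x, 2, stats::var)
  w <- mean(s2)
  if (w == 0) return(0)
  b_over_n <- stats::var(colMeans(x))
  var_plus <- (n - 1) / n * w + b_over_n
  acfs <- vapply(seq_len(m), function(c)
    drop(stats::acf(x[, c], lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf), numeric(n))
  # combined autocorrelation at each lag
  rho <- 1 - (w - rowMeans(t(t(acfs) * s2))) / var_plus
  rho[1] <- 1
  # Geyer initial positive sequence over lag pairs, then monotone envelope
  npair <- floor(length(rho) / 2)
  p <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  pos <- which(p <= 0)
  if (length(pos)) p <- p[seq_len(pos[1] - 1)]
  if (length(p) > 1) p <- cummin(p)
  tau <- max(-1 + 2 * sum(p), 1 / (m * n))
  min(m * n / tau, m * n)
}

#' Highest posterior density interval
#'
#' Narrowest interval containing `prob` posterior mass, computed by the
#' sorted sliding-window method.
#'
#' @param x posterior draws (numeric vector).
#' @param prob interval mass, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(length(x) >= 2, prob > 0, prob < 1)
  s <- sort(x)
  n <- length(s)
  m <- max(2, ceiling(prob * n))
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

#' HPD-based significance of a posterior effect
#'
#' An effect is declared significant when its `prob` highest-posterior-
#' density interval excludes zero.
#'
#' @param x posterior draws of the effect (>= 100 draws).
#' @param prob interval mass, default 0.95.
#' @return list with `lower`, `upper`, `prob`, `significant`.
#' @export
hpd_significance <- function(x, prob = 0.95) {
  if (length(x) < 100) stop("need at least 100 draws for HPD significance")
  h <- hpd_interval(x, prob)
  list(lower = h[["lower"]], upper = h[["upper"]], prob = prob,
       significant = h[["lower"]] > 0 | h[["upper"]] < 0)
}

#' Convergence report across monitored parameters
#'
#' Per-parameter rank-normalised split R-hat and autocorrelation effective
#' sample size, with pass flags at the conventional thresholds.
#'
#' @param fit a `growth_fit`/`longevity_fit`, or an iterations x chains x
#'   parameters array.
#' @param rhat_threshold,ess_threshold pass thresholds (defaults 1.1, 300).
#' @return data frame with `parameter`, `rhat`, `ess`, `rhat_ok`, `ess_ok`.
#' @export
convergence_report <- function(fit, rhat_threshold = 1.1,
                               ess_threshold = 300) {
  draws <- if (is.array(fit) && length(dim(fit)) == 3) fit else fit$draws
  pars <- dimnames(draws)[[3]]
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- draws[, , p, drop = TRUE]
    data.frame(parameter = p, rhat = split_rhat(x), ess = ess_draws(x),
               stringsAsFactors = FALSE)
  }))
  out$rhat_ok <- !is.na(out$rhat) & out$rhat < rhat_threshold
  out$ess_ok <- out$ess > ess_threshold
  rownames(out) <- NULL
  out
}
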