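# Thermal covariates: annual growing degree days above a 5 deg C base and
# their trailing multi-year mean, z-scored for modelling.

#' Annual growing degree days above a base temperature
#'
#' `sum(max(temp - base, 0))` over the supplied daily temperatures; a
#' standard index of the thermal energy a lake receives in a year.
#'
#' @param temp_c daily temperatures (deg C), one value per day.
#' @param base base temperature (deg C), default 5.
#' @return degree-days (deg C day), non-negative.
#' @examples
#' compute_gdd5(c(6, 7, 5, 10))  # 1 + 2 + 0 + 5 = 8
#' @export
compute_gdd5 <- function(temp_c, base = 5) {
  stopifnot(is.numeric(temp_c))
  sum(pmax(temp_c - base, 0))
}

#' Annual GDD5 per lake-year
#'
#' Aggregates a daily temperature table to one GDD5 value per lake and
#' calendar year, checking calendar completeness against the year's true
#' day count.
#'
#' @param daily data frame with columns `lake_id`, `date` (Date or
#'   ISO-8601 character) and `temp_c`.
#' @param base base temperature (deg C).
#' @param max_missing_frac tolerated fraction of missing days per
#'   lake-year; the default 0 demands complete coverage.  A lake-year above
#'   the tolerance aborts with an error naming it.
#' @return data frame with `lake_id`, `year`, `gdd5`, `n_days`.
#' @export
gdd5_table <- function(daily, base = 5, max_missing_frac = 0) {
  stopifnot(all(c("lake_id", "date", "temp_c") %in% names(daily)))
  date <- as.Date(daily$date)
  year <- as.integer(format(date, "%Y"))
  days_in_year <- function(y) ifelse((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0,
                                     366L, 365L)
  sp <- split(seq_len(nrow(daily)), list(daily$lake_id, year), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(i) {
    y <- year[i[1]]
    n <- length(unique(date[i]))
    missing_frac <- 1 - n / days_in_year(y)
    if (missing_frac > max_missing_frac + 1e-12)
      stop(sprintf("lake %s year %d: %d of %d days missing",
                   daily$lake_id[i[1]], y, days_in_year(y) - n, days_in_year(y)))
    data.frame(lake_id = daily$lake_id[i[1]], year = y,
               gdd5 = compute_gdd5(daily$temp_c[i], base), n_days = n,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lake_id, out$year), ]
  rownames(out) <- NULL
  out
}

#' Trailing-window mean of annual GDD5 for one lake
#'
#' Arithmetic mean of annual GDD5 over the `window` years ending at (and
#' including) `survey_year`.  With the default 10-year window this is the
#' thermal covariate used throughout the analysis.
#'
#' @param annual data frame with columns `year` and `gdd5` for a single lake.
#' @param survey_year year the survey was conducted.
#' @param window number of years in the trailing window.
#' @param policy `"strict"` (default) errors unless every window year is
#'   present; `"available"` averages whatever window years exist.
#' @return mean GDD5 (degree-days) over the window.
#' @export
compute_window_mean <- function(annual, survey_year, window = 10,
                                policy = c("strict", "available")) {
  policy <- match.arg(policy)
  stopifnot(all(c("year", "gdd5") %in% names(annual)), window >= 1)
  want <- seq(survey_year - window + 1, survey_year)
  have <- annual$year %in% want
  if (policy == "strict" && sum(have) < window)
    stop(sprintf("only %d of %d window years available for survey year %d",
                 sum(have), window, survey_year))
  if (sum(have) == 0)
    stop(sprintf("no window years available for survey year %d", survey_year))
  mean(annual$gdd5[have])
}

#' Thermal covariate table for survey lake-years
#'
#' Applies [compute_window_mean()] to every lake and survey year.
#'
#' @param gdd data frame from [gdd5_table()].
#' @param survey_years survey years to cover.
#' @inheritParams compute_window_mean
#' @return data frame with `lake_id`, `year`, `gdd5` (that year's GDD5) and
#'   `t_window_mean`.
#' @export
thermal_covariates <- function(gdd, survey_years, window = 10,
                               policy = c("strict", "available")) {
  policy <- match.arg(policy)
  out <- expand.grid(lake_id = sort(unique(gdd$lake_id)),
                     year = sort(unique(as.integer(survey_years))),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$gdd5 <- gdd$gdd5[match(paste(out$lake_id, out$year),
                             paste(gdd$lake_id, gdd$year))]
  out$t_window_mean <- vapply(seq_len(nrow(out)), function(i) {
    compute_window_mean(gdd[gdd$lake_id == out$lake_id[i], ],
                        out$year[i], window, policy)
  }, numeric(1))
  out
}

#' Z-score a thermal covariate, keeping the scaling record
#'
#' Centres and scales to unit SD across all modelled lake-years so the
#' Normal(0, 1) slope priors of the growth model are sensible, and stores
#' the mean/SD so derived quantities can be mapped back to degree-days.
#'
#' @param x covariate values (degree-days); needs >= 2 distinct values.
#' @return object of class `covariate_scaling`: list with `scaled`,
#'   `center`, `scale`.
#' @seealso [unscale_covariate()]
#' @export
scale_covariate <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("covariate has zero variance; cannot scale")
  structure(list(scaled = (x - mean(x)) / s, center = mean(x), scale = s),
            class = "covariate_scaling")
}

#' Map a scaled covariate back to degree-days
#'
#' @param scaled values on the z-score scale.
#' @param scaling a `covariate_scaling` record from [scale_covariate()].
#' @return values on the original degree-day scale.
#' @export
unscale_covariate <- function(scaled, scaling) {
  stopifnot(inherits(scaling, "covariate_scaling"))
  scaled * scaling$scale + scaling$center
}
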