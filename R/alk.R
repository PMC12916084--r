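# Age-length keys: per-survey length-bin x age probability tables built from
# the aged subsample, used to assign ages to length-only fish, plus the
# survey inclusion filter (>= 5 age groups with >= 5 aged fish each).

#' Build an age-length key for one survey
#'
#' Bins the aged subsample into half-open length bins `[lo, hi)` of width
#' `bin_width` and tabulates, within each bin, the proportion of aged fish
#' at each age.  Rows of non-empty bins sum to one.
#'
#' @param aged data frame of aged records for a single survey, with columns
#'   `length_cm` and `age_yr` (no missing ages).
#' @param bin_width length-bin width in cm (default 1, standard fisheries
#'   practice).
#' @return object of class `age_length_key`: list with `breaks` (bin edges),
#'   `ages` (observed age values), `prob` (bins x ages matrix; empty-bin
#'   rows are `NA`) and `n` (aged fish per bin).
#' @export
build_alk <- function(aged, bin_width = 1) {
  stopifnot(bin_width > 0)
  if (nrow(aged) == 0 || any(is.na(aged$age_yr)))
    stop("age-length key needs at least one aged fish and no missing ages")
  lo <- floor(min(aged$length_cm) / bin_width) * bin_width
  hi <- (floor(max(aged$length_cm) / bin_width) + 1) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin <- findInterval(aged$length_cm, breaks, rightmost.closed = FALSE)
  ages <- sort(unique(aged$age_yr))
  counts <- table(factor(bin, levels = seq_len(length(breaks) - 1)),
                  factor(aged$age_yr, levels = ages))
  counts <- matrix(as.numeric(counts), nrow = length(breaks) - 1,
                   dimnames = list(NULL, as.character(ages)))
  n <- rowSums(counts)
  prob <- counts / ifelse(n > 0, n, NA_real_)
  structure(list(breaks = breaks, ages = ages, prob = prob, n = n,
                 bin_width = bin_width), class = "age_length_key")
}

#' Assign ages to length-only fish from an age-length key
#'
#' Unaged fish receive a seeded stochastic draw from their length bin's age
#' distribution (stochastic rather than modal assignment preserves the age
#' composition variance the growth model's likelihood assumes).  Fish whose
#' length falls outside the key's range, or into an empty bin, are dropped
#' with a count (`policy = "drop"`) or assigned from the nearest non-empty
#' bin (`policy = "nearest"`).  Already-aged fish pass through unchanged.
#'
#' @param key an [build_alk()] key built from the same survey.
#' @param records fish records of that survey (mixed aged/unaged).
#' @param seed RNG seed for the assignment draws.
#' @param policy out-of-range handling, `"drop"` (default) or `"nearest"`.
#' @return list with `records` (all retained fish, every one aged,
#'   `aged_flag` preserved from input) and `dropped` (the dropped rows).
#' @export
apply_alk <- function(key, records, seed = 1, policy = c("drop", "nearest")) {
  stopifnot(inherits(key, "age_length_key"))
  policy <- match.arg(policy)
  set.seed(seed)
  unaged <- which(is.na(records$age_yr))
  if (length(unaged) == 0)
    return(list(records = records, dropped = records[0, ]))
  nbin <- length(key$breaks) - 1
  bin <- findInterval(records$length_cm[unaged], key$breaks,
                      rightmost.closed = FALSE)
  usable <- which(key$n > 0)
  bad <- bin < 1 | bin > nbin
  bad[!bad] <- key$n[bin[!bad]] == 0
  if (policy == "nearest") {
    bin[bad] <- usable[vapply(pmin(pmax(bin[bad], 1), nbin), function(b)
      which.min(abs(usable - b)), integer(1))]
    bad[] <- FALSE
  }
  drop_rows <- unaged[bad]
  assign_rows <- unaged[!bad]
  for (i in seq_along(assign_rows)) {
    p <- key$prob[bin[!bad][i], ]
    records$age_yr[assign_rows[i]] <- key$ages[
      sample.int(length(key$ages), 1, prob = p)]
  }
  dropped <- records[drop_rows, ]
  kept <- if (length(drop_rows)) records[-drop_rows, ] else records
  rownames(kept) <- NULL
  list(records = kept, dropped = dropped)
}

#' Survey inclusion filter on the aged subsample
#'
#' A survey (species x lake x year) qualifies for key construction and
#' modelling when its aged subsample holds at least `min_groups` distinct
#' age groups each containing at least `min_per_group` fish.  Sparse extra
#' age groups do not disqualify a survey.
#'
#' @param records fish records (only rows with `aged_flag` and a non-missing
#'   age count toward the quota).
#' @param min_groups,min_per_group the filter thresholds (default 5 and 5).
#' @return data frame with one row per survey: `species`, `lake_id`,
#'   `year`, `n_aged`, `n_age_groups_meeting_quota`, `passed`.
#' @export
filter_surveys <- function(records, min_groups = 5, min_per_group = 5) {
  aged <- records[records$aged_flag & !is.na(records$age_yr), ]
  all_k <- unique(records[c("species", "lake_id", "year")])
  sp <- split(aged, interaction(aged$species, aged$lake_id, aged$year,
                                drop = TRUE))
  res <- do.call(rbind, lapply(sp, function(d) {
    counts <- table(d$age_yr)
    data.frame(species = d$species[1], lake_id = d$lake_id[1],
               year = d$year[1], n_aged = nrow(d),
               n_age_groups_meeting_quota = sum(counts >= min_per_group),
               stringsAsFactors = FALSE)
  }))
  out <- merge(all_k, res, all.x = TRUE, sort = FALSE)
  out$n_aged[is.na(out$n_aged)] <- 0L
  out$n_age_groups_meeting_quota[is.na(out$n_age_groups_meeting_quota)] <- 0L
  out$passed <- out$n_age_groups_meeting_quota >= min_groups
  out <- out[order(out$species, out$lake_id, out$year), ]
  rownames(out) <- NULL
  out
}

#' Expand every passing survey with its age-length key
#'
#' Convenience wrapper: applies [filter_surveys()], builds a key per passing
#' survey from its aged subsample, and ages the full sample with
#' [apply_alk()].  Surveys failing the filter are excluded entirely.
#'
#' @param records mixed aged/unaged fish records across surveys.
#' @param bin_width length-bin width in cm.
#' @param seed RNG seed (one deterministic substream per survey).
#' @param min_groups,min_per_group filter thresholds.
#' @param policy out-of-range policy passed to [apply_alk()].
#' @return list with `records` (aged fish of passing surveys), `filter`
#'   (the [filter_surveys()] table), `keys` (named list of keys) and
#'   `dropped` (rows dropped by the out-of-range policy).
#' @export
expand_with_alk <- function(records, bin_width = 1, seed = 1,
                            min_groups = 5, min_per_group = 5,
                            policy = "drop") {
  filt <- filter_surveys(records, min_groups, min_per_group)
  keys <- list()
  kept <- list()
  dropped <- list()
  pass <- filt[filt$passed, ]
  for (i in seq_len(nrow(pass))) {
    sel <- records$species == pass$species[i] &
      records$lake_id == pass$lake_id[i] & records$year == pass$year[i]
    surv <- records[sel, ]
    key <- build_alk(surv[surv$aged_flag & !is.na(surv$age_yr), ], bin_width)
    res <- apply_alk(key, surv, seed = derive_seed(seed, i), policy = policy)
    id <- paste(pass$species[i], pass$lake_id[i], pass$year[i], sep = ":")
    keys[[id]] <- key
    kept[[id]] <- res$records
    dropped[[id]] <- res$dropped
  }
  list(records = do.call(rbind, kept), filter = filt, keys = keys,
       dropped = do.call(rbind, dropped))
}

#' Serialise an age-length key to a long-format data frame
#'
#' @param key an [build_alk()] key.
#' @return data frame with `bin_lo`, `bin_hi`, `age`, `prob`, `n_aged`
#'   (empty bins omitted).
#' @export
alk_to_df <- function(key) {
  stopifnot(inherits(key, "age_length_key"))
  nb <- length(key$breaks) - 1
  out <- expand.grid(bin = seq_len(nb), age = key$ages,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[key$n[out$bin] > 0, ]
  data.frame(bin_lo = key$breaks[out$bin], bin_hi = key$breaks[out$bin + 1],
             age = out$age,
             prob = key$prob[cbind(out$bin, match(out$age, key$ages))],
             n_aged = key$n[out$bin])
}
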