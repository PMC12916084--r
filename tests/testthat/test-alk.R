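aged_df <- function(length_cm, age_yr, species = "walleye") {
  data.frame(fish_id = seq_along(length_cm), species = species,
             lake_id = "L001", year = 2010, length_cm = length_cm,
             age_yr = age_yr, structure = "otolith",
             aged_flag = !is.na(age_yr), stringsAsFactors = FALSE)
}

test_that("key rows are hand-countable probabilities that sum to one", {
  aged <- aged_df(c(10.2, 10.5, 10.7, 10.9, 14.1), c(2, 2, 2, 3, 5))
  key <- build_alk(aged, bin_width = 1)
  row10 <- key$prob[which(key$breaks == 10), ]
  expect_equal(unname(row10[c("2", "3")]), c(0.75, 0.25))
  filled <- key$n > 0
  expect_equal(unname(rowSums(key$prob[filled, , drop = FALSE])),
               rep(1, sum(filled)), tolerance = 1e-12)
  expect_true(all(key$prob[filled, ] >= 0))
  expect_error(build_alk(aged[0, ]), "at least one aged fish")
})

test_that("single-age surveys produce one-hot keys and deterministic assignment", {
  aged <- aged_df(c(10.1, 11.5, 12.2), c(4, 4, 4))
  key <- build_alk(aged)
  filled <- key$n > 0
  expect_true(all(key$prob[filled, "4"] == 1))
  unaged <- aged_df(c(10.4, 12.9), c(NA, NA))
  for (s in 1:3) {
    res <- apply_alk(key, unaged, seed = s)
    expect_equal(res$records$age_yr, c(4, 4))
  }
})

test_that("assignment conserves fish and converges to the key row", {
  aged <- aged_df(c(rep(10.5, 6), rep(10.6, 3)), c(rep(2, 6), rep(5, 3)))
  key <- build_alk(aged)
  n <- 6000
  unaged <- aged_df(runif(n, 10, 11), rep(NA_real_, n))
  res <- apply_alk(key, unaged, seed = 7)
  expect_equal(nrow(res$records) + nrow(res$dropped), n)
  freq <- mean(res$records$age_yr == 2)
  expect_equal(freq, 2 / 3, tolerance = 0.03)
  # fully aged input is untouched
  res2 <- apply_alk(key, aged, seed = 1)
  expect_identical(res2$records, aged)
})

test_that("fish outside the key's bins are dropped or mapped to the nearest bin", {
  aged <- aged_df(c(10.5, 10.6, 10.8), c(2, 2, 3))
  key <- build_alk(aged)
  mixed <- aged_df(c(10.2, 25.0, 3.0), c(NA, NA, NA))
  res <- apply_alk(key, mixed, seed = 2)
  expect_equal(nrow(res$dropped), 2)
  expect_equal(nrow(res$records), 1)
  res_near <- apply_alk(key, mixed, seed = 2, policy = "nearest")
  expect_equal(nrow(res_near$dropped), 0)
  expect_true(all(res_near$records$age_yr %in% c(2, 3)))
})

test_that("the survey filter demands five age groups of five aged fish", {
  mk <- function(counts) {
    ages <- rep(seq_along(counts), counts)
    aged_df(10 + ages + runif(length(ages)), ages)
  }
  # exactly 5 x 5: pass
  expect_true(filter_surveys(mk(rep(5, 5)))$passed)
  # four groups of any size: fail
  expect_false(filter_surveys(mk(rep(50, 4)))$passed)
  # {10, 8, 6, 5, 5, 2}: five qualifying groups, sparse sixth does not disqualify
  f <- filter_surveys(mk(c(10, 8, 6, 5, 5, 2)))
  expect_equal(f$n_age_groups_meeting_quota, 5L)
  expect_true(f$passed)
  # unaged fish never count toward the quota
  d <- mk(rep(5, 5))
  d$age_yr[1] <- NA
  d$aged_flag[1] <- FALSE
  expect_false(filter_surveys(d)$passed)
})

test_that("adding aged fish never flips a passing survey to failing", {
  set.seed(41)
  base <- aged_df(10 + runif(40, 0, 10), sample(1:6, 40, replace = TRUE))
  for (rep in 1:10) {
    extra <- aged_df(10 + runif(10, 0, 10), sample(1:8, 10, replace = TRUE))
    extra$fish_id <- extra$fish_id + 1000 + rep
    before <- filter_surveys(base)$passed
    after <- filter_surveys(rbind(base, extra))$passed
    expect_true(!before || after)
  }
})

test_that("expand_with_alk ages every fish of passing surveys and keeps counts", {
  cfg <- simulation_config(n_lakes = 4, n_species = 2, years_per_lake = 1,
                           fish_per_survey = 60, seed = 13)
  sim <- simulate_dataset(cfg)
  alk <- expand_with_alk(sim$fish, seed = 3)
  expect_true(all(!is.na(alk$records$age_yr)))
  n_pass_fish <- sum(paste(sim$fish$species, sim$fish$lake_id, sim$fish$year) %in%
                       with(alk$filter[alk$filter$passed, ],
                            paste(species, lake_id, year)))
  n_dropped <- if (is.null(alk$dropped)) 0L else nrow(alk$dropped)
  expect_equal(nrow(alk$records) + n_dropped, n_pass_fish)
  # serialised keys carry normalised rows
  df <- alk_to_df(alk$keys[[1]])
  sums <- as.vector(tapply(df$prob, df$bin_lo, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
})
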