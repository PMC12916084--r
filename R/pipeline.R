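# End-to-end orchestration: simulate -> thermal -> age-length keys ->
# growth fit -> longevity fit -> derived sizes -> report, with CSV
# artifacts and a reproducibility manifest at every stage.

#' Pipeline configuration
#'
#' Validates and assembles the configuration of [run_pipeline()]: the
#' synthetic-survey settings, the MCMC settings of both fits, and the
#' stage toggles.  Can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param sim a [simulation_config()] (or a list of its arguments).
#' @param mcmc_growth,mcmc_longevity [mcmc_config()]s for the two fits.
#' @param regimes covariate quantiles for the derived size regimes.
#' @param alk_policy out-of-range policy for [apply_alk()].
#' @param stages character vector of stages to run, in dependency order.
#' @param seed master seed for the fitting and derivation stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            mcmc_growth = mcmc_config(),
                            mcmc_longevity = mcmc_config(),
                            regimes = c(0.05, 0.5, 0.95),
                            alk_policy = "drop",
                            stages = c("simulate", "thermal", "alk",
                                       "fit_growth", "fit_longevity",
                                       "derive", "report"),
                            seed = 1) {
  if (!inherits(sim, "sim_config")) sim <- do.call(simulation_config, sim)
  if (!inherits(mcmc_growth, "mcmc_config"))
    mcmc_growth <- do.call(mcmc_config, mcmc_growth)
  if (!inherits(mcmc_longevity, "mcmc_config"))
    mcmc_longevity <- do.call(mcmc_config, mcmc_longevity)
  known <- c("simulate", "thermal", "alk", "fit_growth", "fit_longevity",
             "derive", "report")
  stopifnot(all(stages %in% known))
  structure(list(sim = sim, mcmc_growth = mcmc_growth,
                 mcmc_longevity = mcmc_longevity, regimes = regimes,
                 alk_policy = alk_policy, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()] (`sim`, `mcmc_growth`, ... as nested maps).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Filter records by aging structure
#'
#' Restricts records to the given aging structures (e.g. the most reliable
#' ones, otoliths and cleithra), enabling sensitivity refits without
#' further code.
#'
#' @param records fish records with a `structure` column.
#' @param allowed character vector of allowed structure labels.
#' @return the matching subset (a warning is raised if empty).
#' @export
structure_filter <- function(records, allowed) {
  stopifnot("structure" %in% names(records))
  out <- records[records$structure %in% allowed, ]
  if (nrow(out) == 0) warning("structure filter removed every record")
  rownames(out) <- NULL
  out
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# long-format draws table (chain, iteration, parameter, value)
draws_to_long <- function(draws) {
  d <- dim(draws)
  data.frame(
    chain = rep(seq_len(d[2]), each = d[1], times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(dimnames(draws)[[3]], each = d[1] * d[2]),
    value = as.vector(draws))
}

#' Temperature-effect tables with HPD significance flags
#'
#' Summarise the marginal temperature slopes (`gamma1_*`, species "all")
#' and the species-specific effect totals (`gamma1 + tau` for the growth
#' fit; `slope + interaction` for the longevity fit), each with its
#' posterior mean, 95% HPD interval and significance flag.
#'
#' @param fit a `growth_fit` ([growth_effects_table()]) or
#'   `longevity_fit` ([longevity_effects_table()]).
#' @param prob HPD interval mass.
#' @return data frame with `effect`, `species`, `mean`, `hpd_lower`,
#'   `hpd_upper`, `significant`.
#' @export
growth_effects_table <- function(fit, prob = 0.95) {
  rows <- list()
  for (p in PAR3) {
    g1 <- pooled_draws(fit, paste0("gamma1_", p))
    h <- hpd_significance(g1, prob)
    rows[[p]] <- data.frame(effect = paste0("gamma1_", p), species = "all",
                            mean = mean(g1), hpd_lower = h$lower,
                            hpd_upper = h$upper, significant = h$significant,
                            stringsAsFactors = FALSE)
    for (sp in fit$data$species) {
      tot <- g1 + pooled_draws(fit, sprintf("tau_%s[%s]", p, sp))
      h <- hpd_significance(tot, prob)
      rows[[paste(p, sp)]] <- data.frame(
        effect = paste0("gamma1_", p), species = sp, mean = mean(tot),
        hpd_lower = h$lower, hpd_upper = h$upper, significant = h$significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @rdname growth_effects_table
#' @export
longevity_effects_table <- function(fit, prob = 0.95) {
  slope <- pooled_draws(fit, "temp_slope")
  rows <- list()
  h <- hpd_significance(slope, prob)
  rows[["all"]] <- data.frame(effect = "gamma1_amax", species = "all",
                              mean = mean(slope), hpd_lower = h$lower,
                              hpd_upper = h$upper, significant = h$significant,
                              stringsAsFactors = FALSE)
  for (sp in fit$species) {
    tot <- if (sp == fit$species[1]) slope else
      slope + pooled_draws(fit, sprintf("temp_interaction[%s]", sp))
    h <- hpd_significance(tot, prob)
    rows[[sp]] <- data.frame(effect = "gamma1_amax", species = sp,
                             mean = mean(tot), hpd_lower = h$lower,
                             hpd_upper = h$upper, significant = h$significant,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every
#' intermediate as CSV under `outdir` together with a JSON run manifest
#' (config hash, per-stage seeds, row counts, artifact hashes).  Re-running
#' with the same configuration reproduces every artifact byte-identically.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param outdir output directory (created if missing).
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) list with the in-memory stage results and
#'   `artifacts`, the named vector of written file paths.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- c()
  counts <- list()
  res <- list(config = config)
  stages <- config$stages

  if ("simulate" %in% stages) {
    say("stage simulate: %d lakes x %d species x %d years",
        config$sim$n_lakes, config$sim$n_species, config$sim$years_per_lake)
    res$sim <- simulate_dataset(config$sim)
    artifacts["daily_temps"] <- write_stage_csv(res$sim$temps, outdir,
                                                "daily_temps.csv")
    artifacts["fish_records"] <- write_stage_csv(res$sim$fish, outdir,
                                                 "fish_records.csv")
    artifacts["truth_params"] <- write_stage_csv(res$sim$truth$params, outdir,
                                                 "truth_params.csv")
    counts$fish_simulated <- nrow(res$sim$fish)
  }

  if ("thermal" %in% stages) {
    thermal <- res$sim$thermal
    say("stage thermal: %d lake-years, GDD5 %.0f-%.0f degree-days",
        nrow(thermal), min(thermal$gdd5), max(thermal$gdd5))
    artifacts["thermal"] <- write_stage_csv(thermal, outdir, "thermal.csv")
    counts$lake_years <- nrow(thermal)
  }

  if ("alk" %in% stages) {
    fish <- res$sim$fish
    alk <- expand_with_alk(fish, bin_width = config$sim$bin_width,
                           seed = derive_seed(config$seed, 31),
                           policy = config$alk_policy)
    res$alk <- alk
    n_in <- nrow(fish)
    n_pass_surveys <- sum(alk$filter$passed)
    n_dropped <- if (is.null(alk$dropped)) 0 else nrow(alk$dropped)
    say("stage alk: %d/%d surveys pass the 5x5 filter; %d fish aged, %d dropped out-of-key",
        n_pass_surveys, nrow(alk$filter), nrow(alk$records), n_dropped)
    artifacts["survey_filter"] <- write_stage_csv(alk$filter, outdir,
                                                  "survey_filter.csv")
    keys_long <- do.call(rbind, lapply(names(alk$keys), function(id) {
      parts <- strsplit(id, ":")[[1]]
      cbind(species = parts[1], lake_id = parts[2], year = parts[3],
            alk_to_df(alk$keys[[id]]))
    }))
    artifacts["alk_keys"] <- write_stage_csv(keys_long, outdir, "alk_keys.csv")
    artifacts["fish_aged"] <- write_stage_csv(alk$records, outdir,
                                              "fish_aged.csv")
    counts$fish_in <- n_in
    counts$fish_aged <- nrow(alk$records)
    counts$fish_dropped_out_of_key <- n_dropped
    counts$surveys_passing_filter <- n_pass_surveys
  }

  if ("fit_growth" %in% stages) {
    say("stage fit_growth: %d records, %d chains x %d iterations",
        nrow(res$alk$records), config$mcmc_growth$n_chains,
        config$mcmc_growth$n_iter)
    res$growth_fit <- fit_growth_model(res$alk$records, res$sim$thermal,
                                       mcmc = config$mcmc_growth,
                                       seed = derive_seed(config$seed, 41))
    artifacts["growth_draws"] <- write_stage_csv(
      draws_to_long(res$growth_fit$draws), outdir, "growth_draws.csv")
    artifacts["growth_summary"] <- write_stage_csv(
      posterior_summary(res$growth_fit), outdir, "growth_summary.csv")
    artifacts["growth_convergence"] <- write_stage_csv(
      convergence_report(res$growth_fit), outdir, "growth_convergence.csv")
  }

  if ("fit_longevity" %in% stages) {
    lrec <- longevity_records(res$alk$records, res$sim$thermal)
    say("stage fit_longevity: %d population records", nrow(lrec))
    res$longevity_fit <- fit_longevity_model(
      lrec, mcmc = config$mcmc_longevity, seed = derive_seed(config$seed, 42))
    artifacts["longevity_records"] <- write_stage_csv(lrec, outdir,
                                                      "longevity_records.csv")
    artifacts["longevity_draws"] <- write_stage_csv(
      draws_to_long(res$longevity_fit$draws), outdir, "longevity_draws.csv")
    artifacts["longevity_summary"] <- write_stage_csv(
      posterior_summary(res$longevity_fit), outdir, "longevity_summary.csv")
    artifacts["longevity_convergence"] <- write_stage_csv(
      convergence_report(res$longevity_fit), outdir,
      "longevity_convergence.csv")
    counts$longevity_records <- nrow(lrec)
  }

  if ("derive" %in% stages) {
    say("stage derive: regimes at covariate quantiles %s",
        paste(config$regimes, collapse = ", "))
    res$derived <- derive_size_curves(res$growth_fit, res$longevity_fit,
                                      regimes = config$regimes,
                                      seed = derive_seed(config$seed, 43))
    artifacts["derived_curves"] <- write_stage_csv(res$derived$curves, outdir,
                                                   "derived_curves.csv")
    artifacts["derived_summary"] <- write_stage_csv(res$derived$summary,
                                                    outdir,
                                                    "derived_summary.csv")
  }

  if ("report" %in% stages) {
    effects <- rbind(growth_effects_table(res$growth_fit),
                     longevity_effects_table(res$longevity_fit))
    res$effects <- effects
    artifacts["effects"] <- write_stage_csv(effects, outdir, "effects.csv")
    say("stage report: %d effects, %d significant", nrow(effects),
        sum(effects$significant))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tsrgrowth")),
    seed = config$seed, sim_seed = config$sim$seed,
    config_hash = object_hash(unclass(config)[c("regimes", "alk_policy",
                                                "stages", "seed")]),
    sim_hash = object_hash(unclass(config$sim)),
    stages = stages, counts = counts,
    artifact_hashes = as.list(stats::setNames(
      unname(tools::md5sum(unname(artifacts))), basename(artifacts))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts["manifest"] <- manifest_path
  res$artifacts <- artifacts
  invisible(res)
}
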