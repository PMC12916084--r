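#!/usr/bin/env Rscript
# Stage 2: thermal covariates.  Annual growing degree days above 5 C per
# lake-year, the trailing 10-year mean for each survey year, and its
# z-scored version used by both models.

suppressMessages(library(tsrgrowth))

daily <- read.csv("results/data/daily_temps.csv")
gdd <- gdd5_table(daily)
survey_years <- sort(unique(read.csv("results/data/fish_records.csv")$year))

thermal <- thermal_covariates(gdd, survey_years, window = 10)
scaling <- scale_covariate(thermal$t_window_mean)
thermal$t_scaled <- scaling$scaled

write.csv(gdd, "results/data/gdd5_by_lake_year.csv", row.names = FALSE)
write.csv(thermal, "results/data/thermal.csv", row.names = FALSE)
jsonlite::write_json(list(center = scaling$center, scale = scaling$scale),
                     "results/data/thermal_scaling.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("annual GDD5 spans %.0f-%.0f degree-days across %d lakes\n",
            min(gdd$gdd5), max(gdd$gdd5), length(unique(gdd$lake_id))))
cat(sprintf("10-year mean covariate: %.0f +/- %.0f degree-days (z-scored for modelling)\n",
            scaling$center, scaling$scale))
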