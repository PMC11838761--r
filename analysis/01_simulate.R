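#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study dataset.
#
# Generates a 2-region / 4-country / 16-province geography, monthly
# covariates, ground-truth OD flows over 2018-2019, applies the privacy
# mechanism (Laplace noise, scale 1/0.66; suppression below 100), and
# removes one region's worth of country blocks to emulate missing coverage.
# Everything downstream regenerates this dataset deterministically from the
# same seed; this stage writes the on-disk record.

suppressPackageStartupMessages(library(afrimob))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- run_config(seed = seed,
                  simulate = list(missing_fractions = list(R2 = 0.5)))
study <- simulate_study(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_flows_csv(study$flows, "results/data/flows_private.csv")
write_flows_csv(study$flows_raw, "results/data/flows_raw.csv")
write_geography_json(study$geo, "results/data/geography.geojson")
utils::write.csv(as.data.frame(study$covs), "results/data/covariates.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(beta = as.list(study$truth$beta), hyper = study$truth$hyper,
       removed_countries = study$removed_countries, seed = seed),
  "results/data/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated %d raw flow cells; %d retained after privacy/missingness (%d suppressed)\n",
  nrow(study$flows_raw), nrow(study$flows),
  nrow(study$flows_raw) - nrow(study$flows)))
cat("countries removed for missing coverage:",
    paste(study$removed_countries, collapse = ", "), "\n")
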