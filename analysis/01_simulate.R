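#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic study cohorts.
#
# Two modalities mirror the two data sources the analysis contrasts: a
# pediatric health system's EMR (encounters, medications, procedures and
# clinical notes) and an administrative claims database (coded encounters and
# coverage periods, no note text). The claims cohort is drawn at a slightly
# higher latent recurrence prevalence, matching the pattern that nationwide
# claims cohorts skew a little more severe than a single tertiary center.

suppressMessages(library(szrecur))
seed <- 2026L

dir.create("results", showWarnings = FALSE)
emr <- simulate_cohort(sim_config(n_patients = 2000, seed = seed))
claims <- simulate_cohort(sim_config(n_patients = 2000, seed = seed + 1L,
                                     recurrence_prevalence = 0.63,
                                     modality = "claims"))

write_dataset(emr, "results/data_emr")
write_dataset(claims, "results/data_claims")

cat(sprintf("EMR cohort:    %d patients, %d encounters, %d notes\n",
            nrow(emr$patients), nrow(emr$encounters), nrow(emr$notes)))
cat(sprintf("claims cohort: %d patients, %d encounters, %d coverage periods\n",
            nrow(claims$patients), nrow(claims$encounters),
            nrow(claims$coverage)))
cat("wrote results/data_emr and results/data_claims\n")
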