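#!/usr/bin/env Rscript
# Stage 2: apply the temporal inclusion criteria and the composite label.
#
# Inclusion requires (1) contact or coverage at least a year before the index
# seizure-like event (a week, for other purposes, when the index falls in
# infancy), (2) an index encounter before age 21, and (3) follow-up at least
# two years later. Included patients are then labelled with the seven
# expert-derived recurrence measures over the two-year outcome window.

suppressMessages(library(szrecur))
reg <- code_registry()

for (mod in c("emr", "claims")) {
  co <- read_dataset(sprintf("results/data_%s", mod))
  ct <- build_cohort(co, reg)
  lab <- label_cohort(co, ct, reg)
  readr::write_csv(ct, sprintf("results/cohort_%s.csv", mod), na = "")
  readr::write_csv(lab, sprintf("results/labels_%s.csv", mod), na = "")
  cat(sprintf("%s: %d/%d included; exclusions: %s\n", mod, sum(ct$included),
              nrow(ct),
              paste(names(table(ct$exclusion_reason)),
                    table(ct$exclusion_reason), collapse = ", ")))
  cat(sprintf("%s: composite prevalence %.3f; per-criterion rates:\n", mod,
              mean(lab$composite)))
  print(round(colMeans(lab[-1]), 3))
}
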