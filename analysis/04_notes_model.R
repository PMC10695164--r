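#!/usr/bin/env Rscript
# Stage 4: the clinical-note pipeline on the EMR cohort.
#
# Notes dated up to a week after the index event are scored by the default
# term-frequency scorer (any scorer honouring fit/score can be plugged in;
# this is where a fine-tuned long-context transformer would sit). Long notes
# are chunked into overlapping 4096-token windows with 512-token overlap;
# chunk, note and patient scores all reduce by the largest-margin-from-0.5
# rule.

suppressMessages(library(szrecur))
reg <- code_registry()
seed <- 2026L

co <- read_dataset("results/data_emr")
ct <- readr::read_csv("results/cohort_emr.csv", show_col_types = FALSE)
lab <- readr::read_csv("results/labels_emr.csv", show_col_types = FALSE)

y <- stats::setNames(lab$composite, lab$patient_id)
folds <- make_folds(lab$patient_id, 5, seed, labels = y)
notes <- filter_notes_for_prediction(
  co$notes[co$notes$patient_id %in% lab$patient_id, ], ct)

res <- evaluate_notes_pipeline(notes, y, folds, n_boot = 1000, seed = seed)
readr::write_csv(res$pooled, "results/notes_predictions.csv")
readr::write_csv(res$metrics, "results/notes_metrics.csv")
cat(sprintf("note pipeline: F1 %.3f [%.3f, %.3f]  AUROC %.3f [%.3f, %.3f]  (%d patients without eligible notes)\n",
            res$metrics$f1, res$metrics$f1_lower, res$metrics$f1_upper,
            res$metrics$auroc, res$metrics$auroc_lower,
            res$metrics$auroc_upper, res$n_excluded))
cat("wrote results/notes_metrics.csv\n")
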