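#!/usr/bin/env Rscript
# Stage 5: note-type ablation on the EMR cohort.
#
# Retrains the note pipeline restricted to each note type (neurology,
# communication, EEG / brain MRI / head CT reports, discharge summaries) and
# to all types together, localising where prognostic language lives. The
# generator plants the strongest label-conditional vocabulary shift in
# neurology notes and the weakest in head CT reports, so a working harness
# should rank neurology first among single types.

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

tab <- ablate_by_note_type(notes, y, folds, n_boot = 1000, seed = seed)
readr::write_csv(tab, "results/ablation.csv")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("%-18s n=%4d (excl %4d)  AUROC %.3f [%.3f, %.3f]\n",
              tab$group[i], tab$n_patients[i], tab$n_excluded[i],
              tab$auroc[i], tab$auroc_lower[i], tab$auroc_upper[i]))
}
cat("wrote results/ablation.csv\n")
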