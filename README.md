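# szrecur

Tools for studying prediction of **seizure recurrence after a first
seizure-like event in children** from routinely collected clinical data —
without access to any protected health data. The package simulates
longitudinal pediatric cohorts in two modalities (health-system EMR with
clinical notes; administrative claims with coverage periods), applies
temporal inclusion criteria around the index seizure-like encounter, derives
a composite recurrence label from seven code-based criteria, and compares
structured-data classifiers with a clinical-note scoring path under a common
cross-validated, bootstrap-CI evaluation protocol.

## The core definitions

**Cohort.** The index event is the earliest encounter with a broad
seizure-like code (ICD-9 `345.*`/`780.3*`, ICD-10 `G40.*`/`R56.*`) before
age 21. Patients need contact (EMR) or coverage (claims) ≥ 1 year before the
index — for infants, a non-seizure encounter ≥ 1 week before — and follow-up
≥ 2 years after.

**Outcome.** A patient is labelled *recurrent* if any of seven criteria fire
in the window (index + 7 d, index + 730 d]: an antiseizure medication on a
day with an epilepsy-specific diagnosis (ICD-9 `345.*` or ICD-10 `G40.*`,
convulsions excluded); status epilepticus in primary/admitting position (or
with an epilepsy-specific primary/admitting code); seizure-related inpatient
admission; ≥ 2 distinct seizure-related encounter days; ≥ 4 distinct
all-cause encounter days; seizure-related diagnostic testing; or an
epilepsy-directed procedure confirmed by an epilepsy diagnosis ≥ 1 week
later.

**Models.** Structured features are one-year pre-index code counts,
normalised as `min(log(count + 1), 1)`, selected either by ≥ 1% prevalence
(for gradient-boosted trees, 500 estimators, L1 = L2 = 0.1) or by top-500
chi-square ranking (for class-balanced elastic-net logistic regression).
The note path chunks long notes into overlapping 4096-token windows (512
overlap), scores them with a pluggable scorer (default: a term-frequency
log-odds model; a fine-tuned long-context transformer would plug into the
same interface), and aggregates by the prediction with the **largest margin
from the 0.5 threshold** — chunk → note → patient. Evaluation is
patient-level 5-fold cross-validation with F1 and AUROC (Mann–Whitney, tie
credit 0.5) and 95% percentile bootstrap CIs over 1000 patient resamples.

## Worked example

```r
library(szrecur)
reg <- code_registry()

co  <- simulate_cohort(sim_config(n_patients = 600, seed = 11))
ct  <- build_cohort(co, reg)
lab <- label_cohort(co, ct, reg)
cat(sum(ct$included), "included of", nrow(ct), "\n")
cat("composite prevalence:", round(mean(lab$composite), 3), "\n")

ex <- run_experiment(co, reg, seed = 5, n_boot = 1000)
print(ex$results[, c("pipeline", "f1", "auroc", "auroc_lower", "auroc_upper")])
```

```
494 included of 600 
composite prevalence: 0.65 
# A tibble: 3 × 5
  pipeline                  f1 auroc auroc_lower auroc_upper
  <chr>                  <dbl> <dbl>       <dbl>       <dbl>
1 elasticnet_logistic    0.597 0.636       0.585       0.687
2 gradient_boosted_trees 0.699 0.573       0.524       0.623
3 notes_tf               0.898 0.913       0.885       0.938
```

Reading: of 600 simulated patients, 494 pass the three inclusion criteria,
and 65% of those meet at least one recurrence criterion. Under the default
generator conditions the structured models sit around 0.6 AUROC while
the note pipeline reaches ~0.9 — the text of clinical notes carries
more prognostic signal than the structured record, which is the central
comparison the pipeline is built to expose.

The full analysis (2000-patient EMR and claims cohorts, structured and note
models, note-type ablation) runs as numbered scripts:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cohort_label.R
Rscript analysis/03_structured_models.R
Rscript analysis/04_notes_model.R
Rscript analysis/05_ablation.R
```

Each stage prints what it found and writes its tables under `results/`.

## Package layout

- `R/` — simulator, registry, cohort/outcome logic, features, note
  pipeline, evaluation (every function exported and unit-tested)
- `analysis/` — the numbered analysis drivers
- `tests/testthat/` — unit, property and end-to-end acceptance tests,
  including independently coded brute-force oracles for labelling, AUROC
  and aggregation
- `vignettes/seizure-recurrence-pipeline.Rmd` — methods and design notes
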