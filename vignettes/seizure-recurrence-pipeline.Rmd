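---
title: "Predicting seizure recurrence from routine clinical data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting seizure recurrence from routine clinical data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A first seizure-like event in a child may be an isolated episode, a seizure
mimic, or the beginning of epilepsy. Routine clinical data — coded
encounters, medications, procedures, and the free text physicians write —
carry prognostic information about which of these it will be. `szrecur`
implements an end-to-end pipeline for studying that question at desk scale:
it simulates longitudinal pediatric cohorts in two modalities (a health
system's EMR with clinical notes, and administrative claims with coverage
periods), applies temporal inclusion criteria around the index seizure-like
encounter, derives a composite recurrence label from seven code-based
criteria, and compares structured-data classifiers against a pluggable
clinical-note scoring path under a common evaluation protocol.

Everything is driven from code; no protected health data is used or needed.
The package is organised as an analysis: the numbered scripts under
`analysis/` run the stages in order and write their tables under `results/`,
while all computation lives in exported package functions that the test
suite exercises directly.

## Cohort definition

The *index event* is the earliest encounter carrying a code from a broad
seizure-like set — epilepsy (ICD-9 `345.*`, ICD-10 `G40.*`), convulsions and
febrile seizures (`780.3*`, `R56.*`) — occurring before age 21. The broad
set is deliberately wider than the outcome codes: at first presentation the
diagnosis is often recorded as an unspecified convulsion rather than
epilepsy. Three criteria then gate inclusion:

1. **Prior contact.** An encounter for any reason (EMR) or insurance
   coverage (claims) at least one year before the index event, to enrich
   for genuinely first-time events. When the index falls before age one
   year, a full year of history cannot exist; such infants instead need an
   encounter *for other purposes* (carrying no seizure-like code) at least
   one week before the index, which filters referrals after earlier
   seizures elsewhere.
2. **Index encounter** before age 21.
3. **Follow-up.** An encounter or coverage at least two years after the
   index, so the outcome window is observable.

All window arithmetic uses fixed day counts (1 year = 365 days, 2 years =
730, 1 week = 7); dates are handled as calendar dates internally and
ISO-8601 in every file format. Code matching is prefix-based on
dot-stripped, upper-cased codes with an explicit dialect tag per code
(`ICD9:345.10`, `ICD10:G40.9`, `CPT:95819`), so the `345.**` / `G40.*`
wildcard conventions translate directly and ICD-9 prefixes can never match
ICD-10 codes.

## The composite recurrence label

Neither EMRs nor claims record every seizure, so recurrence is proxied by a
composite of seven expert-style criteria evaluated in the window from one
week to two years after the index event (the one-week blanking interval
applies to every criterion — the earliest a patient can become recurrent is
seven days post-index):

* **Antiseizure medication (ASM).** A lexicon drug recorded on the same
  calendar day as an encounter carrying an epilepsy-specific diagnosis
  (ICD-9 `345.*` / ICD-10 `G40.*`, convulsion codes excluded). Same-day
  co-occurrence rather than same-encounter linkage is used because claims
  data lack reliable encounter ids; the epilepsy-diagnosis requirement
  filters ASMs prescribed for other indications, gabapentin for neuropathic
  pain being the canonical example. An optional switch restricts the
  criterion to adjunctive-use ASMs.
* **Status epilepticus.** An encounter with a status epilepticus code where
  either that code sits in the primary or admitting position, or the
  primary/admitting code is epilepsy-specific — the positional rule guards
  against incidental mentions.
* **Seizure-related inpatient admissions** (≥ 1 inpatient encounter with a
  seizure-related code, configurable).
* **Seizure-related health-care utilisation**: ≥ 2 *distinct days* with
  seizure-related codes. Two encounters on one day count once.
* **All health-care utilisation**: ≥ 4 distinct encounter days of any kind.
  Whether this is a recurrence criterion in its own right or a descriptive
  measure is genuinely ambiguous; it is implemented as an enabled-by-default
  criterion with an `enable_all_utilisation` switch.
* **Seizure-related diagnostic testing**: ≥ 1 EEG/MRI/CT order co-occurring
  with a seizure-related diagnosis.
* **Epilepsy-directed procedures**: a procedure from the epilepsy procedure
  set in an encounter whose primary/admitting diagnosis is
  epilepsy-specific, *plus* another epilepsy-specific diagnosis at least one
  week after the procedure, so that the procedure itself is not mistaken
  for recurrence.

The composite is the OR of the seven. "Seizure-related" for the
utilisation-style criteria is the union of epilepsy-specific and convulsion
codes — broader than the strict outcome set, mirroring how utilisation is
tracked separately from outcome-defining codes. The utilisation and count
thresholds are exposed in `outcome_config()` because their exact reference
values are site conventions rather than fixed constants; the defaults (2
seizure-related days, 4 all-cause days, 1 admission, 1 test) are the
package's own choices.

Every criterion is monotone in the event set — adding a post-index event can
only switch criteria on — and this, along with blanking-boundary behaviour
and agreement with an independently coded brute-force evaluator, is asserted
by the test suite.

## What the generator emulates — and what it does not

`simulate_cohort()` draws each patient's latent recurrence status at the
configured prevalence (default 0.57; the bundled claims scenario uses 0.63),
then builds a timeline around it:

* a pre-index history of routine pediatric care, with configurable fractions
  of patients violating each inclusion criterion, and an infant subgroup
  exercising the one-week special case;
* post-index epilepsy-coded days, status epilepticus, ASM starts (always on
  an epilepsy-coded day), diagnostic testing and epilepsy procedures, each
  at class-conditional rates chosen so that the composite label recovers the
  latent status for most patients and the composite prevalence lands in the
  0.57–0.65 range;
* a *structured signal* channel: non-seizure "risk marker" codes
  (developmental delay, coordination disorder, encephalopathy, prematurity)
  whose pre-index rates scale with `structured_signal_strength`, plus a
  label-conditional developmental work-up visit carrying several distinct
  markers. Marker visits cluster in the year before the index event so they
  fall inside the one-year feature lookback. Seizure-like codes cannot carry
  the pre-index signal by construction: any such code would itself become
  the index event;
* a *text signal* channel: note tokens drawn from a background distribution
  mixed with prognosis vocabulary whose label-conditional odds scale with
  `text_signal_strength`, strongest in neurology notes and weakest in head
  CT reports — a planted gradient the ablation harness should recover;
* notes of the six study types, a configurable fraction longer than the
  4096-token chunking limit, occasional medication sections with negated
  mentions, and ASM prescriptions that appear *only* in a discharge note
  (not in structured data) for a fraction of treated EMR patients;
* in claims mode, coverage periods instead of notes.

At signal strength 0 both channels are exactly label-independent, which is
what the null-calibration checks rely on. At the default strength of 1 the
structured models land in the mid-0.6s AUROC and the note pipeline in the
high-0.8s, reproducing the qualitative ordering that motivates the analysis:
physicians' notes encode more prognostic signal than the structured record.

The generator does *not* model disease progression, laboratory values,
demographic structure beyond age and sex, inter-site coding variation, or
realistic clinical language — notes are bags of tokens with planted
statistics. Passing tests therefore demonstrate that the pipeline's logic is
correct and that its statistical machinery recovers known signal under
controlled conditions; they say nothing about performance on real clinical
data.

## Features and classifiers

Structured features are counts of each observed code in the year before the
index event, up to and including the index day, namespaced by record type
(`dx:`, `rx:`, `px:`). Counts are log-normalised as `min(log(count + 1), 1)`
with the natural logarithm: 0 maps to 0, a single occurrence to ln 2 ≈
0.693, and two or more occurrences clip at 1, so the first observation of a
code carries the most information and billing-driven repeat coding cannot
dominate. An injectable code-to-group table supports phenotype grouping
(e.g. PheCodes); the default identity mapping keeps the package
self-contained.

Two feature-selection schemes are fitted on training folds only: keeping
features present in at least 1% of training rows (used with the boosted
trees) and keeping the top 500 features by the one-degree-of-freedom
chi-square statistic on presence/absence versus the label (used with the
logistic model; no continuity correction, ties broken by vocabulary order
for determinism).

The two classifier families carry the settings that won the original
pipeline comparisons: elastic-net logistic regression with class-balanced
weights (penalty chosen by internal cross-validation with deterministic fold
ids, the standard glmnet practice), and gradient-boosted trees with 500
estimators and L1/L2 regularisation terms of 0.1, other parameters at their
defaults, single-threaded for reproducibility. The >600k-combination
hyperparameter sweep behind those choices is compute, not method, and is not
reproduced; `model_spec()` exposes the parameters for anyone who wants to
sweep.

## The note pipeline

Notes are whitespace-tokenised; the subword tokenizer of a specific language
model is out of scope, since what matters here is the chunk arithmetic and
the aggregation logic. Notes longer than 4096 tokens are split into windows
whose starts advance by a stride of 4096 − 512 tokens, so consecutive
windows share exactly 512 tokens; the final window is truncated at the note
end (its length always exceeds the overlap, so the exact-overlap property
holds throughout, and concatenating windows with overlaps removed
reconstructs the note). A design note: an alternative "anchor the last
window to the right edge" rule was considered and rejected because it breaks
the uniform stride-offset property that makes chunk provenance trivial to
audit.

Scoring is pluggable: anything with `fit(notes, labels)` and
`score(tokens) → [0, 1]` works, which is where a fine-tuned long-context
transformer would plug in. The default `scorer_tf()` is a term-frequency
model: per-token log-odds with Laplace smoothing, averaged over the chunk,
scaled and passed through the logistic function. Three choices matter for
calibration. Tokens seen fewer than 5 times in training are ignored (rare
tokens carry mostly spurious label association). The vocabulary is
significance-screened: only tokens whose note-level presence associates
with the label beyond a chi-square cut (p = 0.001 by default) enter the
model, so on label-independent text the scorer degenerates to a constant
0.5 instead of amplifying dataset-level chance token correlations into
spurious held-out discrimination. And the score contains no class-prior
term, so the score scale is centred at 0.5 in every cross-validation fold
regardless of training prevalence — with a prior term, pooling folds
induces a small systematic anticorrelation between scores and held-out
labels, visible as below-0.5 AUROC under a null.

Chunk scores reduce to a note score, and note scores to the patient class,
by one consistent rule: the prediction with the largest margin from the 0.5
threshold wins. A score exactly at the threshold, or tied margins on
opposite sides, resolve to the positive class — deterministic and clinically
conservative, favouring a flag for recurrence risk. Margin ties are detected
with a small numeric tolerance so floating-point rounding cannot split an
exact tie.

To keep outcome-window documentation from leaking the label into the
predictors, only notes dated up to one week after the index event feed the
scorer by default (`filter_notes_for_prediction()`, configurable).

Rules-based medication extraction (`extract_medications()`) finds medication
sections by header keywords (history, changes, orders, discharge lists),
matches lexicon entries including abbreviations such as `LEV` for
levetiracetam, and flags mentions within a short window after negation cues
("no", "denies", "not taking", "discontinued"); negated mentions are
excluded downstream.

## Evaluation protocol

Patients are dealt into five folds (each fold the held-out 20% once);
assignments are patient-level so a patient's notes and features never
straddle the train/test boundary, and the test suite asserts the fit/score
id sets are disjoint in every fold. When labels are available the folds are
stratified by class (each class shuffled and dealt round-robin), the
standard practice for classification cross-validation: with unstratified
folds, fold-to-fold prevalence imbalance shifts each fold's score scale
slightly and pooling the held-out predictions then biases AUROC a little
below 0.5 even under a pure null. F1 and AUROC are implemented from first
principles — F1 as the harmonic mean of precision and recall at the 0.5
threshold, AUROC as the Mann-Whitney statistic with half credit for ties —
and are cross-checked against pairwise enumeration and `pROC` in tests.
Confidence intervals are percentile bootstrap over 1000 patient-level
resamples (single-class resamples are redrawn and counted). Pooled held-out
predictions are the default basis for the intervals; per-fold metrics are
also reported since the alternative reading (intervals across folds) is
defensible.

The note-type ablation retrains the pipeline per note type plus all types
together, excludes (and counts) patients without notes of a type, and
reports the same metrics.

## Problem sizes and numerical choices

The bundled analyses and acceptance checks use cohorts of 2000 patients,
five folds and 1000 bootstrap resamples — large enough for stable AUROC
comparisons on a single CPU while keeping any single stage under a few
minutes. Null-calibration checks repeat over ten generator seeds. Unit
tests use cohorts of 50–600. Determinism is end-to-end: a fixed seed yields
byte-identical datasets, fold assignments, selection masks and reports
(boosting runs single-threaded; all stochastic steps draw from explicit
seeds).

Degenerate inputs are handled explicitly: empty cohorts round-trip as
header-only files; single-class training labels are a documented error;
single-class bootstrap resamples are redrawn; degenerate chi-square tables
score zero; a test fold whose labels are single-class yields NA per-fold
metrics without disturbing pooled ones.

## Known limitations

* The composite label is a proxy; its thresholds are conventions, and its
  imperfect agreement with the latent simulation truth bounds the AUROC any
  model can reach against it.
* The default note scorer is a linear term-frequency model standing at the
  interface where a transformer would sit; absolute text-pipeline numbers
  on synthetic notes say nothing about language-model performance on real
  notes.
* Claims-mode coverage is a single interval per patient in the generator,
  though the inclusion logic handles arbitrary interval sets.
* The ICD-to-PheCode mapping is injectable but not bundled; the identity
  mapping is used throughout the analyses.
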