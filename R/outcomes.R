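#' Configuration of the composite recurrence label
#'
#' Controls the outcome window and per-criterion thresholds. The outcome
#' window is `(index + blanking_days, index + window_days]`: a 7-day blanking
#' interval after the index event applies to every criterion, so the nearest
#' a patient can be considered recurrent is one week after the index event.
#'
#' @param window_days Length of the post-index outcome window (default 730 =
#'   two years).
#' @param blanking_days Post-index blanking interval (default 7).
#' @param thresholds Named list: `seizure_utilisation_min_distinct_days`
#'   (default 2), `all_utilisation_min_distinct_days` (default 4),
#'   `inpatient_min_admissions` (default 1), `diagnostics_min_count`
#'   (default 1). All must be at least 1.
#' @param require_adjunctive_only If `TRUE`, only ASMs flagged for adjunctive
#'   use count toward the medication criterion.
#' @param enable_all_utilisation Treat all-cause utilisation as a recurrence
#'   criterion (default `TRUE`); set `FALSE` to use it descriptively only.
#' @return An object of class `outcome_config`.
#' @export
outcome_config <- function(window_days = 730L, blanking_days = 7L,
                           thresholds = list(),
                           require_adjunctive_only = FALSE,
                           enable_all_utilisation = TRUE) {
  th <- list(seizure_utilisation_min_distinct_days = 2L,
             all_utilisation_min_distinct_days = 4L,
             inpatient_min_admissions = 1L,
             diagnostics_min_count = 1L)
  for (nm in names(thresholds)) {
    if (!nm %in% names(th)) stop("outcome_config: unknown threshold '", nm, "'")
    th[[nm]] <- thresholds[[nm]]
  }
  if (any(unlist(th) < 1)) stop("outcome_config: thresholds must be >= 1")
  if (blanking_days < 0 || window_days <= blanking_days) {
    stop("outcome_config: need window_days > blanking_days >= 0")
  }
  structure(list(window_days = as.integer(window_days),
                 blanking_days = as.integer(blanking_days),
                 thresholds = th,
                 require_adjunctive_only = require_adjunctive_only,
                 enable_all_utilisation = enable_all_utilisation),
            class = "outcome_config")
}

#' Is a code epilepsy-specific?
#'
#' True for ICD-9 `345.*` and ICD-10 `G40.*`; convulsion codes (`780.*`,
#' `R56.*`) are not epilepsy-specific.
#'
#' @param codes Character vector of tagged codes.
#' @param registry A [code_registry()].
#' @return Logical vector.
#' @export
is_epilepsy_specific <- function(codes, registry) {
  code_in_set(codes, registry, "epilepsy_specific") &
    !code_in_set(codes, registry, "convulsion_excluded")
}

# window helper: days strictly after blanking, up to and including window end
in_outcome_window <- function(dates, index_date, config) {
  d <- as.integer(dates - index_date)
  d > config$blanking_days & d <= config$window_days
}

# per-encounter helpers -----------------------------------------------------

enc_primary_admitting <- function(enc_row) {
  codes <- enc_row$codes[[1]]
  pa <- codes[[enc_row$primary_pos]]
  if (!is.na(enc_row$admitting_pos)) pa <- c(pa, codes[[enc_row$admitting_pos]])
  pa
}

enc_has_set <- function(encounters, registry, set_name) {
  vapply(encounters$codes, function(cc) any(code_in_set(cc, registry, set_name)),
         logical(1))
}

#' Status epilepticus criterion
#'
#' True when an encounter in the outcome window carries a status epilepticus
#' code and either that code sits in the primary or admitting position, or
#' the primary/admitting code is epilepsy-specific. The positional rule
#' filters miscoded incidental mentions.
#'
#' @param patient A `patient_record`.
#' @param index Index event from [find_index_event()].
#' @param registry A [code_registry()].
#' @param config An [outcome_config()].
#' @return Logical scalar.
#' @export
criterion_status_epilepticus <- function(patient, index, registry, config) {
  enc <- patient$encounters
  enc <- enc[in_outcome_window(enc$date, index$index_date, config), , drop = FALSE]
  if (nrow(enc) == 0) return(FALSE)
  for (i in seq_len(nrow(enc))) {
    codes <- enc$codes[[i]]
    se <- code_in_set(codes, registry, "status_epilepticus")
    if (!any(se)) next
    pa_idx <- c(enc$primary_pos[[i]],
                if (!is.na(enc$admitting_pos[[i]])) enc$admitting_pos[[i]])
    if (any(se[pa_idx])) return(TRUE)
    if (any(is_epilepsy_specific(codes[pa_idx], registry))) return(TRUE)
  }
  FALSE
}

#' Epilepsy-procedure criterion
#'
#' True when the outcome window contains a procedure from the epilepsy
#' procedure set performed in an encounter whose primary or admitting
#' diagnosis is epilepsy-specific, and an epilepsy-specific diagnosis is
#' recorded at least one week after the procedure (guarding against the
#' procedure itself being misread as recurrence).
#'
#' @inheritParams criterion_status_epilepticus
#' @return Logical scalar.
#' @export
criterion_procedure <- function(patient, index, registry, config) {
  prc <- patient$procedures
  if (nrow(prc) == 0) return(FALSE)
  prc <- prc[in_outcome_window(prc$date, index$index_date, config), , drop = FALSE]
  prc <- prc[code_in_set(prc$code, registry, "epilepsy_procedures"), , drop = FALSE]
  if (nrow(prc) == 0) return(FALSE)
  enc <- patient$encounters
  # dates of any epilepsy-specific diagnosis, any position
  ep_any <- enc_has_set(enc, registry, "epilepsy_specific") &
    !enc_has_set(enc, registry, "convulsion_excluded")
  ep_dates <- enc$date[ep_any]
  for (i in seq_len(nrow(prc))) {
    j <- match(prc$encounter_id[[i]], enc$encounter_id)
    host <- if (!is.na(j)) enc[j, , drop = FALSE] else
      enc[enc$date == prc$date[[i]], , drop = FALSE]
    ok <- FALSE
    for (k in seq_len(nrow(host))) {
      if (any(is_epilepsy_specific(enc_primary_admitting(host[k, , drop = FALSE]),
                                   registry))) { ok <- TRUE; break }
    }
    if (!ok) next
    if (any(as.integer(ep_dates - prc$date[[i]]) >= DAYS_WEEK)) return(TRUE)
  }
  FALSE
}

#' Antiseizure-medication criterion
#'
#' True when a medication from the ASM lexicon is recorded in the outcome
#' window on the same calendar day as an encounter carrying an
#' epilepsy-specific diagnosis. The co-occurrence requirement filters ASMs
#' prescribed for other indications (e.g. gabapentin for neuropathic pain).
#' Medication names absent from the lexicon are ignored with a warning.
#'
#' @inheritParams criterion_status_epilepticus
#' @return Logical scalar.
#' @export
criterion_asm <- function(patient, index, registry, config) {
  med <- patient$medications
  if (nrow(med) == 0) return(FALSE)
  med <- med[in_outcome_window(med$date, index$index_date, config), , drop = FALSE]
  if (nrow(med) == 0) return(FALSE)
  resolved <- resolve_drug(med$drug, registry)
  unknown <- is.na(resolved$name)
  if (any(unknown)) {
    warning("criterion_asm: ignoring medication(s) absent from lexicon: ",
            paste(unique(med$drug[unknown]), collapse = ", "), call. = FALSE)
  }
  keep <- !unknown
  if (config$require_adjunctive_only) keep <- keep & resolved$adjunctive %in% TRUE
  med <- med[keep, , drop = FALSE]
  if (nrow(med) == 0) return(FALSE)
  enc <- patient$encounters
  ep_any <- enc_has_set(enc, registry, "epilepsy_specific") &
    !enc_has_set(enc, registry, "convulsion_excluded")
  ep_dates <- unique(enc$date[ep_any])
  any(med$date %in% ep_dates)
}

#' Health-care utilisation criteria
#'
#' Counts distinct encounter dates in the outcome window — restricted to
#' encounters carrying a seizure-related code when `which =
#' "seizure_related"` — and compares against the configured minimum number of
#' distinct days. Two encounters on the same day count once.
#'
#' @inheritParams criterion_status_epilepticus
#' @param which `"seizure_related"` or `"all"`.
#' @return Logical scalar.
#' @export
criterion_utilisation <- function(patient, index, registry, config,
                                  which = c("seizure_related", "all")) {
  which <- match.arg(which)
  enc <- patient$encounters
  enc <- enc[in_outcome_window(enc$date, index$index_date, config), , drop = FALSE]
  if (which == "seizure_related") {
    enc <- enc[enc_has_set(enc, registry, "seizure_related"), , drop = FALSE]
    thr <- config$thresholds$seizure_utilisation_min_distinct_days
  } else {
    thr <- config$thresholds$all_utilisation_min_distinct_days
  }
  length(unique(enc$date)) >= thr
}

#' Seizure-related inpatient admissions criterion
#'
#' @inheritParams criterion_status_epilepticus
#' @return `TRUE` when at least the configured number of inpatient encounters
#'   in the outcome window carry a seizure-related code.
#' @export
criterion_inpatient <- function(patient, index, registry, config) {
  enc <- patient$encounters
  enc <- enc[in_outcome_window(enc$date, index$index_date, config) &
               enc$setting == "inpatient", , drop = FALSE]
  if (nrow(enc) == 0) return(FALSE)
  sum(enc_has_set(enc, registry, "seizure_related")) >=
    config$thresholds$inpatient_min_admissions
}

#' Seizure-related diagnostic-testing criterion
#'
#' Counts procedure records in the outcome window whose code is in the
#' diagnostic-testing set (EEG, brain MRI, head CT orders) and that
#' co-occur (same calendar day) with an encounter carrying a seizure-related
#' diagnosis.
#'
#' @inheritParams criterion_status_epilepticus
#' @return Logical scalar.
#' @export
criterion_diagnostics <- function(patient, index, registry, config) {
  prc <- patient$procedures
  if (nrow(prc) == 0) return(FALSE)
  prc <- prc[in_outcome_window(prc$date, index$index_date, config), , drop = FALSE]
  prc <- prc[code_in_set(prc$code, registry, "diagnostic_testing"), , drop = FALSE]
  if (nrow(prc) == 0) return(FALSE)
  enc <- patient$encounters
  sz_dates <- unique(enc$date[enc_has_set(enc, registry, "seizure_related")])
  sum(prc$date %in% sz_dates) >= config$thresholds$diagnostics_min_count
}

#' Composite recurrence label for one patient
#'
#' Evaluates the seven expert-derived recurrence criteria over the two-year
#' outcome window and combines them: a patient meeting any criterion is
#' labelled recurrent; only patients matching none are seizure-free.
#'
#' @inheritParams criterion_status_epilepticus
#' @return One-row tibble with the seven criterion booleans and `composite`.
#' @export
composite_label <- function(patient, index, registry,
                            config = outcome_config()) {
  asm <- criterion_asm(patient, index, registry, config)
  se <- criterion_status_epilepticus(patient, index, registry, config)
  inpt <- criterion_inpatient(patient, index, registry, config)
  szu <- criterion_utilisation(patient, index, registry, config, "seizure_related")
  allu <- criterion_utilisation(patient, index, registry, config, "all")
  dx <- criterion_diagnostics(patient, index, registry, config)
  prc <- criterion_procedure(patient, index, registry, config)
  comp <- asm || se || inpt || szu ||
    (config$enable_all_utilisation && allu) || dx || prc
  tibble::tibble(patient_id = patient$patient_id,
                 asm = asm, status_epilepticus = se, inpatient_seizure = inpt,
                 seizure_utilisation = szu, all_utilisation = allu,
                 diagnostics = dx, procedure = prc, composite = comp)
}

#' Label every included patient in a cohort
#'
#' @param cohort An `ehr_cohort` (or list of `patient_record`s).
#' @param cohort_table Output of [build_cohort()].
#' @param registry A [code_registry()].
#' @param config An [outcome_config()].
#' @return Tibble with one row per included patient: the seven criterion
#'   booleans plus `composite`.
#' @export
label_cohort <- function(cohort, cohort_table, registry,
                         config = outcome_config()) {
  records <- if (inherits(cohort, "ehr_cohort")) as_patient_records(cohort)
    else cohort
  inc <- cohort_table[cohort_table$included, , drop = FALSE]
  if (nrow(inc) == 0) {
    return(tibble::tibble(patient_id = character(), asm = logical(),
                          status_epilepticus = logical(),
                          inpatient_seizure = logical(),
                          seizure_utilisation = logical(),
                          all_utilisation = logical(), diagnostics = logical(),
                          procedure = logical(), composite = logical()))
  }
  rows <- lapply(seq_len(nrow(inc)), function(i) {
    p <- records[[inc$patient_id[[i]]]]
    idx <- list(patient_id = inc$patient_id[[i]],
                index_date = inc$index_date[[i]],
                qualifying_code = inc$qualifying_code[[i]],
                age_at_index_days = inc$age_at_index_days[[i]])
    composite_label(p, idx, registry, config)
  })
  dplyr::bind_rows(rows)
}
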