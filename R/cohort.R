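# Temporal windows, fixed-day arithmetic throughout: 1 year = 365 days,
# 2 years = 730 days, 1 week = 7 days; "before age 21" = index < birth + 21*365.
DAYS_YEAR <- 365L
DAYS_2YEARS <- 730L
DAYS_WEEK <- 7L
DAYS_21YEARS <- 21L * 365L

#' Find a patient's index seizure-like event
#'
#' The index event is the earliest encounter carrying any code from the broad
#' seizure-like set (epilepsy, seizures including febrile, convulsions),
#' provided the patient is younger than 21 years at that encounter. If the
#' earliest seizure-like encounter falls at or after age 21 the patient has
#' no index event.
#'
#' @param patient A `patient_record` (see [patient_record()]); encounters
#'   must be date-sorted.
#' @param registry A [code_registry()].
#' @return A list with `patient_id`, `index_date`, `qualifying_code`,
#'   `age_at_index_days`, or `NULL` when no index event exists.
#' @export
find_index_event <- function(patient, registry) {
  enc <- patient$encounters
  if (nrow(enc) == 0) return(NULL)
  if (is.unsorted(enc$date)) {
    stop("find_index_event: encounters must be sorted by date")
  }
  for (i in seq_len(nrow(enc))) {
    hits <- code_in_set(enc$codes[[i]], registry, "seizure_like_broad")
    if (any(hits)) {
      age <- as.integer(enc$date[[i]] - patient$birth_date)
      if (age >= DAYS_21YEARS) return(NULL)
      return(list(patient_id = patient$patient_id,
                  index_date = enc$date[[i]],
                  qualifying_code = enc$codes[[i]][which(hits)[1]],
                  age_at_index_days = age))
    }
  }
  NULL
}

#' Apply the three temporal inclusion criteria to one patient
#'
#' Criterion 1 (prior contact): in EMR mode, an encounter for any reason at
#' least one year (365 days) before the index event; patients whose index
#' falls before age one year instead need an encounter for other purposes
#' (carrying no seizure-like code) at least one week before the index. In
#' claims mode the same lead is assessed against coverage intervals (closed;
#' an interval containing the required lead date qualifies). Criterion 2: an
#' index encounter exists (guaranteed here since `index` is supplied).
#' Criterion 3 (follow-up): an encounter (EMR) or coverage (claims) at least
#' two years (730 days) after the index event.
#'
#' @param patient A `patient_record`.
#' @param index Result of [find_index_event()] for the same patient.
#' @param registry A [code_registry()].
#' @param modality `"emr"` or `"claims"`.
#' @return A list with the per-criterion booleans, `included`, and
#'   `exclusion_reason` (`NA` when included).
#' @export
check_inclusion <- function(patient, index, registry,
                            modality = c("emr", "claims")) {
  modality <- match.arg(modality)
  stopifnot(!is.null(index), index$patient_id == patient$patient_id)
  if (modality == "claims" && nrow(patient$coverage) == 0 &&
      nrow(patient$encounters) > 0) {
    stop("check_inclusion: claims modality but record carries no coverage periods")
  }
  infant <- index$age_at_index_days < DAYS_YEAR
  lead_required <- if (infant) DAYS_WEEK else DAYS_YEAR

  if (modality == "emr") {
    enc <- patient$encounters
    lead <- as.integer(index$index_date - enc$date)
    if (infant) {
      # "for other purposes": the qualifying encounter must carry no
      # seizure-like code
      non_seiz <- !vapply(enc$codes, function(cc) {
        any(code_in_set(cc, registry, "seizure_like_broad"))
      }, logical(1))
      prior <- any(lead >= lead_required & non_seiz)
    } else {
      prior <- any(lead >= lead_required)
    }
    followup <- any(as.integer(enc$date - index$index_date) >= DAYS_2YEARS)
  } else {
    cov <- patient$coverage
    lead_date <- index$index_date - lead_required
    fup_date <- index$index_date + DAYS_2YEARS
    prior <- any(cov$start_date <= lead_date & cov$end_date >= lead_date)
    followup <- any(cov$start_date <= fup_date & cov$end_date >= fup_date)
  }

  included <- prior && followup
  reason <- if (included) NA_character_ else
    if (!prior) "prior_contact" else "followup"
  list(patient_id = patient$patient_id,
       has_index = TRUE,
       criterion_prior_contact = prior,
       criterion_index = TRUE,
       criterion_followup = followup,
       included = included,
       exclusion_reason = reason)
}

#' Build the cohort table for a set of patients
#'
#' Runs [find_index_event()] and [check_inclusion()] over every patient and
#' returns one row per patient with the index event, per-criterion flags, the
#' inclusion decision and the exclusion reason (`no_index`, `prior_contact`
#' or `followup`; the first failing criterion in that order).
#'
#' @param records List of `patient_record` objects, or an `ehr_cohort`.
#' @param registry A [code_registry()].
#' @param modality `"emr"` or `"claims"`; defaults to the cohort's own
#'   modality when `records` is an `ehr_cohort`.
#' @return A tibble with columns `patient_id`, `index_date`,
#'   `qualifying_code`, `age_at_index_days`, `has_index`,
#'   `criterion_prior_contact`, `criterion_index`, `criterion_followup`,
#'   `included`, `exclusion_reason`.
#' @export
build_cohort <- function(records, registry, modality = NULL) {
  if (inherits(records, "ehr_cohort")) {
    if (is.null(modality)) modality <- records$modality
    records <- as_patient_records(records)
  }
  if (is.null(modality)) modality <- "emr"
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) {
    stop("build_cohort: duplicate patient_id: ", ids[anyDuplicated(ids)])
  }
  if (length(records) == 0) {
    return(tibble::tibble(
      patient_id = character(), index_date = as.Date(character()),
      qualifying_code = character(), age_at_index_days = integer(),
      has_index = logical(), criterion_prior_contact = logical(),
      criterion_index = logical(), criterion_followup = logical(),
      included = logical(), exclusion_reason = character()))
  }
  rows <- lapply(records, function(p) {
    idx <- find_index_event(p, registry)
    if (is.null(idx)) {
      return(tibble::tibble(
        patient_id = p$patient_id, index_date = as.Date(NA),
        qualifying_code = NA_character_, age_at_index_days = NA_integer_,
        has_index = FALSE, criterion_prior_contact = FALSE,
        criterion_index = FALSE, criterion_followup = FALSE,
        included = FALSE, exclusion_reason = "no_index"))
    }
    inc <- check_inclusion(p, idx, registry, modality)
    tibble::tibble(
      patient_id = p$patient_id, index_date = idx$index_date,
      qualifying_code = idx$qualifying_code,
      age_at_index_days = idx$age_at_index_days,
      has_index = TRUE,
      criterion_prior_contact = inc$criterion_prior_contact,
      criterion_index = TRUE,
      criterion_followup = inc$criterion_followup,
      included = inc$included, exclusion_reason = inc$exclusion_reason)
  })
  dplyr::bind_rows(rows)
}
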