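#' Write a cohort to a directory of plain-text files
#'
#' Serializes an `ehr_cohort` as RFC-4180 CSV files plus one JSON object per
#' line for notes: `patients.csv`, `coverage.csv`, `encounters.csv`
#' (ordered codes pipe-delimited, primary/admitting as integer positions,
#' absent admitting position serialized as an empty field), `medications.csv`,
#' `procedures.csv`, `notes.jsonl` and `meta.json` (modality). The simulation
#' truth (`truth.csv`) is written separately and never read by any pipeline
#' stage. Dates are ISO-8601. Output is byte-deterministic for a given
#' cohort.
#'
#' @param cohort An `ehr_cohort`.
#' @param directory Target directory (created if missing).
#' @param write_truth Write `truth.csv`? Defaults to `TRUE` when the cohort
#'   carries simulation truth.
#' @return `directory`, invisibly.
#' @export
write_dataset <- function(cohort, directory,
                          write_truth = nrow(cohort$truth) > 0) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  wcsv <- function(x, f) readr::write_csv(x, p(f), na = "")

  wcsv(cohort$patients, "patients.csv")
  wcsv(cohort$coverage, "coverage.csv")
  enc <- cohort$encounters
  enc_flat <- tibble::tibble(
    patient_id = enc$patient_id, encounter_id = enc$encounter_id,
    date = enc$date, setting = enc$setting,
    codes = vapply(enc$codes, paste, "", collapse = "|"),
    primary_pos = enc$primary_pos, admitting_pos = enc$admitting_pos)
  wcsv(enc_flat, "encounters.csv")
  wcsv(cohort$medications, "medications.csv")
  wcsv(cohort$procedures, "procedures.csv")
  con <- file(p("notes.jsonl"), open = "wb")
  on.exit(close(con))
  if (nrow(cohort$notes) > 0) {
    for (i in seq_len(nrow(cohort$notes))) {
      writeLines(jsonlite::toJSON(list(
        note_id = cohort$notes$note_id[[i]],
        patient_id = cohort$notes$patient_id[[i]],
        date = as.character(cohort$notes$date[[i]]),
        note_type = cohort$notes$note_type[[i]],
        text = cohort$notes$text[[i]]
      ), auto_unbox = TRUE), con)
    }
  }
  writeLines(jsonlite::toJSON(list(modality = cohort$modality),
                              auto_unbox = TRUE),
             p("meta.json"))
  if (write_truth) wcsv(cohort$truth, "truth.csv")
  invisible(directory)
}

#' Read a cohort from a dataset directory
#'
#' Inverse of [write_dataset()]: `read_dataset(write_dataset(x)) == x` up to
#' the simulation-truth table, including code order and primary/admitting
#' positions. Schema violations raise a parse error naming the file and
#' field.
#'
#' @param directory Directory written by [write_dataset()].
#' @param read_truth Also read `truth.csv` if present (off by default:
#'   pipeline stages must never see the latent status).
#' @return An `ehr_cohort`.
#' @export
read_dataset <- function(directory, read_truth = FALSE) {
  p <- function(f) file.path(directory, f)
  need <- c("patients.csv", "coverage.csv", "encounters.csv",
            "medications.csv", "procedures.csv", "meta.json")
  missing <- need[!file.exists(p(need))]
  if (length(missing) > 0) {
    stop("read_dataset: missing files in '", directory, "': ",
         paste(missing, collapse = ", "))
  }
  rcsv <- function(f, col_types) {
    # readr's parse warnings are promoted to errors below
    out <- suppressWarnings(readr::read_csv(p(f), col_types = col_types,
                                            na = "", progress = FALSE))
    prob <- readr::problems(out)
    if (nrow(prob) > 0) {
      stop(sprintf("read_dataset: parse error in %s, line %d, column %s",
                   f, prob$row[[1]], prob$col[[1]]))
    }
    attr(out, "spec") <- NULL
    attr(out, "problems") <- NULL
    out
  }
  patients <- rcsv("patients.csv", readr::cols(patient_id = "c",
                                               birth_date = "D", sex = "c"))
  coverage <- rcsv("coverage.csv", readr::cols(patient_id = "c",
                                               start_date = "D",
                                               end_date = "D"))
  enc_flat <- rcsv("encounters.csv",
                   readr::cols(patient_id = "c", encounter_id = "c",
                               date = "D", setting = "c", codes = "c",
                               primary_pos = "i", admitting_pos = "i"))
  if (nrow(enc_flat) > 0 && anyNA(enc_flat$codes)) {
    stop("read_dataset: parse error in encounters.csv, field codes: empty code list")
  }
  encounters <- tibble::tibble(
    patient_id = enc_flat$patient_id, encounter_id = enc_flat$encounter_id,
    date = enc_flat$date, setting = enc_flat$setting,
    codes = strsplit(enc_flat$codes %||% character(0), "|", fixed = TRUE),
    primary_pos = enc_flat$primary_pos, admitting_pos = enc_flat$admitting_pos)
  if (nrow(enc_flat) == 0) encounters <- empty_encounters()
  medications <- rcsv("medications.csv", readr::cols(patient_id = "c",
                                                     date = "D", drug = "c"))
  procedures <- rcsv("procedures.csv", readr::cols(patient_id = "c",
                                                   date = "D", code = "c",
                                                   encounter_id = "c"))
  notes <- empty_notes()
  if (file.exists(p("notes.jsonl"))) {
    lines <- readLines(p("notes.jsonl"))
    if (length(lines) > 0) {
      parsed <- lapply(lines, jsonlite::fromJSON)
      notes <- tibble::tibble(
        note_id = vapply(parsed, `[[`, "", "note_id"),
        patient_id = vapply(parsed, `[[`, "", "patient_id"),
        date = as.Date(vapply(parsed, `[[`, "", "date")),
        note_type = vapply(parsed, `[[`, "", "note_type"),
        text = vapply(parsed, `[[`, "", "text"))
    }
  }
  meta <- jsonlite::fromJSON(p("meta.json"))
  truth <- empty_truth()
  if (read_truth && file.exists(p("truth.csv"))) {
    truth <- rcsv("truth.csv", readr::cols(patient_id = "c",
                                           latent_recurrence = "l"))
  }
  new_ehr_cohort(patients = patients, coverage = coverage,
                 encounters = encounters, medications = medications,
                 procedures = procedures, notes = notes, truth = truth,
                 modality = meta$modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
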