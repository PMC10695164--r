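# Hand-built patient fixtures. Days are offsets from a base date so windows
# can be read directly off the fixture definitions (day 0 = intended index).

fx_base <- as.Date("2015-01-01")

fx_enc <- function(day, codes, setting = "outpatient", primary = 1L,
                   admitting = NA_integer_, id = NULL) {
  list(day = day, codes = codes, setting = setting,
       primary = as.integer(primary), admitting = as.integer(admitting),
       id = id)
}

fx_patient <- function(id = "P1", birth_day = -2000, encs = list(),
                       meds = NULL, procs = NULL, notes = NULL,
                       coverage = NULL, base = fx_base) {
  days <- vapply(encs, `[[`, 0, "day")
  ord <- order(days)
  encs <- encs[ord]
  enc_tbl <- tibble::tibble(
    patient_id = id,
    encounter_id = vapply(seq_along(encs), function(i) {
      encs[[i]]$id %||% sprintf("%s-e%04d", id, i)
    }, ""),
    date = base + vapply(encs, `[[`, 0, "day"),
    setting = vapply(encs, `[[`, "", "setting"),
    codes = lapply(encs, `[[`, "codes"),
    primary_pos = vapply(encs, `[[`, 1L, "primary"),
    admitting_pos = vapply(encs, `[[`, NA_integer_, "admitting"))
  med_tbl <- if (is.null(meds)) {
    tibble::tibble(patient_id = character(), date = as.Date(character()),
                   drug = character())
  } else {
    tibble::tibble(patient_id = id, date = base + meds$day, drug = meds$drug)
  }
  prc_tbl <- if (is.null(procs)) {
    tibble::tibble(patient_id = character(), date = as.Date(character()),
                   code = character(), encounter_id = character())
  } else {
    tibble::tibble(patient_id = id, date = base + procs$day, code = procs$code,
                   encounter_id = procs$encounter_id %||% NA_character_)
  }
  note_tbl <- if (is.null(notes)) {
    tibble::tibble(note_id = character(), patient_id = character(),
                   date = as.Date(character()), note_type = character(),
                   text = character())
  } else {
    tibble::tibble(note_id = sprintf("%s-n%03d", id, seq_len(nrow(notes))),
                   patient_id = id, date = base + notes$day,
                   note_type = notes$note_type, text = notes$text)
  }
  cov_tbl <- if (is.null(coverage)) {
    tibble::tibble(patient_id = character(), start_date = as.Date(character()),
                   end_date = as.Date(character()))
  } else {
    tibble::tibble(patient_id = id, start_date = base + coverage$start_day,
                   end_date = base + coverage$end_day)
  }
  structure(list(patient_id = id, birth_date = base + birth_day, sex = "F",
                 encounters = enc_tbl, medications = med_tbl,
                 procedures = prc_tbl, notes = note_tbl, coverage = cov_tbl),
            class = "patient_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Six-patient inclusion fixture: two pass, one fails each criterion, plus an
# infant special case that passes via the one-week rule.
fx_inclusion_cohort <- function() {
  list(
    # passes: age 5y at index, prior contact 400d before, follow-up 750d after
    fx_patient("A-pass", birth_day = -5 * 365, encs = list(
      fx_enc(-400, "ICD10:Z00.129"),
      fx_enc(0, "ICD10:R56.9"),
      fx_enc(750, "ICD10:J06.9"))),
    # passes: infant (6 months), well-child visit 10d before, follow-up 800d
    fx_patient("B-pass-infant", birth_day = -182, encs = list(
      fx_enc(-10, "ICD9:V20.2"),
      fx_enc(0, "ICD9:780.39"),
      fx_enc(800, "ICD10:J06.9"))),
    # fails prior contact: only 200d of lead at age 5
    fx_patient("C-prior", birth_day = -5 * 365, encs = list(
      fx_enc(-200, "ICD10:Z00.129"),
      fx_enc(0, "ICD10:G40.909"),
      fx_enc(760, "ICD10:J06.9"))),
    # fails index: no seizure-like code anywhere
    fx_patient("D-noindex", birth_day = -3000, encs = list(
      fx_enc(-400, "ICD10:Z00.129"),
      fx_enc(0, "ICD10:J45.909"),
      fx_enc(740, "ICD10:J06.9"))),
    # fails follow-up: last encounter 600d after index
    fx_patient("E-followup", birth_day = -4000, encs = list(
      fx_enc(-500, "ICD10:Z00.129"),
      fx_enc(0, "ICD10:R56.9"),
      fx_enc(600, "ICD10:J06.9"))),
    # fails index by age: first seizure-like code at age 22
    fx_patient("F-age", birth_day = -22 * 365, encs = list(
      fx_enc(-400, "ICD10:Z00.129"),
      fx_enc(0, "ICD10:G40.909"),
      fx_enc(740, "ICD10:J06.9")))
  )
}
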