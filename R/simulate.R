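#' Configuration for the synthetic cohort generator
#'
#' Describes the study conditions a simulated cohort is drawn under: cohort
#' size, latent recurrence prevalence, temporal structure (pre-index history
#' and follow-up), per-criterion post-index event rates conditional on the
#' latent recurrence status, the strengths of the label-conditional signal
#' planted in structured codes and in note text, and the data modality
#' (`emr` emits clinical notes, `claims` emits coverage periods and no note
#' text).
#'
#' Event rates are length-2 vectors `c(nonrecurrent = ..., recurrent = ...)`.
#' The defaults emulate a pediatric first-seizure cohort: most recurrent
#' patients accumulate several epilepsy-coded days, a majority start an
#' antiseizure medication, while non-recurrent patients see mostly routine
#' care; the latent prevalence defaults to 0.57.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   datasets.
#' @param recurrence_prevalence Probability a patient is latently recurrent.
#' @param modality `"emr"` or `"claims"`.
#' @param pre_index_history_days List with `min`/`max` days of lead time from
#'   first contact to the index event (non-infants).
#' @param followup_days List with `min`/`max` days of post-index observation.
#' @param event_rates Named list of rates, see Details in the package
#'   vignette.
#' @param text_signal_strength Nonnegative scale of the label-conditional
#'   token-frequency shift in notes (0 removes all text signal).
#' @param structured_signal_strength Nonnegative scale of the
#'   label-conditional pre-index code-rate shift (0 removes all structured
#'   signal).
#' @param note_length_distribution List with `mean_tokens`, `frac_long`,
#'   `long_min`, `long_max`: note lengths are Poisson around `mean_tokens`
#'   except a `frac_long` fraction drawn uniformly in
#'   `[long_min, long_max]` to exceed the note-chunking limit.
#' @param violate_fraction Named numeric: fractions of patients constructed
#'   to violate each inclusion criterion (`prior_contact`, `no_index`,
#'   `followup`).
#' @param infant_fraction Fraction of patients whose index falls before age
#'   one year (these exercise the one-week prior-contact special case).
#' @param note_only_med_fraction Among EMR patients starting an ASM, the
#'   fraction whose prescription appears only in a clinical note, not in the
#'   structured medication table.
#' @param blanking_days Days after the index event during which no outcome
#'   events are generated deliberately close to the boundary.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       seed = 1L,
                       recurrence_prevalence = 0.57,
                       modality = c("emr", "claims"),
                       pre_index_history_days = list(min = 380, max = 2400),
                       followup_days = list(min = 830, max = 1600),
                       event_rates = list(),
                       text_signal_strength = 1,
                       structured_signal_strength = 1,
                       note_length_distribution = list(mean_tokens = 120,
                                                       frac_long = 0.02,
                                                       long_min = 4200,
                                                       long_max = 6000),
                       violate_fraction = c(prior_contact = 0.06,
                                            no_index = 0.05,
                                            followup = 0.06),
                       infant_fraction = 0.08,
                       note_only_med_fraction = 0.15,
                       blanking_days = 7) {
  modality <- match.arg(modality)
  default_rates <- list(
    epilepsy_day_rate       = c(nonrecurrent = 0.30, recurrent = 5.0),
    se_probability          = c(nonrecurrent = 0.010, recurrent = 0.15),
    asm_probability         = c(nonrecurrent = 0.040, recurrent = 0.60),
    procedure_probability   = c(nonrecurrent = 0.005, recurrent = 0.10),
    diagnostics_probability = c(nonrecurrent = 0.040, recurrent = 0.50),
    inpatient_fraction      = c(nonrecurrent = 0.080, recurrent = 0.30),
    background_visit_rate   = 1.2,
    pre_index_visit_rate    = 3.0,
    risk_marker_rate        = 0.4
  )
  for (nm in names(event_rates)) {
    if (!nm %in% names(default_rates)) {
      stop("sim_config: unknown event_rates entry '", nm, "'")
    }
    default_rates[[nm]] <- event_rates[[nm]]
  }
  cfg <- list(
    n_patients = n_patients, seed = as.integer(seed),
    recurrence_prevalence = recurrence_prevalence, modality = modality,
    pre_index_history_days = pre_index_history_days,
    followup_days = followup_days, event_rates = default_rates,
    text_signal_strength = text_signal_strength,
    structured_signal_strength = structured_signal_strength,
    note_length_distribution = note_length_distribution,
    violate_fraction = violate_fraction,
    infant_fraction = infant_fraction,
    note_only_med_fraction = note_only_med_fraction,
    blanking_days = blanking_days
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1) || anyNA(x)) {
      stop("sim_config: field '", field, "' must be a probability in [0, 1]")
    }
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients)) {
    stop("sim_config: field 'n_patients' must be a nonnegative integer")
  }
  chk_prob(cfg$recurrence_prevalence, "recurrence_prevalence")
  chk_prob(cfg$violate_fraction, "violate_fraction")
  if (sum(cfg$violate_fraction) > 1) {
    stop("sim_config: field 'violate_fraction' fractions sum to more than 1")
  }
  chk_prob(cfg$infant_fraction, "infant_fraction")
  chk_prob(cfg$note_only_med_fraction, "note_only_med_fraction")
  for (nm in names(cfg$event_rates)) {
    r <- cfg$event_rates[[nm]]
    if (!is.numeric(r) || any(r < 0) || anyNA(r)) {
      stop("sim_config: field 'event_rates$", nm, "' must be nonnegative")
    }
  }
  if (cfg$text_signal_strength < 0) {
    stop("sim_config: field 'text_signal_strength' must be nonnegative")
  }
  if (cfg$structured_signal_strength < 0) {
    stop("sim_config: field 'structured_signal_strength' must be nonnegative")
  }
  nl <- cfg$note_length_distribution
  chk_prob(nl$frac_long, "note_length_distribution$frac_long")
  if (nl$long_min > nl$long_max) {
    stop("sim_config: field 'note_length_distribution' has long_min > long_max")
  }
  invisible(cfg)
}

# token pools for note text ------------------------------------------------

note_background_tokens <- function() {
  c("patient", "the", "a", "of", "with", "and", "was", "is", "seen", "today",
    "history", "presented", "episode", "event", "seizure-like", "activity",
    "witnessed", "by", "parent", "lasting", "minutes", "no", "fever",
    "afebrile", "exam", "neurological", "examination", "alert", "oriented",
    "tone", "reflexes", "symmetric", "gait", "age", "appropriate",
    "development", "vaccinations", "up", "to", "date", "follow",
    "clinic", "weeks", "return", "precautions", "discussed", "family",
    "mother", "father", "reports", "sleep", "deprivation", "denies",
    "trauma", "ingestion", "head", "impression", "plan", "continue",
    "observation", "routine", "study", "ordered", "results", "pending",
    "findings", "within", "limits", "without", "acute", "process",
    "ventricles", "midline", "signal", "gray", "white", "matter",
    "background", "rhythm", "sleep-wake", "stages", "awake", "drowsy",
    "photic", "stimulation", "hyperventilation", "performed", "well",
    "tolerated", "technically", "adequate", "recording", "duration")
}

note_positive_tokens <- function() {
  # tokens a clinician writing about a concerning course over-uses
  c("recurrent", "refractory", "epileptiform", "spikes", "sharp-waves",
    "abnormal", "concerning", "breakthrough", "persistent", "focal-slowing",
    "escalation", "intractable")
}

note_negative_tokens <- function() {
  # reassuring / benign-course vocabulary
  c("reassuring", "unremarkable", "benign", "resolved", "isolated",
    "provoked", "normalizing", "self-limited", "single", "low-risk")
}

# label-conditional shift per note type: neurology notes carry the most
# prognostic language, head CT reports the least
note_type_signal_weights <- function() {
  c(neurology = 1.0, discharge_summary = 0.6, eeg_report = 0.5,
    mri_report = 0.4, communication = 0.3, ct_report = 0.1)
}

sim_code_pools <- function() {
  list(
    index = c("ICD10:R56.9", "ICD9:780.39", "ICD10:G40.909", "ICD9:345.90"),
    index_w = c(0.45, 0.2, 0.25, 0.1),
    epilepsy = c("ICD10:G40.909", "ICD10:G40.309", "ICD10:G40.209",
                 "ICD10:G40.109", "ICD9:345.90", "ICD9:345.10"),
    status = c("ICD10:G40.901", "ICD10:G40.911", "ICD9:345.3"),
    # background pediatric care
    filler = c("ICD10:Z00.129", "ICD10:J06.9", "ICD10:J45.909", "ICD10:H66.90",
               "ICD10:K59.00", "ICD10:L20.9", "ICD9:V20.2", "ICD9:465.9",
               "ICD10:S09.90", "ICD10:R51.9", "ICD10:B34.9", "ICD9:382.9"),
    # pre-index markers of neurological risk; not seizure-like codes, so they
    # never move the index event
    marker = c("ICD10:R62.0", "ICD10:F82", "ICD10:G93.40", "ICD10:R27.8",
               "ICD9:315.2", "ICD10:P07.10"),
    pain = c("ICD10:G89.29", "ICD10:M54.9"),
    eeg = c("CPT:95819", "CPT:95816"),
    imaging = c("CPT:70551", "CPT:70450"),
    procedures = c("CPT:95951", "CPT:64568"),
    asm_w = c(levetiracetam = 0.40, valproate = 0.10, oxcarbazepine = 0.12,
              lamotrigine = 0.08, topiramate = 0.06, ethosuximide = 0.05,
              phenobarbital = 0.07, carbamazepine = 0.04, zonisamide = 0.03,
              clobazam = 0.03, lacosamide = 0.02)
  )
}

make_note_text <- function(n_tokens, latent, type_weight, signal, med_tokens = NULL) {
  bg <- note_background_tokens()
  bg_w <- 1 / seq_along(bg)
  pos <- note_positive_tokens()
  neg <- note_negative_tokens()
  is_prog <- stats::runif(n_tokens) < 0.08
  n_prog <- sum(is_prog)
  toks <- sample(bg, n_tokens, replace = TRUE, prob = bg_w)
  if (n_prog > 0) {
    p_pos <- stats::plogis(type_weight * signal * (2 * latent - 1))
    take_pos <- stats::runif(n_prog) < p_pos
    prog <- ifelse(take_pos,
                   sample(pos, n_prog, replace = TRUE),
                   sample(neg, n_prog, replace = TRUE))
    toks[is_prog] <- prog
  }
  if (!is.null(med_tokens)) toks <- c(toks, med_tokens)
  paste(toks, collapse = " ")
}

#' Generate a synthetic pediatric seizure cohort
#'
#' Draws a seeded cohort with the longitudinal, coding and textual structure
#' the downstream stages assume: a pre-index history of healthy-care
#' encounters, an index seizure-like encounter before age 21 (with a
#' configurable fraction of patients violating each inclusion criterion), and
#' post-index seizure-related events (epilepsy-coded days, status
#' epilepticus, ASM starts, procedures, diagnostic testing) whose rates
#' depend on a latent recurrence status. In EMR mode every index encounter is
#' accompanied by at least one clinical note; note tokens are drawn from a
#' background distribution mixed with prognosis vocabulary whose
#' label-conditional odds scale with `text_signal_strength` (largest for
#' neurology notes, smallest for head CT reports). In claims mode coverage
#' periods are emitted and notes are absent.
#'
#' @param config A [sim_config()].
#' @return An `ehr_cohort`: a list of tables `patients`, `coverage`,
#'   `encounters`, `medications`, `procedures`, `notes`, `truth`, plus the
#'   `modality`. `truth` holds the latent recurrence status and is never read
#'   by the pipeline stages.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  pools <- sim_code_pools()
  er <- cfg$event_rates
  s_struct <- cfg$structured_signal_strength
  s_text <- cfg$text_signal_strength
  type_w <- note_type_signal_weights()
  n <- cfg$n_patients
  blank <- cfg$blanking_days

  pat_l <- vector("list", n); cov_l <- vector("list", n)
  enc_l <- vector("list", n); med_l <- vector("list", n)
  prc_l <- vector("list", n); note_l <- vector("list", n)
  truth_l <- vector("list", n)

  note_len <- function() {
    nl <- cfg$note_length_distribution
    if (stats::runif(1) < nl$frac_long) {
      sample(nl$long_min:nl$long_max, 1)
    } else {
      max(20L, stats::rpois(1, nl$mean_tokens))
    }
  }

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    latent <- stats::runif(1) < cfg$recurrence_prevalence
    li <- latent + 1L  # index into c(nonrecurrent, recurrent) rate vectors

    u <- stats::runif(1)
    vf <- cfg$violate_fraction
    kind <- if (u < vf[["no_index"]]) "no_index" else
      if (u < vf[["no_index"]] + vf[["prior_contact"]]) "prior_contact" else
        if (u < sum(vf[c("no_index", "prior_contact", "followup")])) "followup" else
          "clean"
    infant <- stats::runif(1) < cfg$infant_fraction

    over_age <- kind == "no_index" && stats::runif(1) < 0.5
    age_days <- if (over_age) sample(7700:9000, 1) else
      if (infant) sample(60:360, 1) else sample(500:7600, 1)
    no_seizure_codes <- kind == "no_index" && !over_age

    index_date <- as.Date("2015-06-01") + sample(-1400:1400, 1)
    birth_date <- index_date - age_days

    lead <- if (infant) {
      if (kind == "prior_contact") sample(1:6, 1) else sample(8:min(45, age_days - 10), 1)
    } else {
      if (kind == "prior_contact") sample(30:300, 1) else {
        hi <- min(cfg$pre_index_history_days$max, age_days - 30)
        sample(cfg$pre_index_history_days$min:max(cfg$pre_index_history_days$min, hi), 1)
      }
    }
    horizon <- if (kind == "followup") sample(100:700, 1) else
      sample(cfg$followup_days$min:cfg$followup_days$max, 1)

    enc <- list(); prc <- list(); med <- list(); nts <- list()
    eid <- 0L
    add_enc <- function(day, setting, codes, primary = 1L, admitting = NA_integer_) {
      eid <<- eid + 1L
      enc[[length(enc) + 1L]] <<- list(
        encounter_id = sprintf("%s-e%04d", pid, eid),
        date = index_date + day, setting = setting,
        codes = list(codes), primary_pos = as.integer(primary),
        admitting_pos = as.integer(admitting))
      sprintf("%s-e%04d", pid, eid)
    }
    add_note <- function(day, type, latent, med_tokens = NULL) {
      nts[[length(nts) + 1L]] <<- list(
        note_id = sprintf("%s-n%03d", pid, length(nts) + 1L),
        patient_id = pid, date = index_date + day, note_type = type,
        text = make_note_text(note_len(), latent, type_w[[type]], s_text,
                              med_tokens))
    }

    # ---- pre-index history -------------------------------------------
    first_code <- if (infant || age_days < 1100) "ICD9:V20.2" else "ICD10:Z00.129"
    add_enc(-lead, "outpatient", first_code)
    if (lead >= 3) {
      nvis <- stats::rpois(1, er$background_visit_rate * 0 +
                             er$pre_index_visit_rate * (1 + 0.3 * s_struct * latent))
      if (nvis > 0) {
        for (d in sample(seq(-lead + 1L, -1L), nvis, replace = TRUE)) {
          add_enc(d, "outpatient", sample(pools$filler, sample(1:2, 1)))
        }
      }
      # risk-marker visits cluster in the year leading up to the first
      # seizure-like event (prodromal neurological concerns), so they fall
      # inside the one-year feature lookback
      recent <- seq(max(-lead + 1L, -360L), -1L)
      nm <- stats::rpois(1, er$risk_marker_rate * (1 + s_struct * latent))
      if (nm > 0) {
        for (d in sample(recent, nm, replace = TRUE)) {
          add_enc(d, "outpatient",
                  c(sample(pools$marker, 1), sample(pools$filler, 1)))
        }
      }
      # pre-index developmental/neurological work-up: one visit carrying
      # several distinct risk-marker codes, more likely ahead of a recurrent
      # course; at zero signal strength both classes share the base rate
      p_workup <- stats::plogis(-2 + if (latent) s_struct else 0)
      if (stats::runif(1) < p_workup) {
        add_enc(sample(recent, 1), "outpatient",
                c(sample(pools$marker, 3), sample(pools$filler, 1)))
      }
    }

    # ---- index encounter ---------------------------------------------
    has_index <- !no_seizure_codes
    index_setting <- "outpatient"
    if (has_index) {
      qcode <- sample(pools$index, 1, prob = pools$index_w)
      index_setting <- sample(c("emergency", "outpatient", "inpatient"), 1,
                              prob = c(0.5, 0.35, 0.15))
      codes <- c(qcode, sample(pools$filler, 1))
      add_enc(0L, index_setting, codes, primary = 1L,
              admitting = if (index_setting == "inpatient") 1L else NA_integer_)
    }

    # ---- post-index events -------------------------------------------
    win_hi <- min(730L, horizon - 5L)
    ep_days <- integer(0)
    if (has_index && win_hi > blank + 1L) {
      nd <- stats::rpois(1, er$epilepsy_day_rate[[li]])
      if (nd > 0) {
        ep_days <- sort(unique(sample(seq(blank + 1L, win_hi), min(nd, win_hi - blank),
                                      replace = FALSE)))
        for (d in ep_days) {
          setting <- if (stats::runif(1) < er$inpatient_fraction[[li]])
            "inpatient" else "outpatient"
          add_enc(d, setting, c(sample(pools$epilepsy, 1), sample(pools$filler, 1)),
                  primary = 1L,
                  admitting = if (setting == "inpatient") 1L else NA_integer_)
        }
      }
      if (stats::runif(1) < er$se_probability[[li]]) {
        d <- sample(seq(blank + 1L, win_hi), 1)
        add_enc(d, "emergency", c(sample(pools$status, 1), sample(pools$filler, 1)),
                primary = 1L)
      }
      # antiseizure medication start, co-occurring with an epilepsy dx day
      if (stats::runif(1) < er$asm_probability[[li]]) {
        d <- if (length(ep_days) > 0) ep_days[[1L]] else {
          dd <- sample(seq(blank + 1L, win_hi), 1)
          add_enc(dd, "outpatient", sample(pools$epilepsy, 1))
          dd
        }
        drug <- sample(names(pools$asm_w), 1, prob = pools$asm_w)
        note_only <- cfg$modality == "emr" &&
          stats::runif(1) < cfg$note_only_med_fraction
        if (note_only) {
          add_note(d, "discharge_summary", latent,
                   med_tokens = c("discharge", "medications", ":", "1.", drug,
                                  "250", "mg", "twice", "daily"))
        } else {
          med[[length(med) + 1L]] <- list(patient_id = pid,
                                          date = index_date + d, drug = drug)
        }
      }
      # gabapentin prescribed for neuropathic pain, not epilepsy
      if (stats::runif(1) < 0.03) {
        d <- sample(seq(blank + 1L, win_hi), 1)
        add_enc(d, "outpatient", sample(pools$pain, 1))
        med[[length(med) + 1L]] <- list(patient_id = pid,
                                        date = index_date + d, drug = "gabapentin")
      }
      # diagnostic testing co-occurring with a seizure-related encounter
      if (stats::runif(1) < er$diagnostics_probability[[li]]) {
        code <- sample(pools$eeg, 1)
        if (length(ep_days) > 0) {
          d <- ep_days[[sample(length(ep_days), 1)]]
          eidx <- add_enc(d, "outpatient", "ICD10:R56.9")
        } else {
          d <- sample(seq(blank + 1L, win_hi), 1)
          eidx <- add_enc(d, "outpatient", "ICD10:R56.9")
        }
        prc[[length(prc) + 1L]] <- list(patient_id = pid, date = index_date + d,
                                        code = code, encounter_id = eidx)
      }
      # routine early EEG inside the blanking window (never counts)
      if (stats::runif(1) < 0.4 && blank >= 3) {
        d <- sample(seq(2L, blank - 1L), 1)
        eidx <- add_enc(d, "outpatient", "ICD10:R56.9")
        prc[[length(prc) + 1L]] <- list(patient_id = pid, date = index_date + d,
                                        code = sample(pools$eeg, 1),
                                        encounter_id = eidx)
      }
      # epilepsy-directed procedure with confirmation dx >= 1 week later
      if (stats::runif(1) < er$procedure_probability[[li]] && win_hi > 40) {
        d <- sample(seq(30L, min(600L, win_hi - 10L)), 1)
        eidx <- add_enc(d, "inpatient", sample(pools$epilepsy, 1),
                        primary = 1L, admitting = 1L)
        prc[[length(prc) + 1L]] <- list(patient_id = pid, date = index_date + d,
                                        code = sample(pools$procedures, 1),
                                        encounter_id = eidx)
        add_enc(d + sample(8:60, 1), "outpatient", sample(pools$epilepsy, 1))
      }
    }
    # background post-index care (all-cause utilisation)
    if (horizon > blank + 2L) {
      nb <- stats::rpois(1, er$background_visit_rate)
      if (nb > 0) {
        for (d in sample(seq(blank + 1L, horizon), nb, replace = TRUE)) {
          add_enc(d, "outpatient", sample(pools$filler, sample(1:2, 1)))
        }
      }
    }
    # follow-up anchor beyond two years for non-violators
    if (kind != "followup" && horizon >= 735L) {
      add_enc(sample(735:horizon, 1), "outpatient", sample(pools$filler, 1))
    }

    # ---- notes (EMR mode) --------------------------------------------
    if (cfg$modality == "emr" && has_index) {
      med_section <- if (stats::runif(1) < 0.25) {
        if (stats::runif(1) < 0.3) {
          c("medications", ":", "denies", "taking", "levetiracetam")
        } else {
          c("medications", ":", "none")
        }
      } else NULL
      add_note(0L, "neurology", latent, med_tokens = med_section)
      if (stats::runif(1) < 0.45) add_note(sample(1:5, 1), "eeg_report", latent)
      if (stats::runif(1) < 0.30) add_note(sample(1:6, 1), "mri_report", latent)
      if (stats::runif(1) < 0.25) add_note(sample(0:3, 1), "ct_report", latent)
      if (stats::runif(1) < 0.40) add_note(sample(2:7, 1), "communication", latent)
      if (index_setting == "inpatient" && stats::runif(1) < 0.8) {
        add_note(sample(2:6, 1), "discharge_summary", latent)
      }
    }

    # ---- coverage (claims mode) --------------------------------------
    if (cfg$modality == "claims") {
      cov_l[[i]] <- list(patient_id = pid,
                         start_date = index_date - lead,
                         end_date = index_date + horizon)
    }

    pat_l[[i]] <- list(patient_id = pid, birth_date = birth_date,
                       sex = sample(c("F", "M"), 1))
    truth_l[[i]] <- list(patient_id = pid, latent_recurrence = latent)
    enc_l[[i]] <- enc; med_l[[i]] <- med; prc_l[[i]] <- prc; note_l[[i]] <- nts
  }

  bind_rows_of_lists <- function(ll) {
    ll <- ll[!vapply(ll, is.null, logical(1))]
    if (length(ll) == 0) return(list())
    ll
  }
  flat_enc <- unlist(enc_l, recursive = FALSE)
  encounters <- if (length(flat_enc) == 0) empty_encounters() else {
    tibble::tibble(
      patient_id = sub("-e[0-9]+$", "", vapply(flat_enc, `[[`, "", "encounter_id")),
      encounter_id = vapply(flat_enc, `[[`, "", "encounter_id"),
      date = as.Date(vapply(flat_enc, function(e) as.character(e$date), "")),
      setting = vapply(flat_enc, `[[`, "", "setting"),
      codes = lapply(flat_enc, function(e) e$codes[[1]]),
      primary_pos = vapply(flat_enc, `[[`, 1L, "primary_pos"),
      admitting_pos = vapply(flat_enc, `[[`, NA_integer_, "admitting_pos")
    )
  }
  encounters <- encounters[order(encounters$patient_id, encounters$date,
                                 encounters$encounter_id), , drop = FALSE]

  to_tbl <- function(ll, empty) {
    flat <- unlist(ll, recursive = FALSE)
    flat <- flat[!vapply(flat, is.null, logical(1))]
    if (length(flat) == 0) return(empty)
    dplyr::bind_rows(lapply(flat, tibble::as_tibble))
  }
  meds <- to_tbl(med_l, empty_medications())
  if (nrow(meds) > 0) meds <- meds[order(meds$patient_id, meds$date, meds$drug), ]
  prcs <- to_tbl(prc_l, empty_procedures())
  if (nrow(prcs) > 0) prcs <- prcs[order(prcs$patient_id, prcs$date, prcs$code), ]
  notes <- to_tbl(note_l, empty_notes())
  if (nrow(notes) > 0) notes <- notes[order(notes$patient_id, notes$note_id), ]

  patients <- if (n == 0) empty_patients() else
    dplyr::bind_rows(lapply(pat_l, tibble::as_tibble))
  coverage <- to_tbl(list(bind_rows_of_lists(cov_l)), empty_coverage())
  truth <- if (n == 0) empty_truth() else
    dplyr::bind_rows(lapply(truth_l, tibble::as_tibble))

  new_ehr_cohort(patients = patients, coverage = coverage,
                 encounters = encounters, medications = meds,
                 procedures = prcs, notes = notes, truth = truth,
                 modality = cfg$modality)
}

# ---- cohort container ----------------------------------------------------

empty_patients <- function() tibble::tibble(patient_id = character(),
                                            birth_date = as.Date(character()),
                                            sex = character())
empty_coverage <- function() tibble::tibble(patient_id = character(),
                                            start_date = as.Date(character()),
                                            end_date = as.Date(character()))
empty_encounters <- function() tibble::tibble(patient_id = character(),
                                              encounter_id = character(),
                                              date = as.Date(character()),
                                              setting = character(),
                                              codes = list(),
                                              primary_pos = integer(),
                                              admitting_pos = integer())
empty_medications <- function() tibble::tibble(patient_id = character(),
                                               date = as.Date(character()),
                                               drug = character())
empty_procedures <- function() tibble::tibble(patient_id = character(),
                                              date = as.Date(character()),
                                              code = character(),
                                              encounter_id = character())
empty_notes <- function() tibble::tibble(note_id = character(),
                                         patient_id = character(),
                                         date = as.Date(character()),
                                         note_type = character(),
                                         text = character())
empty_truth <- function() tibble::tibble(patient_id = character(),
                                         latent_recurrence = logical())

#' Construct an `ehr_cohort` container
#'
#' Relational container for a longitudinal cohort: one table per record type,
#' linked by `patient_id`. Invariants checked: event dates never precede
#' birth; encounters are sorted by date within patient; primary/admitting
#' positions index into the code list.
#'
#' @param patients,coverage,encounters,medications,procedures,notes,truth
#'   Tables as produced by [simulate_cohort()] or [read_dataset()].
#' @param modality `"emr"` or `"claims"`.
#' @return An object of class `ehr_cohort`.
#' @export
new_ehr_cohort <- function(patients, coverage, encounters, medications,
                           procedures, notes, truth = NULL, modality = "emr") {
  x <- structure(list(patients = patients, coverage = coverage,
                      encounters = encounters, medications = medications,
                      procedures = procedures, notes = notes,
                      truth = if (is.null(truth)) empty_truth() else truth,
                      modality = modality),
                 class = "ehr_cohort")
  validate_ehr_cohort(x)
  x
}

validate_ehr_cohort <- function(x) {
  if (anyDuplicated(x$patients$patient_id)) {
    stop("ehr_cohort: duplicate patient_id in patients table")
  }
  if (nrow(x$encounters) > 0) {
    nc <- lengths(x$encounters$codes)
    if (any(nc == 0)) stop("ehr_cohort: encounter with empty code list")
    if (any(x$encounters$primary_pos < 1 | x$encounters$primary_pos > nc)) {
      stop("ehr_cohort: primary_pos out of range")
    }
    adm <- x$encounters$admitting_pos
    ok <- is.na(adm) | (adm >= 1 & adm <= nc)
    if (!all(ok)) stop("ehr_cohort: admitting_pos out of range")
    bd <- x$patients$birth_date[match(x$encounters$patient_id,
                                      x$patients$patient_id)]
    if (any(x$encounters$date < bd, na.rm = TRUE)) {
      stop("ehr_cohort: encounter dated before birth")
    }
  }
  invisible(x)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %s: %d patients, %d encounters, %d medications, %d procedures, %d notes\n",
              x$modality, nrow(x$patients), nrow(x$encounters),
              nrow(x$medications), nrow(x$procedures), nrow(x$notes)))
  invisible(x)
}

#' Assemble one patient's record from a cohort
#'
#' @param cohort An `ehr_cohort`.
#' @param patient_id Patient identifier.
#' @return A `patient_record`: list with the patient's demographics and the
#'   patient's slices of the encounter, medication, procedure, note and
#'   coverage tables (encounters date-sorted).
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id)
  rec <- list(
    patient_id = patient_id,
    birth_date = cohort$patients$birth_date[[i]],
    sex = cohort$patients$sex[[i]],
    encounters = cohort$encounters[cohort$encounters$patient_id == patient_id, ,
                                   drop = FALSE],
    medications = cohort$medications[cohort$medications$patient_id == patient_id, ,
                                     drop = FALSE],
    procedures = cohort$procedures[cohort$procedures$patient_id == patient_id, ,
                                   drop = FALSE],
    notes = cohort$notes[cohort$notes$patient_id == patient_id, , drop = FALSE],
    coverage = cohort$coverage[cohort$coverage$patient_id == patient_id, ,
                               drop = FALSE]
  )
  structure(rec, class = "patient_record")
}

#' Split a cohort into per-patient records
#'
#' @param cohort An `ehr_cohort`.
#' @return Named list of `patient_record` objects, one per patient, in
#'   `patients` table order.
#' @export
as_patient_records <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  ids <- cohort$patients$patient_id
  f <- function(tbl) split(tbl, factor(tbl$patient_id, levels = ids))
  encs <- f(cohort$encounters); meds <- f(cohort$medications)
  prcs <- f(cohort$procedures); nts <- f(cohort$notes); cov <- f(cohort$coverage)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    out[[i]] <- structure(list(
      patient_id = ids[[i]],
      birth_date = cohort$patients$birth_date[[i]],
      sex = cohort$patients$sex[[i]],
      encounters = encs[[i]], medications = meds[[i]],
      procedures = prcs[[i]], notes = nts[[i]], coverage = cov[[i]]
    ), class = "patient_record")
  }
  out
}
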