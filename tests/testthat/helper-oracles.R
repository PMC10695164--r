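# Independent brute-force oracles. Deliberately written with naive loops and
# their own code normalization so they share no logic with the package
# implementation they check.

orc_norm <- function(code) {
  # "DIALECT:value" -> c(dialect, VALUE-without-dots)
  parts <- strsplit(code, ":", fixed = TRUE)[[1]]
  c(toupper(parts[1]), toupper(gsub("\\.", "", parts[2])))
}

orc_in_set <- function(code, set_df) {
  nc <- orc_norm(code)
  for (i in seq_len(nrow(set_df))) {
    pref <- set_df$prefix[i]
    if (nc[1] == set_df$dialect[i] &&
        substr(nc[2], 1, nchar(pref)) == pref) {
      return(TRUE)
    }
  }
  FALSE
}

orc_is_ep_specific <- function(code, registry) {
  orc_in_set(code, registry$sets$epilepsy_specific) &&
    !orc_in_set(code, registry$sets$convulsion_excluded)
}

# brute-force index event: scan encounters in date order
orc_index_event <- function(patient, registry) {
  enc <- patient$encounters
  if (nrow(enc) == 0) return(NULL)
  for (i in order(enc$date)) {
    for (code in enc$codes[[i]]) {
      if (orc_in_set(code, registry$sets$seizure_like_broad)) {
        age <- as.numeric(enc$date[i] - patient$birth_date)
        if (age >= 21 * 365) return(NULL)
        return(list(index_date = enc$date[i], qualifying_code = code,
                    age_at_index_days = age))
      }
    }
  }
  NULL
}

# brute-force inclusion decision
orc_inclusion <- function(patient, registry, modality = "emr") {
  idx <- orc_index_event(patient, registry)
  if (is.null(idx)) return(list(included = FALSE, reason = "no_index"))
  infant <- idx$age_at_index_days < 365
  need <- if (infant) 7 else 365
  prior <- FALSE
  followup <- FALSE
  if (modality == "emr") {
    enc <- patient$encounters
    for (i in seq_len(nrow(enc))) {
      gap <- as.numeric(idx$index_date - enc$date[i])
      if (gap >= need) {
        if (!infant) {
          prior <- TRUE
        } else {
          seiz <- FALSE
          for (code in enc$codes[[i]]) {
            if (orc_in_set(code, registry$sets$seizure_like_broad)) seiz <- TRUE
          }
          if (!seiz) prior <- TRUE
        }
      }
      if (as.numeric(enc$date[i] - idx$index_date) >= 730) followup <- TRUE
    }
  } else {
    cov <- patient$coverage
    for (i in seq_len(nrow(cov))) {
      if (cov$start_date[i] <= idx$index_date - need &&
          cov$end_date[i] >= idx$index_date - need) prior <- TRUE
      if (cov$start_date[i] <= idx$index_date + 730 &&
          cov$end_date[i] >= idx$index_date + 730) followup <- TRUE
    }
  }
  reason <- if (prior && followup) NA_character_ else
    if (!prior) "prior_contact" else "followup"
  list(included = prior && followup, reason = reason)
}

# brute-force composite label: re-derives all seven criteria with loops
orc_label <- function(patient, idx, registry, config = outcome_config()) {
  idd <- idx$index_date
  in_win <- function(d) {
    off <- as.numeric(d - idd)
    off > config$blanking_days && off <= config$window_days
  }
  enc <- patient$encounters
  n_enc <- nrow(enc)

  pa_codes <- function(i) {
    cc <- enc$codes[[i]]
    out <- cc[enc$primary_pos[i]]
    if (!is.na(enc$admitting_pos[i])) out <- c(out, cc[enc$admitting_pos[i]])
    out
  }
  enc_any <- function(i, set) {
    for (code in enc$codes[[i]]) if (orc_in_set(code, set)) return(TRUE)
    FALSE
  }

  # dates with epilepsy-specific / seizure-related diagnoses (any position)
  ep_dates <- as.Date(character())
  sz_dates <- as.Date(character())
  for (i in seq_len(n_enc)) {
    has_ep <- FALSE; has_sz <- FALSE
    for (code in enc$codes[[i]]) {
      if (orc_is_ep_specific(code, registry)) has_ep <- TRUE
      if (orc_in_set(code, registry$sets$seizure_related)) has_sz <- TRUE
    }
    if (has_ep) ep_dates <- c(ep_dates, enc$date[i])
    if (has_sz) sz_dates <- c(sz_dates, enc$date[i])
  }

  # ASM criterion
  asm <- FALSE
  med <- patient$medications
  for (i in seq_len(nrow(med))) {
    if (!in_win(med$date[i])) next
    nm <- tolower(trimws(med$drug[i]))
    ali <- registry$asm_aliases
    hit <- match(nm, ali$alias)
    if (!is.na(hit)) nm <- ali$name[hit]
    row <- match(nm, registry$asm_lexicon$name)
    if (is.na(row)) next
    if (config$require_adjunctive_only &&
        !isTRUE(registry$asm_lexicon$adjunctive[row])) next
    if (med$date[i] %in% ep_dates) asm <- TRUE
  }

  # status epilepticus
  se <- FALSE
  for (i in seq_len(n_enc)) {
    if (!in_win(enc$date[i])) next
    if (!enc_any(i, registry$sets$status_epilepticus)) next
    pa <- pa_codes(i)
    pa_se <- FALSE; pa_ep <- FALSE
    for (code in pa) {
      if (orc_in_set(code, registry$sets$status_epilepticus)) pa_se <- TRUE
      if (orc_is_ep_specific(code, registry)) pa_ep <- TRUE
    }
    if (pa_se || pa_ep) se <- TRUE
  }

  # inpatient admissions with seizure-related code
  n_inpt <- 0
  for (i in seq_len(n_enc)) {
    if (in_win(enc$date[i]) && enc$setting[i] == "inpatient" &&
        enc_any(i, registry$sets$seizure_related)) {
      n_inpt <- n_inpt + 1
    }
  }
  inpt <- n_inpt >= config$thresholds$inpatient_min_admissions

  # utilisation: distinct days
  sz_days <- unique(sz_dates[vapply(sz_dates, in_win, TRUE)])
  all_days <- unique(enc$date[vapply(enc$date, in_win, TRUE)])
  szu <- length(sz_days) >= config$thresholds$seizure_utilisation_min_distinct_days
  allu <- length(all_days) >= config$thresholds$all_utilisation_min_distinct_days

  # diagnostics co-occurring with a seizure-related dx
  n_dx <- 0
  prc <- patient$procedures
  for (i in seq_len(nrow(prc))) {
    if (in_win(prc$date[i]) &&
        orc_in_set(prc$code[i], registry$sets$diagnostic_testing) &&
        prc$date[i] %in% sz_dates) {
      n_dx <- n_dx + 1
    }
  }
  dxc <- n_dx >= config$thresholds$diagnostics_min_count

  # epilepsy procedure + confirmation dx >= 7 days later
  proc <- FALSE
  for (i in seq_len(nrow(prc))) {
    if (!in_win(prc$date[i])) next
    if (!orc_in_set(prc$code[i], registry$sets$epilepsy_procedures)) next
    host_ok <- FALSE
    for (j in seq_len(n_enc)) {
      same <- if (!is.na(prc$encounter_id[i]) &&
                  prc$encounter_id[i] %in% enc$encounter_id) {
        enc$encounter_id[j] == prc$encounter_id[i]
      } else {
        enc$date[j] == prc$date[i]
      }
      if (!same) next
      for (code in pa_codes(j)) {
        if (orc_is_ep_specific(code, registry)) host_ok <- TRUE
      }
    }
    if (!host_ok) next
    for (d in as.numeric(ep_dates)) {
      if (d - as.numeric(prc$date[i]) >= 7) proc <- TRUE
    }
  }

  comp <- asm || se || inpt || szu || dxc || proc ||
    (config$enable_all_utilisation && allu)
  list(asm = asm, status_epilepticus = se, inpatient_seizure = inpt,
       seizure_utilisation = szu, all_utilisation = allu, diagnostics = dxc,
       procedure = proc, composite = comp)
}

# pairwise-enumeration AUROC with half credit for ties
orc_auroc <- function(labels, scores) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

orc_f1 <- function(labels, scores, threshold = 0.5) {
  y <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y)
  prec <- if (sum(pred) == 0) NA else tp / sum(pred)
  rec <- if (sum(y) == 0) NA else tp / sum(y)
  if (is.na(prec) || is.na(rec) || prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# brute-force largest-margin aggregation (ties resolve positive; ties are
# compared with a tolerance so decimal margins equal on paper stay equal)
orc_aggregate <- function(scores, threshold = 0.5) {
  margins <- abs(scores - threshold)
  winners <- which(margins >= max(margins) - 1e-9)
  cls <- any(scores[winners] >= threshold)
  list(class = cls, margin = max(margins))
}
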