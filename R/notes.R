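#' Note-chunking configuration
#'
#' Notes longer than `max_tokens` are split into overlapping windows:
#' consecutive windows share exactly `overlap_tokens` tokens, i.e. window
#' starts advance by a stride of `max_tokens - overlap_tokens`.
#'
#' @param max_tokens Maximum window length (default 4096).
#' @param overlap_tokens Overlap between consecutive windows (default 512);
#'   must be smaller than `max_tokens`.
#' @return An object of class `chunking_config`.
#' @export
chunking_config <- function(max_tokens = 4096L, overlap_tokens = 512L) {
  max_tokens <- as.integer(max_tokens)
  overlap_tokens <- as.integer(overlap_tokens)
  if (max_tokens < 1) stop("chunking_config: max_tokens must be positive")
  if (overlap_tokens < 0 || overlap_tokens >= max_tokens) {
    stop("chunking_config: need 0 <= overlap_tokens < max_tokens")
  }
  structure(list(max_tokens = max_tokens, overlap_tokens = overlap_tokens),
            class = "chunking_config")
}

#' Split a token sequence into overlapping windows
#'
#' A note of at most `max_tokens` tokens is returned whole. Longer notes are
#' windowed with starts at multiples of the stride
#' `max_tokens - overlap_tokens`; each window holds at most `max_tokens`
#' tokens, consecutive windows share exactly `overlap_tokens` tokens, the
#' last window is truncated at the end of the note, and every token is
#' covered by at least one window.
#'
#' @param tokens Nonempty character vector of tokens.
#' @param config A [chunking_config()].
#' @return List of character vectors. Attribute `starts` holds the 0-based
#'   start offsets.
#' @export
chunk_note <- function(tokens, config = chunking_config()) {
  n <- length(tokens)
  if (n == 0) stop("chunk_note: empty token list")
  mx <- config$max_tokens
  if (n <= mx) {
    out <- list(tokens)
    attr(out, "starts") <- 0L
    return(out)
  }
  stride <- mx - config$overlap_tokens
  starts <- 0L
  while (starts[length(starts)] + mx < n) {
    starts <- c(starts, starts[length(starts)] + stride)
  }
  out <- lapply(starts, function(s) tokens[(s + 1L):min(s + mx, n)])
  attr(out, "starts") <- starts
  out
}

# ---- rules-based medication extraction -----------------------------------

med_section_headers <- function() {
  # header keyword -> section tag; matched on lowercased tokens
  list(
    c("discharge", "medications", "discharge_meds"),
    c("home", "medications", "history"),
    c("current", "medications", "history"),
    c("medication", "changes", "changes"),
    c("medication", "history", "history"),
    c("medications", "", "history"),
    c("orders", "", "orders")
  )
}

negation_cues <- function() {
  c("no", "denies", "not", "without", "discontinued", "stopped", "off")
}

#' Rules-based medication extraction from note text
#'
#' Finds medication sections by header keyword rules (history, changes,
#' orders and discharge medication lists), matches ASM lexicon entries —
#' including abbreviations such as `LEV` for levetiracetam — within those
#' sections, and flags mentions inside a negation scope (a short window after
#' cues such as "no", "denies", "not taking", "discontinued"). Negated
#' mentions are excluded from downstream medication features.
#'
#' @param note One-row note table (or list) with `note_id` and `text`.
#' @param registry A [code_registry()] supplying the lexicon.
#' @param section_span Tokens a section extends past its header before
#'   falling back to `other` (default 40).
#' @param negation_window Tokens after a negation cue considered negated
#'   (default 4).
#' @return Tibble with columns `note_id`, `surface`, `name`, `class`,
#'   `negated`, `section`.
#' @export
extract_medications <- function(note, registry, section_span = 40L,
                                negation_window = 4L) {
  toks_raw <- strsplit(trimws(note$text), "\\s+")[[1]]
  toks <- tolower(gsub("[,;.]$", "", toks_raw))
  n <- length(toks)
  section <- rep("other", n)
  hdrs <- med_section_headers()
  i <- 1L
  while (i <= n) {
    matched <- NULL
    for (h in hdrs) {
      if (h[[2]] == "") {
        if (toks[i] == h[[1]]) { matched <- h; break }
      } else if (i < n && toks[i] == h[[1]] && toks[i + 1L] == h[[2]]) {
        matched <- h; break
      }
    }
    if (!is.null(matched)) {
      len <- if (matched[[2]] == "") 1L else 2L
      span <- seq(i, min(n, i + len - 1L + section_span))
      section[span] <- matched[[3]]
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  in_section <- section != "other"
  resolved <- resolve_drug(toks, registry)
  hit <- !is.na(resolved$name) & in_section
  if (!any(hit)) {
    return(tibble::tibble(note_id = character(), surface = character(),
                          name = character(), class = character(),
                          negated = logical(), section = character()))
  }
  cue_pos <- which(toks %in% negation_cues())
  idx <- which(hit)
  negated <- vapply(idx, function(j) {
    any(cue_pos < j & cue_pos >= j - negation_window)
  }, logical(1))
  tibble::tibble(note_id = rep(note$note_id, length(idx)),
                 surface = toks_raw[idx],
                 name = resolved$name[idx],
                 class = resolved$class[idx],
                 negated = negated,
                 section = section[idx])
}

# ---- note scoring --------------------------------------------------------

#' Term-frequency note scorer
#'
#' The default pluggable scorer: a multinomial term-frequency model fit on
#' the training patients' notes. Per-token log-odds are estimated with
#' Laplace smoothing; a chunk's score is the logistic transform of the class
#' prior log-odds plus the scaled mean token log-odds. Any object exposing
#' `fit(notes, labels)` and `score(tokens)` returning values in `[0, 1]` can
#' replace it — this is where a fine-tuned long-context transformer would
#' plug in.
#'
#' Three choices keep the scorer honest on data without signal. The score is
#' prior-free — the logistic transform is centred at 0.5 regardless of the
#' training prevalence — so score scales are comparable across
#' cross-validation folds. Tokens below a minimum document count are ignored
#' (very rare tokens carry mostly spurious label association). And the
#' vocabulary is significance-thresholded: only tokens whose note-level
#' presence associates with the label beyond a chi-square cut enter the
#' model, so on label-independent text the scorer degenerates to a constant
#' 0.5 instead of amplifying chance token correlations.
#'
#' @param alpha Laplace smoothing pseudo-count (default 0.5).
#' @param scale Multiplier on the mean token log-odds (default 8).
#' @param min_count Minimum total training occurrences for a token to enter
#'   the model (default 5).
#' @param min_chi2 Minimum one-degree-of-freedom chi-square statistic of
#'   note-level token presence versus the note label (default
#'   `qchisq(0.999, 1)` ~ 10.8).
#' @return A scorer object (class `note_scorer`).
#' @export
scorer_tf <- function(alpha = 0.5, scale = 8, min_count = 5,
                      min_chi2 = stats::qchisq(0.999, 1)) {
  env <- new.env(parent = emptyenv())
  env$fitted <- FALSE
  fit <- function(notes, labels) {
    stopifnot(all(notes$patient_id %in% names(labels)))
    y <- as.logical(labels[notes$patient_id])
    toks <- strsplit(tolower(notes$text), "\\s+")
    pos_tab <- table(unlist(toks[y], use.names = FALSE))
    neg_tab <- table(unlist(toks[!y], use.names = FALSE))
    vocab <- sort(union(names(pos_tab), names(neg_tab)))
    cp <- as.numeric(pos_tab[vocab]); cp[is.na(cp)] <- 0
    cn <- as.numeric(neg_tab[vocab]); cn[is.na(cn)] <- 0
    # note-level presence counts for the vocabulary significance screen
    pres_pos <- table(unlist(lapply(toks[y], unique), use.names = FALSE))
    pres_neg <- table(unlist(lapply(toks[!y], unique), use.names = FALSE))
    a <- as.numeric(pres_pos[vocab]); a[is.na(a)] <- 0
    b <- sum(y) - a
    c1 <- as.numeric(pres_neg[vocab]); c1[is.na(c1)] <- 0
    d <- sum(!y) - c1
    n <- length(y)
    den <- (a + b) * (c1 + d) * (a + c1) * (b + d)
    chi2 <- ifelse(den == 0, 0, n * (a * d - b * c1)^2 / den)
    keep <- (cp + cn) >= min_count & chi2 >= min_chi2
    vocab <- vocab[keep]; cp <- cp[keep]; cn <- cn[keep]
    lp <- log((cp + alpha) / (sum(cp) + alpha * length(vocab)))
    ln <- log((cn + alpha) / (sum(cn) + alpha * length(vocab)))
    env$logodds <- stats::setNames(lp - ln, vocab)
    env$fitted <- TRUE
    invisible(NULL)
  }
  score <- function(tokens) {
    if (!env$fitted) stop("scorer_tf: score() called before fit()")
    lo <- env$logodds[tolower(tokens)]
    lo <- lo[!is.na(lo)]
    m <- if (length(lo) == 0) 0 else mean(lo)
    stats::plogis(scale * m)
  }
  structure(list(fit = fit, score = score, name = "term_frequency"),
            class = "note_scorer")
}

#' Constant scorer (for calibration checks)
#'
#' @param value Score returned for every chunk.
#' @return A scorer object.
#' @export
scorer_constant <- function(value = 0.5) {
  structure(list(fit = function(notes, labels) invisible(NULL),
                 score = function(tokens) value,
                 name = "constant"),
            class = "note_scorer")
}

#' Score notes with a pluggable scorer
#'
#' Fits the scorer on the notes of the training patients (labels are
#' patient-level), then scores every supplied note: long notes are chunked
#' with [chunk_note()], each chunk is scored, and chunk scores are reduced to
#' the note score by the same largest-margin-from-threshold rule used for
#' patient aggregation. Training and evaluation patients must be disjoint;
#' callers evaluate only on notes of patients outside `train_ids`.
#'
#' @param notes Notes table (`note_id`, `patient_id`, `note_type`, `text`).
#' @param scorer A scorer, e.g. [scorer_tf()].
#' @param train_ids Patient ids whose notes the scorer is fit on.
#' @param labels Named logical vector of patient labels (must cover
#'   `train_ids`).
#' @param chunking A [chunking_config()].
#' @param threshold Decision threshold for the margin reduction (default 0.5).
#' @return Tibble `note_id`, `patient_id`, `note_type`, `score`.
#' @export
score_notes <- function(notes, scorer, train_ids, labels,
                        chunking = chunking_config(), threshold = 0.5) {
  stopifnot(inherits(scorer, "note_scorer"))
  train_notes <- notes[notes$patient_id %in% train_ids, , drop = FALSE]
  scorer$fit(train_notes, labels)
  if (nrow(notes) == 0) {
    return(tibble::tibble(note_id = character(), patient_id = character(),
                          note_type = character(), score = numeric()))
  }
  scores <- vapply(seq_len(nrow(notes)), function(i) {
    tokens <- strsplit(trimws(notes$text[[i]]), "\\s+")[[1]]
    chunks <- chunk_note(tokens, chunking)
    cs <- vapply(chunks, scorer$score, numeric(1))
    if (any(cs < 0 | cs > 1)) {
      stop("score_notes: scorer returned a score outside [0, 1]")
    }
    margin_reduce(cs, threshold)$score
  }, numeric(1))
  tibble::tibble(note_id = notes$note_id, patient_id = notes$patient_id,
                 note_type = notes$note_type, score = scores)
}

# shared reduction: the prediction with largest |score - threshold| wins;
# exact threshold or tied margins on opposite sides resolve positive
margin_reduce <- function(scores, threshold = 0.5) {
  margins <- abs(scores - threshold)
  best <- max(margins)
  # tolerance guards against ties lost to floating-point rounding
  cand <- which(margins >= best - 1e-9)
  pos <- cand[scores[cand] >= threshold]
  win <- if (length(pos) > 0) pos[[1]] else cand[[1]]
  list(index = win, score = scores[[win]], margin = best,
       class = scores[[win]] >= threshold)
}

#' Aggregate note predictions to the patient level
#'
#' Selects the class of the prediction with the largest margin from the
#' threshold (0.5): the most confident note in either direction decides the
#' patient. A score exactly at the threshold, or tied margins on opposite
#' sides, resolve to the positive class (clinically conservative: favours
#' flagging recurrence risk).
#'
#' @param predictions Tibble of one patient's predictions with `score` and
#'   optionally `note_id`.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `class` (logical), `margin`, `score`, `note_id`.
#' @export
aggregate_patient <- function(predictions, threshold = 0.5) {
  if (is.numeric(predictions)) {
    predictions <- tibble::tibble(score = predictions,
                                  note_id = as.character(seq_along(predictions)))
  }
  if (nrow(predictions) == 0) stop("aggregate_patient: empty prediction list")
  r <- margin_reduce(predictions$score, threshold)
  nid <- if ("note_id" %in% names(predictions))
    predictions$note_id[[r$index]] else NA_character_
  list(class = r$class, margin = r$margin, score = r$score, note_id = nid)
}

#' Aggregate a prediction table over all patients
#'
#' @param predictions Tibble with `patient_id`, `note_id`, `score`.
#' @param threshold Decision threshold.
#' @return Tibble `patient_id`, `class`, `margin`, `score`, `note_id`.
#' @export
aggregate_patients <- function(predictions, threshold = 0.5) {
  ids <- unique(predictions$patient_id)
  rows <- lapply(ids, function(pid) {
    agg <- aggregate_patient(
      predictions[predictions$patient_id == pid, , drop = FALSE], threshold)
    tibble::tibble(patient_id = pid, class = agg$class, margin = agg$margin,
                   score = agg$score, note_id = agg$note_id)
  })
  dplyr::bind_rows(rows)
}

#' Restrict notes to the prediction-eligible window
#'
#' By default only notes dated up to `blanking_days` after the patient's
#' index event feed the note classifiers, so outcome-window documentation
#' cannot leak the label into the predictors.
#'
#' @param notes Notes table.
#' @param cohort_table Output of [build_cohort()].
#' @param max_days_after_index Latest note date relative to index (default 7).
#' @return Filtered notes table.
#' @export
filter_notes_for_prediction <- function(notes, cohort_table,
                                        max_days_after_index = 7L) {
  idx <- cohort_table$index_date[match(notes$patient_id,
                                       cohort_table$patient_id)]
  keep <- !is.na(idx) &
    as.integer(notes$date - idx) <= max_days_after_index
  notes[keep, , drop = FALSE]
}
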